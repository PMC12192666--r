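# Constrained tensor factorization of a multi-view drug similarity tensor.
#
# The tensor chi stacks n_drugs x n_drugs similarity slices (structural,
# biological, target views). It is decomposed as a rank-R CP model
# chi_{ijv} ~ sum_r U_{ir} V_{jr} W_{vr}, minimizing
#   ||chi - U o V o W||_F^2 + lambda1 ||U||_{2,1} + lambda2 tr(U' L U),
# where the L2,1 row-sparsity term selects informative drugs and the
# Laplacian trace smooths drug factors along the similarity graph. The
# solver is block-coordinate descent: exact least squares for V and W, and
# an iteratively reweighted (majorize-minimize) Sylvester solve for U that
# handles the non-smooth L2,1 term plus the Laplacian quadratic.

#' Build a multi-view similarity tensor from feature matrices
#'
#' Each view contributes a cosine-similarity slice mapped to [0, 1]
#' (`(cos + 1)/2`) with unit diagonal.
#'
#' @param views Named list of numeric matrices (drugs x features), all with
#'   the same row count.
#' @return 3-axis array `n_drugs x n_drugs x n_views` with view names.
#' @export
similarity_tensor <- function(views) {
  stopifnot(is.list(views), length(views) >= 1L)
  n <- nrow(views[[1]])
  slices <- lapply(views, function(X) {
    stopifnot(nrow(X) == n)
    nrm <- sqrt(rowSums(X^2)); nrm[nrm == 0] <- 1
    Xn <- X / nrm
    S <- (Xn %*% t(Xn) + 1) / 2
    S <- (S + t(S)) / 2
    S[S < 0] <- 0; S[S > 1] <- 1
    diag(S) <- 1
    S
  })
  chi <- array(unlist(slices), dim = c(n, n, length(views)),
               dimnames = list(rownames(views[[1]]), rownames(views[[1]]),
                               names(views)))
  chi
}

#' Graph Laplacian of a similarity matrix
#'
#' `L = D - S` with `D = diag(row sums)`; rows sum to zero and `L` is
#' positive semidefinite for symmetric non-negative `S`.
#'
#' @param S Symmetric non-negative similarity matrix.
#' @return Laplacian matrix.
#' @export
build_laplacian <- function(S) {
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop("build_laplacian: S must be symmetric", call. = FALSE)
  if (any(S < 0)) stop("build_laplacian: S must be non-negative",
                       call. = FALSE)
  diag(rowSums(S), nrow(S)) - S
}

# CP reconstruction sum_r u_r o v_r o w_r as an array.
.cp_reconstruct <- function(U, V, W) {
  n <- nrow(U); m <- nrow(V); v <- nrow(W)
  out <- array(0, dim = c(n, m, v))
  for (s in seq_len(v)) out[, , s] <- U %*% (t(V) * W[s, ])
  out
}

#' Constrained factorization objective
#'
#' @param chi Similarity tensor (n x n x n_views).
#' @param U,V,W Factor matrices (n x R, n x R, n_views x R).
#' @param lambda1,lambda2 Non-negative regularization weights.
#' @param L Laplacian matrix (n x n); defaults to zero contribution when
#'   `lambda2 = 0`.
#' @return Scalar objective value.
#' @export
ctf_objective <- function(chi, U, V, W, lambda1 = 0, lambda2 = 0, L = NULL) {
  d <- dim(chi)
  if (nrow(U) != d[1] || nrow(V) != d[2] || nrow(W) != d[3] ||
      ncol(U) != ncol(V) || ncol(V) != ncol(W))
    stop_shape("ctf_objective: factor shapes inconsistent with tensor")
  rec <- .cp_reconstruct(U, V, W)
  fit <- sum((chi - rec)^2)
  l21 <- sum(sqrt(rowSums(U^2)))
  lap <- if (lambda2 > 0) {
    if (is.null(L)) stop("ctf_objective: lambda2 > 0 requires L",
                         call. = FALSE)
    sum(diag(t(U) %*% L %*% U))
  } else 0
  fit + lambda1 * l21 + lambda2 * lap
}

#' Fit the constrained tensor factorization
#'
#' Block-coordinate descent with ridge-stabilized least squares for V and W
#' and an IRLS/Sylvester step for U. After convergence the factors are put
#' in a canonical form: columns of U and V normalized to unit Euclidean
#' norm with compensating scales folded into W.
#'
#' @param chi Similarity tensor (n x n x n_views).
#' @param rank Target rank R (1 <= R <= n_drugs).
#' @param lambda1,lambda2 Regularization weights (default 0.01 each).
#' @param max_iter Maximum sweeps (default 500).
#' @param tol Convergence tolerance on the relative objective change.
#' @param seed Initialization seed (used by the `"random"` scheme and to
#'   perturb degenerate starts).
#' @param init `"svd"` (default) starts from the leading singular vectors
#'   of the mode unfoldings, which is deterministic and converges quickly
#'   on near-low-rank tensors; `"random"` draws a seeded uniform start.
#' @return List of class `ctf_fit`: `U`, `V`, `W`, `objective` trace,
#'   `iterations`, `converged`, config echo.
#' @export
ctf_fit <- function(chi, rank = 16L, lambda1 = 0.01, lambda2 = 0.01,
                    max_iter = 500L, tol = 1e-6, seed = 1L,
                    init = c("svd", "random")) {
  init <- match.arg(init)
  d <- dim(chi)
  if (length(d) != 3L) stop("ctf_fit: chi must be a 3-axis array",
                            call. = FALSE)
  n <- d[1]; nv <- d[3]
  if (rank > n) stop("ctf_fit: rank may not exceed the number of drugs",
                     call. = FALSE)
  if (lambda1 < 0 || lambda2 < 0 || tol <= 0)
    stop("ctf_fit: lambdas must be non-negative and tol positive",
         call. = FALSE)
  # Laplacian built from the mean similarity slice (only needed when the
  # smoothness penalty is active; arbitrary tensors may have negative
  # entries that are no valid similarity graph).
  L <- if (lambda2 > 0) {
    S <- apply(chi, c(1, 2), mean)
    S <- (S + t(S)) / 2
    build_laplacian(S)
  } else matrix(0, n, n)
  set.seed(split_seed(seed, 1L))
  X1 <- matrix(chi, n, n * nv)                       # mode-1 unfolding
  X2 <- matrix(aperm(chi, c(2, 1, 3)), n, n * nv)    # mode-2
  X3 <- matrix(aperm(chi, c(3, 1, 2)), nv, n * n)    # mode-3
  if (init == "svd") {
    lead <- function(M, r) {
      u <- svd(M, nu = min(r, nrow(M)), nv = 0)$u
      if (ncol(u) < r)
        u <- cbind(u, matrix(runif(nrow(M) * (r - ncol(u)), 0.1, 1),
                             nrow(M)))
      u + matrix(runif(length(u), 0, 1e-6), nrow(u))  # break exact ties
    }
    U <- lead(X1, rank); V <- lead(X2, rank); W <- lead(X3, rank)
  } else {
    U <- matrix(runif(n * rank, 0.1, 1), n, rank)
    V <- matrix(runif(n * rank, 0.1, 1), n, rank)
    W <- matrix(runif(nv * rank, 0.1, 1), nv, rank)
  }
  khatri_rao <- function(A, B) {
    # Columnwise Kronecker: rows ordered so B's index varies fastest.
    out <- matrix(0, nrow(A) * nrow(B), ncol(A))
    for (r in seq_len(ncol(A))) out[, r] <- kronecker(A[, r], B[, r])
    out
  }
  ridge <- 1e-10
  eps <- 1e-10
  obj <- ctf_objective(chi, U, V, W, lambda1, lambda2, L)
  trace <- obj
  eL <- eigen(L, symmetric = TRUE)
  for (it in seq_len(max_iter)) {
    # U step: 0.5-weighted IRLS majorizer for L2,1 + Laplacian quadratic.
    B <- khatri_rao(W, V)                            # (n*nv) x R
    BtB <- crossprod(B)
    MB <- X1 %*% B
    rn <- sqrt(rowSums(U^2) + eps^2)
    # Solve  U (BtB) + (lambda2 L + lambda1/2 D) U = MB  via eigen of the
    # symmetric left operator.
    Aop <- lambda2 * L + diag(lambda1 / (2 * rn), n)
    eA <- eigen(Aop, symmetric = TRUE)
    Mtil <- t(eA$vectors) %*% MB
    Util <- matrix(0, n, rank)
    for (i in seq_len(n))
      Util[i, ] <- solve(BtB + diag(eA$values[i] + ridge, rank), Mtil[i, ])
    U <- eA$vectors %*% Util
    # V step: plain least squares.
    B <- khatri_rao(W, U)
    V <- t(solve(crossprod(B) + diag(ridge, rank), t(X2 %*% B)))
    # W step.
    B <- khatri_rao(V, U)
    W <- t(solve(crossprod(B) + diag(ridge, rank), t(X3 %*% B)))
    obj_new <- ctf_objective(chi, U, V, W, lambda1, lambda2, L)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(1, abs(obj))) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  # Canonical form: unit-norm columns of U and V, scales folded into W.
  su <- sqrt(colSums(U^2)); su[su == 0] <- 1
  sv <- sqrt(colSums(V^2)); sv[sv == 0] <- 1
  Uc <- sweep(U, 2, su, "/"); Vc <- sweep(V, 2, sv, "/")
  Wc <- sweep(W, 2, su * sv, "*")
  structure(list(U = Uc, V = Vc, W = Wc, U_raw = U,
                 objective = trace, iterations = length(trace) - 1L,
                 converged = length(trace) - 1L < max_iter,
                 rank = rank, lambda1 = lambda1, lambda2 = lambda2),
            class = "ctf_fit")
}

#' Per-drug latent embedding from a fitted factorization
#'
#' Rows of the (canonical) drug factor matrix U.
#'
#' @param fit A `ctf_fit`.
#' @return Matrix n_drugs x R; row i is drug i's embedding.
#' @export
drug_ctf_embedding <- function(fit) {
  stopifnot(inherits(fit, "ctf_fit"))
  fit$U
}
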