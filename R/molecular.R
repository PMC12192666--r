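# Molecular graphs and descriptors from SMILES.
#
# SMILES strings are parsed with OpenBabel (via ChemmineR/ChemmineOB), which
# keeps heavy atoms in input order and leaves hydrogens implicit. Implicit
# hydrogen counts are recovered from a standard-valence model, and molecular
# weight is computed from a pinned table of IUPAC 2021 standard atomic masses
# so that descriptor values are reproducible across toolkit versions.

# IUPAC 2021 standard atomic weights, 3 decimals (conventional values).
.ATOMIC_MASSES <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  Na = 22.990, K = 39.098, Li = 6.94, Ca = 40.078, Mg = 24.305, Fe = 55.845,
  Zn = 65.38, Se = 78.971
)

# Default valences used to assign implicit hydrogens to neutral atoms.
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

# Element vocabulary for one-hot atom features; slot "other" is reserved for
# anything outside it.
.ELEMENT_VOCAB <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B", "other")

# MDL charge codes in SDF atom blocks: 0 none, 1..3 = +3..+1, 5..7 = -1..-3.
.mdl_charge <- function(code) {
  ch <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
          `5` = -1L, `6` = -2L, `7` = -3L)
  out <- ch[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

# Pre-validate a SMILES string so syntax errors can point at a token position.
.validate_smiles_tokens <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  allowed <- c(LETTERS, letters, as.character(0:9),
               "(", ")", "[", "]", "=", "#", "-", "+", "/", "\\",
               "@", "%", ".", ":", "*")
  depth <- 0L
  bracket <- FALSE
  ring <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (!ch %in% allowed)
      stop(sprintf("SMILES parse error at position %d: illegal character '%s'",
                   i, ch), call. = FALSE)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("SMILES parse error at position %d: unmatched ')'", i),
             call. = FALSE)
    }
    if (ch == "[") {
      if (bracket)
        stop(sprintf("SMILES parse error at position %d: nested '['", i),
             call. = FALSE)
      bracket <- TRUE
    }
    if (ch == "]") {
      if (!bracket)
        stop(sprintf("SMILES parse error at position %d: unmatched ']'", i),
             call. = FALSE)
      bracket <- FALSE
    }
    if (!bracket && ch %in% as.character(0:9)) {
      d <- as.integer(ch)
      if (d %in% ring) ring <- setdiff(ring, d) else ring <- c(ring, d)
    }
  }
  if (depth > 0L)
    stop(sprintf("SMILES parse error at position %d: unmatched '('",
                 nchar(smiles)), call. = FALSE)
  if (bracket)
    stop(sprintf("SMILES parse error at position %d: unclosed '['",
                 nchar(smiles)), call. = FALSE)
  if (length(ring) > 0L)
    stop(sprintf(
      "SMILES parse error at position %d: unmatched ring closure digit %d",
      max(which(chars == as.character(ring[1]))), ring[1]), call. = FALSE)
  invisible(TRUE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Atoms become nodes (heavy atoms only, in SMILES input order) and chemical
#' bonds become edges. Aromaticity is perceived by ring analysis on the
#' parsed structure; implicit hydrogen counts are assigned from standard
#' valences adjusted for formal charge.
#'
#' @param smiles Non-empty SMILES string.
#' @param id Optional molecule identifier stored on the graph.
#' @return An object of class `molecular_graph` with components
#'   `atoms` (data.frame: `element`, `aromatic`, `charge`, `n_h`),
#'   `bonds` (data.frame: `i`, `j`, `order` where aromatic-ring bonds carry
#'   their kekulized order and `aromatic = TRUE`), and `id`.
#' @examples
#' g <- parse_smiles("CC(=O)OC1=CC=CC=C1C(=O)O", id = "aspirin")
#' nrow(g$atoms)  # 13 heavy atoms
#' @export
parse_smiles <- function(smiles, id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string", call. = FALSE)
  .validate_smiles_tokens(smiles)
  sdf_text <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", smiles),
    error = function(e)
      stop(sprintf("SMILES parse error at position 1: %s",
                   conditionMessage(e)), call. = FALSE))
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L)
    stop("SMILES parse error at position 1: empty OpenBabel output",
         call. = FALSE)
  n_at <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  n_bd <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(n_at) || n_at < 1L)
    stop("SMILES parse error at position 1: no atoms parsed", call. = FALSE)
  if (is.na(n_bd) || n_bd == 0L) {
    # ChemmineR's SDF reader rejects bond-less molecules; read the V2000
    # atom lines directly (fixed-width records).
    at <- lines[4L + seq_len(n_at)]
    elements <- trimws(substr(at, 32, 34))
    charge <- .mdl_charge(as.integer(trimws(substr(at, 37, 39))))
    mol <- NULL
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        aromatic = logical(0))
  } else {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smiles)),
      error = function(e)
        stop(sprintf("SMILES parse error at position 1: %s",
                     conditionMessage(e)), call. = FALSE))
    mol <- sdf[[1]]
    ab <- ChemmineR::atomblock(mol)
    elements <- sub("_.*$", "", rownames(ab))
    charge <- .mdl_charge(ab[, "C5"])
    bb <- ChemmineR::bondblock(mol)
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]), aromatic = FALSE)
  }
  # Aromatic perception: ChemmineR ring analysis flags aromatic rings.
  aromatic <- rep(FALSE, length(elements))
  if (!is.null(mol) && nrow(bonds) > 0L) {
    rg <- tryCatch(ChemmineR::rings(mol, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rg) && length(rg$RINGS) > 0L) {
      for (k in seq_along(rg$RINGS)) {
        if (isTRUE(rg$AROMATIC[[k]])) {
          idx <- as.integer(sub("^.*_", "", rg$RINGS[[k]]))
          aromatic[idx] <- TRUE
          inring <- bonds$i %in% idx & bonds$j %in% idx
          bonds$aromatic[inring] <- TRUE
        }
      }
    }
  }
  # Implicit hydrogens from standard valence minus bond order sum, adjusted
  # by formal charge sign (N+ gains a slot, O- loses one).
  bsum <- rep(0, length(elements))
  if (nrow(bonds) > 0L) {
    for (r in seq_len(nrow(bonds))) {
      o <- bonds$order[r]
      bsum[bonds$i[r]] <- bsum[bonds$i[r]] + o
      bsum[bonds$j[r]] <- bsum[bonds$j[r]] + o
    }
  }
  val <- .DEFAULT_VALENCE[elements]
  val[is.na(val)] <- 0
  n_h <- pmax(0, val + charge - bsum)
  atoms <- data.frame(element = elements, aromatic = aromatic,
                      charge = charge, n_h = as.integer(round(n_h)),
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, bonds = bonds, id = id %||% smiles,
                 smiles = smiles),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph %s: %d heavy atoms, %d bonds>\n",
              x$id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Molecular descriptors of a parsed graph
#'
#' Molecular weight sums pinned standard atomic masses over heavy atoms plus
#' 1.008 per hydrogen (implicit hydrogens included), reported to 2 decimals.
#' Hydrogen-bond donors/acceptors use Lipinski-style definitions: donors are
#' N/O atoms carrying at least one hydrogen, acceptors are all N/O atoms.
#'
#' @param g A `molecular_graph` from [parse_smiles()].
#' @return List with `mol_weight` (g/mol), `heavy_atom_count`, `bond_count`,
#'   `hbd`, `hba`.
#' @examples
#' descriptors(parse_smiles("CC(=O)OC1=CC=CC=C1C(=O)O"))$mol_weight  # 180.16
#' @export
descriptors <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  el <- g$atoms$element
  mass <- .ATOMIC_MASSES[el]
  if (anyNA(mass))
    stop(sprintf("no pinned atomic mass for element(s): %s",
                 paste(unique(el[is.na(mass)]), collapse = ", ")),
         call. = FALSE)
  mw <- sum(mass) + 1.008 * sum(g$atoms$n_h)
  no <- el %in% c("N", "O")
  list(mol_weight = round(mw, 2),
       heavy_atom_count = nrow(g$atoms),
       bond_count = nrow(g$bonds),
       hbd = sum(no & g$atoms$n_h > 0L),
       hba = sum(no))
}

#' Node feature matrix for a molecular graph
#'
#' One row per heavy atom: one-hot element over the documented vocabulary
#' (C, N, O, S, F, Cl, Br, I, P, B, other), heavy-atom degree, aromatic flag,
#' and formal charge. Unknown elements map to the reserved `other` slot.
#'
#' @param g A `molecular_graph`.
#' @return Numeric matrix, `heavy_atom_count` rows, `length(vocab) + 3`
#'   columns.
#' @export
atom_features <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  n <- nrow(g$atoms)
  voc <- .ELEMENT_VOCAB
  feat <- matrix(0, nrow = n, ncol = length(voc) + 3L,
                 dimnames = list(NULL, c(voc, "degree", "aromatic", "charge")))
  slot <- match(g$atoms$element, voc)
  slot[is.na(slot)] <- length(voc)
  feat[cbind(seq_len(n), slot)] <- 1
  deg <- rep(0, n)
  if (nrow(g$bonds) > 0L) {
    tab <- table(factor(c(g$bonds$i, g$bonds$j), levels = seq_len(n)))
    deg <- as.numeric(tab)
  }
  feat[, "degree"] <- deg
  feat[, "aromatic"] <- as.numeric(g$atoms$aromatic)
  feat[, "charge"] <- g$atoms$charge
  feat
}

#' Compute descriptors for a table of molecules
#'
#' @param molecules Data frame with columns `id` and `smiles` (as produced by
#'   [gen_molecules()] or [read_molecules_tsv()]).
#' @return Data frame `id, mol_weight, heavy_atoms, bonds, hbd, hba`.
#' @export
descriptor_table <- function(molecules) {
  rows <- lapply(seq_len(nrow(molecules)), function(i) {
    d <- descriptors(parse_smiles(molecules$smiles[i], id = molecules$id[i]))
    data.frame(id = molecules$id[i], mol_weight = d$mol_weight,
               heavy_atoms = d$heavy_atom_count, bonds = d$bond_count,
               hbd = d$hbd, hba = d$hba, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read molecules from a two-column TSV (`id<TAB>smiles`)
#' @param path File path.
#' @return Data frame with columns `id`, `smiles`.
#' @export
read_molecules_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", "smiles")
  df
}

#' Write molecules to a two-column TSV
#' @param molecules Data frame with `id`, `smiles`.
#' @param path Output path.
#' @export
write_molecules_tsv <- function(molecules, path) {
  utils::write.table(molecules[, c("id", "smiles")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
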