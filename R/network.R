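# Typed drug-target-enzyme-transporter-AE attribute network for mechanistic
# interpretation of interaction signals.

# Edge-type vocabulary and the node types at each endpoint.
.EDGE_TYPES <- list(
  drug_target = c("drug", "target"),
  drug_enzyme = c("drug", "enzyme"),
  drug_transporter = c("drug", "transporter"),
  ppi = c("target", "target"),
  target_ae = c("target", "ae"),
  enzyme_ae = c("enzyme", "ae"),
  transporter_ae = c("transporter", "ae"))

#' Build the attribute network from typed edge lists
#'
#' Protein-protein (`ppi`) edges carry raw STRING-style confidences in
#' [0, 1000]; edges at or below `ppi_min_conf` are dropped (the filter is
#' strict: "above 700" keeps only confidence > 700) and survivors are
#' rescaled to [0, 1] by division by 1000. All other edge weights are
#' clipped to [0, 1]. Node types are derived from the edge-type vocabulary.
#'
#' @param edges Data frame `src`, `dst`, `type`, `weight` (the
#'   [gen_bio_network()] dialect).
#' @param ppi_min_conf PPI confidence threshold (default 700).
#' @return List of class `attribute_network`: an igraph `graph` with vertex
#'   attribute `node_type` and edge attributes `weight` (in [0, 1]),
#'   `edge_type`, `raw_conf`; plus the filtered `edges` table.
#' @export
build_network <- function(edges, ppi_min_conf = 700) {
  stopifnot(all(c("src", "dst", "type", "weight") %in% names(edges)))
  bad <- setdiff(unique(edges$type), names(.EDGE_TYPES))
  if (length(bad) > 0L)
    stop(sprintf("build_network: unknown edge/node type(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (any(edges$src == edges$dst))
    stop("build_network: self-edges are not allowed", call. = FALSE)
  is_ppi <- edges$type == "ppi"
  keep <- !is_ppi | edges$weight > ppi_min_conf
  edges <- edges[keep, , drop = FALSE]
  raw <- edges$weight
  w <- ifelse(edges$type == "ppi", edges$weight / 1000,
              pmin(pmax(edges$weight, 0), 1))
  node_type <- character(0)
  for (r in seq_len(nrow(edges))) {
    tp <- .EDGE_TYPES[[edges$type[r]]]
    node_type[edges$src[r]] <- tp[1]
    node_type[edges$dst[r]] <- tp[2]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$src, to = edges$dst, weight = w,
               edge_type = edges$type, raw_conf = raw,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = names(node_type),
                          node_type = unname(node_type),
                          stringsAsFactors = FALSE))
  structure(list(graph = g, edges = cbind(edges, norm_weight = w)),
            class = "attribute_network")
}

#' @export
print.attribute_network <- function(x, ...) {
  cat(sprintf("<attribute_network: %d nodes, %d edges>\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Shortest mechanistic path from a drug to an adverse event
#'
#' Edge cost is `1 - weight + eps` (eps = 1e-6), so strong interactions are
#' cheap to traverse while every hop still carries a positive cost and
#' minimal-cost paths stay short. Ties are broken deterministically by the
#' lexicographically smallest node-id sequence.
#'
#' @param net An `attribute_network`.
#' @param drug,ae Node identifiers (both must exist in the network).
#' @param eps Per-edge cost floor.
#' @return List `path` (node ids), `cost`, `found`; `found = FALSE` with an
#'   empty path when the AE is unreachable.
#' @export
shortest_path <- function(net, drug, ae, eps = 1e-6) {
  stopifnot(inherits(net, "attribute_network"))
  g <- net$graph
  nm <- igraph::V(g)$name
  if (!drug %in% nm || !ae %in% nm)
    stop(sprintf("shortest_path: node '%s' not in network",
                 setdiff(c(drug, ae), nm)[1]), call. = FALSE)
  cost <- 1 - igraph::E(g)$weight + eps
  d <- igraph::distances(g, v = drug, to = ae, weights = cost)[1, 1]
  if (!is.finite(d))
    return(list(path = character(0), cost = Inf, found = FALSE))
  paths <- igraph::all_shortest_paths(g, from = drug, to = ae,
                                      weights = cost)$vpaths
  seqs <- vapply(paths, function(p) paste(nm[as.integer(p)], collapse = ">"),
                 character(1))
  best <- paths[[order(seqs)[1]]]
  list(path = nm[as.integer(best)], cost = d, found = TRUE)
}

#' Rank shared metabolic mechanisms of a drug pair
#'
#' Enzyme and transporter nodes adjacent to both drugs, scored by the
#' product of the two incident edge weights and sorted descending (ties by
#' node id).
#'
#' @param net An `attribute_network`.
#' @param drugA,drugB Drug node identifiers.
#' @return Data frame `node`, `node_type`, `score` (possibly empty).
#' @export
rank_mechanisms <- function(net, drugA, drugB) {
  stopifnot(inherits(net, "attribute_network"))
  g <- net$graph
  nm <- igraph::V(g)$name
  for (d in c(drugA, drugB))
    if (!d %in% nm)
      stop(sprintf("rank_mechanisms: drug '%s' not in network", d),
           call. = FALSE)
  wts <- function(drug) {
    inc <- igraph::incident(g, drug)
    ends <- igraph::ends(g, inc)
    other <- ifelse(ends[, 1] == drug, ends[, 2], ends[, 1])
    stats::setNames(igraph::E(g)$weight[as.integer(inc)], other)
  }
  wA <- wts(drugA); wB <- wts(drugB)
  shared <- intersect(names(wA), names(wB))
  types <- stats::setNames(igraph::V(g)$node_type, nm)
  shared <- shared[types[shared] %in% c("enzyme", "transporter")]
  if (length(shared) == 0L)
    return(data.frame(node = character(0), node_type = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  out <- data.frame(node = shared, node_type = unname(types[shared]),
                    score = unname(wA[shared] * wB[shared]),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$node), , drop = FALSE]
}
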