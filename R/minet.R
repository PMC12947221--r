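#' Trajectory-averaged C-alpha distance matrix
#'
#' Per-frame pairwise C-alpha distances reduced over the pooled frames of
#' the ensemble (`mean` by default; `min` selects the closest approach).
#' Residues without a C-alpha are flagged and excluded.
#'
#' @param ensemble a `Trajectory` or list of replicates.
#' @param sel optional `Selection` of one atom per residue (default: all
#'   `CA` atoms).
#' @param reduce `"mean"` or `"min"` over frames.
#' @return An object of class `DistanceMatrix`: list with `matrix`
#'   (Angstrom, symmetric, zero diagonal), `residues`, `reduce`,
#'   `n_frames`, `excluded` (residues lacking a C-alpha).
#' @export
distance_matrix <- function(ensemble, sel = NULL, reduce = c("mean", "min")) {
  reduce <- match.arg(reduce)
  trajs <- .as_ensemble(ensemble)
  .check_same_atoms(trajs)
  tr1 <- trajs[[1L]]
  excluded <- data.frame()
  if (is.null(sel)) {
    sel <- select_atoms(tr1, name = "CA")
    all_res <- residue_table(tr1)
    with_ca <- unique(tr1$atoms[sel$indices, c("chain", "res_id")])
    miss <- !paste(all_res$chain, all_res$res_id) %in%
      paste(with_ca$chain, with_ca$res_id)
    excluded <- all_res[miss, , drop = FALSE]
    if (nrow(excluded) > 0L)
      warning("residue(s) without C-alpha excluded from the network: ",
              paste0(excluded$chain, excluded$res_id, collapse = ", "))
  }
  idx <- .sel_idx(tr1, sel)
  acc <- NULL
  total <- 0L
  for (tr in trajs) {
    for (t in seq_len(n_frames(tr))) {
      dm <- as.matrix(stats::dist(frame_coords(tr, t)[idx, , drop = FALSE]))
      if (is.null(acc)) acc <- if (reduce == "mean") dm * 0 else dm
      acc <- if (reduce == "mean") acc + dm else pmin(acc, dm)
      total <- total + 1L
    }
  }
  m <- if (reduce == "mean") acc / total else acc
  at <- tr1$atoms[idx, , drop = FALSE]
  residues <- data.frame(chain = at$chain, res_id = at$res_id,
                         res_name = at$res_name, stringsAsFactors = FALSE)
  lab <- paste0(residues$chain, residues$res_id)
  dimnames(m) <- list(lab, lab)
  structure(list(matrix = m, residues = residues, reduce = reduce,
                 n_frames = total, excluded = excluded),
            class = "DistanceMatrix")
}

#' Network construction parameters
#'
#' @param mi_threshold minimum MI for an edge (bits, default 0.25).
#' @param dist_cutoff spatial cutoff tau in Angstrom (default 6.0, the
#'   contact-map cutoff): only pairs at or beyond it — distant pairs
#'   without contact — are connected.
#' @param min_sep minimum sequence separation (default 6).
#' @return list of class `NetworkConfig`.
#' @export
network_config <- function(mi_threshold = 0.25, dist_cutoff = 6.0,
                           min_sep = 6L) {
  if (mi_threshold < 0) stop("mi_threshold must be >= 0")
  if (dist_cutoff <= 0) stop("dist_cutoff must be > 0")
  if (min_sep < 0) stop("min_sep must be >= 0")
  structure(list(mi_threshold = mi_threshold, dist_cutoff = dist_cutoff,
                 min_sep = as.integer(min_sep)),
            class = "NetworkConfig")
}

#' Build the MI-thresholded long-range residue network
#'
#' An undirected edge joins residues i, j iff all three hold: sequence
#' separation `|i - j| > min_sep`, trajectory-averaged distance
#' `D_ij >= dist_cutoff` (spatially distant, non-contacting pairs), and
#' `MI_ij >= mi_threshold`.  Edge weights are MI normalized by the
#' maximum MI over included edges, so the strongest edge has weight 1.
#'
#' @param mi an `MIMatrix`.
#' @param dist a `DistanceMatrix` on the same residues.
#' @param cfg a [network_config()].
#' @return An object of class `ResidueGraph`: list with `graph` (igraph,
#'   all residues as vertices), `edges` (data.frame: res_i, res_j, mi,
#'   weight), `residues`, `cfg`.
#' @export
build_graph <- function(mi, dist, cfg = network_config()) {
  if (!all(dim(mi$matrix) == dim(dist$matrix)))
    stop("MI and distance matrices cover different residue sets")
  res <- mi$residues
  n <- nrow(res)
  sep <- abs(outer(res$res_id, res$res_id, "-"))
  keep <- sep > cfg$min_sep &
    dist$matrix >= cfg$dist_cutoff &
    !is.na(mi$matrix) & mi$matrix >= cfg$mi_threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  lab <- paste0(res$chain, res$res_id)
  if (nrow(idx) == 0L) {
    warning("empty edge set: no residue pair satisfies all conditions")
    edges <- data.frame(res_i = character(), res_j = character(),
                        mi = numeric(), weight = numeric(),
                        stringsAsFactors = FALSE)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(g)$name <- lab
  } else {
    mi_vals <- mi$matrix[idx]
    edges <- data.frame(res_i = lab[idx[, 1L]], res_j = lab[idx[, 2L]],
                        mi = mi_vals, weight = mi_vals / max(mi_vals),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = lab, stringsAsFactors = FALSE))
  }
  structure(list(graph = g, edges = edges, residues = res, cfg = cfg),
            class = "ResidueGraph")
}

#' @export
print.ResidueGraph <- function(x, ...) {
  cat("ResidueGraph:", nrow(x$residues), "residues,", nrow(x$edges),
      "edges",
      sprintf("(MI >= %.2f, D >= %.1f A, |i-j| > %d)\n",
              x$cfg$mi_threshold, x$cfg$dist_cutoff, x$cfg$min_sep))
  invisible(x)
}

#' Degree centrality of the residue network
#'
#' `C_D(i) = deg(i) / (N - 1)` with `N` the number of residues (isolated
#' residues included); 0 when `N <= 1`.
#'
#' @param rg a `ResidueGraph`.
#' @return data.frame with `residue`, `degree`, `degree_centrality`.
#' @export
degree_centrality <- function(rg) {
  n <- nrow(rg$residues)
  deg <- igraph::degree(rg$graph)
  cd <- if (n <= 1L) rep(0, n) else deg / (n - 1)
  data.frame(residue = igraph::V(rg$graph)$name, degree = as.integer(deg),
             degree_centrality = as.numeric(cd),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Betweenness centrality of the residue network
#'
#' `C_B(i) = sum_{s != i != t} sigma_st(i) / sigma_st` over unordered
#' pairs within each connected component, on unweighted (hop-count)
#' shortest paths, unnormalized.  Set `weighted = TRUE` to use `1/w` as
#' edge length instead.
#'
#' @param rg a `ResidueGraph`.
#' @param weighted use inverse edge weights as path lengths.
#' @return data.frame with `residue`, `betweenness`.
#' @export
betweenness_centrality <- function(rg, weighted = FALSE) {
  w <- if (weighted && nrow(rg$edges) > 0L) 1 / rg$edges$weight else NA
  b <- igraph::betweenness(rg$graph, directed = FALSE, weights = w)
  data.frame(residue = igraph::V(rg$graph)$name,
             betweenness = as.numeric(b),
             stringsAsFactors = FALSE, row.names = NULL)
}
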