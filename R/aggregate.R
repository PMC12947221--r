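#' Aggregate a residue-pair MI matrix
#'
#' Summaries of an [mi_matrix_calpha()] / [mi_matrix_dihedral()] result
#' over distant residue pairs (sequence separation greater than the
#' matrix's `min_sep`):
#' \describe{
#'   \item{`residue_mean`}{per-residue mean MI over distant partners
#'     (the <MI> profile).}
#'   \item{`delta`}{per-residue difference of <MI> against a reference
#'     matrix (condition minus reference).}
#'   \item{`by_type`}{mean MI of distant pairs involving each residue
#'     type.}
#'   \item{`type_pair`}{residue-type-pair mean MI matrix (the type-level
#'     network).}
#'   \item{`by_nchi`}{mean MI by the residue's rotatable-bond (chi)
#'     count.}
#'   \item{`by_class`}{mean MI of pairs involving each chemical class.}
#'   \item{`class_pair`}{chemical-class-pair mean MI matrix.}
#' }
#'
#' @param mim an `MIMatrix`.
#' @param scheme one of the schemes above.
#' @param class_table a [residue_class_table()] (or extension) covering
#'   every residue type in the matrix; needed by the type/class/nchi
#'   schemes.
#' @param ref reference `MIMatrix` for `scheme = "delta"`.
#' @param min_sep override of the matrix's sequence-separation default.
#' @return a data.frame (or matrix for the `*_pair` schemes).
#' @export
aggregate_mi <- function(mim, scheme = c("residue_mean", "delta", "by_type",
                                         "type_pair", "by_nchi", "by_class",
                                         "class_pair"),
                         class_table = residue_class_table(), ref = NULL,
                         min_sep = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(min_sep)) min_sep <- mim$min_sep
  m <- mim$matrix
  res <- mim$residues
  n <- nrow(m)
  sep_ok <- abs(outer(res$res_id, res$res_id, "-")) > min_sep
  diag(sep_ok) <- FALSE
  mm <- m
  mm[!sep_ok] <- NA_real_

  if (scheme == "residue_mean" || scheme == "delta") {
    mean_mi <- vapply(seq_len(n), function(i) {
      v <- mm[i, ]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    out <- data.frame(res[, c("chain", "res_id", "res_name")],
                      mean_mi = mean_mi, stringsAsFactors = FALSE)
    if (scheme == "delta") {
      if (is.null(ref)) stop("scheme 'delta' needs a reference matrix")
      ref_mean <- aggregate_mi(ref, "residue_mean", min_sep = min_sep)
      if (!all(ref_mean$res_id == out$res_id))
        stop("table error: reference matrix covers different residues")
      out$delta_mi <- out$mean_mi - ref_mean$mean_mi
    }
    return(out)
  }

  type_of <- function(col) {
    mt <- match(res$res_name, class_table$res_name)
    if (anyNA(mt))
      stop("table error: residue type(s) missing from class table: ",
           paste(unique(res$res_name[is.na(mt)]), collapse = ", "))
    class_table[[col]][mt]
  }
  pair_vals <- function(group) {
    ## mean MI of distant pairs, keyed by the groups of the two residues
    idx <- which(sep_ok & upper.tri(sep_ok) & !is.na(m), arr.ind = TRUE)
    data.frame(g1 = group[idx[, 1L]], g2 = group[idx[, 2L]],
               mi = m[idx], stringsAsFactors = FALSE)
  }

  if (scheme == "by_type" || scheme == "by_class" || scheme == "by_nchi") {
    group <- switch(scheme, by_type = type_of("res_name"),
                    by_class = type_of("class"),
                    by_nchi = type_of("n_chi"))
    pv <- pair_vals(group)
    levels_all <- sort(unique(group))
    vals <- vapply(levels_all, function(g) {
      v <- pv$mi[pv$g1 == g | pv$g2 == g]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    out <- data.frame(group = levels_all, mean_mi = vals,
                      stringsAsFactors = FALSE)
    names(out)[1L] <- switch(scheme, by_type = "res_name",
                             by_class = "class", by_nchi = "n_chi")
    return(out)
  }

  ## type_pair / class_pair: symmetric group-pair mean matrix
  group <- if (scheme == "type_pair") type_of("res_name") else
    type_of("class")
  pv <- pair_vals(group)
  levels_all <- sort(unique(group))
  k <- length(levels_all)
  out <- matrix(NA_real_, k, k, dimnames = list(levels_all, levels_all))
  for (a in seq_len(k)) for (b in a:k) {
    v <- pv$mi[(pv$g1 == levels_all[a] & pv$g2 == levels_all[b]) |
               (pv$g1 == levels_all[b] & pv$g2 == levels_all[a])]
    if (length(v)) out[a, b] <- out[b, a] <- mean(v)
  }
  out
}
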