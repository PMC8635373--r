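#' Structure-function coupling of one subject in one subnetwork
#'
#' The SC-FC coupling is the Spearman rank correlation between the
#' log-transformed structural edge weights (fiber counts) and the
#' functional connectivity values over the same region pairs. Both
#' matrices are restricted to the subnetwork, their strict upper triangles
#' are vectorized, and region pairs without a structural connection
#' (zero fibers) are dropped before the log transform (the default;
#' `zero_mode = "log1p"` instead keeps all pairs and uses `log(1 + SC)`).
#' Ties receive average ranks. Because Spearman correlation is invariant
#' to strictly monotone transforms, it makes no difference whether FC
#' enters as raw correlations or Fisher-z values.
#'
#' A coupling estimated from fewer than 3 edge pairs is reported as
#' undefined (`rho = NA`), never silently zero.
#'
#' @param sc,fc SC and FC `connectivity_matrix` objects sharing node labels.
#' @param regions Subnetwork region labels or a subnetwork name
#'   (see [extract_subnetwork()]).
#' @param zero_mode `"exclude"` (drop SC == 0 pairs, correlate `log(SC)`
#'   with FC) or `"log1p"` (keep all pairs, correlate `log(1 + SC)` with FC).
#' @return List with `rho` (Spearman correlation, or `NA` if undefined)
#'   and `n_edges` (number of edge pairs used).
#' @export
sc_fc_coupling <- function(sc, fc, regions = "whole_brain",
                           zero_mode = c("exclude", "log1p")) {
  zero_mode <- match.arg(zero_mode)
  if (!identical(rownames(sc), rownames(fc))) {
    stop("SC and FC matrices must share node labels")
  }
  s <- extract_subnetwork(sc, regions)
  f <- extract_subnetwork(fc, regions)
  ut <- upper.tri(s)
  sv <- unclass(s)[ut]
  fv <- unclass(f)[ut]
  if (zero_mode == "exclude") {
    keep <- sv > 0
    sv <- log(sv[keep])
    fv <- fv[keep]
  } else {
    sv <- log1p(sv)
  }
  n_edges <- length(sv)
  if (n_edges < 3) return(list(rho = NA_real_, n_edges = n_edges))
  if (stats::sd(sv) == 0 || stats::sd(fv) == 0) {
    return(list(rho = NA_real_, n_edges = n_edges))
  }
  list(rho = stats::cor(sv, fv, method = "spearman"), n_edges = n_edges)
}

#' Per-subject coupling profile across subnetworks
#'
#' Computes [sc_fc_coupling()] for every subject of a cohort in each
#' subnetwork (DMN, ECN, SAN, whole brain by default).
#'
#' @param cohort A cohort as returned by [generate_cohort()] or
#'   [read_cohort()]: list with `subjects` (data frame) and `matrices`
#'   (per-subject list with `sc` and `fc`).
#' @param subnetworks Named list of region-label vectors; defaults to
#'   [subnetwork_definitions()].
#' @inheritParams sc_fc_coupling
#' @return Data frame with one row per subject x subnetwork:
#'   `subject_id`, `subnetwork`, `rho`, `n_edges`.
#' @export
coupling_profile <- function(cohort, subnetworks = subnetwork_definitions(),
                             zero_mode = c("exclude", "log1p")) {
  zero_mode <- match.arg(zero_mode)
  ids <- cohort$subjects$subject_id
  rows <- lapply(ids, function(id) {
    m <- cohort$matrices[[id]]
    per_net <- lapply(names(subnetworks), function(nm) {
      cp <- sc_fc_coupling(m$sc, m$fc, subnetworks[[nm]], zero_mode)
      data.frame(subject_id = id, subnetwork = nm,
                 rho = cp$rho, n_edges = cp$n_edges,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_net)
  })
  do.call(rbind, rows)
}
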