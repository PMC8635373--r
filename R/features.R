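FEATURE_MEASURES <- c("Eglob_SC", "Eglob_FC", "coupling")

#' Feature table container
#'
#' Holds the subject-level network features the group analysis runs on: a
#' numeric matrix with one row per feature (measure x subnetwork, e.g.
#' `Eglob_SC.DMN`) and one column per subject, aligned with a subject
#' data frame carrying group, site, and covariates.
#'
#' @param values Numeric matrix, features x subjects.
#' @param subjects Data frame with at least `subject_id`; columns `group`,
#'   `site`, `age`, `sex` are used downstream. Row order must match the
#'   matrix columns.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, subjects) {
  stopifnot(is.matrix(values), ncol(values) == nrow(subjects))
  colnames(values) <- subjects$subject_id
  structure(list(values = values, subjects = subjects),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d subjects\n",
              nrow(x$values), ncol(x$values)))
  cat("  features:", paste(utils::head(rownames(x$values), 6), collapse = ", "),
      if (nrow(x$values) > 6) "..." else "", "\n")
  invisible(x)
}

#' Extract subject-level network features for a cohort
#'
#' For every subject and subnetwork, computes the binary global
#' efficiency of the thresholded structural network (edges with at least
#' one fiber), the binary global efficiency of the FDR-thresholded
#' positive functional network, and the SC-FC coupling. Matrices are
#' thresholded at the whole-brain level first, then restricted to each
#' subnetwork (thresholding and extraction commute, but FDR correction is
#' applied over the full matrix's edge family).
#'
#' @param cohort Cohort list (`subjects` + `matrices`), from
#'   [generate_cohort()] or [read_cohort()].
#' @param subnetworks Named list of region-label vectors; defaults to the
#'   shipped DMN/ECN/SAN plus `whole_brain`.
#' @param t_points Time-series length behind the FC Fisher-z values (used
#'   by the FDR thresholding).
#' @param q FDR level for functional thresholding.
#' @param zero_mode Zero-fiber handling for coupling, see
#'   [sc_fc_coupling()].
#' @param verbose Print progress every 50 subjects.
#' @return A [feature_table()] with rows
#'   `{Eglob_SC, Eglob_FC, coupling} x subnetworks`.
#' @export
build_feature_table <- function(cohort, subnetworks = subnetwork_definitions(),
                                t_points = 200, q = 0.05,
                                zero_mode = c("exclude", "log1p"),
                                verbose = FALSE) {
  zero_mode <- match.arg(zero_mode)
  subjects <- cohort$subjects
  ids <- subjects$subject_id
  missing <- ids[!ids %in% names(cohort$matrices)]
  if (length(missing) > 0) {
    stop("no matrices for subjects: ", paste(missing, collapse = ", "))
  }
  feat_names <- as.vector(outer(FEATURE_MEASURES, names(subnetworks),
                                paste, sep = "."))
  values <- matrix(NA_real_, length(feat_names), length(ids),
                   dimnames = list(feat_names, ids))
  for (j in seq_along(ids)) {
    m <- cohort$matrices[[ids[j]]]
    g_sc <- threshold_structural(m$sc)
    g_fc <- threshold_functional(m$fc, t_points = t_points, q = q)
    for (nm in names(subnetworks)) {
      reg <- subnetworks[[nm]]
      values[paste0("Eglob_SC.", nm), j] <-
        global_efficiency(extract_subnetwork(g_sc, reg))
      values[paste0("Eglob_FC.", nm), j] <-
        global_efficiency(extract_subnetwork(g_fc, reg))
      values[paste0("coupling.", nm), j] <-
        sc_fc_coupling(m$sc, m$fc, reg, zero_mode)$rho
    }
    if (verbose && j %% 50 == 0) {
      message(sprintf("features: %d / %d subjects", j, length(ids)))
    }
  }
  feature_table(values, subjects)
}

#' Inject site (batch) effects into a feature table
#'
#' Applies the location/scale acquisition-site model the harmonization
#' stage is meant to undo: each feature value of a subject at site `s`
#' becomes `site_scale[s] * value + site_shift[s]`. The input table is
#' left untouched.
#'
#' @param features A [feature_table()].
#' @param site_shift,site_scale Named numeric vectors keyed by site label.
#' @param site Site labels per subject; defaults to the table's `site`
#'   column.
#' @return A new [feature_table()] with shifted values.
#' @export
inject_site_effects <- function(features, site_shift, site_scale,
                                site = features$subjects$site) {
  site <- as.character(site)
  if (length(unique(site)) < 2) stop("need two or more sites")
  unknown <- setdiff(unique(site), names(site_shift))
  unknown <- union(unknown, setdiff(unique(site), names(site_scale)))
  if (length(unknown) > 0) {
    stop("unknown site label(s): ", paste(unknown, collapse = ", "))
  }
  values <- sweep(features$values, 2, site_scale[site], `*`)
  values <- sweep(values, 2, site_shift[site], `+`)
  feature_table(values, features$subjects)
}

#' Write / read a feature table as CSV
#'
#' The CSV holds features as rows and subjects as columns; the subject
#' metadata (group, site, age, sex, scores) goes to a companion
#' `<path>_subjects.csv`, keeping both files plain rectangular CSV.
#'
#' @param features A [feature_table()].
#' @param path CSV path for the feature matrix.
#' @return `write_feature_table`: `path`, invisibly; `read_feature_table`:
#'   a [feature_table()].
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(as.data.frame(features$values), path, row.names = TRUE)
  utils::write.csv(features$subjects,
                   sub("\\.csv$", "_subjects.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  values <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  subjects <- utils::read.csv(sub("\\.csv$", "_subjects.csv", path),
                              stringsAsFactors = FALSE,
                              colClasses = c(site = "character"))
  feature_table(values, subjects)
}
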