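#' Pipeline configuration
#'
#' Collects everything an end-to-end run needs: the output directory, the
#' FC thresholding parameters, coupling zero handling, harmonization and
#' post-hoc options, the random seed, and (for simulated runs) the cohort
#' generator configuration.
#'
#' @param out_dir Output directory for all pipeline artifacts.
#' @param cohort_dir Directory holding an existing cohort
#'   (`manifest.csv` + matrices); defaults to `<out_dir>/cohort`, which
#'   [run_simulate()] populates.
#' @param t_points Time-series length behind the FC Fisher-z values.
#' @param fdr_q FDR level for functional thresholding and edgewise
#'   contrasts, in (0, 1).
#' @param zero_mode Coupling zero-fiber handling (see [sc_fc_coupling()]).
#' @param posthoc Post-hoc method for the group report (see
#'   [pairwise_posthoc()]).
#' @param include_group Keep diagnostic group as a protected ComBat
#'   covariate.
#' @param inject_site_effects Apply the generator's site location/scale
#'   effects to the extracted features before harmonization (simulated
#'   cohorts only; features computed from simulated matrices carry no
#'   acquisition effect of their own).
#' @param seed Random seed for the whole run.
#' @param cohort A [cohort_config()] used by [run_simulate()]; its seed is
#'   overridden by `seed`.
#' @param subnetwork_file Optional JSON subnetwork definition override
#'   (see [subnetwork_definitions()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            cohort_dir = file.path(out_dir, "cohort"),
                            t_points = 200, fdr_q = 0.05,
                            zero_mode = c("exclude", "log1p"),
                            posthoc = c("tukey", "welch_t", "bonferroni"),
                            include_group = TRUE,
                            inject_site_effects = TRUE,
                            seed = 1L,
                            cohort = cohort_config(seed = seed),
                            subnetwork_file = NULL) {
  stopifnot(fdr_q > 0, fdr_q < 1)
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir,
                 t_points = t_points, fdr_q = fdr_q,
                 zero_mode = match.arg(zero_mode),
                 posthoc = match.arg(posthoc),
                 include_group = include_group,
                 inject_site_effects = inject_site_effects,
                 seed = as.integer(seed), cohort = cohort,
                 subnetwork_file = subnetwork_file),
            class = "pipeline_config")
}

#' Simulate a cohort to disk
#'
#' Generates the configured synthetic cohort and writes it under the
#' pipeline's cohort directory: manifest, matrices with sidecars, and a
#' `ground_truth.yaml` sidecar recording the generating parameters (true
#' per-group coupling alphas, densities, behavioral slopes, site
#' effects).
#'
#' @param config A [pipeline_config()].
#' @return The cohort directory, invisibly.
#' @export
run_simulate <- function(config) {
  cohort <- generate_cohort(config$cohort)
  dir.create(config$cohort_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$cohort_dir)) {
    stop("cannot create cohort directory: ", config$cohort_dir)
  }
  write_cohort(cohort, config$cohort_dir)
  invisible(config$cohort_dir)
}

#' Validate an on-disk cohort
#'
#' Checks the manifest vocabulary (groups, sites), positive ages, matrix
#' files present, square shape matching the node-label sidecar, symmetry
#' within tolerance, and non-negative SC entries. Findings are returned
#' as a data frame (zero rows means the cohort is valid) rather than
#' raised, so a runner can report all problems at once.
#'
#' @param cohort_dir Directory with `manifest.csv` and matrices.
#' @param symmetry_tol Maximum tolerated `max|A - t(A)|`.
#' @return Data frame with `subject_id`, `check`, `detail`.
#' @export
validate_inputs <- function(cohort_dir, symmetry_tol = 1e-6) {
  findings <- list()
  note <- function(subject, check, detail) {
    findings[[length(findings) + 1]] <<- data.frame(
      subject_id = subject, check = check, detail = detail,
      stringsAsFactors = FALSE)
  }
  manifest_path <- file.path(cohort_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    note(NA_character_, "manifest", "manifest.csv not found")
    return(do.call(rbind, findings))
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = c(site = "character"))
  required <- c("subject_id", "group", "site", "age", "sex",
                "sc_path", "fc_path")
  absent <- setdiff(required, names(man))
  if (length(absent) > 0) {
    note(NA_character_, "manifest",
         paste("missing columns:", paste(absent, collapse = ", ")))
    return(do.call(rbind, findings))
  }
  for (i in seq_len(nrow(man))) {
    id <- man$subject_id[i]
    if (!man$group[i] %in% GROUPS) {
      note(id, "vocabulary", paste("unknown group label:", man$group[i]))
    }
    if (!man$site[i] %in% SITES) {
      note(id, "vocabulary", paste("unknown site label:", man$site[i]))
    }
    if (!is.finite(man$age[i]) || man$age[i] <= 0) {
      note(id, "covariates", paste("non-positive age:", man$age[i]))
    }
    for (mod_col in c("sc_path", "fc_path")) {
      path <- file.path(cohort_dir, man[[mod_col]][i])
      if (!file.exists(path)) {
        note(id, "files", paste("missing matrix file:", man[[mod_col]][i]))
        next
      }
      m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
      if (nrow(m) != ncol(m)) {
        note(id, "shape", sprintf("%s: %d x %d not square",
                                  mod_col, nrow(m), ncol(m)))
        next
      }
      sidecar <- paste0(path, ".json")
      if (file.exists(sidecar)) {
        labels <- jsonlite::fromJSON(sidecar)$node_labels
        if (length(labels) != nrow(m)) {
          note(id, "shape", sprintf(
            "%s: %d nodes but %d sidecar labels", mod_col, nrow(m),
            length(labels)))
        }
      }
      asym <- max(abs(m - t(m)))
      if (asym > symmetry_tol) {
        note(id, "symmetry",
             sprintf("%s: max asymmetry %.3g", mod_col, asym))
      }
      if (mod_col == "sc_path" && any(m < 0)) {
        note(id, "sc_range", "negative fiber counts")
      }
    }
  }
  if (length(findings) == 0) {
    return(data.frame(subject_id = character(), check = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Table-style group report for every feature
#'
#' Runs the ANCOVA group test (age and sex covariates) and the pairwise
#' post-hoc comparisons on every row of a feature table, producing one
#' report row per feature: per-group mean and SEM, ANCOVA F and p, and
#' the adjusted p of every group pair.
#'
#' @param features A [feature_table()].
#' @param posthoc Post-hoc method (see [pairwise_posthoc()]).
#' @return Data frame, one row per feature.
#' @export
group_report <- function(features,
                         posthoc = c("tukey", "welch_t", "bonferroni")) {
  posthoc <- match.arg(posthoc)
  subjects <- features$subjects
  covs <- data.frame(age = subjects$age,
                     sex = as.numeric(factor(subjects$sex)) - 1)
  rows <- lapply(rownames(features$values), function(feat) {
    y <- features$values[feat, ]
    parts <- strsplit(feat, ".", fixed = TRUE)[[1]]
    an <- ancova_group_test(y, subjects$group, covs$age, covs$sex)
    ph <- pairwise_posthoc(y, subjects$group, covariates = covs,
                           method = posthoc)
    row <- data.frame(feature = feat, measure = parts[1],
                      subnetwork = paste(parts[-1], collapse = "."),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(an$group_means))) {
      g <- an$group_means$group[i]
      row[[paste0("mean_", g)]] <- an$group_means$mean[i]
      row[[paste0("sem_", g)]] <- an$group_means$sem[i]
    }
    row$F <- an$statistic
    row$p <- an$p
    for (i in seq_len(nrow(ph))) {
      row[[paste0("p_", ph$group1[i], "_vs_", ph$group2[i])]] <- ph$p[i]
    }
    row
  })
  do.call(rbind, rows)
}

#' In-memory analysis of a cohort
#'
#' The computational core of [run_all()]: feature extraction, optional
#' site-effect injection (simulated cohorts), ComBat harmonization, the
#' group report, edgewise group contrasts, and the behavior-coupling
#' analysis, all returned in memory.
#'
#' @param cohort Cohort list (`subjects` + `matrices`).
#' @param config A [pipeline_config()].
#' @return List: `features_raw`, `features_observed`,
#'   `features_harmonized`, `combat_model`, `group_report`, `edgewise`
#'   (named list per contrast), `behavior`.
#' @export
analyze_cohort <- function(cohort, config) {
  subnets <- subnetwork_definitions(config$subnetwork_file)
  features <- build_feature_table(cohort, subnets,
                                  t_points = config$t_points,
                                  q = config$fdr_q,
                                  zero_mode = config$zero_mode)
  observed <- features
  if (isTRUE(config$inject_site_effects)) {
    shift <- config$cohort$site_shift
    scale <- config$cohort$site_scale
    observed <- inject_site_effects(features, unlist(shift), unlist(scale))
  }
  harm <- combat_fit_transform(observed,
                               covariates = c("age", "sex"),
                               include_group = config$include_group)
  report <- group_report(harm$features, posthoc = config$posthoc)

  groups_present <- intersect(GROUPS, unique(cohort$subjects$group))
  edgewise <- list()
  if (length(groups_present) >= 2) {
    prs <- utils::combn(groups_present, 2)
    for (k in seq_len(ncol(prs))) {
      g1 <- prs[1, k]; g2 <- prs[2, k]
      ids1 <- cohort$subjects$subject_id[cohort$subjects$group == g1]
      ids2 <- cohort$subjects$subject_id[cohort$subjects$group == g2]
      for (tf in c("log1p_sc", "fc_z")) {
        mats <- if (tf == "log1p_sc") "sc" else "fc"
        edgewise[[sprintf("%s_vs_%s_%s", g1, g2, mats)]] <-
          edgewise_group_contrast(
            lapply(cohort$matrices[ids1], `[[`, mats),
            lapply(cohort$matrices[ids2], `[[`, mats),
            transform = tf, q = config$fdr_q)
      }
    }
  }
  behavior <- behavior_coupling_analysis(harm$features, "DMN")
  list(features_raw = features, features_observed = observed,
       features_harmonized = harm$features, combat_model = harm$model,
       group_report = report, edgewise = edgewise, behavior = behavior)
}

#' Run the full pipeline end to end
#'
#' Simulate (unless a cohort already sits in `config$cohort_dir`),
#' validate, extract features, harmonize, and run the statistics,
#' writing every artifact under `config$out_dir`: raw/observed/
#' harmonized feature CSVs, harmonization report, group report, one
#' edgewise CSV per contrast, behavior-correlation CSVs, and a plain-text
#' run log echoing the configuration.
#'
#' @param config A [pipeline_config()].
#' @return The result of [analyze_cohort()], invisibly, with
#'   `$validation` attached.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(
    sprintf("scfc %s | R %s", as.character(utils::packageVersion("scfc")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", config$seed),
    sprintf("t_points: %d | fdr_q: %g | coupling zero_mode: %s",
            config$t_points, config$fdr_q, config$zero_mode),
    sprintf("posthoc: %s | include_group: %s | inject_site_effects: %s",
            config$posthoc, config$include_group,
            config$inject_site_effects))

  stage <- "simulate"
  result <- tryCatch({
    if (!file.exists(file.path(config$cohort_dir, "manifest.csv"))) {
      run_simulate(config)
      log_lines <- c(log_lines, sprintf("simulated cohort -> %s",
                                        config$cohort_dir))
    } else {
      log_lines <- c(log_lines, sprintf("using existing cohort at %s",
                                        config$cohort_dir))
    }

    stage <- "validate"
    validation <- validate_inputs(config$cohort_dir)
    if (nrow(validation) > 0) {
      utils::write.csv(validation,
                       file.path(config$out_dir, "validation_findings.csv"),
                       row.names = FALSE)
      stop(sprintf("%d validation finding(s); see validation_findings.csv",
                   nrow(validation)))
    }

    stage <- "features"
    cohort <- read_cohort(config$cohort_dir)
    res <- analyze_cohort(cohort, config)

    stage <- "write-outputs"
    out <- config$out_dir
    write_feature_table(res$features_raw,
                        file.path(out, "features_raw.csv"))
    write_feature_table(res$features_observed,
                        file.path(out, "features_observed.csv"))
    write_feature_table(res$features_harmonized,
                        file.path(out, "features_harmonized.csv"))
    utils::write.csv(harmonization_report(res$combat_model),
                     file.path(out, "harmonization_report.csv"),
                     row.names = FALSE)
    utils::write.csv(res$group_report,
                     file.path(out, "group_report.csv"), row.names = FALSE)
    for (nm in names(res$edgewise)) {
      utils::write.csv(res$edgewise[[nm]]$edges,
                       file.path(out, sprintf("edgewise_%s.csv", nm)),
                       row.names = FALSE)
    }
    utils::write.csv(res$behavior$correlations,
                     file.path(out, "behavior_correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(res$behavior$differences,
                     file.path(out, "behavior_correlation_differences.csv"),
                     row.names = FALSE)
    res$validation <- validation
    res
  }, error = function(e) {
    log_lines <- c(log_lines, sprintf("FAILED at stage '%s': %s",
                                      stage, conditionMessage(e)))
    writeLines(log_lines, log_path)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  log_lines <- c(log_lines, sprintf("finished: %s",
                                    format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, log_path)
  invisible(result)
}
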