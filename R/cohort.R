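GROUPS <- c("TDC", "ADHD-I", "ADHD-C")
SITES <- c("1", "2")

#' Configuration of the synthetic cohort generator
#'
#' Bundles every knob of the simulated study: per-group sample sizes,
#' structural edge density and fiber-count distribution, the SC-FC
#' coupling strength `coupling_alpha`, time-series length, two-site
#' batch effects, behavioral-score structure, and covariate
#' distributions. All per-group parameters are named vectors (or lists)
#' over exactly the three diagnostic groups `TDC`, `ADHD-I`, `ADHD-C`.
#'
#' Defaults emulate the study design the package targets: 56/75/70
#' subjects per group; lower structural edge density in the ADHD groups
#' (lowest in ADHD-C); coupling strength highest in ADHD-C so that
#' group-mean DMN coupling lands near 0.27 (TDC), 0.27 (ADHD-I) and 0.37
#' (ADHD-C); SWAN-like hyperactivity/inattention scores whose group means,
#' inattention-hyperactivity correlations (higher in ADHD-C than ADHD-I)
#' and negative hyperactivity-coupling slope in ADHD-I mirror the targeted
#' effect pattern; and a Bernoulli(0.5) two-site assignment with a small
#' additive site-2 feature shift for the harmonization stage to remove.
#'
#' @param n_per_group Named integer vector: subjects per group.
#' @param n_nodes Number of network nodes (default 90, the AAL-90 atlas).
#' @param edge_density Named vector in (0, 1]: per-group probability that
#'   a region pair is structurally connected.
#' @param fiber_logmean,fiber_logsd Log-normal parameters of fiber counts
#'   on structural edges.
#' @param coupling_alpha Named vector in `[0, 1]`: per-group weight mixing
#'   the structure-derived correlation target into the FC covariance;
#'   larger values couple FC more tightly to SC.
#' @param t_points Simulated time-series length used to sample FC (>= 10).
#' @param site_prob Probability a subject is scanned at site 2.
#' @param site_shift,site_scale Named (by site `"1"`, `"2"`) additive and
#'   multiplicative effects applied to features by [inject_site_effects()].
#' @param beta_hyper Named vector: per-group slope of hyperactivity on the
#'   standardized DMN coupling (in hyperactivity-score units).
#' @param rho_inatt_hyper Named vector in `[-1, 1]`: per-group target
#'   correlation between inattention and hyperactivity scores.
#' @param hyper_mean,hyper_sd,inatt_mean,inatt_sd Named vectors: group
#'   means and SDs of the two behavioral scores.
#' @param age_range Named list of `c(min, max)` ages (years) per group
#'   (sampled uniformly); `sex_prob` the per-group probability of male sex.
#' @param sex_prob See `age_range`.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_per_group = c("TDC" = 56, "ADHD-I" = 75, "ADHD-C" = 70),
    n_nodes = 90,
    edge_density = c("TDC" = 0.32, "ADHD-I" = 0.28, "ADHD-C" = 0.26),
    fiber_logmean = 3,
    fiber_logsd = 1,
    coupling_alpha = c("TDC" = 0.40, "ADHD-I" = 0.36, "ADHD-C" = 0.55),
    t_points = 200,
    site_prob = 0.5,
    site_shift = c("1" = -0.025, "2" = 0.025),
    site_scale = c("1" = 1, "2" = 1),
    beta_hyper = c("TDC" = 0, "ADHD-I" = -0.33, "ADHD-C" = 0),
    rho_inatt_hyper = c("TDC" = 0.30, "ADHD-I" = 0.25, "ADHD-C" = 0.62),
    hyper_mean = c("TDC" = -0.9, "ADHD-I" = 0.2, "ADHD-C" = 1.2),
    hyper_sd = c("TDC" = 1.1, "ADHD-I" = 1.1, "ADHD-C" = 0.8),
    inatt_mean = c("TDC" = -0.8, "ADHD-I" = 1.2, "ADHD-C" = 1.4),
    inatt_sd = c("TDC" = 1.1, "ADHD-I" = 0.9, "ADHD-C" = 0.8),
    age_range = list("TDC" = c(6.2, 16.5), "ADHD-I" = c(6.4, 17.0),
                     "ADHD-C" = c(5.0, 16.7)),
    sex_prob = c("TDC" = 0.357, "ADHD-I" = 0.72, "ADHD-C" = 0.80),
    seed = 1L) {
  cfg <- list(
    n_per_group = n_per_group, n_nodes = n_nodes,
    edge_density = edge_density,
    fiber_logmean = fiber_logmean, fiber_logsd = fiber_logsd,
    coupling_alpha = coupling_alpha, t_points = t_points,
    site_prob = site_prob, site_shift = site_shift, site_scale = site_scale,
    beta_hyper = beta_hyper, rho_inatt_hyper = rho_inatt_hyper,
    hyper_mean = hyper_mean, hyper_sd = hyper_sd,
    inatt_mean = inatt_mean, inatt_sd = inatt_sd,
    age_range = age_range, sex_prob = sex_prob, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  per_group <- c("n_per_group", "edge_density", "coupling_alpha",
                 "beta_hyper", "rho_inatt_hyper", "hyper_mean", "hyper_sd",
                 "inatt_mean", "inatt_sd", "age_range", "sex_prob")
  for (fld in per_group) {
    nm <- names(cfg[[fld]])
    if (!setequal(nm, GROUPS) || length(nm) != 3) {
      stop(sprintf("config field '%s' must be named by exactly the groups %s",
                   fld, paste(GROUPS, collapse = ", ")))
    }
  }
  if (any(cfg$coupling_alpha < 0 | cfg$coupling_alpha > 1)) {
    stop("coupling_alpha must lie in [0, 1]")
  }
  if (any(cfg$edge_density <= 0 | cfg$edge_density > 1)) {
    stop("edge_density must lie in (0, 1]")
  }
  if (cfg$t_points < 10) stop("t_points must be >= 10")
  if (!setequal(names(cfg$site_shift), SITES) ||
      !setequal(names(cfg$site_scale), SITES)) {
    stop("site_shift and site_scale must be named by sites 1 and 2")
  }
  invisible(cfg)
}

#' Simulate one structural connectivity matrix
#'
#' Draws an Erdos-Renyi graph over the node set with the given edge
#' density and puts a log-normal fiber count on every edge:
#' `max(1, round(exp(Normal(fiber_logmean, fiber_logsd))))`, so connected
#' pairs always carry at least one fiber. The result is symmetric with a
#' zero diagonal, like a tract-count matrix from probabilistic
#' tractography.
#'
#' @param n_nodes Number of nodes.
#' @param density Edge probability in `[0, 1]`.
#' @param fiber_logmean,fiber_logsd Log-normal fiber-count parameters.
#' @param node_labels Optional node labels.
#' @return An SC [connectivity_matrix()].
#' @export
generate_sc_matrix <- function(n_nodes, density, fiber_logmean = 3,
                               fiber_logsd = 1, node_labels = NULL) {
  stopifnot(density >= 0, density <= 1)
  m <- matrix(0, n_nodes, n_nodes)
  ut <- upper.tri(m)
  n_pairs <- sum(ut)
  on_edge <- stats::runif(n_pairs) < density
  w <- numeric(n_pairs)
  w[on_edge] <- pmax(1, round(exp(stats::rnorm(
    sum(on_edge), fiber_logmean, fiber_logsd))))
  m[ut] <- w
  m <- m + t(m)
  connectivity_matrix(m, node_labels = node_labels, modality = "SC")
}

# Nearest positive-definite correlation matrix: clip eigenvalues at `eps`,
# reconstruct, re-standardize to unit diagonal.
nearest_pd_correlation <- function(c0, eps = 1e-8) {
  e <- eigen((c0 + t(c0)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, eps)
  m <- e$vectors %*% (lam * t(e$vectors))
  stats::cov2cor(m)
}

#' Simulate a functional connectivity matrix coupled to structure
#'
#' Builds a target covariance `Sigma = (1 - alpha) * I + alpha * C`,
#' where `C` is the subject's standardized `log(1 + SC)` matrix projected
#' to the nearest positive-definite correlation matrix, draws `t_points`
#' independent multivariate normal "time points" from it, and returns the
#' Fisher-z transform of their sample correlation matrix (diagonal stored
#' as 0). `alpha = 0` gives FC independent of SC; increasing `alpha`
#' increases the expected edgewise Spearman coupling between log fiber
#' counts and FC. Finite `t_points` supplies both realistic sampling noise
#' and the degrees of freedom that FC thresholding assumes.
#'
#' @param sc Subject's SC [connectivity_matrix()].
#' @param alpha Covariance mixing weight in `[0, 1]`.
#' @param t_points Number of simulated time points.
#' @return An FC [connectivity_matrix()] of Fisher-z values.
#' @export
generate_fc_matrix <- function(sc, alpha, t_points = 200) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  n <- nrow(sc)
  m <- log1p(unclass(sc))
  c0 <- if (max(m) > 0) m / max(m) else matrix(0, n, n)
  diag(c0) <- 1
  cc <- nearest_pd_correlation(c0)
  sigma <- (1 - alpha) * diag(n) + alpha * cc
  if (alpha == 1) sigma <- sigma + 1e-8 * diag(n)
  r_chol <- chol(sigma)
  x <- matrix(stats::rnorm(t_points * n), t_points, n) %*% r_chol
  r <- stats::cor(x)
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  diag(z) <- 0
  connectivity_matrix(z, node_labels = rownames(sc), modality = "FC")
}

#' Simulate SWAN-like behavioral scores tied to DMN coupling
#'
#' Hyperactivity is the group mean plus `beta_hyper[group]` times the
#' standardized DMN coupling plus Gaussian noise scaled so the group SD
#' matches `hyper_sd[group]`. Inattention is built from the standardized
#' hyperactivity score to carry the target correlation
#' `rho_inatt_hyper[group]`: `inatt = mean + sd * (rho * h + sqrt(1 -
#' rho^2) * eps)`. With `|rho| = 1` the noise term vanishes and the
#' correlation is exact.
#'
#' @param coupling_dmn Numeric vector of the group's per-subject DMN
#'   couplings.
#' @param group Group label (one of `TDC`, `ADHD-I`, `ADHD-C`).
#' @param config A [cohort_config()].
#' @return Data frame with `swan_hyper` and `swan_inatt`.
#' @export
generate_behavior <- function(coupling_dmn, group, config) {
  if (!group %in% GROUPS) stop("unknown group: ", group)
  if (any(!is.finite(coupling_dmn))) stop("coupling values must be finite")
  n <- length(coupling_dmn)
  beta <- config$beta_hyper[[group]]
  sd_h <- config$hyper_sd[[group]]
  cs <- if (n > 1 && stats::sd(coupling_dmn) > 0) {
    as.numeric(scale(coupling_dmn))
  } else {
    rep(0, n)
  }
  resid_sd <- sqrt(max(sd_h^2 - beta^2, 0))
  hyper <- config$hyper_mean[[group]] + beta * cs +
    stats::rnorm(n, 0, resid_sd)
  rho <- config$rho_inatt_hyper[[group]]
  h_std <- if (n > 1 && stats::sd(hyper) > 0) as.numeric(scale(hyper)) else rep(0, n)
  inatt <- config$inatt_mean[[group]] + config$inatt_sd[[group]] *
    (rho * h_std + sqrt(1 - rho^2) * stats::rnorm(n))
  data.frame(swan_hyper = hyper, swan_inatt = inatt)
}

#' Generate a full synthetic cohort
#'
#' Produces, deterministically for a given `config$seed`, a cohort of
#' subject records (group, site, age, sex, SWAN scores) with paired SC/FC
#' matrices whose statistical structure matches the generator model:
#' group-dependent structural density, FC coupled to log-SC with
#' group-dependent strength, random two-site assignment, and behavioral
#' scores tied to each subject's DMN coupling.
#'
#' @param config A [cohort_config()].
#' @return List with `subjects` (data frame: `subject_id`, `group`,
#'   `site`, `age`, `sex`, `swan_hyper`, `swan_inatt`), `matrices` (named
#'   list per subject of `list(sc, fc)`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  labels <- if (config$n_nodes == 90) aal90_labels() else
    sprintf("node%03d", seq_len(config$n_nodes))
  dmn <- subnetwork_definitions()$DMN
  use_dmn <- all(dmn %in% labels)

  subjects <- list()
  matrices <- list()
  counter <- 0
  for (g in GROUPS) {
    n <- config$n_per_group[[g]]
    ids <- sprintf("sub-%04d", counter + seq_len(n))
    counter <- counter + n
    coup <- numeric(n)
    for (k in seq_len(n)) {
      sc <- generate_sc_matrix(config$n_nodes, config$edge_density[[g]],
                               config$fiber_logmean, config$fiber_logsd,
                               node_labels = labels)
      fc <- generate_fc_matrix(sc, config$coupling_alpha[[g]],
                               config$t_points)
      matrices[[ids[k]]] <- list(sc = sc, fc = fc)
      cp <- if (use_dmn) sc_fc_coupling(sc, fc, dmn) else
        sc_fc_coupling(sc, fc, labels)
      coup[k] <- if (is.na(cp$rho)) 0 else cp$rho
    }
    beh <- generate_behavior(coup, g, config)
    ar <- config$age_range[[g]]
    subjects[[g]] <- data.frame(
      subject_id = ids,
      group = g,
      site = as.character(1 + stats::rbinom(n, 1, config$site_prob)),
      age = stats::runif(n, ar[1], ar[2]),
      sex = ifelse(stats::runif(n) < config$sex_prob[[g]], "male", "female"),
      swan_hyper = beh$swan_hyper,
      swan_inatt = beh$swan_inatt,
      stringsAsFactors = FALSE)
  }
  subjects <- do.call(rbind, subjects)
  rownames(subjects) <- NULL
  list(subjects = subjects, matrices = matrices, config = config)
}

#' Write / read a cohort on disk
#'
#' `write_cohort()` lays a cohort out as the pipeline's on-disk interface:
#' a `manifest.csv` (columns `subject_id`, `group`, `site`, `age`, `sex`,
#' `swan_hyper`, `swan_inatt`, `sc_path`, `fc_path`), one tab-delimited
#' matrix file per subject and modality under `matrices/` with JSON
#' node-label sidecars, and a `ground_truth.yaml` echoing the generator
#' configuration (true alphas, densities, site effects) for downstream
#' test harnesses. `read_cohort()` loads that layout back.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_cohort`: the manifest path, invisibly. `read_cohort`: a
#'   cohort list (without `config` unless the sidecar is present).
#' @export
write_cohort <- function(cohort, dir) {
  mat_dir <- file.path(dir, "matrices")
  dir.create(mat_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- cohort$subjects
  subjects$sc_path <- file.path("matrices",
                                paste0(subjects$subject_id, "_sc.txt"))
  subjects$fc_path <- file.path("matrices",
                                paste0(subjects$subject_id, "_fc.txt"))
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    write_matrix(cohort$matrices[[id]]$sc, file.path(dir, subjects$sc_path[i]))
    write_matrix(cohort$matrices[[id]]$fc, file.path(dir, subjects$fc_path[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(subjects, manifest, row.names = FALSE)
  if (!is.null(cohort$config)) {
    yaml::write_yaml(config_to_list(cohort$config),
                     file.path(dir, "ground_truth.yaml"))
  }
  invisible(manifest)
}

config_to_list <- function(cfg) {
  lapply(unclass(cfg), function(x) if (is.list(x)) x else as.list(x))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) stop("no manifest.csv under ", dir)
  subjects <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                              colClasses = c(site = "character"))
  matrices <- list()
  for (i in seq_len(nrow(subjects))) {
    sc_file <- file.path(dir, subjects$sc_path[i])
    fc_file <- file.path(dir, subjects$fc_path[i])
    missing <- c(sc_file, fc_file)[!file.exists(c(sc_file, fc_file))]
    if (length(missing) > 0) {
      stop("missing matrix files for subject ", subjects$subject_id[i], ": ",
           paste(missing, collapse = ", "))
    }
    matrices[[subjects$subject_id[i]]] <- list(
      sc = read_matrix(sc_file, modality = "SC"),
      fc = read_matrix(fc_file, modality = "FC"))
  }
  out <- list(subjects = subjects, matrices = matrices)
  gt <- file.path(dir, "ground_truth.yaml")
  if (file.exists(gt)) out$config <- yaml::read_yaml(gt)
  out
}
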