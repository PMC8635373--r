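#' Parametric empirical-Bayes ComBat batch correction
#'
#' Removes additive and multiplicative batch (acquisition-site) effects
#' from a features x samples matrix while preserving modeled biological
#' covariates. The model for feature g of sample j in batch i is
#' `Y = alpha + X beta + gamma_i + delta_i * eps`; the algorithm is the
#' standard parametric empirical-Bayes procedure: (1) feature-wise least
#' squares with the batch-size-weighted identifiability constraint
#' `sum_i n_i gamma_hat_i = 0`, standardization
#' `Z = (Y - alpha_hat - X beta_hat) / sigma_hat`; (2) method-of-moments
#' hyperpriors (normal prior on the location effects, inverse-gamma on
#' the squared scale effects) with iterative conditional-posterior
#' updates of `gamma*` and `delta*^2`; (3) adjustment
#' `Y* = sigma_hat * (Z - gamma*) / delta* + alpha_hat + X beta_hat`.
#'
#' @param y Numeric matrix, features x samples, no missing values.
#' @param batch Factor or vector of batch labels, one per sample; every
#'   batch needs at least 2 samples.
#' @param mod Optional design matrix of biological covariates to preserve
#'   (an intercept column is tolerated and dropped; columns confounded
#'   with batch raise an error naming the column).
#' @param tol Convergence tolerance of the EB posterior iteration.
#' @param max_iter Maximum posterior iterations.
#' @return List with `corrected` (matrix like `y`) and `model` (a
#'   `combat_model`: per-batch `gamma_hat`, `delta_hat`, posterior
#'   `gamma_star`, `delta_star`, hyperparameters `gamma_bar`, `tau2`,
#'   `a_prior`, `b_prior`, and the pooled variance `var_pooled`).
#' @export
combat <- function(y, batch, mod = NULL, tol = 1e-4, max_iter = 100) {
  stopifnot(is.matrix(y), ncol(y) == length(batch))
  if (any(!is.finite(y))) stop("feature matrix has missing/non-finite values")
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("need at least 2 batches")
  n_batches <- table(batch)
  if (any(n_batches < 2)) {
    stop("batch with a single sample: ",
         paste(names(n_batches)[n_batches < 2], collapse = ", "))
  }
  n_array <- ncol(y)
  batch_design <- stats::model.matrix(~ -1 + batch)
  colnames(batch_design) <- levels(batch)

  if (!is.null(mod)) {
    mod <- as.matrix(mod)
    keep <- !apply(mod, 2, function(x) all(x == x[1]))  # drop constant cols
    mod <- mod[, keep, drop = FALSE]
  }
  if (!is.null(mod) && ncol(mod) > 0) {
    # a covariate lying in the batch space is unidentifiable
    fit <- stats::lm.fit(batch_design, mod)
    resid_norm <- sqrt(colSums(as.matrix(fit$residuals)^2))
    confounded <- resid_norm < 1e-8 * (1 + sqrt(colSums(mod^2)))
    if (any(confounded)) {
      stop("covariate column(s) confounded with batch: ",
           paste(colnames(mod)[confounded], collapse = ", "))
    }
    design <- cbind(batch_design, mod)
  } else {
    design <- batch_design
  }
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")

  # feature-wise least squares; batch-size-weighted grand mean
  b_hat <- solve(crossprod(design), t(design) %*% t(y))
  nb <- nlevels(batch)
  grand_mean <- crossprod(as.numeric(n_batches) / n_array,
                          b_hat[seq_len(nb), , drop = FALSE])
  var_pooled <- ((y - t(design %*% b_hat))^2) %*% rep(1 / n_array, n_array)
  if (any(var_pooled <= 0)) stop("feature with zero residual variance")
  stand_mean <- t(grand_mean) %*% t(rep(1, n_array))
  if (ncol(design) > nb) {
    tmp <- design
    tmp[, seq_len(nb)] <- 0
    stand_mean <- stand_mean + t(tmp %*% b_hat)
  }
  z <- (y - stand_mean) / (sqrt(var_pooled) %*% t(rep(1, n_array)))

  gamma_hat <- solve(crossprod(batch_design), t(batch_design) %*% t(z))
  delta_hat <- t(vapply(levels(batch), function(lv) {
    apply(z[, batch == lv, drop = FALSE], 1, stats::var)
  }, numeric(nrow(y))))
  if (nrow(y) == 1) delta_hat <- matrix(delta_hat, nrow = nb)

  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  a_prior <- apply(delta_hat, 1, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 1, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })
  if (nrow(y) == 1) {
    stop("ComBat needs >= 2 features to pool information across features")
  }

  gamma_star <- matrix(NA_real_, nb, nrow(y))
  delta_star <- matrix(NA_real_, nb, nrow(y))
  for (i in seq_len(nb)) {
    zi <- z[, batch == levels(batch)[i], drop = FALSE]
    post <- eb_posterior(zi, gamma_hat[i, ], delta_hat[i, ], gamma_bar[i],
                         tau2[i], a_prior[i], b_prior[i], tol, max_iter)
    gamma_star[i, ] <- post$gamma
    delta_star[i, ] <- post$delta2
  }

  corrected <- z
  for (i in seq_len(nb)) {
    sel <- batch == levels(batch)[i]
    corrected[, sel] <- (z[, sel, drop = FALSE] - gamma_star[i, ]) /
      sqrt(delta_star[i, ])
  }
  corrected <- corrected * (sqrt(var_pooled) %*% t(rep(1, n_array))) +
    stand_mean

  model <- structure(list(
    batch_levels = levels(batch), n_batches = as.numeric(n_batches),
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = sqrt(delta_star),
    gamma_bar = gamma_bar, tau2 = tau2,
    a_prior = a_prior, b_prior = b_prior,
    var_pooled = as.numeric(var_pooled),
    feature_names = rownames(y), fitted = TRUE),
    class = "combat_model")
  list(corrected = corrected, model = model)
}

# Iterative conditional posterior solve for one batch: normal posterior
# mean for the location effect given the scale, inverse-gamma posterior
# mode-like update for the scale given the location, until relative
# change drops below tol.
eb_posterior <- function(zi, g_hat, d_hat, g_bar, t2, a, b, tol, max_iter) {
  n <- ncol(zi)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((zi - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    # relative change with signed denominators, as in the reference
    # implementation; 0/0 (an exactly unchanged estimate) counts as 0
    ratios <- c(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
    ratios <- ratios[is.finite(ratios)]
    change <- if (length(ratios) == 0) 0 else max(ratios)
    g_old <- g_new
    d_old <- d_new
    if (change < tol) break
  }
  list(gamma = g_old, delta2 = d_old, iterations = it)
}

#' Harmonize a feature table across acquisition sites
#'
#' Runs [combat()] on a [feature_table()], using the `site` column as
#' batch and, by default, age, sex, and diagnostic group as biological
#' covariates to preserve. All feature rows are harmonized jointly in one
#' fit, so the empirical-Bayes step pools batch-effect information across
#' features. The input table is left untouched.
#'
#' @param features A [feature_table()] (subjects must carry `site`,
#'   `age`, `sex`, and `group` columns as needed).
#' @param covariates Character vector of subject columns to protect
#'   (numeric, or 2-level factors coded 0/1 internally).
#' @param include_group Include diagnostic group indicators among the
#'   protected covariates (default `TRUE`), so harmonization cannot erase
#'   group differences.
#' @param tol,max_iter Passed to [combat()].
#' @return List with `features` (harmonized [feature_table()]) and
#'   `model` (the fitted `combat_model`).
#' @export
combat_fit_transform <- function(features, covariates = c("age", "sex"),
                                 include_group = TRUE,
                                 tol = 1e-4, max_iter = 100) {
  subjects <- features$subjects
  terms <- covariates
  if (include_group) terms <- c(terms, "group")
  mod <- NULL
  if (length(terms) > 0) {
    fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    mod <- stats::model.matrix(fml, data = subjects)[, -1, drop = FALSE]
  }
  fit <- combat(features$values, batch = subjects$site, mod = mod,
                tol = tol, max_iter = max_iter)
  list(features = feature_table(fit$corrected, subjects),
       model = fit$model)
}

#' Summarize fitted site effects
#'
#' Tabulates, per feature and batch, the estimated and posterior location
#' (`gamma_hat`, `gamma_star`) and scale (`delta_hat`, `delta_star`)
#' effects of a fitted [combat()] model, flagging features whose
#' posterior scale ratio is extreme (outside `[1/flag_ratio,
#' flag_ratio]`).
#'
#' @param model A fitted `combat_model`.
#' @param flag_ratio Scale-ratio threshold for flagging (default 2).
#' @return Data frame with `feature`, `batch`, `n`, `gamma_hat`,
#'   `gamma_star`, `delta_hat`, `delta_star`, `flag` (one row per
#'   feature x batch).
#' @export
harmonization_report <- function(model, flag_ratio = 2) {
  if (!inherits(model, "combat_model") || !isTRUE(model$fitted)) {
    stop("harmonization_report needs a fitted combat_model")
  }
  nb <- length(model$batch_levels)
  nf <- length(model$feature_names)
  out <- data.frame(
    feature = rep(model$feature_names, times = nb),
    batch = rep(model$batch_levels, each = nf),
    n = rep(model$n_batches, each = nf),
    gamma_hat = as.vector(t(model$gamma_hat)),
    gamma_star = as.vector(t(model$gamma_star)),
    delta_hat = sqrt(as.vector(t(model$delta_hat))),
    delta_star = as.vector(t(model$delta_star)),
    stringsAsFactors = FALSE)
  out$flag <- out$delta_star > flag_ratio | out$delta_star < 1 / flag_ratio
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d features, batches: %s (n = %s)\n",
              length(x$feature_names),
              paste(x$batch_levels, collapse = ", "),
              paste(x$n_batches, collapse = ", ")))
  invisible(x)
}
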