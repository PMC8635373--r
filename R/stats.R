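#' ANCOVA group test with age and sex covariates
#'
#' Partial F test of the group factor in a linear model: the full model
#' `y ~ group + age + sex` is compared against the reduced model
#' `y ~ age + sex`, `F = ((SSE_r - SSE_f)/df_diff) / (SSE_f/df_f)`.
#' Raw per-group means and standard errors of the mean are reported
#' alongside.
#'
#' @param y Numeric response (one feature across subjects).
#' @param group Group labels (factor or character).
#' @param age,sex Covariates; `sex` may be character/factor (coded as a
#'   0/1 indicator) or numeric.
#' @return A `stat_result` list: `test`, `statistic` (F), `df` (numerator,
#'   denominator), `p`, and `group_means` (data frame with `group`, `n`,
#'   `mean`, `sem`).
#' @export
ancova_group_test <- function(y, group, age, sex) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("need at least 2 subjects per group")
  if (!is.numeric(sex)) sex <- as.numeric(factor(sex)) - 1
  if (any(!is.finite(c(y, age, sex)))) stop("non-finite values in y/covariates")
  gm_table <- function() {
    do.call(rbind, lapply(levels(group), function(lv) {
      yy <- y[group == lv]
      data.frame(group = lv, n = length(yy), mean = mean(yy),
                 sem = stats::sd(yy) / sqrt(length(yy)),
                 stringsAsFactors = FALSE)
    }))
  }
  if (stats::var(y) == 0) {  # constant response: no group sum of squares
    return(stat_result("ANCOVA (partial F, group)", 0,
                       df = c(nlevels(group) - 1,
                              length(y) - nlevels(group) - 2),
                       p = 1, group_means = gm_table()))
  }
  dat <- data.frame(y = y, group = group, age = age, sex = sex)
  full <- stats::lm(y ~ group + age + sex, data = dat)
  if (any(is.na(stats::coef(full)))) stop("singular design in ANCOVA")
  reduced <- stats::lm(y ~ age + sex, data = dat)
  an <- stats::anova(reduced, full)
  f_val <- an$F[2]
  p_val <- an$`Pr(>F)`[2]
  if (!is.finite(f_val)) {  # numerically zero residual + group SS
    f_val <- 0
    p_val <- 1
  }
  stat_result("ANCOVA (partial F, group)", f_val,
              df = c(an$Df[2], an$Res.Df[2]), p = p_val,
              group_means = gm_table())
}

stat_result <- function(test, statistic, df = NULL, p, ...) {
  structure(list(test = test, statistic = statistic, df = df, p = p, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  df_txt <- if (is.null(x$df)) "" else
    sprintf(" (df = %s)", paste(signif(x$df, 4), collapse = ", "))
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n",
              x$test, x$statistic, df_txt, x$p))
  if (!is.null(x$group_means)) {
    print(x$group_means, row.names = FALSE)
  }
  invisible(x)
}

#' Pairwise post-hoc group comparisons
#'
#' All pairwise group contrasts on a feature, by one of three methods:
#' `"tukey"` - Tukey-Kramer comparisons of covariate-adjusted group means
#' (the linear model `y ~ group + covariates`, adjusted p-values from the
#' studentized-range distribution via \pkg{emmeans}); `"welch_t"` -
#' unadjusted Welch two-sample t tests on the raw values; `"bonferroni"` -
#' Welch t with p multiplied by the number of pairs, capped at 1.
#'
#' @param y Numeric response.
#' @param group Group labels.
#' @param covariates Optional data frame of covariates (used by
#'   `"tukey"`).
#' @param method `"tukey"`, `"welch_t"`, or `"bonferroni"`.
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `estimate` (difference in means, adjusted for `"tukey"`),
#'   `statistic`, `p` (adjusted where the method adjusts).
#' @export
pairwise_posthoc <- function(y, group, covariates = NULL,
                             method = c("tukey", "welch_t", "bonferroni")) {
  method <- match.arg(method)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (method == "tukey") {
    dat <- data.frame(y = y, group = group)
    rhs <- "group"
    if (!is.null(covariates)) {
      covariates <- as.data.frame(covariates)
      dat <- cbind(dat, covariates)
      rhs <- paste(c("group", names(covariates)), collapse = " + ")
    }
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
    emm <- emmeans::emmeans(fit, "group")
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "tukey"))
    nm <- strsplit(as.character(prs$contrast), " - ")
    out <- data.frame(
      group1 = trimws(sub("^\\((.*)\\)$", "\\1", vapply(nm, `[`, "", 1))),
      group2 = trimws(sub("^\\((.*)\\)$", "\\1", vapply(nm, `[`, "", 2))),
      estimate = prs$estimate, statistic = prs$t.ratio, p = prs$p.value,
      stringsAsFactors = FALSE)
    return(out)
  }
  pairs <- utils::combn(levels(group), 2)
  n_pairs <- ncol(pairs)
  out <- lapply(seq_len(n_pairs), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    tt <- stats::t.test(y[group == g1], y[group == g2], var.equal = FALSE)
    p <- tt$p.value
    if (method == "bonferroni") p <- min(1, p * n_pairs)
    data.frame(group1 = g1, group2 = g2,
               estimate = unname(diff(rev(tt$estimate))),
               statistic = unname(tt$statistic), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Edgewise two-group contrast with FDR control
#'
#' Welch two-sample t test at every upper-triangle edge of a set of
#' connectivity matrices, comparing two groups, with Benjamini-Hochberg
#' correction across the tested edge family. SC matrices are compared on
#' the `log(1 + count)` scale (`transform = "log1p_sc"`); FC matrices on
#' their Fisher-z values (`"fc_z"`). Edges with zero variance in both
#' groups have no defined t statistic; they are excluded from the family
#' and reported.
#'
#' @param mats1,mats2 Lists of `connectivity_matrix` objects (one per
#'   subject) for the two groups; at least 2 subjects each.
#' @param transform `"log1p_sc"` or `"fc_z"`.
#' @param q FDR level.
#' @return List with `edges` (data frame: `node_i`, `node_j`, `t`, `p`,
#'   `significant`), `mask` (binary N x N matrix of significant edges),
#'   and `n_excluded` (zero-variance edges dropped).
#' @export
edgewise_group_contrast <- function(mats1, mats2,
                                    transform = c("log1p_sc", "fc_z"),
                                    q = 0.05) {
  transform <- match.arg(transform)
  if (length(mats1) < 2 || length(mats2) < 2) {
    stop("need at least 2 subjects per group")
  }
  f <- if (transform == "log1p_sc") function(m) log1p(unclass(m)) else unclass
  n <- nrow(mats1[[1]])
  ut <- which(upper.tri(matrix(0, n, n)))
  stack <- function(mats) {
    vapply(mats, function(m) f(m)[ut], numeric(length(ut)))
  }
  x1 <- stack(mats1)  # edges x subjects
  x2 <- stack(mats2)
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  defined <- se2 > 0
  t_stat <- rep(NA_real_, length(ut))
  p <- rep(NA_real_, length(ut))
  t_stat[defined] <- (m1[defined] - m2[defined]) / sqrt(se2[defined])
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p[defined] <- 2 * stats::pt(-abs(t_stat[defined]), df[defined])
  sig <- rep(FALSE, length(ut))
  sig[defined] <- stats::p.adjust(p[defined], method = "BH") <= q
  idx <- arrayInd(ut, c(n, n))
  labels <- rownames(mats1[[1]]) %||% as.character(seq_len(n))
  mask <- matrix(0, n, n, dimnames = list(labels, labels))
  mask[ut[sig]] <- 1
  mask <- mask + t(mask)
  list(edges = data.frame(node_i = labels[idx[, 1]],
                          node_j = labels[idx[, 2]],
                          t = t_stat, p = p, significant = sig,
                          stringsAsFactors = FALSE),
       mask = mask,
       n_excluded = sum(!defined))
}

#' Pearson correlation test
#'
#' Pearson correlation with the exact two-sided t test:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 4`, finite, non-constant.
#' @param method `"pearson"` (default) or `"spearman"` (rank correlation,
#'   same t approximation on the rank correlation).
#' @return A `stat_result` with `statistic` (r), `t`, `df`, `p`, `n`.
#' @export
pearson_corr_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 4) stop("need n >= 4")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  n <- length(x)
  r <- stats::cor(x, y, method = method)
  t_val <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_val), df = n - 2)
  stat_result(test = paste0(method, " correlation"), statistic = r,
              df = n - 2, p = p, t = t_val, n = n)
}

#' Test for a difference between two independent correlations
#'
#' Fisher r-to-z test: both correlations are variance-stabilized with
#' `atanh`, and the difference is referred to a standard normal,
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with the
#' two-sided p-value `2 * (1 - pnorm(|z|))`. This is the classical test
#' for comparing a correlation measured in two independent samples.
#'
#' @param r1,r2 Sample correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, each > 3.
#' @return A `corr_diff_result` list: `r1`, `n1`, `r2`, `n2`, `z`, `p`.
#' @examples
#' # inattention-hyperactivity correlation, two diagnostic subgroups
#' independent_corr_diff_test(0.25, 75, 0.62, 70)
#' @export
independent_corr_diff_test <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
                 z = z, p = 2 * stats::pnorm(-abs(z))),
            class = "corr_diff_result")
}

#' @export
print.corr_diff_result <- function(x, ...) {
  cat(sprintf(
    "Fisher r-to-z test: r1 = %.3f (n = %d) vs r2 = %.3f (n = %d), z = %.3f, p = %.4g\n",
    x$r1, x$n1, x$r2, x$n2, x$z, x$p))
  invisible(x)
}

#' Behavior-coupling correlation analysis
#'
#' For each diagnostic group, correlates the subjects' coupling in one
#' subnetwork (DMN by default) with their hyperactivity and inattention
#' scores, then tests every group pair for a difference between the
#' correlations with [independent_corr_diff_test()]. Subjects with
#' missing scores or couplings are excluded and counted; a group with
#' fewer than 4 usable subjects is reported as not estimable.
#'
#' @param features A [feature_table()] containing `coupling.<subnetwork>`.
#' @param subnetwork Subnetwork name (default `"DMN"`).
#' @param method Correlation estimator, `"pearson"` (default) or
#'   `"spearman"`.
#' @return List with `correlations` (data frame: `group`, `score`, `n`,
#'   `n_excluded`, `r`, `p`, `estimable`) and `differences` (data frame:
#'   `score`, `group1`, `group2`, `z`, `p`).
#' @export
behavior_coupling_analysis <- function(features, subnetwork = "DMN",
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  row_name <- paste0("coupling.", subnetwork)
  if (!row_name %in% rownames(features$values)) {
    stop("feature table has no row ", row_name)
  }
  coupling <- features$values[row_name, ]
  subjects <- features$subjects
  groups <- unique(subjects$group)
  scores <- c(hyperactivity = "swan_hyper", inattention = "swan_inatt")

  cor_rows <- list()
  r_by <- list()
  for (g in groups) {
    sel <- subjects$group == g
    for (sc_name in names(scores)) {
      s <- subjects[[scores[[sc_name]]]][sel]
      cp <- coupling[sel]
      ok <- is.finite(s) & is.finite(cp)
      n_excl <- sum(!ok)
      s <- s[ok]; cp <- cp[ok]
      estimable <- length(s) >= 4 && stats::sd(s) > 0 && stats::sd(cp) > 0
      if (estimable) {
        ct <- pearson_corr_test(cp, s, method = method)
        r <- ct$statistic; p <- ct$p
      } else {
        r <- NA_real_; p <- NA_real_
      }
      r_by[[paste(g, sc_name)]] <- list(r = r, n = length(s))
      cor_rows[[paste(g, sc_name)]] <- data.frame(
        group = g, score = sc_name, n = length(s), n_excluded = n_excl,
        r = r, p = p, estimable = estimable, stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cor_rows)
  rownames(correlations) <- NULL

  diffs <- list()
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    for (k in seq_len(ncol(pairs))) {
      for (sc_name in names(scores)) {
        a <- r_by[[paste(pairs[1, k], sc_name)]]
        b <- r_by[[paste(pairs[2, k], sc_name)]]
        if (is.na(a$r) || is.na(b$r) || a$n <= 3 || b$n <= 3) {
          diffs[[length(diffs) + 1]] <- data.frame(
            score = sc_name, group1 = pairs[1, k], group2 = pairs[2, k],
            z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        } else {
          d <- independent_corr_diff_test(a$r, a$n, b$r, b$n)
          diffs[[length(diffs) + 1]] <- data.frame(
            score = sc_name, group1 = pairs[1, k], group2 = pairs[2, k],
            z = d$z, p = d$p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(correlations = correlations, differences = do.call(rbind, diffs))
}
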