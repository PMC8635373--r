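test_that("the ANCOVA partial F matches an explicit normal-equations oracle", {
  set.seed(251)
  for (i in 1:20) {
    n <- sample(c(24, 45, 90), 1)
    group <- factor(sample(c("TDC", "ADHD-I", "ADHD-C"), n, replace = TRUE))
    while (any(table(group) < 2)) {
      group <- factor(sample(c("TDC", "ADHD-I", "ADHD-C"), n,
                             replace = TRUE))
    }
    age <- runif(n, 6, 17)
    sex <- rbinom(n, 1, 0.5)
    y <- rnorm(n) + 0.2 * (group == "TDC") + 0.01 * age
    res <- ancova_group_test(y, group, age, sex)
    dummies <- model.matrix(~group)[, -1, drop = FALSE]
    f_oracle <- brute_partial_f(y, cbind(1, age, sex), dummies)
    expect_equal(res$statistic, f_oracle, tolerance = 1e-8)
    expect_equal(res$p,
                 pf(f_oracle, ncol(dummies), n - 3 - ncol(dummies),
                    lower.tail = FALSE), tolerance = 1e-8)
  }
})

test_that("ANCOVA reports raw group means with their SEMs", {
  set.seed(261)
  group <- rep(c("TDC", "ADHD-I", "ADHD-C"), times = c(10, 12, 11))
  y <- rnorm(33)
  res <- ancova_group_test(y, group, runif(33, 6, 17), rbinom(33, 1, 0.5))
  gm <- res$group_means
  for (g in unique(group)) {
    yy <- y[group == g]
    expect_equal(gm$mean[gm$group == g], mean(yy))
    expect_equal(gm$sem[gm$group == g], sd(yy) / sqrt(length(yy)))
  }
  expect_true(all(gm$sem > 0))
})

test_that("a constant response yields a zero group F", {
  group <- rep(c("TDC", "ADHD-I", "ADHD-C"), each = 5)
  res <- ancova_group_test(rep(1, 15), group, runif(15, 6, 17),
                           rbinom(15, 1, 0.5))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("with covariates orthogonal to both group and response, the group sum of squares equals the one-way ANOVA between-group SS", {
  set.seed(271)
  n <- 60
  group <- factor(rep(c("TDC", "ADHD-I", "ADHD-C"), each = n / 3))
  y <- rnorm(n) + 0.5 * (group == "TDC")
  dummies <- model.matrix(~group)
  # residualize covariates against the group design and y so their
  # fitted coefficients vanish exactly
  raw <- cbind(runif(n, 6, 17), rbinom(n, 1, 0.5))
  basis <- cbind(dummies, y)
  covs <- raw - basis %*% solve(crossprod(basis), crossprod(basis, raw))
  res <- ancova_group_test(y, group, covs[, 1], covs[, 2])
  aov_f <- summary(aov(y ~ group))[[1]]$`F value`[1]
  # SSE_f equals the ANOVA residual SS, so the F statistics agree up to
  # the residual degrees of freedom (n-5 vs n-3)
  expect_equal(res$statistic * (n - 3) / (n - 5), aov_f, tolerance = 1e-8)
})

test_that("the ANCOVA group test holds its nominal size", {
  set.seed(281)
  n_rep <- 400
  rejections <- replicate(n_rep, {
    group <- rep(c("TDC", "ADHD-I", "ADHD-C"), each = 20)
    ancova_group_test(rnorm(60), group, runif(60, 6, 17),
                      rbinom(60, 1, 0.5))$p < 0.05
  })
  band <- 2.58 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rejections) - 0.05), band + 1e-12)
})

test_that("post-hoc methods behave as documented", {
  set.seed(291)
  group <- rep(c("TDC", "ADHD-I", "ADHD-C"), each = 20)
  y <- rnorm(60) + 0.8 * (group == "ADHD-C")
  covs <- data.frame(age = runif(60, 6, 17), sex = rbinom(60, 1, 0.5))

  tk <- pairwise_posthoc(y, group, covs, method = "tukey")
  wt <- pairwise_posthoc(y, group, method = "welch_t")
  bf <- pairwise_posthoc(y, group, method = "bonferroni")
  expect_equal(nrow(tk), 3)
  expect_equal(nrow(wt), 3)

  # bonferroni is exactly 3x the welch p, capped at 1
  expect_equal(bf$p, pmin(1, wt$p * 3))
  # hand arithmetic: p = 0.02 with 3 pairs -> 0.06
  expect_equal(min(1, 0.02 * 3), 0.06)

  # tukey-adjusted p dominates the unadjusted p from the same model
  for (i in 1:10) {
    yy <- rnorm(60)
    tk_i <- pairwise_posthoc(yy, group, covs, method = "tukey")
    fit <- lm(yy ~ g + age + sex,
              data = cbind(data.frame(g = group), covs))
    un <- as.data.frame(emmeans::contrast(emmeans::emmeans(fit, "g"),
                                          method = "pairwise",
                                          adjust = "none"))
    expect_true(all(tk_i$p >= un$p.value - 1e-12))
  }
  expect_error(pairwise_posthoc(y, group, method = "scheffe"))
})

test_that("null group pairs give large post-hoc p-values", {
  set.seed(301)
  meds <- replicate(200, {
    group <- rep(c("A", "B"), each = 50)
    pairwise_posthoc(rnorm(100), group, method = "welch_t")$p
  })
  expect_gt(median(meds), 0.4)
  expect_gt(mean(meds > 0.05), 0.9)
})

test_that("edgewise contrasts control error and detect planted effects", {
  set.seed(311)
  n_nodes <- 15
  make_mats <- function(n_sub, shift_edge = NULL, delta = 0) {
    lapply(seq_len(n_sub), function(i) {
      m <- matrix(0, n_nodes, n_nodes)
      m[upper.tri(m)] <- rnorm(choose(n_nodes, 2), 0.2, 0.1)
      if (!is.null(shift_edge)) m[shift_edge[1], shift_edge[2]] <-
          m[shift_edge[1], shift_edge[2]] + delta
      m <- m + t(m)
      connectivity_matrix(m, modality = "FC")
    })
  }

  # identical groups: empty mask
  mats <- make_mats(10)
  same <- edgewise_group_contrast(mats, mats, transform = "fc_z")
  expect_equal(sum(same$mask), 0)
  expect_equal(same$n_excluded, 0)

  # a 5 SD shift on one edge is found, and only that edge
  hits <- replicate(20, {
    g1 <- make_mats(30)
    g2 <- make_mats(30, shift_edge = c(2, 9), delta = 0.5)
    res <- edgewise_group_contrast(g1, g2, transform = "fc_z")
    res$mask[2, 9] == 1
  })
  expect_gt(mean(hits), 0.95)

  # zero-variance edges are excluded, not crashed on
  g1 <- make_mats(5); g2 <- make_mats(5)
  for (i in seq_along(g1)) {
    m <- unclass(g1[[i]]); m[1, 2] <- m[2, 1] <- 0.3
    g1[[i]] <- connectivity_matrix(m, modality = "FC")
    m2 <- unclass(g2[[i]]); m2[1, 2] <- m2[2, 1] <- 0.3
    g2[[i]] <- connectivity_matrix(m2, modality = "FC")
  }
  res <- edgewise_group_contrast(g1, g2, transform = "fc_z")
  expect_equal(res$n_excluded, 1)
  expect_true(is.na(res$edges$t[res$edges$node_i == rownames(g1[[1]])[1] &
                                  res$edges$node_j == rownames(g1[[1]])[2]]))

  expect_error(edgewise_group_contrast(g1[1], g2, transform = "fc_z"),
               "2 subjects")
})

test_that("edgewise significance equals the brute-force BH rule", {
  set.seed(321)
  for (i in 1:10) {
    g1 <- lapply(1:12, function(.) {
      m <- matrix(0, 8, 8); m[upper.tri(m)] <- rnorm(28, 0, 0.2)
      connectivity_matrix(m + t(m), modality = "FC")
    })
    g2 <- lapply(1:12, function(.) {
      m <- matrix(0, 8, 8); m[upper.tri(m)] <- rnorm(28, 0.1, 0.2)
      connectivity_matrix(m + t(m), modality = "FC")
    })
    res <- edgewise_group_contrast(g1, g2, transform = "fc_z", q = 0.1)
    expect_equal(res$edges$significant,
                 brute_bh_reject(res$edges$p, 0.1))
  }
})

test_that("the Pearson test reproduces hand-computed values", {
  expect_equal(pearson_corr_test(1:10, 1:10)$statistic, 1)
  expect_equal(pearson_corr_test(1:10, 10:1)$statistic, -1)

  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  res <- pearson_corr_test(x, y)
  r_hand <- brute_pearson(x, y)
  expect_equal(res$statistic, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  expect_equal(res$df, 3)

  expect_error(pearson_corr_test(1:3, 1:3), "n >= 4")
  expect_error(pearson_corr_test(rep(1, 5), 1:5), "zero variance")
})

test_that("the independent-correlations z test has its documented symmetries", {
  same <- independent_corr_diff_test(0.4, 30, 0.4, 55)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  a <- independent_corr_diff_test(0.1, 40, 0.5, 60)
  b <- independent_corr_diff_test(0.5, 60, 0.1, 40)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_true(a$p >= 0 && a$p <= 1)

  expect_error(independent_corr_diff_test(1, 30, 0.2, 30), "< 1")
  expect_error(independent_corr_diff_test(0.5, 3, 0.2, 30), "exceed 3")
})

test_that("behavior-coupling reports cover each group and score", {
  set.seed(331)
  n <- c("TDC" = 30, "ADHD-I" = 30, "ADHD-C" = 30)
  subjects <- data.frame(
    subject_id = sprintf("s%03d", 1:90),
    group = rep(names(n), times = n),
    site = rep(c("1", "2"), 45),
    age = runif(90, 6, 17),
    sex = sample(c("male", "female"), 90, TRUE),
    swan_hyper = rnorm(90),
    swan_inatt = rnorm(90),
    stringsAsFactors = FALSE)
  values <- matrix(rnorm(90, 0.3, 0.2), 1, 90,
                   dimnames = list("coupling.DMN", NULL))
  ft <- feature_table(values, subjects)
  out <- behavior_coupling_analysis(ft)
  expect_equal(nrow(out$correlations), 3 * 2)
  expect_equal(nrow(out$differences), 3 * 2)
  expect_true(all(out$correlations$estimable))
  expect_true(all(out$correlations$p >= 0 & out$correlations$p <= 1))

  # constant scores: flagged not estimable, no crash, differences NA
  subjects$swan_hyper <- 1
  ft2 <- feature_table(values, subjects)
  out2 <- behavior_coupling_analysis(ft2)
  hyper_rows <- out2$correlations$score == "hyperactivity"
  expect_false(any(out2$correlations$estimable[hyper_rows]))
  expect_true(all(is.na(
    out2$differences$p[out2$differences$score == "hyperactivity"])))

  # missing scores are excluded and counted
  subjects$swan_hyper <- rnorm(90)
  subjects$swan_hyper[1:5] <- NA
  ft3 <- feature_table(values, subjects)
  out3 <- behavior_coupling_analysis(ft3)
  tdc_h <- out3$correlations$group == "TDC" &
    out3$correlations$score == "hyperactivity"
  expect_equal(out3$correlations$n_excluded[tdc_h], 5)
  expect_equal(out3$correlations$n[tdc_h], 25)
})

test_that("a negative coupling-hyperactivity slope in one group is detected", {
  set.seed(341)
  cfg <- cohort_config(
    beta_hyper = c("TDC" = 0, "ADHD-I" = -0.4, "ADHD-C" = 0),
    hyper_sd = c("TDC" = 1, "ADHD-I" = 1, "ADHD-C" = 1))
  hit_neg <- hit_diff <- logical(100)
  for (i in 1:100) {
    cp_i <- rnorm(75, 0.27, 0.2)
    cp_c <- rnorm(70, 0.37, 0.2)
    beh_i <- generate_behavior(cp_i, "ADHD-I", cfg)
    beh_c <- generate_behavior(cp_c, "ADHD-C", cfg)
    r_i <- cor(cp_i, beh_i$swan_hyper)
    r_c <- cor(cp_c, beh_c$swan_hyper)
    hit_neg[i] <- r_i < 0
    hit_diff[i] <- independent_corr_diff_test(r_i, 75, r_c, 70)$p < 0.05
  }
  expect_gte(mean(hit_neg), 0.95)
  expect_gte(mean(hit_diff), 0.70)
})
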