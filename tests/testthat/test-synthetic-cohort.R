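test_that("cohort generation is deterministic and sized by configuration", {
  cfg <- cohort_config(n_per_group = c("TDC" = 4, "ADHD-I" = 5, "ADHD-C" = 3),
                       n_nodes = 20, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$matrices, b$matrices)
  expect_equal(nrow(a$subjects), 12)
  expect_equal(as.vector(table(a$subjects$group)[c("TDC", "ADHD-I", "ADHD-C")]),
               c(4, 5, 3))
  expect_true(all(a$subjects$site %in% c("1", "2")))
  expect_true(all(a$subjects$age > 0))
})

test_that("the default cohort design has the study's group sizes", {
  cfg <- cohort_config(n_nodes = 20, seed = 3)
  cohort <- generate_cohort(cfg)
  counts <- table(cohort$subjects$group)
  expect_equal(nrow(cohort$subjects), 201)
  expect_equal(as.vector(counts[c("TDC", "ADHD-I", "ADHD-C")]), c(56, 75, 70))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_group = c("TDC" = 5, "ADHD-H" = 5,
                                             "ADHD-C" = 5)),
               "n_per_group")
  expect_error(cohort_config(coupling_alpha = c("TDC" = 1.2, "ADHD-I" = 0.5,
                                                "ADHD-C" = 0.5)),
               "coupling_alpha")
  expect_error(cohort_config(edge_density = c("TDC" = 0, "ADHD-I" = 0.3,
                                              "ADHD-C" = 0.3)),
               "edge_density")
  expect_error(cohort_config(t_points = 5), "t_points")
  expect_error(generate_behavior(c(0.1, 0.2), "ADHD-H", cohort_config()),
               "unknown group")
})

test_that("SC matrices are symmetric integer graphs with the requested density", {
  set.seed(11)
  full <- generate_sc_matrix(15, 1.0)
  off <- full[upper.tri(full)]
  expect_true(all(off >= 1))
  expect_equal(unclass(full), t(unclass(full)), ignore_attr = TRUE)
  expect_true(all(full == round(full)))
  expect_equal(diag(full), rep(0, 15), ignore_attr = TRUE)

  empty <- generate_sc_matrix(15, 0)
  expect_true(all(empty == 0))

  # nonzero fraction within 3 binomial SDs of the target density
  m <- generate_sc_matrix(90, 0.5)
  n_pairs <- sum(upper.tri(m))
  frac <- mean(m[upper.tri(m)] > 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_pairs))
})

test_that("FC generation respects alpha bounds and the null case", {
  set.seed(21)
  sc <- generate_sc_matrix(30, 0.3)
  expect_error(generate_fc_matrix(sc, -0.1), "alpha")
  expect_error(generate_fc_matrix(sc, 1.5), "alpha")

  t_points <- 200
  fc <- generate_fc_matrix(sc, 0, t_points)
  r <- tanh(unclass(fc))
  expect_lt(mean(abs(r[upper.tri(r)])), 3 / sqrt(t_points))
  expect_equal(unclass(fc), t(unclass(fc)), ignore_attr = TRUE)
  expect_equal(diag(fc), rep(0, 30), ignore_attr = TRUE)
  # back-transformed matrix is a valid correlation matrix
  diag(r) <- 1
  expect_true(all(eigen(r, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-8))
  expect_true(all(abs(r[upper.tri(r)]) < 1))
})

test_that("the PD projection returns a unit-diagonal PSD correlation matrix", {
  set.seed(5)
  m <- matrix(runif(64, -1, 1), 8, 8)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  cc <- scfc:::nearest_pd_correlation(m)
  expect_equal(diag(cc), rep(1, 8))
  expect_true(min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values) >=
                0)
  expect_equal(cc, t(cc))
})

test_that("edgewise coupling increases with alpha", {
  set.seed(31)
  mean_coupling <- vapply(c(0.2, 0.5, 0.8), function(alpha) {
    mean(replicate(30, {
      sc <- generate_sc_matrix(30, 0.3)
      sc_fc_coupling(sc, generate_fc_matrix(sc, alpha, 200),
                     rownames(sc))$rho
    }))
  }, numeric(1))
  expect_true(all(diff(mean_coupling) > 0))
})

test_that("alpha = 0 leaves coupling centred at zero", {
  set.seed(41)
  rhos <- replicate(50, {
    sc <- generate_sc_matrix(30, 0.3)
    sc_fc_coupling(sc, generate_fc_matrix(sc, 0, 200), rownames(sc))$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("behavioral scores carry the configured structure", {
  cfg <- cohort_config()
  set.seed(51)

  # independence when slope and correlation are zero
  cfg0 <- cohort_config(
    beta_hyper = c("TDC" = 0, "ADHD-I" = 0, "ADHD-C" = 0),
    rho_inatt_hyper = c("TDC" = 0, "ADHD-I" = 0, "ADHD-C" = 0))
  coupling <- rnorm(400, 0.3, 0.2)
  beh <- generate_behavior(coupling, "ADHD-I", cfg0)
  expect_lt(abs(cor(beh$swan_hyper, coupling)), 3 / sqrt(400))
  expect_lt(abs(cor(beh$swan_hyper, beh$swan_inatt)), 3 / sqrt(400))

  # perfect correlation when rho = 1 (noise term vanishes)
  cfg1 <- cohort_config(
    rho_inatt_hyper = c("TDC" = 1, "ADHD-I" = 1, "ADHD-C" = 1))
  beh1 <- generate_behavior(rnorm(50, 0.3, 0.2), "ADHD-C", cfg1)
  expect_equal(cor(beh1$swan_hyper, beh1$swan_inatt), 1)

  # power: negative hyperactivity-coupling correlation in ADHD-I
  cfg_neg <- cohort_config(
    beta_hyper = c("TDC" = 0, "ADHD-I" = -0.3, "ADHD-C" = 0),
    hyper_sd = c("TDC" = 1, "ADHD-I" = 1, "ADHD-C" = 1))
  neg <- replicate(200, {
    cp <- rnorm(75, 0.3, 0.2)
    cor(generate_behavior(cp, "ADHD-I", cfg_neg)$swan_hyper, cp) < 0
  })
  expect_gte(mean(neg), 0.9)
})

test_that("demographic marginals match the configured distributions", {
  cfg <- cohort_config(n_per_group = c("TDC" = 150, "ADHD-I" = 5,
                                       "ADHD-C" = 5),
                       n_nodes = 12, seed = 61)
  cohort <- generate_cohort(cfg)
  tdc <- cohort$subjects[cohort$subjects$group == "TDC", ]
  ar <- cfg$age_range[["TDC"]]
  expect_true(all(tdc$age >= ar[1] & tdc$age <= ar[2]))
  expect_lt(abs(mean(tdc$age) - mean(ar)),
            3 * diff(ar) / sqrt(12 * nrow(tdc)))
  p_male <- cfg$sex_prob[["TDC"]]
  expect_lt(abs(mean(tdc$sex == "male") - p_male),
            3 * sqrt(p_male * (1 - p_male) / nrow(tdc)))
})

test_that("site effects are injected exactly and detectably", {
  set.seed(71)
  subjects <- data.frame(subject_id = sprintf("s%03d", 1:100),
                         site = rep(c("1", "2"), each = 50),
                         stringsAsFactors = FALSE)
  values <- matrix(rnorm(4 * 100, 0.5, 0.1), 4, 100,
                   dimnames = list(paste0("f", 1:4), NULL))
  ft <- feature_table(values, subjects)

  ident <- inject_site_effects(ft, c("1" = 0, "2" = 0),
                               c("1" = 1, "2" = 1))
  expect_equal(ident$values, ft$values)

  shifted <- inject_site_effects(ft, c("1" = 0, "2" = 0.2),
                                 c("1" = 1, "2" = 1))
  expect_equal(shifted$values[, subjects$site == "2"] -
                 ft$values[, subjects$site == "2"],
               matrix(0.2, 4, 50), ignore_attr = TRUE)
  expect_equal(shifted$values[, subjects$site == "1"],
               ft$values[, subjects$site == "1"])
  # original untouched
  expect_equal(ft$values, values, ignore_attr = TRUE)

  expect_error(inject_site_effects(ft, c("1" = 0), c("1" = 1)),
               "unknown site")

  # a 0.5 shift against SD 0.1 is detected by a two-sample t-test
  big <- inject_site_effects(ft, c("1" = 0, "2" = 0.5), c("1" = 1, "2" = 1))
  p <- t.test(big$values[1, subjects$site == "1"],
              big$values[1, subjects$site == "2"])$p.value
  expect_lt(p, 0.05)
})

test_that("cohorts round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_per_group = c("TDC" = 3, "ADHD-I" = 2,
                                       "ADHD-C" = 2),
                       n_nodes = 15, seed = 81)
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects$subject_id, cohort$subjects$subject_id)
  expect_equal(back$subjects$site, cohort$subjects$site)
  for (id in cohort$subjects$subject_id) {
    expect_equal(unclass(back$matrices[[id]]$sc),
                 unclass(cohort$matrices[[id]]$sc))
    expect_equal(unclass(back$matrices[[id]]$fc),
                 unclass(cohort$matrices[[id]]$fc), tolerance = 1e-10)
  }
  expect_true(file.exists(file.path(dir, "ground_truth.yaml")))
  gt <- yaml::read_yaml(file.path(dir, "ground_truth.yaml"))
  expect_length(gt$coupling_alpha, 3)
})
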