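test_that("clustered logistic matches an independent IRLS oracle", {
  d <- toy_logistic()
  fit <- fit_glm_clustered(y ~ x, d, "logistic", d$cluster)
  X <- cbind(1, d$x)
  expect_equal(unname(fit$coefficients), irls_logistic(X, d$y),
               tolerance = 1e-8)
  # cluster-sandwich SEs against the hand-rolled CR1 oracle
  vc <- sandwich_cluster_oracle(fit$fit, d$cluster)
  expect_equal(unname(fit$se), unname(sqrt(diag(vc))), tolerance = 1e-8)
  expect_identical(fit$n_clusters, 2L)
  expect_equal(unname(fit$ci95[, "upper"] - fit$coefficients),
               unname(1.96 * fit$se))
})

test_that("duplicating rows within clusters leaves clustered SEs stable", {
  set.seed(8)
  d <- data.frame(y = rbinom(60, 1, 0.5), x = rnorm(60),
                  cluster = rep(1:6, each = 10))
  d2 <- rbind(d, d)
  f1 <- fit_glm_clustered(y ~ x, d, "logistic", d$cluster)
  f2 <- fit_glm_clustered(y ~ x, d2, "logistic", d2$cluster)
  # identical up to the (n-1)/(n-k) small-sample factor
  adj <- sqrt((nrow(d) - 1) / (nrow(d) - 2) /
                ((nrow(d2) - 1) / (nrow(d2) - 2)))
  expect_equal(unname(f2$se * adj), unname(f1$se), tolerance = 1e-8)
  # naive (model-based) SEs shrink by ~ sqrt(2)
  naive1 <- sqrt(diag(vcov(f1$fit)))
  naive2 <- sqrt(diag(vcov(f2$fit)))
  expect_equal(unname(naive1 / naive2), rep(sqrt(2), 2),
               tolerance = 1e-6)
})

test_that("one cluster per row reduces to heteroskedasticity-robust SEs", {
  set.seed(10)
  d <- data.frame(y = rnorm(40), x = rnorm(40))
  f <- fit_glm_clustered(y ~ x, d, "linear", seq_len(40))
  # CR1 with singleton clusters collapses to HC1 exactly
  hc <- sqrt(diag(sandwich::vcovHC(f$fit, type = "HC1")))
  expect_equal(unname(f$se), unname(hc), tolerance = 1e-10)
})

test_that("separation and rank deficiency raise explicit errors", {
  d <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 10, 11, 12),
                  cluster = rep(1:2, 3))
  expect_error(fit_glm_clustered(y ~ x, d, "logistic", d$cluster),
               "separation")
  d2 <- data.frame(y = rnorm(10), x = 1:10, x2 = 2 * (1:10),
                   cluster = rep(1:2, 5))
  expect_error(fit_glm_clustered(y ~ x + x2, d2, "linear", d2$cluster),
               "x2")
})

test_that("K-S statistic matches brute force and its edge cases", {
  r <- ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_equal(r$D, 1 / 3, tolerance = 1e-12)
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:4, 6:9)$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
  brute_D <- function(x, y) {
    qs <- c(x, y)
    max(vapply(qs, function(q) abs(mean(x <= q) - mean(y <= q)),
               numeric(1)))
  }
  set.seed(12)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(sample(3:20, 1), sample(c(0, 1), 1))
    expect_equal(ks_two_sample(x, y)$D, brute_D(x, y),
                 tolerance = 1e-15)
  }
  # asymptotic p agrees with the standard implementation
  set.seed(13)
  x <- rnorm(200); y <- rnorm(150, 0.2)
  expect_equal(ks_two_sample(x, y)$p,
               suppressWarnings(ks.test(x, y, exact = FALSE)$p.value))
})

test_that("paired t matches the closed form", {
  x <- c(1.2, 1.4, 1.1); y <- c(1.0, 1.3, 0.9)
  tt <- t.test(x, y, paired = TRUE)
  d <- x - y
  expect_equal(unname(tt$statistic),
               mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-10)
  expect_equal(unname(tt$parameter), 2)
})

test_that("behavioral statistics are invariant to row order", {
  ds <- generate_dataset(tiny_config(seed = 3))
  perm <- sample(nrow(ds$trials))
  ds2 <- ds
  ds2$trials <- ds$trials[perm, ]
  ds2$fixations <- ds$fixations[sample(nrow(ds$fixations)), ]
  f1 <- analyze_choice(ds)
  f2 <- analyze_choice(ds2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
  q1 <- dwell_quintile_curve(ds)
  q2 <- dwell_quintile_curve(ds2)
  expect_equal(q1$p_left, q2$p_left, tolerance = 1e-12)
})

test_that("first-fixation analyses recover generator properties", {
  ds <- generate_dataset(experiment_config(n_fef = 6, n_vertex = 6,
                                           n_trials = 60, n_items = 60,
                                           seed = 21))
  ff <- analyze_first_fixations(ds)
  n <- sum(ds$trials$subject %in% ds$trials$subject)  # all trials
  p_hat <- ff$proportions["left_first", "prop"]
  # generated with P(left first) = 0.693
  expect_lt(abs(p_hat - 0.693), 3 * sqrt(0.693 * 0.307 / 360))
  # no OV dependence was generated
  expect_lt(abs(ff$left_first$coefficients["ov"]),
            2 * ff$left_first$se["ov"])
  expect_lt(abs(ff$left_first$coefficients["ov:fef"]),
            2 * ff$left_first$se["ov:fef"])
  # first gaze is value-blind by construction
  expect_lt(abs(ff$proportions["best_first", "prop"] - 0.5), 0.08)
})

test_that("dwell regressions see the generated duration structure", {
  ds <- generate_dataset(tiny_config(seed = 6))
  fits <- analyze_dwells(ds)
  expect_named(fits, c("first", "middle", "last"))
  fx <- ds$fixations
  expect_gt(mean(fx$duration_ms[fx$ordinal_class == "middle"]),
            mean(fx$duration_ms[fx$ordinal_class == "first"]))
  # no group effect generated: stimulation terms within 2 SE of zero
  for (cl in names(fits)) {
    co <- fits[[cl]]$coefficients["fef"]
    expect_lt(abs(co), 2.5 * fits[[cl]]$se["fef"])
  }
  # doubling durations shifts only the intercept, by log 2
  ds2 <- ds
  ds2$fixations$duration_ms <- 2 * ds2$fixations$duration_ms
  f2 <- analyze_dwells(ds2)
  expect_equal(f2$first$coefficients["(Intercept)"] -
                 fits$first$coefficients["(Intercept)"],
               c(`(Intercept)` = log(2)), tolerance = 1e-8)
  expect_equal(f2$first$coefficients[-1], fits$first$coefficients[-1],
               tolerance = 1e-8)
})

test_that("choice model sees the dwell-advantage effect and null groups", {
  # equal theta across groups: triple interaction consistent with zero
  ds0 <- generate_dataset(experiment_config(n_fef = 5, n_vertex = 5,
                                            n_trials = 80, n_items = 60,
                                            theta_fef = 0.7,
                                            theta_vertex = 0.7,
                                            seed = 14))
  f0 <- analyze_choice(ds0)
  tri <- grep("fef:ov:dwell_adv", names(f0$coefficients), value = TRUE)
  expect_length(tri, 1)
  expect_lt(abs(f0$coefficients[tri]), 2.5 * f0$se[tri])
  # theta < 1: positive dwell-advantage main effect
  expect_gt(f0$coefficients["dwell_adv"], 0)
  # robustness variants run and keep the dwell-advantage terms
  expect_s3_class(analyze_choice(ds0, "vd"), "clustered_fit")
  expect_s3_class(analyze_choice(ds0, "trial"), "clustered_fit")
  # with a strong left-first bias most (possibly all) subjects are
  # left-biased; empty splits are dropped
  bs <- analyze_choice(ds0, "bias_split")
  expect_true(all(names(bs) %in% c("left_bias", "right_bias")))
  expect_gte(length(bs), 1)
  expect_s3_class(bs[[1]], "clustered_fit")
})

test_that("RT analysis reports medians, paired tests and K-S table", {
  ds <- generate_dataset(tiny_config(seed = 15))
  rt <- analyze_rt(ds)
  expect_setequal(unique(rt$medians$ov_condition), c("low", "high"))
  expect_identical(nrow(rt$paired_t), 2L)
  expect_identical(nrow(rt$ks), 4L)
  expect_true(all(rt$ks$D >= 0 & rt$ks$D <= 1))
  # strong-discount data: high-OV trials are faster
  ds2 <- generate_dataset(experiment_config(n_fef = 4, n_vertex = 4,
                                            n_trials = 80, n_items = 60,
                                            theta_fef = 0.3,
                                            theta_vertex = 0.3,
                                            seed = 16))
  med <- analyze_rt(ds2)$medians
  expect_lt(mean(med$rt_s[med$ov_condition == "high"]),
            mean(med$rt_s[med$ov_condition == "low"]))
})

test_that("quintile binning matches a brute-force quantile oracle", {
  # hand-built 10-trial toy subject
  adv <- c(-0.9, -0.7, -0.4, -0.2, -0.05, 0.05, 0.2, 0.4, 0.7, 0.9)
  bins <- gazeddm:::quintile_bin(adv)
  expect_identical(bins, rep(-2:2, each = 2L))
  # midpoint-rank tie-break
  expect_identical(gazeddm:::quintile_bin(rep(0, 5)),
                   rep(0L, 5))
  ds <- generate_dataset(tiny_config(seed = 18))
  qc <- dwell_quintile_curve(ds)
  expect_true(all(qc$quintile %in% -2:2))
  expect_true(all(qc$p_left >= 0 & qc$p_left <= 1))
})

test_that("strong gaze discount yields a rising quintile curve", {
  ds <- generate_dataset(experiment_config(n_fef = 6, n_vertex = 6,
                                           n_trials = 100, n_items = 60,
                                           theta_fef = 0.3,
                                           theta_vertex = 0.3,
                                           seed = 19))
  qc <- dwell_quintile_curve(ds)
  hi <- qc[qc$ov_condition == "high", ]
  hi <- aggregate(p_left ~ quintile, hi, mean)
  expect_gt(hi$p_left[hi$quintile == 2], hi$p_left[hi$quintile == -2])
  # rank correlation of the pooled curve is strongly positive
  expect_gt(cor(hi$quintile, hi$p_left, method = "spearman"), 0.8)
})
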