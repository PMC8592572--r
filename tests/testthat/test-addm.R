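test_that("instantaneous drift matches the update rule", {
  d53 <- trial_design(5, 3)
  expect_equal(drift_at("left", d53, addm_params(d = 1, theta = 0.3)),
               4.1)
  # theta = 1 removes the fixation dependence
  p1 <- addm_params(d = 1, theta = 1)
  expect_equal(drift_at("left", d53, p1), 2)
  expect_equal(drift_at("right", d53, p1), 2)
  # theta = 0 ignores the unfixated item completely
  expect_equal(drift_at("right", d53, addm_params(d = 1, theta = 0)),
               -3)
  expect_error(drift_at("up", d53, p1), "left")
})

test_that("rescaling ratings and 1/d leaves drift bit-identical", {
  # halving ratings while doubling d (exact powers of two) must give
  # the identical floating-point drift: drift depends on d*r products
  p <- addm_params(d = 2e-4, theta = 0.37)
  p_double <- addm_params(d = 4e-4, theta = 0.37)
  for (r in list(c(5, 3), c(2, 2), c(8, 7))) {
    expect_identical(
      drift_at(c("left", "right"), trial_design(r[1] / 2, r[2] / 2),
               p_double),
      drift_at(c("left", "right"), trial_design(r[1], r[2]), p))
  }
})

test_that("noiseless constant drift crosses at the deterministic time", {
  p <- addm_params(d = 0.001, theta = 1, sigma = 0)
  for (i in 1:3) {
    tr <- simulate_trial(trial_design(2, 1), p, fixation_stream())
    expect_identical(tr$choice, "left")
    expect_identical(tr$decision_time, 1000L)
    expect_equal(sum(tr$fixations$duration), 1000)
  }
})

test_that("realized fixations account exactly for the decision time", {
  set.seed(7)
  p <- addm_params(theta = 0.3)
  sims <- sim_trials(50, trial_design(8, 7), p, fixation_stream())
  for (tr in sims) {
    expect_equal(sum(tr$fixations$duration), tr$decision_time)
    expect_true(all(tr$fixations$duration > 0))
    locs <- tr$fixations$location
    if (length(locs) > 1)
      expect_true(all(locs[-1] != locs[-length(locs)]))
    expect_identical(tr$fixations$ordinal_class,
                     dwell_ordinal_class(nrow(tr$fixations)))
  }
})

test_that("equal values with symmetric gaze give unbiased choices", {
  set.seed(11)
  n <- 2500
  sims <- sim_trials(n, trial_design(5, 5), addm_params(theta = 1),
                     fixation_stream(p_left_first = 0.5))
  p_left <- mean(vapply(sims, `[[`, "", "choice") == "left")
  expect_lt(abs(p_left - 0.5), 3 * sqrt(0.25 / n))
})

test_that("with theta = 1 the model collapses to a plain DDM", {
  # alternating-gaze aDDM vs a single-fixation accumulator with the
  # same net drift: choice frequencies agree within 3 MC SEs
  set.seed(13)
  n <- 2500
  p <- addm_params(theta = 1)
  des <- trial_design(3, 2)
  alt <- sim_trials(n, des, p, fixation_stream(p_left_first = 0.5))
  const_src <- function(total_ms)
    data.frame(location = "left", duration = total_ms + 1)
  con <- sim_trials(n, des, p, const_src)
  pa <- mean(vapply(alt, `[[`, "", "choice") == "left")
  pc <- mean(vapply(con, `[[`, "", "choice") == "left")
  se <- sqrt(pa * (1 - pa) / n + pc * (1 - pc) / n)
  expect_lt(abs(pa - pc), 3 * se)
})

test_that("mirrored designs swap choice frequencies", {
  set.seed(17)
  n <- 2000
  p <- addm_params(theta = 0.5)
  a <- sim_trials(n, trial_design(8, 7), p,
                  fixation_stream(p_left_first = 0.7))
  b <- sim_trials(n, trial_design(7, 8), p,
                  fixation_stream(p_left_first = 0.3))
  pa <- mean(vapply(a, `[[`, "", "choice") == "left")
  pb <- mean(vapply(b, `[[`, "", "choice") == "right")
  se <- sqrt(pa * (1 - pa) / n + pb * (1 - pb) / n)
  expect_lt(abs(pa - pb), 3 * se)
})

test_that("stronger fixed-gaze drift speeds decisions", {
  set.seed(19)
  const_src <- function(total_ms)
    data.frame(location = "left", duration = total_ms + 1)
  mean_dt <- vapply(list(c(5, 5), c(7, 4), c(9, 1)), function(r) {
    sims <- sim_trials(800, trial_design(r[1], r[2]),
                       addm_params(theta = 0.5), const_src)
    mean(vapply(sims, `[[`, 0L, "decision_time"))
  }, numeric(1))
  # |r_left - theta r_right| = 2.5, 5, 8.5: monotone speed-up
  expect_true(all(diff(mean_dt) < 0))
})

test_that("value-condition contrasts shrink as the gaze discount weakens", {
  set.seed(23)
  tab <- simulate_fig_conditions(theta_values = c(0.3, 0.5), n = 700)
  expect_setequal(names(tab), c("theta", "ov_condition", "mean_rt_ms",
                                "p_choose_longest", "n"))
  gap <- function(th, col) {
    x <- tab[tab$theta == th, ]
    x[x$ov_condition == "low", col] - x[x$ov_condition == "high", col]
  }
  # high OV is faster and more gaze-coupled, more so at low theta
  expect_gt(gap(0.3, "mean_rt_ms"), 0)
  expect_gt(gap(0.3, "mean_rt_ms"), gap(0.5, "mean_rt_ms"))
  expect_gt(abs(gap(0.3, "p_choose_longest")),
            abs(gap(0.5, "p_choose_longest")))
})

test_that("without a gaze discount the choice-gaze coupling vanishes", {
  set.seed(29)
  tab <- simulate_fig_conditions(theta_values = 1, n = 800)
  expect_true(all(abs(tab$p_choose_longest - 0.5) < 0.06))
})

test_that("summaries are stable across seeds within Monte-Carlo error", {
  run <- function(seed) {
    set.seed(seed)
    simulate_fig_conditions(theta_values = 0.3,
                            designs = list(high = trial_design(8, 8,
                                                               "high")),
                            n = 600)
  }
  a <- run(101); b <- run(202)
  # ~3 MC SEs for a binomial proportion at n = 600
  expect_lt(abs(a$p_choose_longest - b$p_choose_longest),
            3 * sqrt(0.5^2 / 600 * 2))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(addm_params(theta = 1.2), "theta")
  expect_error(addm_params(d = 0))
  expect_error(trial_design(11, 3))
  expect_error(trial_design(5, 3, check_vd = TRUE), "-1, 0 or")
})
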