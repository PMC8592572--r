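#' Configuration of a synthetic two-condition experiment
#'
#' Defaults emulate the study design the analyses assume: 45 subjects
#' split 23 (stimulation, "FEF") / 22 (control, "vertex"), 180 binary
#' choices per subject among 148 rated food items, value differences
#' constrained to \{-1, 0, +1\}, trials split between low and high
#' overall-value conditions, a strong left-first fixation bias
#' (69.3%), first dwells shorter than middle dwells, and
#' choices/RTs generated by the aDDM with group-specific gaze
#' discounts (vertex 0.744, FEF 0.902). Non-decision time is drawn per
#' subject from a truncated normal anchored to fitted group values
#' (~0.68 s).
#'
#' @param n_fef,n_vertex Subjects per group.
#' @param n_trials Trials per subject (split evenly across OV
#'   conditions).
#' @param n_items Number of rated items.
#' @param theta_fef,theta_vertex Group gaze-discount parameters.
#' @param d,sigma aDDM simulator parameters (per ms).
#' @param p_left_first Probability the first fixation is on the left.
#' @param first_mean,first_shape,mid_mean,mid_shape Gamma dwell-duration
#'   parameters (ms) for first and middle dwells.
#' @param ter_mean,ter_sd,ter_min Subject-level non-decision time
#'   distribution (seconds), normal truncated below at `ter_min`.
#' @param seed Integer seed for [generate_dataset()].
#' @param max_ms Per-trial simulation cap, ms.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_fef = 23, n_vertex = 22, n_trials = 180,
                              n_items = 148,
                              theta_fef = 0.902, theta_vertex = 0.744,
                              d = 2e-4, sigma = 0.02,
                              p_left_first = 0.693,
                              first_mean = 400, first_shape = 3,
                              mid_mean = 650, mid_shape = 3,
                              ter_mean = 0.68, ter_sd = 0.08,
                              ter_min = 0.2,
                              seed = 1L, max_ms = 20000) {
  stopifnot(n_fef >= 0, n_vertex >= 0, n_fef + n_vertex >= 1,
            n_trials >= 2, n_items >= 20,
            theta_fef >= 0, theta_fef <= 1,
            theta_vertex >= 0, theta_vertex <= 1,
            d > 0, sigma >= 0,
            p_left_first >= 0, p_left_first <= 1,
            first_mean > 0, mid_mean > 0, first_shape > 0, mid_shape > 0,
            ter_mean > 0, ter_sd >= 0, ter_min >= 0)
  structure(as.list(environment()), class = "experiment_config")
}

#' Alternating fixation-dwell generator
#'
#' Returns a generator function for the dwell schedule of one trial:
#' the first fixation lands left with probability `p_left_first`,
#' locations strictly alternate thereafter, the first dwell is drawn
#' from a gamma with a shorter mean than subsequent (middle) dwells.
#' Calling the generator with a total duration (ms) yields a
#' data.frame (`location`, `duration`) covering at least that span.
#'
#' @inheritParams experiment_config
#' @return A function `function(total_ms)` suitable as the
#'   `fixation_source` of [simulate_trial()].
#' @export
fixation_stream <- function(p_left_first = 0.693,
                            first_mean = 400, first_shape = 3,
                            mid_mean = 650, mid_shape = 3) {
  force(p_left_first)
  function(total_ms) {
    # expected dwell count plus slack; extend if a draw runs short
    n_guess <- max(4L, ceiling(total_ms / mid_mean * 1.5))
    repeat {
      dur <- c(rgamma(1, shape = first_shape,
                      scale = first_mean / first_shape),
               rgamma(n_guess - 1, shape = mid_shape,
                      scale = mid_mean / mid_shape))
      dur <- pmax(1, round(dur))
      if (sum(dur) >= total_ms) break
      n_guess <- n_guess * 2L
    }
    first_left <- runif(1) < p_left_first
    loc <- rep(c("left", "right"), length.out = length(dur))
    if (!first_left) loc <- rep(c("right", "left"), length.out = length(dur))
    data.frame(location = loc, duration = dur)
  }
}

#' Generate a rated item set
#'
#' Integer ratings on the 0-10 scale in two value pools: a low pool
#' (ratings 1-4) and a high pool (ratings 7-10), so that both
#' overall-value conditions can be populated with value differences in
#' \{-1, 0, +1\} and the pools never overlap in overall value.
#'
#' @param config An [experiment_config()].
#' @return data.frame with columns `item`, `rating`, `pool`.
#' @export
generate_items <- function(config = experiment_config()) {
  n <- config$n_items
  stopifnot(n >= 20)
  n_low <- floor(n / 2)
  n_high <- n - n_low
  ratings <- c(sample(1:4, n_low, replace = TRUE),
               sample(7:10, n_high, replace = TRUE))
  pool <- rep(c("low", "high"), c(n_low, n_high))
  # every rating level must be represented so all VD pairs are feasible
  for (p in c("low", "high")) {
    lv <- if (p == "low") 1:4 else 7:10
    miss <- setdiff(lv, ratings[pool == p])
    if (length(miss)) {
      idx <- which(pool == p)[seq_along(miss)]
      ratings[idx] <- miss
    }
  }
  data.frame(item = seq_len(n), rating = ratings, pool = pool)
}

#' Build a subject's trial designs
#'
#' Draws `n_trials` designs, half from the low-value pool and half from
#' the high-value pool, with the left-minus-right rating difference
#' sampled uniformly from \{-1, 0, +1\} and left/right assignment
#' randomized.
#'
#' @param ratings Item table from [generate_items()].
#' @param config An [experiment_config()].
#' @return data.frame with columns `r_left`, `r_right`, `ov_condition`,
#'   `vd`.
#' @export
build_trials <- function(ratings, config = experiment_config()) {
  n <- config$n_trials
  n_low <- floor(n / 2)
  one_pool <- function(pool, m) {
    avail <- sort(unique(ratings$rating[ratings$pool == pool]))
    if (length(avail) < 2)
      stop("pool '", pool, "' has fewer than 2 distinct ratings; ",
           "cannot satisfy the value-difference constraint")
    vd <- sample(c(-1L, 0L, 1L), m, replace = TRUE)
    r_left <- integer(m)
    r_right <- integer(m)
    for (i in seq_len(m)) {
      ok <- avail[(avail + vd[i]) %in% avail]
      if (!length(ok))
        stop("no rating pair with difference ", vd[i], " in pool '",
             pool, "'")
      r_right[i] <- if (length(ok) == 1) ok else sample(ok, 1)
      r_left[i] <- r_right[i] + vd[i]
    }
    data.frame(r_left = r_left, r_right = r_right,
               ov_condition = pool, vd = vd)
  }
  out <- rbind(one_pool("low", n_low), one_pool("high", n - n_low))
  out[sample(nrow(out)), , drop = FALSE]
}

#' Generate a complete synthetic experiment
#'
#' For each subject: draw a non-decision time, build trial designs,
#' simulate every trial with the aDDM at the subject's group gaze
#' discount, and assemble tidy trial and fixation tables with the same
#' schema the ingestion functions consume. Trials that fail to reach a
#' boundary within the cap are re-drawn (up to 10 times each).
#'
#' @param config An [experiment_config()]; `config$seed` seeds all
#'   randomness, so equal configurations yield identical tables.
#' @return An object of class `gaze_dataset`: list with `trials`
#'   (subject, group, trial, r_left, r_right, ov_condition, vd, choice,
#'   rt_s, g_left, g_right, dwell_advantage_s), `fixations` (subject,
#'   trial, index, location, duration_ms, ordinal_class), `exclusions`
#'   (empty), and `provenance`.
#' @export
generate_dataset <- function(config = experiment_config()) {
  set.seed(config$seed)
  items <- generate_items(config)
  groups <- rep(c("fef", "vertex"), c(config$n_fef, config$n_vertex))
  fs <- fixation_stream(config$p_left_first, config$first_mean,
                        config$first_shape, config$mid_mean,
                        config$mid_shape)
  trial_rows <- vector("list", length(groups))
  fix_rows <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    grp <- groups[s]
    theta <- if (grp == "fef") config$theta_fef else config$theta_vertex
    pars <- addm_params(d = config$d, theta = theta,
                        sigma = config$sigma)
    ter <- rnorm_trunc(1, config$ter_mean, config$ter_sd, config$ter_min)
    des <- build_trials(items, config)
    n <- nrow(des)
    tr <- data.frame(subject = s, group = grp, trial = seq_len(n),
                     r_left = des$r_left, r_right = des$r_right,
                     ov_condition = des$ov_condition, vd = des$vd,
                     choice = NA_character_, rt_s = NA_real_,
                     g_left = NA_real_, g_right = NA_real_,
                     dwell_advantage_s = NA_real_)
    fx_list <- vector("list", n)
    for (i in seq_len(n)) {
      dsn <- trial_design(des$r_left[i], des$r_right[i],
                          des$ov_condition[i])
      sim <- NULL
      for (try in 1:10) {
        sim <- tryCatch(simulate_trial(dsn, pars, fs,
                                       max_ms = config$max_ms),
                        error = function(e) NULL)
        if (!is.null(sim)) break
      }
      if (is.null(sim))
        stop("trial simulation timed out 10 times (subject ", s,
             ", trial ", i, "); degenerate configuration?")
      dl <- sum(sim$fixations$duration[sim$fixations$location == "left"])
      dtot <- sim$decision_time
      tr$choice[i] <- sim$choice
      tr$rt_s[i] <- dtot / 1000 + ter
      tr$g_left[i] <- dl / dtot
      tr$g_right[i] <- 1 - dl / dtot
      tr$dwell_advantage_s[i] <- (2 * dl - dtot) / 1000
      fx_list[[i]] <- data.frame(subject = s, trial = i,
                                 index = seq_len(nrow(sim$fixations)),
                                 location = sim$fixations$location,
                                 duration_ms = sim$fixations$duration,
                                 ordinal_class =
                                   sim$fixations$ordinal_class)
    }
    trial_rows[[s]] <- tr
    fix_rows[[s]] <- do.call(rbind, fx_list)
  }
  trials <- do.call(rbind, trial_rows)
  fixations <- do.call(rbind, fix_rows)
  rownames(trials) <- rownames(fixations) <- NULL
  new_gaze_dataset(trials, fixations,
                   exclusions = trials[0, c("subject", "trial")],
                   provenance = list(source = "synthetic",
                                     seed = config$seed,
                                     config_hash = config_hash(config)))
}

rnorm_trunc <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- out < lower
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower)
}

config_hash <- function(config) {
  x <- unlist(config[order(names(config))])
  # cheap order-stable checksum; only used to tag provenance
  sum(utf8ToInt(paste(names(x), format(x, digits = 12), collapse = ";"))) %%
    1e9
}

#' Generate data directly from the fitted diffusion model
#'
#' Estimation-side counterpart of [generate_dataset()]: subject
#' parameters `(a, z, Ter, b0..b3)` are drawn from group-level normal
#' distributions, per-trial drifts follow the gaze-weighted
#' regression, and choices/RTs are simulated from the constant-drift
#' diffusion (Euler with continuity correction), with a 5% uniform
#' outlier admixture matching the fitted model. Used for parameter
#' recovery studies of [fit_subject_mle()] and [fit_hierarchical()].
#'
#' @param n_subjects,n_trials Design size.
#' @param group_mu,group_tau Length-7 numeric (a, z, ter, b0..b3):
#'   group-level means and SDs of the subject parameters.
#' @param p_outlier Outlier admixture rate; outlier RTs are uniform on
#'   the simulated RT range with random choices.
#' @param seed Integer seed.
#' @param dt Euler step, seconds.
#' @return A `gaze_dataset` whose trial table carries ratings and gaze
#'   fractions (fixation table contains one synthetic dwell pair per
#'   trial consistent with the gaze fractions), plus attribute
#'   `truth` (the subject-parameter matrix).
#' @export
generate_ddm_dataset <- function(n_subjects = 20, n_trials = 200,
                                 group_mu = c(a = 2, z = 0.5,
                                              ter = 0.4, b0 = 0.1,
                                              b1 = 0.3, b2 = 0.2,
                                              b3 = 0.5),
                                 group_tau = c(a = 0.2, z = 0.03,
                                               ter = 0.05, b0 = 0.1,
                                               b1 = 0.05, b2 = 0.05,
                                               b3 = 0.15),
                                 p_outlier = 0.05, seed = 1,
                                 dt = 1e-3) {
  stopifnot(length(group_mu) == 7, length(group_tau) == 7)
  set.seed(seed)
  truth <- matrix(NA_real_, n_subjects, 7,
                  dimnames = list(NULL, hier_par_names))
  trial_rows <- vector("list", n_subjects)
  fix_rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    repeat {
      phi <- rnorm(7, group_mu, group_tau)
      if (phi[1] > 0.3 && phi[2] > 0.1 && phi[2] < 0.9 && phi[3] > 0.05)
        break
    }
    truth[s, ] <- phi
    r_right <- sample(c(1:4, 7:10), n_trials, replace = TRUE)
    vd <- sample(c(-1L, 0L, 1L), n_trials, replace = TRUE)
    r_left <- pmin(pmax(r_right + vd, 0), 10)
    g_left <- rbeta(n_trials, 2, 2)
    X <- build_drift_regressors(r_left, r_right, g_left, 1 - g_left)
    v <- phi[4] + X %*% phi[5:7]
    sim <- simulate_ddm(n_trials, as.numeric(v), phi[1], phi[2], dt = dt)
    cens <- is.na(sim$upper)
    sim$upper[cens] <- rbinom(sum(cens), 1, 0.5)
    rt <- sim$rt + phi[3]
    out <- runif(n_trials) < p_outlier
    if (any(out)) {
      rt[out] <- runif(sum(out), min(rt), max(rt))
      sim$upper[out] <- rbinom(sum(out), 1, 0.5)
    }
    dtot_ms <- pmax(round(1000 * (rt - phi[3])), 2)
    dl <- pmin(pmax(round(g_left * dtot_ms), 1), dtot_ms - 1)
    tr <- data.frame(subject = s,
                     group = if (s <= ceiling(n_subjects / 2)) "fef"
                             else "vertex",
                     trial = seq_len(n_trials), r_left = r_left,
                     r_right = r_right,
                     ov_condition = ifelse(r_right >= 5, "high", "low"),
                     vd = r_left - r_right,
                     choice = ifelse(sim$upper == 1, "left", "right"),
                     rt_s = rt, g_left = dl / dtot_ms,
                     g_right = 1 - dl / dtot_ms,
                     dwell_advantage_s = (2 * dl - dtot_ms) / 1000)
    fix_rows[[s]] <- data.frame(
      subject = s, trial = rep(seq_len(n_trials), each = 2),
      index = rep(1:2, n_trials),
      location = as.vector(rbind("left", "right")),
      duration_ms = as.vector(rbind(dl, dtot_ms - dl)),
      ordinal_class = rep(c("first", "last"), n_trials))
    trial_rows[[s]] <- tr
  }
  trials <- do.call(rbind, trial_rows)
  fixations <- do.call(rbind, fix_rows)
  ds <- new_gaze_dataset(trials, fixations,
                         exclusions = trials[0, c("subject", "trial")],
                         provenance = list(source = "synthetic-ddm",
                                           seed = seed))
  attr(ds, "truth") <- truth
  ds
}
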