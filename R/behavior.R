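#' Regression with cluster-robust standard errors
#'
#' Logistic (IRLS via [stats::glm()]) or linear regression with
#' sandwich standard errors clustered on subjects, including the
#' standard small-sample cluster correction (CR1). Mirrors the common
#' robustness strategy for repeated observations per subject when
#' mixed-effects models are unstable.
#'
#' @param formula Model formula.
#' @param data data.frame with one row per observation.
#' @param family `"logistic"` or `"linear"`.
#' @param cluster Cluster identifiers (normally subjects), length
#'   `nrow(data)`, or the name of a column of `data`.
#' @return Object of class `clustered_fit`: `coefficients`, `se`
#'   (cluster-robust), `ci95` (normal approximation), `p` (two-sided),
#'   `n_obs`, `n_clusters`, `model_spec`, and the underlying `fit`.
#' @export
fit_glm_clustered <- function(formula, data,
                              family = c("logistic", "linear"),
                              cluster) {
  family <- match.arg(family)
  if (is.character(cluster) && length(cluster) == 1)
    cluster <- data[[cluster]]
  stopifnot(length(cluster) == nrow(data))
  fam <- if (family == "logistic") binomial() else gaussian()
  fit <- suppressWarnings(glm(formula, data = data, family = fam))
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (family == "logistic" &&
      (!fit$converged || any(abs(coef(fit)) > 15)))
    stop("perfect (or quasi-perfect) separation detected: ",
         "coefficients diverged")
  vc <- sandwich::vcovCL(fit, cluster = cluster, type = "HC1",
                         cadjust = TRUE)
  est <- coef(fit)
  se <- sqrt(diag(vc))
  z <- est / se
  structure(list(coefficients = est, se = se,
                 ci95 = cbind(lower = est - 1.96 * se,
                              upper = est + 1.96 * se),
                 p = 2 * pnorm(-abs(z)),
                 n_obs = nrow(data),
                 n_clusters = length(unique(cluster)),
                 model_spec = paste(family, "regression:",
                                    deparse(formula)),
                 fit = fit),
            class = "clustered_fit")
}

#' @export
print.clustered_fit <- function(x, ...) {
  cat("<clustered_fit>", x$model_spec, "\n  n =", x$n_obs,
      "obs in", x$n_clusters, "clusters\n")
  print(data.frame(estimate = round(x$coefficients, 4),
                   se = round(x$se, 4),
                   p = signif(x$p, 3)))
  invisible(x)
}

#' Tidy a clustered fit into a coefficient table
#'
#' @param x A `clustered_fit`.
#' @return data.frame with `term`, `estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `p`.
#' @export
tidy_clustered <- function(x) {
  data.frame(term = names(x$coefficients),
             estimate = unname(x$coefficients), se = unname(x$se),
             ci_lower = unname(x$ci95[, "lower"]),
             ci_upper = unname(x$ci95[, "upper"]),
             p = unname(x$p), row.names = NULL)
}

# trial table augmented with first-fixation info and standard codings:
# ov (high = 1), fef (stimulation group = 1), choice_left
augment_trials <- function(dataset) {
  tr <- dataset$trials
  fx <- dataset$fixations
  first <- fx[fx$index == 1, c("subject", "trial", "location")]
  key <- paste(tr$subject, tr$trial)
  tr$first_loc <- first$location[match(key, paste(first$subject,
                                                  first$trial))]
  tr$left_first <- as.integer(tr$first_loc == "left")
  tr$ov <- as.integer(tr$ov_condition == "high")
  tr$fef <- as.integer(tolower(tr$group) %in% c("fef", "stim",
                                                "stimulation"))
  tr$choice_left <- as.integer(tr$choice == "left")
  tr
}

#' First-fixation analyses
#'
#' Two clustered logistic regressions on trial-level first fixations:
#' (1) probability of looking left first as a function of the
#' overall-value condition interacted with stimulation group; (2)
#' probability of looking first at the higher-rated item (trials with
#' tied ratings excluded), same design. Raw proportions with
#' subject-level 95% CIs are also returned.
#'
#' @param dataset A `gaze_dataset` whose fixation table has `index`.
#' @return List with `left_first`, `best_first` (`clustered_fit`s) and
#'   `proportions` (left-first and best-first rates with CIs).
#' @export
analyze_first_fixations <- function(dataset) {
  tr <- augment_trials(dataset)
  if (anyNA(tr$first_loc))
    stop("trials without a first item fixation present; exclude upstream")
  m1 <- fit_glm_clustered(left_first ~ ov * fef, tr, "logistic",
                          tr$subject)
  trb <- tr[tr$vd != 0, ]
  trb$best_first <- as.integer((trb$first_loc == "left") ==
                                 (trb$vd > 0))
  m2 <- fit_glm_clustered(best_first ~ ov * fef, trb, "logistic",
                          trb$subject)
  prop_ci <- function(x, id) {
    per <- tapply(x, id, mean)
    m <- mean(per)
    half <- 1.96 * sd(per) / sqrt(length(per))
    c(prop = m, lower = m - half, upper = m + half)
  }
  list(left_first = m1, best_first = m2,
       proportions = rbind(
         left_first = prop_ci(tr$left_first, tr$subject),
         best_first = prop_ci(trb$best_first, trb$subject)))
}

#' Dwell-duration regressions by ordinal class
#'
#' For first, middle and last dwells separately, regresses log dwell
#' time on stimulation group, fixation position, overall-value
#' condition and value difference, all interacted, with SEs clustered
#' on subjects.
#'
#' @param dataset A `gaze_dataset`.
#' @return Named list of `clustered_fit`s (`first`, `middle`, `last`).
#' @export
analyze_dwells <- function(dataset) {
  tr <- augment_trials(dataset)
  fx <- dataset$fixations
  if (any(fx$duration_ms <= 0)) stop("non-positive dwell durations")
  key <- paste(fx$subject, fx$trial)
  tkey <- paste(tr$subject, tr$trial)
  idx <- match(key, tkey)
  d <- data.frame(subject = fx$subject,
                  log_dur = log(fx$duration_ms),
                  left = as.integer(fx$location == "left"),
                  ov = tr$ov[idx], vd = tr$vd[idx], fef = tr$fef[idx],
                  ordinal_class = fx$ordinal_class)
  out <- lapply(c(first = "first", middle = "middle", last = "last"),
                function(cl) {
                  di <- d[d$ordinal_class == cl, ]
                  fit_glm_clustered(log_dur ~ fef * left * ov * vd, di,
                                    "linear", di$subject)
                })
  out
}

#' Choice regression with the gaze-by-value interaction
#'
#' Clustered logistic regression of choosing the left item on value
#' difference plus the stimulation-group x overall-value x
#' dwell-time-advantage interaction. The triple interaction is the
#' quantity of interest: a negative coefficient means the stimulation
#' group's gaze effect grows less from low- to high-value trials,
#' i.e. a weakened multiplicative effect of gaze. Robustness variants:
#' `"vd"` adds value-difference x group x dwell-advantage
#' interactions, `"trial"` adds trial-number interactions, `"bias_split"`
#' fits the base model separately on left- and right-bias subjects
#' (bias = majority first-fixation side).
#'
#' @param dataset A `gaze_dataset`.
#' @param robustness `"none"`, `"vd"`, `"trial"` or `"bias_split"`.
#' @return A `clustered_fit`, or for `"bias_split"` a list of two.
#' @export
analyze_choice <- function(dataset,
                           robustness = c("none", "vd", "trial",
                                          "bias_split")) {
  robustness <- match.arg(robustness)
  tr <- augment_trials(dataset)
  tr$dwell_adv <- tr$dwell_advantage_s
  base <- choice_left ~ vd + fef * ov * dwell_adv
  if (robustness == "none")
    return(fit_glm_clustered(base, tr, "logistic", tr$subject))
  if (robustness == "vd")
    return(fit_glm_clustered(
      choice_left ~ fef * ov * dwell_adv + vd * fef * dwell_adv, tr,
      "logistic", tr$subject))
  if (robustness == "trial") {
    tr$trial_c <- as.numeric(scale(tr$trial))
    return(fit_glm_clustered(
      choice_left ~ vd + fef * ov * dwell_adv * trial_c, tr,
      "logistic", tr$subject))
  }
  per <- tapply(tr$left_first, tr$subject, mean)
  left_biased <- names(per)[per >= 0.5]
  splits <- list(left_bias = tr[tr$subject %in% left_biased, ],
                 right_bias = tr[!tr$subject %in% left_biased, ])
  splits <- splits[vapply(splits, nrow, 0L) > 0]
  lapply(splits,
         function(d) fit_glm_clustered(base, d, "logistic", d$subject))
}

#' Response-time analyses
#'
#' Per-subject median RTs by overall-value condition with paired
#' t-tests within each group, a clustered linear regression of log RT
#' on absolute value difference plus the group x overall-value
#' interaction, and the four pooled two-sample K-S comparisons
#' (between groups within each OV condition; between OV conditions
#' within each group).
#'
#' @param dataset A `gaze_dataset`.
#' @return List with `medians` (per subject x condition), `paired_t`
#'   (per group), `log_rt_fit` (`clustered_fit`) and `ks`
#'   (data.frame of the four comparisons).
#' @export
analyze_rt <- function(dataset) {
  tr <- augment_trials(dataset)
  stopifnot(all(tr$rt_s > 0))
  med <- aggregate(rt_s ~ subject + group + ov_condition, tr, median)
  paired <- lapply(split(med, med$group), function(d) {
    w <- merge(d[d$ov_condition == "high", c("subject", "rt_s")],
               d[d$ov_condition == "low", c("subject", "rt_s")],
               by = "subject", suffixes = c("_high", "_low"))
    dropped <- setdiff(unique(d$subject), w$subject)
    if (length(dropped))
      warning("subject(s) missing an OV condition dropped from the ",
              "paired test: ", paste(dropped, collapse = ", "))
    tt <- t.test(w$rt_s_high, w$rt_s_low, paired = TRUE)
    data.frame(group = d$group[1], n = nrow(w),
               mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  tr$abs_vd <- abs(tr$vd)
  fit <- fit_glm_clustered(log(rt_s) ~ abs_vd + fef * ov, tr, "linear",
                           tr$subject)
  ks <- rbind(
    cbind(comparison = "groups_low_ov",
          as.data.frame(ks_two_sample(tr$rt_s[tr$fef == 1 & tr$ov == 0],
                                      tr$rt_s[tr$fef == 0 & tr$ov == 0]))),
    cbind(comparison = "groups_high_ov",
          as.data.frame(ks_two_sample(tr$rt_s[tr$fef == 1 & tr$ov == 1],
                                      tr$rt_s[tr$fef == 0 & tr$ov == 1]))),
    cbind(comparison = "ov_within_fef",
          as.data.frame(ks_two_sample(tr$rt_s[tr$fef == 1 & tr$ov == 1],
                                      tr$rt_s[tr$fef == 1 & tr$ov == 0]))),
    cbind(comparison = "ov_within_vertex",
          as.data.frame(ks_two_sample(tr$rt_s[tr$fef == 0 & tr$ov == 1],
                                      tr$rt_s[tr$fef == 0 & tr$ov == 0]))))
  list(medians = med, paired_t = do.call(rbind, paired),
       log_rt_fit = fit, ks = ks)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the sup-norm distance between the two empirical
#' CDFs; the p-value uses the asymptotic Kolmogorov distribution with
#' effective sample size `n1 * n2 / (n1 + n2)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return List of class `ks_result`: `D`, `p`, `n1`, `n2`.
#' @export
#' @examples
#' ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))  # D = 1/3
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(q) mean(x <= q), numeric(1))
  Fy <- vapply(pts, function(q) mean(y <= q), numeric(1))
  D <- max(abs(Fx - Fy))
  p <- suppressWarnings(ks.test(x, y, exact = FALSE)$p.value)
  structure(list(D = D, p = p, n1 = n1, n2 = n2), class = "ks_result")
}

#' @export
as.data.frame.ks_result <- function(x, ...) {
  data.frame(D = x$D, p = x$p, n1 = x$n1, n2 = x$n2)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("K-S two-sample: D = %.4f, p = %.4g (n = %d, %d)\n",
              x$D, x$p, x$n1, x$n2))
  invisible(x)
}

#' Choice probability by dwell-advantage quintile
#'
#' Bins each subject's trials into dwell-time-advantage quintiles
#' (labels -2..+2; 0 holds trials where the two items received similar
#' dwell; ties broken by midpoint rank), then averages the probability
#' of choosing the left item per group x OV-condition x quintile cell,
#' with subject-level SEM.
#'
#' @param dataset A `gaze_dataset`.
#' @param min_trials Minimum trials per subject per condition cell;
#'   subjects below it are skipped with a warning.
#' @return data.frame: `group`, `ov_condition`, `quintile`,
#'   `p_left`, `sem`, `n_subjects`.
#' @export
dwell_quintile_curve <- function(dataset, min_trials = 5) {
  tr <- augment_trials(dataset)
  cnt <- table(tr$subject, tr$ov_condition)
  bad <- rownames(cnt)[apply(cnt, 1, min) < min_trials]
  if (length(bad)) {
    warning("skipping subject(s) with < ", min_trials,
            " trials per condition: ", paste(bad, collapse = ", "))
    tr <- tr[!tr$subject %in% bad, ]
  }
  tr$quintile <- ave(tr$dwell_advantage_s, tr$subject,
                     FUN = quintile_bin)
  per <- aggregate(choice_left ~ subject + group + ov_condition +
                     quintile, tr, mean)
  agg <- aggregate(choice_left ~ group + ov_condition + quintile, per,
                   function(v) c(m = mean(v),
                                 sem = sd(v) / sqrt(length(v)),
                                 n = length(v)))
  out <- data.frame(group = agg$group, ov_condition = agg$ov_condition,
                    quintile = agg$quintile,
                    p_left = agg$choice_left[, "m"],
                    sem = agg$choice_left[, "sem"],
                    n_subjects = agg$choice_left[, "n"])
  out[order(out$group, out$ov_condition, out$quintile), ]
}

# quintile labels -2..+2 from midpoint ranks
quintile_bin <- function(x) {
  r <- rank(x, ties.method = "average")
  as.integer(ceiling(5 * r / length(x))) - 3L
}
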