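#' Generative aDDM parameters
#'
#' Parameters of the attentional drift diffusion simulator. Evidence is
#' accumulated in 1-ms steps between symmetric boundaries; while the
#' left item is fixated the mean increment is `d * (r_left - theta *
#' r_right)` and while the right item is fixated it is `d * (theta *
#' r_left - r_right)`, plus Gaussian noise of standard deviation
#' `sigma` per millisecond.
#'
#' The boundary magnitude and starting value are not identified
#' separately from `d` and `sigma`; they default to 1 and 0 under the
#' usual convention, with `d` and `sigma` absorbing the scale.
#'
#' @param d Drift scaling constant, per ms; `d > 0`.
#' @param theta Gaze discount weight in \[0, 1\]; `theta = 1` removes
#'   the attentional discount (standard DDM).
#' @param sigma Per-millisecond noise SD; `sigma >= 0`.
#' @param boundary Evidence magnitude that triggers a choice; `> 0`.
#' @param v0 Initial relative decision value (a symmetric-start offset
#'   for starting-point-bias simulations); `|v0| < boundary`.
#' @return An object of class `addm_params`.
#' @export
#' @examples
#' addm_params(theta = 0.3)
addm_params <- function(d = 2e-4, theta = 0.3, sigma = 0.02,
                        boundary = 1, v0 = 0) {
  stopifnot(d > 0, theta >= 0, theta <= 1, sigma >= 0, boundary > 0,
            abs(v0) < boundary)
  structure(list(d = d, theta = theta, sigma = sigma,
                 boundary = boundary, v0 = v0),
            class = "addm_params")
}

#' A binary choice trial design
#'
#' @param r_left,r_right Item ratings on the 0-10 scale.
#' @param ov_condition Optional `"low"`/`"high"` overall-value label.
#' @param check_vd Require the experimental value-difference constraint
#'   `r_left - r_right` in \{-1, 0, +1\}?
#' @return An object of class `trial_design` with fields `r_left`,
#'   `r_right`, `ov` (their sum), `vd` (their difference) and
#'   `ov_condition`.
#' @export
trial_design <- function(r_left, r_right, ov_condition = NA_character_,
                         check_vd = FALSE) {
  stopifnot(r_left >= 0, r_left <= 10, r_right >= 0, r_right <= 10)
  vd <- r_left - r_right
  if (check_vd && !vd %in% c(-1, 0, 1))
    stop("value difference must be -1, 0 or +1 for experiment designs")
  structure(list(r_left = r_left, r_right = r_right,
                 ov = r_left + r_right, vd = vd,
                 ov_condition = ov_condition),
            class = "trial_design")
}

#' Instantaneous aDDM drift for a fixation location
#'
#' Mean evidence increment per millisecond while fixating `location`:
#' `d * (r_left - theta * r_right)` for a left fixation and
#' `d * (theta * r_left - r_right)` for a right fixation.
#'
#' @param location `"left"` or `"right"`; vectorized.
#' @param design A [trial_design()].
#' @param params An [addm_params()] object.
#' @return Drift in evidence units per ms.
#' @export
#' @examples
#' drift_at("left", trial_design(5, 3), addm_params(d = 1, theta = 0.3))
drift_at <- function(location, design, params) {
  bad <- !location %in% c("left", "right")
  if (any(bad)) stop("location must be 'left' or 'right'")
  ifelse(location == "left",
         params$d * (design$r_left - params$theta * design$r_right),
         params$d * (params$theta * design$r_left - design$r_right))
}

#' Simulate one aDDM trial
#'
#' Euler accumulation in 1-ms steps with drift given by the currently
#' active fixation and white Gaussian noise sampled once per
#' millisecond. The trial ends at the first step at or beyond a
#' boundary (left choice at `+boundary`, right at `-boundary`); the
#' final dwell is truncated at the crossing.
#'
#' @param design A [trial_design()].
#' @param params An [addm_params()] object.
#' @param fixation_source A function taking a total duration (ms) and
#'   returning a data.frame with columns `location` (strictly
#'   alternating `"left"`/`"right"`) and `duration` (positive ms)
#'   covering at least that duration. See [fixation_stream()].
#' @param max_ms Maximum simulated duration before the trial is
#'   declared degenerate (error), ms.
#' @return An object of class `addm_trial`: `choice`
#'   (`"left"`/`"right"`), `decision_time` (ms), and `fixations`
#'   (data.frame `location`, `duration`, `ordinal_class`), whose
#'   durations sum to `decision_time`.
#' @export
simulate_trial <- function(design, params, fixation_source,
                           max_ms = 20000) {
  fx <- fixation_source(max_ms)
  stopifnot(is.data.frame(fx), all(c("location", "duration") %in% names(fx)))
  if (nrow(fx) > 1 &&
      any(fx$location[-1] == fx$location[-nrow(fx)]))
    stop("fixation stream must alternate locations")
  drifts <- drift_at(fx$location, design, params)
  res <- .addm_accumulate_cpp(drifts, as.integer(round(fx$duration)),
                              params$sigma, params$boundary, params$v0,
                              as.integer(max_ms))
  if (!res$crossed)
    stop("no boundary crossing within ", max_ms,
         " ms; degenerate parameters?")
  k <- res$n_dwell
  fix <- fx[seq_len(k), c("location", "duration"), drop = FALSE]
  # truncate the final dwell at the crossing step
  fix$duration[k] <- res$t - if (k > 1) sum(fix$duration[seq_len(k - 1)]) else 0
  fix$ordinal_class <- dwell_ordinal_class(k)
  rownames(fix) <- NULL
  structure(list(choice = if (res$choice > 0) "left" else "right",
                 decision_time = res$t, fixations = fix),
            class = "addm_trial")
}

dwell_ordinal_class <- function(k) {
  if (k == 1) return("first")
  c("first", rep("middle", k - 2), "last")
}

#' Simulate the overall-value by gaze-discount grid
#'
#' Runs the aDDM for each combination of gaze-discount `theta` and
#' overall-value condition and summarizes mean decision time and the
#' coupling of choice to gaze (probability of choosing the item with
#' the longer realized total dwell). With a substantial discount
#' (low `theta`) the low- versus high-OV contrast in both statistics is
#' larger than with a mild discount, because high item values produce
#' larger drift-rate swings between fixations.
#'
#' @param theta_values Gaze-discount values to simulate.
#' @param designs Named list of [trial_design()] objects, one per OV
#'   condition; defaults to `r = (2, 2)` (low) and `r = (8, 8)` (high).
#' @param n Trials per cell.
#' @param params Template [addm_params()] (its `theta` is overridden).
#' @param fixation_source Dwell generator; defaults to a symmetric
#'   [fixation_stream()] so that gaze itself is unbiased.
#' @param max_ms Per-trial duration cap, ms.
#' @return data.frame with one row per `theta` by condition cell:
#'   `theta`, `ov_condition`, `mean_rt_ms`, `p_choose_longest`, `n`.
#' @export
simulate_fig_conditions <- function(theta_values = c(0.3, 0.5),
                                    designs = list(
                                      low = trial_design(2, 2, "low"),
                                      high = trial_design(8, 8, "high")),
                                    n = 1000,
                                    params = addm_params(),
                                    fixation_source =
                                      fixation_stream(p_left_first = 0.5),
                                    max_ms = 20000) {
  stopifnot(n >= 1, all(theta_values >= 0 & theta_values <= 1))
  cells <- expand.grid(theta = theta_values,
                       ov_condition = names(designs),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    p <- params
    p$theta <- cells$theta[i]
    des <- designs[[cells$ov_condition[i]]]
    rts <- numeric(n)
    longest <- rep(NA, n)
    for (j in seq_len(n)) {
      # re-draw the rare no-crossing tail trials (cap 10), mirroring
      # the exclusion of degenerate trials at generation time
      tr <- NULL
      for (k in 1:10) {
        tr <- tryCatch(simulate_trial(des, p, fixation_source,
                                      max_ms = max_ms),
                       error = function(e) NULL)
        if (!is.null(tr)) break
      }
      if (is.null(tr))
        stop("persistent simulation timeout in cell theta = ",
             cells$theta[i], ", ", cells$ov_condition[i])
      rts[j] <- tr$decision_time
      dl <- sum(tr$fixations$duration[tr$fixations$location == "left"])
      dr <- tr$decision_time - dl
      if (dl != dr)
        longest[j] <- (tr$choice == "left") == (dl > dr)
    }
    data.frame(theta = cells$theta[i],
               ov_condition = cells$ov_condition[i],
               mean_rt_ms = mean(rts),
               p_choose_longest = mean(longest, na.rm = TRUE),
               n = n)
  })
  do.call(rbind, out)
}
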