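#' Probability of an upper-boundary response for a constant-drift diffusion
#'
#' Closed-form probability that a diffusion with drift `v`, boundary
#' separation `a`, relative starting point `z` and unit diffusion
#' coefficient is absorbed at the upper boundary:
#' \deqn{P = \frac{1 - e^{-2 v z a}}{1 - e^{-2 v a}},}
#' with the driftless limit \eqn{P \to z} handled by a series expansion
#' rather than division of near-zero quantities.
#'
#' @param v Drift rate (evidence units per second); vectorized.
#' @param a Boundary separation (evidence units), `a > 0`.
#' @param z Relative starting point in (0, 1), fraction of `a`.
#' @return Numeric vector of upper-boundary probabilities.
#' @export
#' @examples
#' choice_prob_upper(0, 2, 0.3)     # driftless: equals z
#' choice_prob_upper(0.5, 2, 0.5)   # 0.7311
choice_prob_upper <- function(v, a, z) {
  stopifnot(a > 0, z > 0, z < 1)
  p <- numeric(length(v))
  for (i in seq_along(v)) {
    vi <- v[i]
    # reflection keeps the exponentials bounded for negative drift
    if (vi < 0) {
      p[i] <- 1 - choice_prob_upper(-vi, a, 1 - z)
    } else if (abs(vi) * a < 1e-6) {
      p[i] <- z + vi * a * z * (1 - z)
    } else {
      p[i] <- expm1(-2 * vi * z * a) / expm1(-2 * vi * a)
    }
  }
  p
}

#' Wiener first-passage-time density
#'
#' Defective density of the decision time `t` (seconds) for a diffusion
#' with drift `v`, boundary separation `a`, relative starting point `z`
#' and unit diffusion coefficient, absorbed at the requested boundary.
#' Evaluates the series representation with automatic switching between
#' the small-time and large-time forms (whichever needs fewer terms for
#' the target accuracy `eps`); extreme parameters are handled in log
#' space rather than underflowing.
#'
#' @param t Decision times, seconds; `t > 0`. Vectorized.
#' @param v Drift rate(s), per second; length 1 or `length(t)`.
#' @param a Boundary separation.
#' @param z Relative starting point in (0, 1).
#' @param boundary `"upper"` or `"lower"`: which absorption the density
#'   refers to. May be a vector of the same length as `t`.
#' @param log Return the log density?
#' @param eps Target truncation accuracy of the series.
#' @return Density (or log density) values.
#' @export
#' @examples
#' wfpt_density(0.5, v = 1, a = 2, z = 0.5, boundary = "upper")
wfpt_density <- function(t, v, a, z, boundary = c("upper", "lower"),
                         log = FALSE, eps = 1e-10) {
  if (any(t <= 0)) stop("decision times must be positive")
  stopifnot(a > 0, z > 0, z < 1)
  if (length(boundary) %in% c(1L, length(t))) {
    boundary <- match.arg(boundary, several.ok = TRUE)
  } else {
    stop("`boundary` must have length 1 or length(t)")
  }
  up <- boundary == "upper"
  ld <- .wfpt_logdens_cpp(as.numeric(t), as.numeric(v), a, z, up, eps)
  if (log) ld else exp(ld)
}

#' Per-trial log-likelihood under the outlier-mixture diffusion model
#'
#' Mixture of the Wiener first-passage density (weight `1 - p_outlier`)
#' and a uniform contaminant over the observed RT range (weight
#' `p_outlier`). RTs at or below the non-decision time contribute only
#' the outlier component; with `p_outlier = 0` such trials get
#' `-Inf` and are flagged.
#'
#' @param choice `"left"`/`"right"` (left = upper boundary), vectorized.
#' @param rt Response times, seconds.
#' @param params A list or [ddm_fit_params()] object with elements `a`,
#'   `z`, `ter` and `p_outlier`.
#' @param drift Per-trial drift rates (per second).
#' @param rt_range Numeric length-2: support of the uniform contaminant,
#'   normally `range(rt)` of the full dataset.
#' @return List with `loglik` (per-trial contributions), `total`, and
#'   `flagged` (trials whose likelihood is `-Inf`).
#' @export
loglik_trial <- function(choice, rt, params, drift,
                         rt_range = range(rt)) {
  stopifnot(length(choice) == length(rt),
            length(drift) %in% c(1L, length(rt)))
  p_out <- params$p_outlier %||% 0
  stopifnot(p_out >= 0, p_out < 1)
  u_dens <- 1 / diff(rt_range)
  upper <- choice_to_upper(choice)
  td <- rt - params$ter
  lf <- rep(-Inf, length(rt))
  ok <- td > 0
  if (any(ok)) {
    dv <- if (length(drift) == 1L) drift else drift[ok]
    lf[ok] <- .wfpt_logdens_cpp(td[ok], as.numeric(dv), params$a,
                                params$z, upper[ok], 1e-10)
  }
  if (p_out > 0) {
    lo <- log(p_out * u_dens)
    lg <- log1p(-p_out) + lf
    m <- pmax(lg, lo)
    ll <- m + log(exp(lg - m) + exp(lo - m))
    ll[!is.finite(lf)] <- lo
  } else {
    ll <- lf
  }
  list(loglik = ll, total = sum(ll), flagged = which(!is.finite(ll)))
}

#' Estimation-side diffusion parameters
#'
#' Container for the fitted diffusion model: boundary separation `a`,
#' relative starting point `z`, non-decision time `ter` (seconds), the
#' drift-regression coefficients `b0..b3`, and the outlier mixture
#' weight (fixed at 0.05 in all standard fits).
#'
#' @param a,z,ter Standard diffusion parameters.
#' @param b0,b1,b2,b3 Drift-regression coefficients (per second).
#' @param p_outlier Uniform-contaminant weight in \[0, 1).
#' @return An object of class `ddm_fit_params`.
#' @export
ddm_fit_params <- function(a = 2, z = 0.5, ter = 0.4,
                           b0 = 0, b1 = 0, b2 = 0, b3 = 0,
                           p_outlier = 0.05) {
  stopifnot(a > 0, z > 0, z < 1, ter >= 0, p_outlier >= 0, p_outlier < 1)
  structure(list(a = a, z = z, ter = ter, b0 = b0, b1 = b1, b2 = b2,
                 b3 = b3, p_outlier = p_outlier),
            class = "ddm_fit_params")
}

#' Simulate the constant-drift diffusion by Euler-Maruyama
#'
#' Millisecond-scale Euler simulation of the fitted diffusion (unit
#' diffusion coefficient, boundaries 0 and `a`, start `z * a`). By
#' default the boundaries are pulled inward by `0.5826 * sqrt(dt)`
#' (continuity correction), which removes the overshoot bias of the
#' discrete scheme so that simulated choice fractions and RT
#' distributions are comparable to the analytic ones.
#'
#' @param n Number of paths (ignored if `v` has length > 1).
#' @param v Drift rate(s), per second.
#' @param a,z Boundary separation and relative start.
#' @param dt Time step, seconds.
#' @param max_t Censoring horizon, seconds.
#' @param correct_boundary Apply the continuity correction?
#' @return data.frame with columns `rt` (seconds) and `upper`
#'   (1 = upper boundary, 0 = lower, NA = censored).
#' @export
simulate_ddm <- function(n, v, a, z, dt = 1e-3, max_t = 30,
                         correct_boundary = TRUE) {
  if (length(v) > 1) n <- length(v)
  out <- .euler_ddm_cpp(as.integer(n), as.numeric(v), a, z, dt, max_t,
                        correct_boundary)
  data.frame(rt = out$rt, upper = out$upper)
}

#' Mean decision time of the symmetric-start diffusion
#'
#' Closed form `(a / (2 v)) * tanh(v a / 2)` for `z = 0.5`, with the
#' driftless limit `a^2 / 4`.
#'
#' @param v Drift rate, per second.
#' @param a Boundary separation.
#' @return Expected decision time, seconds.
#' @export
ddm_mean_dt <- function(v, a) {
  ifelse(abs(v) < 1e-8, a^2 / 4, (a / (2 * v)) * tanh(v * a / 2))
}

choice_to_upper <- function(choice) {
  if (is.logical(choice)) return(choice)
  if (is.numeric(choice)) return(choice > 0)
  choice <- as.character(choice)
  bad <- !choice %in% c("left", "right")
  if (any(bad)) stop("choice must be 'left' or 'right'")
  choice == "left"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
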