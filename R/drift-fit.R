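#' Gaze-weighted drift-rate regressors
#'
#' Builds the three regressors of the drift-rate regression
#' \deqn{v = \beta_0 + \beta_1 (r_L g_L - r_R g_R)
#'         + \beta_2 (r_L g_R - r_R g_L) + \beta_3 (g_L - g_R),}
#' where `r` are item ratings and `g` the fractions of the trial spent
#' fixating each item. When gaze amplifies the fixated item's value
#' (`beta1 > beta2`), the gaze discount is recovered as
#' `theta = beta2 / beta1`; `beta1 = beta2` is the special case where
#' gaze has no multiplicative effect and the model collapses to a
#' plain value-difference DDM with an additive gaze term.
#'
#' @param r_left,r_right Item ratings; vectorized.
#' @param g_left,g_right Gaze fractions in \[0, 1\], normally summing
#'   to 1 over the item-directed dwell time.
#' @return Matrix with columns `x1`, `x2`, `x3`. Trials with
#'   `g_left + g_right == 0` are returned as `NA` rows (they must be
#'   excluded upstream).
#' @export
#' @examples
#' build_drift_regressors(5, 3, 1, 0)    # (5, -3, 1)
build_drift_regressors <- function(r_left, r_right, g_left, g_right) {
  stopifnot(all(g_left >= 0), all(g_right >= 0))
  x <- cbind(x1 = r_left * g_left - r_right * g_right,
             x2 = r_left * g_right - r_right * g_left,
             x3 = g_left - g_right)
  x[g_left + g_right == 0, ] <- NA_real_
  x
}

#' Gaze discount from drift-regression coefficients
#'
#' `theta = beta2 / beta1`, defined in the amplification regime
#' `beta1 > 0`. Below `eps` the ratio is not identified and `NA` is
#' returned with a warning.
#'
#' @param beta1,beta2 Drift-regression coefficients.
#' @param eps Smallest `beta1` treated as positive.
#' @return The gaze-discount estimate, or `NA` when undefined.
#' @export
#' @examples
#' compute_theta(1.0, 0.3)
compute_theta <- function(beta1, beta2, eps = 1e-6) {
  out <- beta2 / beta1
  und <- beta1 <= eps
  if (any(und)) {
    warning("theta undefined: beta1 <= ", eps, " for ", sum(und),
            " value(s)")
    out[und] <- NA_real_
  }
  out
}

#' Subject-level maximum-likelihood diffusion fit
#'
#' Maximizes the outlier-mixture Wiener likelihood over
#' `(a, z, Ter, b0..b3)` with the outlier weight fixed (default 5%),
#' using bounded quasi-Newton optimization from multiple starting
#' points. The per-trial drift is `b0 + b1 x1 + b2 x2 + b3 x3` with
#' regressors from [build_drift_regressors()].
#'
#' @param trials data.frame with columns `choice`, `rt_s`, `r_left`,
#'   `r_right`, `g_left`, `g_right` (one row per trial).
#' @param p_outlier Fixed outlier mixture weight.
#' @param starts Optional list of numeric start vectors
#'   `(a, z, ter, b0, b1, b2, b3)`; defaults to a small documented set.
#' @param rt_range Support of the uniform contaminant; defaults to the
#'   observed RT range of `trials`.
#' @param control Passed to [stats::optim()] (method `L-BFGS-B`).
#' @return List of class `ddm_mle`: `params` ([ddm_fit_params()]),
#'   `theta`, `se` (asymptotic, from the numerical Hessian), `loglik`,
#'   `converged`, `n_trials`, and `starts_tried`. On non-convergence
#'   from every start, `converged` is `FALSE` and the best incumbent is
#'   returned.
#' @export
fit_subject_mle <- function(trials, p_outlier = 0.05, starts = NULL,
                            rt_range = range(trials$rt_s),
                            control = list(maxit = 500)) {
  stopifnot(nrow(trials) >= 10, all(trials$rt_s > 0))
  X <- build_drift_regressors(trials$r_left, trials$r_right,
                              trials$g_left, trials$g_right)
  if (anyNA(X)) stop("trials with zero item gaze must be excluded first")
  upper <- choice_to_upper(trials$choice)
  u_dens <- 1 / diff(rt_range)
  min_rt <- min(trials$rt_s)

  negll <- function(par) {
    ll <- .ddm_loglik_cpp(trials$rt_s, upper, X, par, p_outlier, u_dens,
                          1e-10)
    if (!is.finite(ll)) 1e10 else -ll
  }

  lower_b <- c(a = 0.3, z = 0.05, ter = 0.01, b0 = -10, b1 = -10,
               b2 = -10, b3 = -10)
  upper_b <- c(a = 8, z = 0.95, ter = max(0.02, min_rt - 1e-3),
               b0 = 10, b1 = 10, b2 = 10, b3 = 10)
  if (is.null(starts)) {
    t0 <- min(max(0.3 * min_rt, 0.05), upper_b["ter"])
    starts <- list(c(2, 0.5, t0, 0, 0.3, 0.2, 0),
                   c(3, 0.5, min(0.6 * min_rt, upper_b["ter"]), 0, 0.1,
                     0.05, 0.3),
                   c(1.5, 0.5, t0, 0, 0.6, 0.4, 0))
  }

  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    s <- pmin(pmax(s, lower_b + 1e-6), upper_b - 1e-6)
    fit <- tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lower_b,
            upper = upper_b, control = control, hessian = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  hess <- tryCatch(optimHess(best$par, negll), error = function(e) NULL)
  se <- rep(NA_real_, 7)
  if (!is.null(hess)) {
    cv <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cv)) {
      dg <- diag(cv)
      se <- ifelse(dg > 0, sqrt(dg), NA_real_)
    }
  }
  names(se) <- c("a", "z", "ter", "b0", "b1", "b2", "b3")
  p <- best$par
  params <- ddm_fit_params(a = p[1], z = p[2], ter = p[3], b0 = p[4],
                           b1 = p[5], b2 = p[6], b3 = p[7],
                           p_outlier = p_outlier)
  theta <- if (p[5] > 1e-6) p[6] / p[5] else NA_real_
  structure(list(params = params, theta = theta, se = se,
                 loglik = -best$value, converged = any_conv,
                 n_trials = nrow(trials), starts_tried = length(starts)),
            class = "ddm_mle")
}

#' @export
print.ddm_mle <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<ddm_mle> n=%d loglik=%.2f conv=%s\n  a=%.3f z=%.3f Ter=%.3f  b=(%.3f, %.3f, %.3f, %.3f)  theta=%.3f\n",
    x$n_trials, x$loglik, x$converged, p$a, p$z, p$ter, p$b0, p$b1,
    p$b2, p$b3, x$theta))
  invisible(x)
}

#' Fit every subject in a dataset by maximum likelihood
#'
#' @param dataset A `gaze_dataset`.
#' @param ... Passed to [fit_subject_mle()].
#' @return data.frame with one row per subject: group, fitted
#'   parameters, `theta`, `loglik`, `converged`.
#' @export
fit_subjects_mle <- function(dataset, ...) {
  tr <- dataset$trials
  out <- lapply(split(tr, tr$subject), function(d) {
    f <- fit_subject_mle(d, ...)
    p <- f$params
    data.frame(subject = d$subject[1], group = d$group[1], a = p$a,
               z = p$z, ter = p$ter, b0 = p$b0, b1 = p$b1, b2 = p$b2,
               b3 = p$b3, theta = f$theta, loglik = f$loglik,
               converged = f$converged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
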