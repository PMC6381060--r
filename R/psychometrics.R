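## Psychometric analysis: maximum-likelihood cumulative-Gaussian fits with a
## shared lapse (asymptote) parameter, PSE-based aftereffect summaries and
## the interval-deviation prediction error.

#' Fit a cumulative-Gaussian psychometric function
#'
#' Fits `psi(theta) = gamma + (1 - 2 * gamma) * Phi((theta - mu) / sigma)`,
#' a cumulative Gaussian with equal lower and upper asymptotes `gamma`
#' (shared lapse rate, bounded in \[0, 0.25\]). For responses given as
#' success counts out of `n` trials the binomial log-likelihood is
#' maximized; for real-valued proportions (e.g. deterministic model
#' read-outs) a least-squares criterion is used. Optimization is bounded
#' quasi-Newton (L-BFGS-B) from a deterministic grid of starts (`mu` at the
#' smallest, central and largest stimulus level crossed with `sigma` at a
#' quarter and half of the stimulus span); ties are broken by objective
#' value, then by smallest `|mu|`.
#'
#' @param theta stimulus levels in degrees (>= 4 distinct values).
#' @param p observed proportion of "upward" responses in \[0, 1\] per level
#'   (may repeat levels).
#' @param n optional trial counts per entry; when supplied, `p * n` must be
#'   (near-)integer success counts and the binomial likelihood is used.
#' @param method `"auto"` (binomial when `n` is given), `"binomial"` or
#'   `"ls"`.
#' @return object of class `psychometric_fit`: list with `pse` (`mu`,
#'   degrees), `slope` (`sigma`, degrees), `asymptote` (`gamma`), `loglik`
#'   (maximized log-likelihood, or minus the residual sum of squares for
#'   least squares), `converged` and `method`.
#' @examples
#' th <- seq(-6, 6, by = 1.2)
#' p <- pnorm((th - 1) / 2)
#' fit_psychometric(th, p)$pse  # close to 1
#' @export
fit_psychometric <- function(theta, p, n = NULL,
                             method = c("auto", "binomial", "ls")) {
  method <- match.arg(method)
  if (length(theta) != length(p)) stop("'theta' and 'p' must match in length")
  if (length(unique(theta)) < 4)
    stop("need at least 4 distinct stimulus levels")
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  if (all(p <= 0) || all(p >= 1))
    stop("degenerate data: all responses are in one category")
  if (method == "auto") method <- if (is.null(n)) "ls" else "binomial"
  if (method == "binomial") {
    if (is.null(n)) stop("binomial fitting requires trial counts 'n'")
    if (length(n) == 1) n <- rep(n, length(p))
    k <- p * n
    if (max(abs(k - round(k))) > 1e-6)
      stop("'p * n' must be integer success counts for the binomial fit")
    k <- round(k)
  }

  span <- diff(range(theta))
  psi_fun <- function(par)
    par[3] + (1 - 2 * par[3]) * pnorm((theta - par[1]) / par[2])
  negobj <- if (method == "binomial") {
    function(par) {
      q <- pmin(pmax(psi_fun(par), 1e-12), 1 - 1e-12)
      -sum(k * log(q) + (n - k) * log(1 - q))
    }
  } else {
    function(par) sum((p - psi_fun(par))^2)
  }

  lower <- c(min(theta) - span, 1e-2, 0)
  upper <- c(max(theta) + span, 5 * span, 0.25)
  starts <- expand.grid(mu = c(min(theta), 0, max(theta)),
                        sigma = c(span / 4, span / 2))
  fits <- list()
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(starts$mu[s], starts$sigma[s], 0.02), negobj,
            method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (!length(fits)) stop("psychometric fit failed from every start")
  pick_best <- function(fl) {
    best <- NULL
    for (fit in fl) {
      if (is.null(best) ||
          fit$value < best$value - 1e-12 ||
          (abs(fit$value - best$value) <= 1e-12 &&
           abs(fit$par[1]) < abs(best$par[1])))
        best <- fit
    }
    best
  }
  ## prefer cleanly converged starts; fall back to the overall best only if
  ## it improves on them beyond numerical noise
  conv <- Filter(function(f) f$convergence == 0, fits)
  best <- pick_best(fits)
  if (best$convergence != 0) {
    ## a terminated line search at a well-identified optimum is benign:
    ## restart once from the best point and keep the polished result
    polish <- tryCatch(
      optim(best$par, negobj, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(polish) && polish$convergence == 0 &&
        polish$value <= best$value + 1e-8 * (1 + abs(best$value)))
      best <- polish
  }
  if (best$convergence != 0 && length(conv)) {
    best_conv <- pick_best(conv)
    if (best$value >= best_conv$value - 1e-3 * (1 + abs(best_conv$value)))
      best <- best_conv
  }
  structure(list(
    pse = best$par[1], slope = best$par[2], asymptote = best$par[3],
    loglik = -best$value, converged = best$convergence == 0,
    method = method), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> PSE=%.3f deg  sigma=%.3f deg  gamma=%.4f  (%s%s)\n",
    x$pse, x$slope, x$asymptote, x$method,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Predicted psychometric curve
#'
#' @param object a `psychometric_fit`.
#' @param newdata stimulus levels in degrees.
#' @param ... unused.
#' @return predicted proportion of upward responses.
#' @export
predict.psychometric_fit <- function(object, newdata, ...) {
  object$asymptote + (1 - 2 * object$asymptote) *
    pnorm((newdata - object$pse) / object$slope)
}

#' PSE-based aftereffect summary
#'
#' Combines the psychometric fits of the up-skew and down-skew adaptation
#' blocks into the two session summaries: `delta_pse = pse_usk - pse_dsk`,
#' the magnitude of the (repulsive) motion aftereffect, and
#' `sum_pse = pse_usk + pse_dsk`, the asymmetry induced by the DSK-first
#' ordering.
#'
#' @param fit_usk,fit_dsk converged [fit_psychometric()] objects for the two
#'   blocks.
#' @return object of class `aftereffect_summary` with fields `pse_usk`,
#'   `pse_dsk`, `delta_pse`, `sum_pse`.
#' @export
aftereffect_summary <- function(fit_usk, fit_dsk) {
  for (f in list(fit_usk, fit_dsk)) {
    if (!inherits(f, "psychometric_fit")) stop("inputs must be psychometric fits")
    if (!isTRUE(f$converged)) stop("refusing to summarize an unconverged fit")
  }
  structure(list(
    pse_usk = fit_usk$pse, pse_dsk = fit_dsk$pse,
    delta_pse = fit_usk$pse - fit_dsk$pse,
    sum_pse = fit_usk$pse + fit_dsk$pse), class = "aftereffect_summary")
}

#' @export
print.aftereffect_summary <- function(x, ...) {
  cat(sprintf(
    "<aftereffect_summary> PSE(USK)=%.3f  PSE(DSK)=%.3f  dPSE=%.3f  sPSE=%.3f deg\n",
    x$pse_usk, x$pse_dsk, x$delta_pse, x$sum_pse))
  invisible(x)
}

interval_deviation <- function(p, interval) {
  if (length(interval) != 2 || interval[1] > interval[2])
    stop("malformed interval (need lo <= hi)")
  max(0, interval[1] - p, p - interval[2])
}

#' Average deviation of predictions from reference intervals
#'
#' For each prediction `p` and interval `[lo, hi]`, the deviation is the
#' distance outside the interval, `max(0, lo - p, p - hi)` (0 inside);
#' `err_avg` is the mean of the deviation magnitudes, so it is zero exactly
#' when every prediction lies inside its interval.
#'
#' @param predictions numeric vector of predicted summaries.
#' @param reference_intervals list of `c(lo, hi)` pairs (or a two-column
#'   matrix), one per prediction.
#' @return list with `deviations` (per prediction) and `err_avg`.
#' @export
prediction_error <- function(predictions, reference_intervals) {
  if (is.matrix(reference_intervals))
    reference_intervals <- split(reference_intervals,
                                 row(reference_intervals))
  if (length(predictions) != length(reference_intervals))
    stop("one reference interval per prediction is required")
  dev <- mapply(interval_deviation, predictions, reference_intervals)
  list(deviations = dev, err_avg = mean(abs(dev)))
}
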