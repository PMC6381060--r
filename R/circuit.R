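## Recurrent V1-MT circuit: shunting membrane dynamics, depressing synapses
## in the feedforward (V1->MT, driving) and feedback (MT->V1, modulatory)
## streams, and a softmax decision readout over two direction channels.

#' Model parameter set (one of the five published variants, or custom)
#'
#' Builds the complete parameter set of the recurrent circuit. The five
#' variants cross circuit complexity (feedforward only versus recurrent
#' feedforward-feedback) with the temporal regime of the depressing synapses
#' (fast, slow, or one of each):
#'
#' * variant 1 -- FF only, fast FF synapse (`lam = 0`, `alpha_ff = 5e-4`,
#'   `beta_ff = 9`, `temp = 1e-5`)
#' * variant 2 -- FF only, slow FF synapse (`lam = 0`, `alpha_ff = 0.5`,
#'   `beta_ff = 10`, `temp = 1e-3`)
#' * variant 3 -- FF-FB, fast FF synapse only (`lam = 20`, `alpha_ff = 1`,
#'   `beta_ff = 10`, `alpha_fb = beta_fb = 0`, `temp = 1e-3`)
#' * variant 4 -- FF-FB, slow FB synapse only (`lam = 20`,
#'   `alpha_ff = beta_ff = 0`, `alpha_fb = 0.04`, `beta_fb = 1.2`,
#'   `temp = 1e-3`)
#' * variant 5 -- FF-FB with both the fast FF rates of variant 3 and the slow
#'   FB rates of variant 4.
#'
#' All variants share the membrane time constant `tau` = 30 ms, the synaptic
#' gating time constant `tau_syn` = 1 s, the direction-kernel width
#' `sigma_c` = 45 degrees and `n` = 37 direction-tuned units per area.
#'
#' @param variant_id integer 1 to 5, or `"custom"` when individual values are
#'   supplied through `...`.
#' @param ... for `variant_id = "custom"` (or to override a published tuple),
#'   any of `tau`, `tau_syn`, `lam`, `sigma_c`, `alpha_ff`, `beta_ff`,
#'   `alpha_fb`, `beta_fb`, `temp`, `n`, `kernel_width_as`.
#' @return an object of class `variant_params`.
#' @examples
#' variant_params(5)
#' variant_params("custom", lam = 0, alpha_ff = 1, beta_ff = 10)
#' @export
variant_params <- function(variant_id = 5, ...) {
  base <- list(
    tau = 0.030, tau_syn = 1, sigma_c = 45, n = 37L,
    lam = 20, alpha_ff = 1, beta_ff = 10, alpha_fb = 0.04, beta_fb = 1.2,
    temp = 0.001, kernel_width_as = "span"
  )
  tuples <- list(
    `1` = list(lam = 0,  alpha_ff = 0.0005, beta_ff = 9,  alpha_fb = 0, beta_fb = 0,   temp = 0.00001),
    `2` = list(lam = 0,  alpha_ff = 0.5,    beta_ff = 10, alpha_fb = 0, beta_fb = 0,   temp = 0.001),
    `3` = list(lam = 20, alpha_ff = 1,      beta_ff = 10, alpha_fb = 0, beta_fb = 0,   temp = 0.001),
    `4` = list(lam = 20, alpha_ff = 0,      beta_ff = 0,  alpha_fb = 0.04, beta_fb = 1.2, temp = 0.001),
    `5` = list(lam = 20, alpha_ff = 1,      beta_ff = 10, alpha_fb = 0.04, beta_fb = 1.2, temp = 0.001)
  )
  dots <- list(...)
  if (identical(variant_id, "custom")) {
    p <- base
  } else {
    if (!(is.numeric(variant_id) && length(variant_id) == 1 &&
          variant_id %in% 1:5))
      stop("'variant_id' must be 1..5 or \"custom\"")
    p <- utils::modifyList(base, tuples[[as.character(as.integer(variant_id))]])
  }
  bad <- setdiff(names(dots), names(base))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- utils::modifyList(p, dots)
  p$variant_id <- if (identical(variant_id, "custom") || length(dots)) "custom"
                  else as.integer(variant_id)
  validate_variant_params(p)
  structure(p, class = "variant_params")
}

validate_variant_params <- function(p) {
  stopifnot(p$tau > 0, p$tau_syn > 0, p$temp > 0, p$sigma_c > 0)
  rates <- c(p$alpha_ff, p$beta_ff, p$alpha_fb, p$beta_fb, p$lam)
  if (any(rates < 0)) stop("synaptic rates and feedback strength must be >= 0")
  invisible(p)
}

#' @export
print.variant_params <- function(x, ...) {
  cat(sprintf(
    "<variant_params> id=%s  lam=%g  FF(a=%g, b=%g)  FB(a=%g, b=%g)  temp=%g\n",
    as.character(x$variant_id), x$lam, x$alpha_ff, x$beta_ff,
    x$alpha_fb, x$beta_fb, x$temp))
  cat(sprintf("  tau=%g s, tau_syn=%g s, sigma_c=%g deg (%s), n=%d\n",
              x$tau, x$tau_syn, x$sigma_c, x$kernel_width_as, x$n))
  invisible(x)
}

#' Direction-domain Gaussian receptive-field kernel
#'
#' The constant synaptic weight profile shared by the V1 and MT filtering
#' stages: a Gaussian over preferred-direction differences, truncated at the
#' grid boundary (no wraparound on the half-circle grid) and renormalized so
#' that each output unit's incoming weights sum to one. Returned as an
#' `n x n` matrix `K` such that `K %*% r` is the filtered signal.
#'
#' @param sigma_c kernel width in degrees (> 0).
#' @param grid a [direction_grid()].
#' @param width_as `"span"` (default) reads `sigma_c` as the full tuning
#'   extent (+/- 2 SD), `"fwhm"` as the full width at half maximum, `"sd"`
#'   as the Gaussian standard deviation.
#' @return an `n x n` numeric matrix with unit row sums.
#' @export
direction_kernel <- function(sigma_c, grid = direction_grid(),
                             width_as = c("span", "fwhm", "sd")) {
  if (!is.numeric(sigma_c) || sigma_c <= 0) stop("'sigma_c' must be > 0")
  sd <- width_to_sd(sigma_c, match.arg(width_as))
  d <- outer(grid$angles, grid$angles, "-")
  K <- exp(-d^2 / (2 * sd^2))
  K / rowSums(K)
}

#' Decision-channel readout weights
#'
#' Two Gaussian weight vectors over the direction grid, centered at +90
#' (upward channel) and -90 degrees (downward channel), mirror images of one
#' another. They weight the rectified MT population response into the
#' excitatory inputs of the two competing motor units.
#'
#' @param grid a [direction_grid()].
#' @param width Gaussian width in degrees.
#' @param width_as width convention, as in [direction_kernel()].
#' @return list with numeric vectors `g_up`, `g_down`.
#' @export
readout_weights <- function(grid = direction_grid(), width = 45,
                            width_as = c("sd", "span", "fwhm")) {
  sd <- width_to_sd(width, match.arg(width_as))
  list(
    g_up   = exp(-(grid$angles - 90)^2 / (2 * sd^2)),
    g_down = exp(-(grid$angles + 90)^2 / (2 * sd^2))
  )
}

#' Fresh circuit state
#'
#' Membrane potentials of both areas start at rest (0) and all synaptic
#' efficacies fully replenished (1). State persists across trials within an
#' experiment; it is only re-initialized at the start of a session.
#'
#' @param grid a [direction_grid()].
#' @return object of class `circuit_state` with per-direction vectors
#'   `v_v1`, `v_mt` (membrane potentials in \[-1, 1\]), `y_ff`, `y_fb`
#'   (synaptic efficacies in \[0, 1\]) and elapsed model time `t` (seconds).
#' @export
circuit_state <- function(grid = direction_grid()) {
  z <- rep(0, grid$n); o <- rep(1, grid$n)
  structure(list(v_v1 = z, v_mt = z, y_ff = o, y_fb = o, t = 0),
            class = "circuit_state")
}

#' @export
print.circuit_state <- function(x, ...) {
  cat(sprintf("<circuit_state> t=%.3f s  v_v1 in [%.3g, %.3g]  v_mt in [%.3g, %.3g]\n",
              x$t, min(x$v_v1), max(x$v_v1), min(x$v_mt), max(x$v_mt)))
  cat(sprintf("  y_ff in [%.3g, %.3g]  y_fb in [%.3g, %.3g]\n",
              min(x$y_ff), max(x$y_ff), min(x$y_fb), max(x$y_fb)))
  invisible(x)
}

check_state <- function(state, grid) {
  if (!inherits(state, "circuit_state")) stop("'state' must be a circuit_state")
  if (length(state$v_v1) != grid$n)
    stop("state and grid disagree on the number of direction units")
  invisible(state)
}

#' Synaptic drives of every model unit
#'
#' Computes the excitatory, modulatory and inhibitory inputs from the current
#' state and the direction signal feeding V1. Wherever a membrane potential
#' acts presynaptically it enters half-wave rectified (`[v]+ = max(v, 0)`);
#' the raw potential remains the state variable. The inhibitory drive of each
#' area is the mean of that area's excitatory drives (pool inhibition), which
#' implements response normalization.
#'
#' @param state a [circuit_state()].
#' @param r_theta numeric direction signal on the grid (driving input to V1).
#' @param params a [variant_params()].
#' @param grid a [direction_grid()].
#' @param kernel optionally, a precomputed [direction_kernel()].
#' @return list with per-direction vectors `i_ex_v1`, `i_ex_mt`, `i_mod_v1`
#'   and scalars `i_inh_v1`, `i_inh_mt`.
#' @export
compute_drives <- function(state, r_theta, params, grid = direction_grid(),
                           kernel = NULL) {
  check_state(state, grid)
  check_signal(r_theta, grid)
  if (is.null(kernel))
    kernel <- direction_kernel(params$sigma_c, grid, params$kernel_width_as)
  v1p  <- pmax(state$v_v1, 0)
  vmtp <- pmax(state$v_mt, 0)
  i_mod_v1 <- state$y_fb * vmtp
  i_ex_v1  <- drop(kernel %*% r_theta) * (1 + params$lam * i_mod_v1)
  i_ex_mt  <- state$y_ff * drop(kernel %*% v1p)
  list(i_ex_v1 = i_ex_v1, i_ex_mt = i_ex_mt, i_mod_v1 = i_mod_v1,
       i_inh_v1 = mean(i_ex_v1), i_inh_mt = mean(i_ex_mt))
}

#' Single forward-Euler step of the circuit
#'
#' Advances membrane potentials (shunting single-compartment dynamics) and
#' synaptic efficacies (vesicle depletion/replenishment gating) by one Euler
#' step of size `dt`. The depletion terms use the rectified presynaptic
#' potentials of the pre-update state. Values may only leave their invariant
#' ranges by less than `1e-6` (they are then clipped); larger excursions
#' signal an unstable step size and raise an error.
#'
#' This is the reference single-step implementation; [run_segment()] runs the
#' identical update in compiled code for long segments.
#'
#' @inheritParams compute_drives
#' @param dt step size in seconds; must satisfy `0 < dt <= tau / 10`.
#' @return the updated `circuit_state`.
#' @export
step <- function(state, r_theta, dt, params, grid = direction_grid(),
                 kernel = NULL) {
  if (!is.numeric(dt) || dt <= 0 || dt > params$tau / 10)
    stop(sprintf("'dt' must satisfy 0 < dt <= tau/10 = %g s", params$tau / 10))
  d <- compute_drives(state, r_theta, params, grid, kernel)
  v1p  <- pmax(state$v_v1, 0)
  vmtp <- pmax(state$v_mt, 0)
  kv <- dt / params$tau
  ks <- dt / params$tau_syn
  state$v_v1 <- state$v_v1 + kv *
    (-state$v_v1 + (1 - state$v_v1) * d$i_ex_v1 - (1 + state$v_v1) * d$i_inh_v1)
  state$v_mt <- state$v_mt + kv *
    (-state$v_mt + (1 - state$v_mt) * d$i_ex_mt - (1 + state$v_mt) * d$i_inh_mt)
  state$y_ff <- state$y_ff + ks *
    (params$alpha_ff * (1 - state$y_ff) - params$beta_ff * state$y_ff * v1p)
  state$y_fb <- state$y_fb + ks *
    (params$alpha_fb * (1 - state$y_fb) - params$beta_fb * state$y_fb * vmtp)
  state$v_v1 <- clip_checked(state$v_v1, -1, 1, "v_v1")
  state$v_mt <- clip_checked(state$v_mt, -1, 1, "v_mt")
  state$y_ff <- clip_checked(state$y_ff, 0, 1, "y_ff")
  state$y_fb <- clip_checked(state$y_fb, 0, 1, "y_fb")
  state$t <- state$t + dt
  state
}

clip_checked <- function(x, lo, hi, what, tol = 1e-6) {
  if (any(x < lo - tol) || any(x > hi + tol))
    stop(sprintf(
      "Euler update pushed %s outside [%g, %g] by more than %g; reduce dt",
      what, lo, hi, tol))
  pmin(pmax(x, lo), hi)
}

#' Integrate the circuit under a constant input signal
#'
#' Repeatedly applies the Euler update of [step()] for `duration` seconds
#' under a constant direction signal, in compiled code. Besides the final
#' state, the segment's time-averaged rectified responses and the running
#' extrema of the state variables are returned as attributes, and optionally
#' a sub-sampled trajectory.
#'
#' @inheritParams step
#' @param signal constant direction signal over the segment (use zeros for a
#'   blank inter-stimulus interval).
#' @param duration segment length in seconds (>= 0).
#' @param record_stride if > 0, record the state every `record_stride` steps
#'   into attribute `"trajectory"` (columns: `t`, then `v_v1`, `v_mt`,
#'   `y_ff`, `y_fb` blocks).
#' @return the final `circuit_state`, with attributes `"mean_rect"` (list of
#'   per-direction time averages of `[v_v1]+` and `[v_mt]+` over the
#'   segment), `"v_range"` and `"y_range"` (running extrema), and optionally
#'   `"trajectory"`.
#' @export
run_segment <- function(state, signal, duration, dt, params,
                        grid = direction_grid(), kernel = NULL,
                        record_stride = 0L) {
  check_state(state, grid)
  check_signal(signal, grid)
  if (!is.numeric(duration) || duration < 0) stop("'duration' must be >= 0")
  if (!is.numeric(dt) || dt <= 0 || dt > params$tau / 10)
    stop(sprintf("'dt' must satisfy 0 < dt <= tau/10 = %g s", params$tau / 10))
  n_steps <- as.integer(round(duration / dt))
  if (is.null(kernel))
    kernel <- direction_kernel(params$sigma_c, grid, params$kernel_width_as)
  if (n_steps == 0L) {
    attr(state, "mean_rect") <- list(v1 = pmax(state$v_v1, 0),
                                     mt = pmax(state$v_mt, 0))
    attr(state, "v_range") <- range(c(state$v_v1, state$v_mt))
    attr(state, "y_range") <- range(c(state$y_ff, state$y_fb))
    return(state)
  }
  res <- cpp_run_segment(
    state$v_v1, state$v_mt, state$y_ff, state$y_fb, state$t,
    kernel, signal, n_steps, dt,
    params$tau, params$tau_syn, params$lam,
    params$alpha_ff, params$beta_ff, params$alpha_fb, params$beta_fb,
    1e-6, as.integer(record_stride))
  out <- structure(list(v_v1 = drop(res$v_v1), v_mt = drop(res$v_mt),
                        y_ff = drop(res$y_ff), y_fb = drop(res$y_fb),
                        t = res$t),
                   class = "circuit_state")
  attr(out, "mean_rect") <- list(v1 = drop(res$mean_v1), mt = drop(res$mean_mt))
  attr(out, "v_range") <- c(res$v_min, res$v_max)
  attr(out, "y_range") <- c(res$y_min, res$y_max)
  if (record_stride > 0L) attr(out, "trajectory") <- res$trajectory
  out
}

#' Steady-state membrane potential under constant drives
#'
#' Analytic fixed point of the shunting membrane equation,
#' `v* = (i_ex - i_inh) / (1 + i_ex + i_inh)`, bounded in (-1, 1) for
#' non-negative drives.
#'
#' @param i_ex,i_inh non-negative excitatory and inhibitory drives
#'   (vectorized).
#' @return the steady-state membrane value(s).
#' @export
steady_state_membrane <- function(i_ex, i_inh) {
  if (any(i_ex < 0) || any(i_inh < 0)) stop("drives must be >= 0")
  (i_ex - i_inh) / (1 + i_ex + i_inh)
}

#' Steady-state synaptic efficacy under constant presynaptic activity
#'
#' Analytic fixed point of the vesicle gating equation,
#' `y* = alpha / (alpha + beta * v)`: full replenishment (1) without
#' presynaptic drive, `alpha / (alpha + beta)` under saturated drive.
#'
#' @param alpha replenishment rate (>= 0).
#' @param beta depletion rate (>= 0).
#' @param v rectified presynaptic activity in \[0, 1\] (vectorized).
#' @return the steady-state efficacy value(s) in (0, 1\].
#' @export
steady_state_synapse <- function(alpha, beta, v) {
  if (alpha < 0 || beta < 0) stop("rates must be >= 0")
  if (any(v < 0) || any(v > 1)) stop("presynaptic 'v' must lie in [0, 1]")
  if (alpha == 0 && all(beta * v == 0))
    stop("undefined equilibrium: alpha = 0 and beta * v = 0")
  alpha / (alpha + beta * v)
}

#' Softmax decision readout over MT responses
#'
#' The rectified MT population response is weighted into the two decision
#' channels and passed through a temperature-controlled softmax, yielding the
#' probability of an "upward" versus "downward" report. The exponent is
#' max-stabilized so that arbitrarily small temperatures are safe.
#'
#' @param v_mt MT membrane potential vector on the grid.
#' @param weights a [readout_weights()] list.
#' @param temp softmax temperature (> 0); small values approach a hard
#'   winner-take-all choice.
#' @return named numeric vector `c(p_up, p_down)` summing to one.
#' @export
readout <- function(v_mt, weights, temp) {
  if (!is.numeric(temp) || temp <= 0) stop("'temp' must be > 0")
  vp <- pmax(v_mt, 0)
  i_up <- sum(weights$g_up * vp)
  i_down <- sum(weights$g_down * vp)
  z <- c(i_up, i_down) / temp
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  c(p_up = p[1], p_down = p[2])
}

#' Population response curves during adaptation
#'
#' Runs the circuit from a given (default fresh) state under a constant
#' adapting signal and returns the normalized direction-tuning curves of the
#' V1 and MT populations, time-averaged over the second part of the segment
#' (the first `discard` fraction is dropped to exclude the onset transient).
#'
#' @param params a [variant_params()].
#' @param signal adapting direction signal on the grid.
#' @param duration exposure duration in seconds.
#' @param dt Euler step in seconds.
#' @param grid a [direction_grid()].
#' @param state starting state; a fresh [circuit_state()] by default.
#' @param discard fraction of the segment treated as onset transient.
#' @return list with vectors `v1`, `mt` (each max-normalized when nonzero),
#'   the final `state`, and `angles`.
#' @export
adaptation_response <- function(params, signal, duration = 0.3, dt = 0.001,
                                grid = direction_grid(), state = NULL,
                                discard = 0.5) {
  if (is.null(state)) state <- circuit_state(grid)
  kernel <- direction_kernel(params$sigma_c, grid, params$kernel_width_as)
  s1 <- run_segment(state, signal, duration * discard, dt, params, grid, kernel)
  s2 <- run_segment(s1, signal, duration * (1 - discard), dt, params, grid, kernel)
  mr <- attr(s2, "mean_rect")
  norm1 <- function(x) if (max(x) > 0) x / max(x) else x
  list(v1 = norm1(mr$v1), mt = norm1(mr$mt), state = s2, angles = grid$angles)
}

#' Direction tuning probed from an adapted state
#'
#' For each probe direction, a test direction signal is presented for
#' `probe_duration` seconds starting from a copy of the adapted synaptic
#' efficacies with membrane potentials reset to rest (as after a blank
#' interval). The time-averaged rectified responses of both areas, after
#' dropping the onset transient, are reported per probe; the adapted state is
#' never mutated.
#'
#' @param adapted_state a [circuit_state()] carrying the adapted efficacies.
#' @param probe_thetas probe directions in degrees (within the grid range).
#' @param params a [variant_params()].
#' @param probe_duration probe length in seconds.
#' @param dt Euler step in seconds.
#' @param grid a [direction_grid()].
#' @param test_width width (Gaussian SD, degrees) of the probe signal.
#' @param amplitude peak amplitude of the probe signal.
#' @param discard onset fraction dropped from the time average.
#' @param normalize max-normalize each response curve.
#' @return list with `angles`, `probe_thetas`, and matrices `v1`, `mt` of
#'   size `grid$n x length(probe_thetas)` (one response curve per probe).
#' @export
probe_tuning <- function(adapted_state, probe_thetas, params,
                         probe_duration = 0.3, dt = 0.001,
                         grid = direction_grid(), test_width = 15,
                         amplitude = 0.05, discard = 1 / 3, normalize = TRUE) {
  check_state(adapted_state, grid)
  kernel <- direction_kernel(params$sigma_c, grid, params$kernel_width_as)
  v1 <- mt <- matrix(0, grid$n, length(probe_thetas))
  for (i in seq_along(probe_thetas)) {
    st <- adapted_state
    st$v_v1 <- rep(0, grid$n)
    st$v_mt <- rep(0, grid$n)
    sig <- test_direction_signal(probe_thetas[i], grid, width = test_width,
                                 amplitude = amplitude)
    s1 <- run_segment(st, sig, probe_duration * discard, dt, params, grid, kernel)
    s2 <- run_segment(s1, sig, probe_duration * (1 - discard), dt, params,
                      grid, kernel)
    mr <- attr(s2, "mean_rect")
    v1[, i] <- mr$v1
    mt[, i] <- mr$mt
  }
  if (normalize) {
    norm1 <- function(x) if (max(x) > 0) x / max(x) else x
    v1 <- apply(v1, 2, norm1)
    mt <- apply(mt, 2, norm1)
    if (length(probe_thetas) == 1L) { v1 <- matrix(v1); mt <- matrix(mt) }
  }
  list(angles = grid$angles, probe_thetas = probe_thetas, v1 = v1, mt = mt)
}

#' Interpolated peak location of a response curve
#'
#' Location of the maximum of a sampled tuning curve, refined by a quadratic
#' fit through the maximum and its two neighbours, giving sub-grid-spacing
#' resolution of population peak shifts.
#'
#' @param curve numeric response values.
#' @param angles sample locations in degrees (uniformly spaced).
#' @return peak location in degrees.
#' @export
response_peak <- function(curve, angles) {
  stopifnot(length(curve) == length(angles), length(curve) >= 3)
  i <- which.max(curve)
  if (i == 1L || i == length(curve)) return(angles[i])
  h <- angles[2] - angles[1]
  y0 <- curve[i - 1]; y1 <- curve[i]; y2 <- curve[i + 1]
  den <- y0 - 2 * y1 + y2
  if (den == 0) return(angles[i])
  angles[i] + 0.5 * h * (y0 - y2) / den
}

#' Local maxima of a sampled curve with a prominence cut
#'
#' Finds interior local maxima and computes each peak's topographic
#' prominence (height above the higher of the two bounding saddles toward
#' larger values), relative to the curve maximum. Used to classify tuning
#' curves as unimodal or bimodal.
#'
#' @param x numeric curve values.
#' @param min_prominence minimal relative prominence (fraction of `max(x)`)
#'   for a peak to be reported.
#' @return integer vector of peak indices.
#' @export
find_peaks <- function(x, min_prominence = 0.05) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  ## plateaus: keep the first index of any flat top
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  mx <- max(x)
  if (mx <= 0) return(integer(0))
  for (k in seq_along(cand)) {
    i <- cand[k]
    ## walk left and right until a strictly higher point; prominence is the
    ## peak height minus the higher of the two valley minima found on the way
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, n)]
    lhigher <- which(left > x[i])
    rhigher <- which(right > x[i])
    lmin <- if (length(lhigher)) min(left[seq(max(lhigher), i - 1)]) else min(left)
    rmin <- if (length(rhigher)) min(right[seq_len(min(rhigher))]) else min(right)
    prom <- x[i] - max(lmin, rmin)
    ## the global maximum has full prominence
    if (x[i] == mx) prom <- mx - min(x)
    keep[k] <- (prom / mx) >= min_prominence
  }
  cand[keep]
}
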