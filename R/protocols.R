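## Simulated psychophysics: the three experiment schedules (sub-second
## top-ups, minutes-long adaptation, and sequential/hysteresis testing),
## session execution with persistent circuit state, and the cross-variant
## prediction pattern.

test_thetas_exp12 <- function() setdiff(seq(-6.6, 6.6, by = 1.2), 0)
test_thetas_exp3 <- function() seq(-13, 13, by = 2)

#' Experiment schedule
#'
#' Builds the ordered segment list of one simulated session. All three
#' experiments run a down-skew (DSK) adaptation block first, then an up-skew
#' (USK) block, with no state reset in between (the carry-over produces the
#' negative bias of the summed PSEs).
#'
#' * Experiment 1 -- short exposure: each trial is a 0.3 s adaptor top-up,
#'   0.3 s blank ISI, 0.3 s test, 0.3 s blank; 12 test directions from -6.6
#'   to 6.6 degrees in steps of 1.2 (0 excluded), 5 repetitions each, order
#'   randomized by `seed`; 60 recorded responses per block.
#' * Experiment 2 -- long exposure: the session opens with 180 s of
#'   adaptation, then each trial is a 0.5 s ISI, 0.5 s test and 15 s
#'   top-up; same 12 directions, 5 repetitions, randomized order. The USK
#'   block switches directly to top-up adaptation (a fresh 3-min
#'   re-adaptation would, by the synaptic time constants, fully erase the
#'   first block's trace and with it the ordering bias).
#' * Experiment 3 -- short exposure with hysteresis: trials as in experiment
#'   1, but 14 test directions from -13 to 13 degrees in steps of 2,
#'   presented sequentially (ascending in the DSK block, descending in the
#'   USK block) for 4 cycles; 56 responses per block.
#'
#' In experiments 1 and 2 the USK block presents the negated DSK test order
#' (mirror-yoked randomization): the order is still random, but the two
#' blocks are exact reflections of each other, so order-sampling noise
#' cancels from the PSE sum and the remaining bias isolates the
#' adaptation-state carry-over of the DSK-first design.
#'
#' @param experiment_id 1, 2 or 3.
#' @param seed integer seed for the randomized test orders.
#' @return object of class `episode_schedule`: a data frame of segments with
#'   columns `block` ("DSK"/"USK"), `kind` ("adapt", "topup", "isi",
#'   "test"), `theta` (degrees, `NA` except for tests) and `duration`
#'   (seconds), plus metadata attributes.
#' @export
build_schedule <- function(experiment_id, seed = 1L) {
  if (!(is.numeric(experiment_id) && length(experiment_id) == 1 &&
        experiment_id %in% 1:3))
    stop("'experiment_id' must be 1, 2 or 3")
  experiment_id <- as.integer(experiment_id)
  set.seed(seed)
  if (experiment_id %in% c(1L, 3L)) {
    if (experiment_id == 1L) {
      reps <- 5L
      ord <- sample(rep(test_thetas_exp12(), reps))
      orders <- list(DSK = ord, USK = -ord)
    } else {
      reps <- 4L
      orders <- list(DSK = rep(sort(test_thetas_exp3()), reps),
                     USK = rep(sort(test_thetas_exp3(), decreasing = TRUE), reps))
    }
    seg <- do.call(rbind, lapply(names(orders), function(b) {
      th <- orders[[b]]
      data.frame(
        block = b,
        kind = rep(c("topup", "isi", "test", "isi"), length(th)),
        theta = as.vector(rbind(NA, NA, th, NA)),
        duration = 0.3
      )
    }))
  } else {
    reps <- 5L
    ord <- sample(rep(test_thetas_exp12(), reps))
    orders <- list(DSK = ord, USK = -ord)
    ## the 180-s adaptation opens the session; the second (USK) block
    ## switches directly to top-up adaptation, so that the adaptation state
    ## of the first block can carry over (a fresh 3-min re-adaptation would,
    ## by the model's own synaptic time constants, fully erase it)
    seg <- do.call(rbind, lapply(names(orders), function(b) {
      th <- orders[[b]]
      rbind(
        if (b == "DSK")
          data.frame(block = b, kind = "adapt", theta = NA, duration = 180),
        data.frame(
          block = b,
          kind = rep(c("isi", "test", "topup"), length(th)),
          theta = as.vector(rbind(NA, th, NA)),
          duration = rep(c(0.5, 0.5, 15), length(th))
        )
      )
    }))
  }
  rownames(seg) <- NULL
  structure(seg, class = c("episode_schedule", "data.frame"),
            experiment = experiment_id, seed = as.integer(seed),
            test_thetas = if (experiment_id == 3L) test_thetas_exp3()
                          else test_thetas_exp12(),
            reps = reps)
}

#' Remove the adaptation exposure from a schedule
#'
#' Drops all `adapt` and `topup` segments, leaving the test/ISI stream
#' untouched: the control protocol in which no aftereffect should arise.
#'
#' @param schedule an [build_schedule()] result.
#' @return the stripped `episode_schedule`.
#' @export
strip_adaptation <- function(schedule) {
  keep <- !(schedule$kind %in% c("adapt", "topup"))
  out <- schedule[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("experiment", "seed", "test_thetas", "reps"))
    attr(out, a) <- attr(schedule, a)
  class(out) <- class(schedule)
  out
}

#' Mirror a schedule about the horizontal
#'
#' Produces the fully reflected protocol: block labels are swapped (so the
#' USK adaptor is presented first), and every test direction is negated
#' while keeping the temporal order. Together with the mirror-symmetric
#' adapting statistics this maps the session onto its reflection about 0
#' degrees, so the fitted PSE pair of the mirrored run is the sign-mirrored,
#' label-swapped PSE pair of the original.
#'
#' @param schedule an [build_schedule()] result.
#' @return the mirrored `episode_schedule`.
#' @export
mirror_schedule <- function(schedule) {
  out <- schedule
  out$block <- c(DSK = "USK", USK = "DSK")[schedule$block]
  out$theta <- -schedule$theta
  for (a in c("experiment", "seed", "test_thetas", "reps"))
    attr(out, a) <- attr(schedule, a)
  class(out) <- class(schedule)
  out
}

#' Run a simulated psychophysical session
#'
#' Iterates the schedule segments over a persistent circuit state: adapt and
#' top-up segments feed the block's adapting direction statistics, ISI
#' segments feed a blank (zero) signal, and test segments feed the
#' random-dot test signal, after which the probability of an "upward" report
#' is read out from the time-averaged rectified MT response of the test
#' interval. The state carries across trials and across the DSK -> USK block
#' boundary; it is initialized fresh at session start.
#'
#' @param params a [variant_params()].
#' @param schedule an [build_schedule()] result.
#' @param signals list with adapting signals `DSK` and `USK` on the grid;
#'   defaults to [skew_signal_pair()].
#' @param dt Euler step in seconds.
#' @param grid a [direction_grid()].
#' @param test_width,test_amplitude parameters of the test direction signal.
#'   The default amplitude (0.05 of the adapting signal's dominant peak)
#'   keeps the random-dot test a weak probe: strong probes adapt the circuit
#'   themselves and contaminate the aftereffect with test-history effects.
#' @param sample_responses if `TRUE`, additionally draw a Bernoulli response
#'   per trial from `p_up` (column `response`), using R's RNG.
#' @return data frame of trial records (`trial`, `block`, `theta`, `p_up`,
#'   `t`), with attributes `"v_range"` and `"y_range"` tracking the extrema
#'   of the state variables over the entire session, and `"final_state"`.
#' @export
run_experiment <- function(params, schedule, signals = NULL, dt = 0.001,
                           grid = direction_grid(), test_width = 15,
                           test_amplitude = 0.05, sample_responses = FALSE) {
  if (is.null(signals)) signals <- skew_signal_pair(grid)
  if (!all(c("DSK", "USK") %in% names(signals)))
    stop("'signals' must provide DSK and USK adapting signals")
  check_signal(signals$DSK, grid, "DSK signal")
  check_signal(signals$USK, grid, "USK signal")
  kernel <- direction_kernel(params$sigma_c, grid, params$kernel_width_as)
  weights <- readout_weights(grid)
  blank <- rep(0, grid$n)
  state <- circuit_state(grid)
  v_range <- c(0, 0); y_range <- c(1, 1)
  n_tests <- sum(schedule$kind == "test")
  rec <- data.frame(trial = seq_len(n_tests),
                    block = character(n_tests), theta = numeric(n_tests),
                    p_up = numeric(n_tests), t = numeric(n_tests))
  ti <- 0L
  for (i in seq_len(nrow(schedule))) {
    kind <- schedule$kind[i]
    sig <- switch(kind,
                  adapt = , topup = signals[[schedule$block[i]]],
                  isi = blank,
                  test = test_direction_signal(schedule$theta[i], grid,
                                               test_width, test_amplitude))
    state <- run_segment(state, sig, schedule$duration[i], dt, params,
                         grid, kernel)
    v_range <- range(v_range, attr(state, "v_range"))
    y_range <- range(y_range, attr(state, "y_range"))
    if (kind == "test") {
      ti <- ti + 1L
      p <- readout(attr(state, "mean_rect")$mt, weights, params$temp)
      rec$block[ti] <- schedule$block[i]
      rec$theta[ti] <- schedule$theta[i]
      rec$p_up[ti] <- p[["p_up"]]
      rec$t[ti] <- state$t
    }
  }
  if (sample_responses) rec$response <- rbinom(n_tests, 1L, rec$p_up)
  attr(rec, "v_range") <- v_range
  attr(rec, "y_range") <- y_range
  attr(rec, "final_state") <- state
  attr(rec, "experiment") <- attr(schedule, "experiment")
  rec
}

#' Aftereffect summary of one session
#'
#' Fits the psychometric function of each adaptation block and returns the
#' PSE-based summaries.
#'
#' @param trials a [run_experiment()] trial table.
#' @param ... passed to [fit_psychometric()].
#' @return an [aftereffect_summary()] object, with the two fits attached as
#'   attribute `"fits"`.
#' @export
session_summary <- function(trials, ...) {
  fits <- lapply(split(trials, trials$block), function(d)
    fit_psychometric(d$theta, d$p_up, ...))
  out <- aftereffect_summary(fits$USK, fits$DSK)
  attr(out, "fits") <- fits
  out
}

#' Simulate the full variant-by-experiment prediction matrix
#'
#' Runs every requested model variant through every requested experiment
#' protocol and summarizes each cell by its PSE pair, `delta_pse`
#' (USK - DSK) and `sum_pse` (USK + DSK).
#'
#' @param variants integer vector of variant ids.
#' @param experiments integer vector of experiment ids.
#' @param seed seed for the schedules' randomized test orders.
#' @param dt Euler step in seconds.
#' @param grid a [direction_grid()].
#' @param signals adapting signal pair; defaults to [skew_signal_pair()].
#' @param verbose print progress lines.
#' @return data frame with one row per (variant, experiment) cell, plus
#'   attribute `"ranges"`: per-cell state-variable extrema.
#' @export
run_variant_matrix <- function(variants = 1:5, experiments = 1:3,
                               seed = 1L, dt = 0.001,
                               grid = direction_grid(), signals = NULL,
                               verbose = FALSE) {
  if (is.null(signals)) signals <- skew_signal_pair(grid)
  schedules <- lapply(experiments, build_schedule, seed = seed)
  rows <- list(); ranges <- list()
  for (v in variants) {
    pv <- variant_params(v)
    for (k in seq_along(experiments)) {
      e <- experiments[k]
      if (verbose) message(sprintf("variant %d, experiment %d ...", v, e))
      tr <- run_experiment(pv, schedules[[k]], signals, dt, grid)
      tt <- attr(schedules[[k]], "test_thetas")
      ## a block whose psychometric function cannot be summarized (all
      ## responses one category, or no converged fit) yields an NA cell;
      ## evaluate_variant_pattern() treats such cells as failures
      s <- tryCatch(session_summary(tr), error = function(e) e)
      failed <- inherits(s, "error")
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, experiment = e,
        pse_dsk = if (failed) NA_real_ else s$pse_dsk,
        pse_usk = if (failed) NA_real_ else s$pse_usk,
        delta_pse = if (failed) NA_real_ else s$delta_pse,
        sum_pse = if (failed) NA_real_ else s$sum_pse,
        theta_min = min(tt), theta_max = max(tt),
        note = if (failed) conditionMessage(s) else NA_character_)
      ranges[[sprintf("v%d_e%d", v, e)]] <-
        list(v = attr(tr, "v_range"), y = attr(tr, "y_range"))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ranges") <- ranges
  out
}

#' Pass/fail pattern and prediction error across variants
#'
#' Applies the criteria for a psychophysically consistent aftereffect to
#' every cell of a [run_variant_matrix()] table. A cell passes when
#' `delta_pse > delta_min`, `sum_pse < -sum_min`, and both fitted PSEs lie
#' inside the tested direction range (a PSE outside the range means the
#' psychometric function never crossed 50 percent within the measured
#' levels, so the cell is not a valid constant-stimuli measurement); cells
#' whose blocks could not be summarized at all (`NA`) fail.
#'
#' Each variant's average prediction error `err_avg` is the mean distance of
#' its `delta_pse`/`sum_pse` summaries from the reference intervals. The
#' defaults bound each summary by the sign threshold on one side and by the
#' tested range on the other (`delta_pse` in `[delta_min, span]`, `sum_pse`
#' in `[-span, -sum_min]`, `span` the width of the tested direction range);
#' measured psychophysical intervals can be supplied instead. Unsummarizable
#' cells contribute the maximal deviation `span` per summary.
#'
#' @param results a [run_variant_matrix()] data frame covering all requested
#'   cells.
#' @param delta_min threshold (degrees) a positive PSE shift must exceed.
#' @param sum_min magnitude (degrees) the negative PSE-sum bias must exceed.
#'   With the mirror-yoked schedules the PSE sum is free of order-sampling
#'   noise, so the default is a strict sign test (`sum_min = 0`); raise it
#'   when analysing sessions with independently randomized block orders.
#' @param intervals optional list of reference intervals per experiment:
#'   `intervals[[as.character(e)]]$delta` and `$sum`, each `c(lo, hi)` in
#'   degrees, replacing the default intervals in the error computation.
#' @return list with `pattern` (variant x experiment logical matrix of
#'   passes) and `err_avg` (named per-variant mean deviation, degrees).
#' @export
evaluate_variant_pattern <- function(results, delta_min = 0.1,
                                     sum_min = 0, intervals = NULL) {
  variants <- sort(unique(results$variant))
  experiments <- sort(unique(results$experiment))
  full <- nrow(results) == length(variants) * length(experiments)
  if (!full) stop("'results' must contain every variant x experiment cell")
  pattern <- matrix(NA, length(variants), length(experiments),
                    dimnames = list(paste0("variant", variants),
                                    paste0("exp", experiments)))
  err <- numeric(length(variants))
  names(err) <- rownames(pattern)
  for (i in seq_along(variants)) {
    devs <- c()
    for (j in seq_along(experiments)) {
      row <- results[results$variant == variants[i] &
                       results$experiment == experiments[j], ]
      span <- row$theta_max - row$theta_min
      ok <- is.finite(row$delta_pse) && is.finite(row$sum_pse)
      pattern[i, j] <- ok &&
        row$delta_pse > delta_min && row$sum_pse < -sum_min &&
        row$pse_dsk >= row$theta_min && row$pse_dsk <= row$theta_max &&
        row$pse_usk >= row$theta_min && row$pse_usk <= row$theta_max
      iv <- if (!is.null(intervals)) intervals[[as.character(experiments[j])]]
      d_iv <- if (!is.null(iv)) iv$delta else c(delta_min, span)
      s_iv <- if (!is.null(iv)) iv$sum else c(-span, -sum_min)
      devs <- c(devs,
                if (ok) interval_deviation(row$delta_pse, d_iv) else span,
                if (ok) interval_deviation(row$sum_pse, s_iv) else span)
    }
    err[i] <- mean(devs)
  }
  list(pattern = pattern, err_avg = err)
}
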