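g <- direction_grid()

test_that("the direction grid places 37 units symmetrically at 5-degree steps", {
  expect_equal(g$n, 37L)
  expect_equal(g$angles, seq(-90, 90, by = 5))
  expect_equal(g$angles, -rev(g$angles))
  expect_error(direction_grid(span = c(-80, 90)), "symmetric")
})

test_that("variant parameter tuples reproduce the published table", {
  v1 <- variant_params(1)
  expect_equal(c(v1$lam, v1$alpha_ff, v1$beta_ff, v1$temp),
               c(0, 0.0005, 9, 0.00001))
  v3 <- variant_params(3); v4 <- variant_params(4); v5 <- variant_params(5)
  expect_equal(c(v3$lam, v3$alpha_fb, v3$beta_fb), c(20, 0, 0))
  expect_equal(c(v4$alpha_ff, v4$beta_ff, v4$alpha_fb, v4$beta_fb),
               c(0, 0, 0.04, 1.2))
  ## variant 5 = variant 3 FF rates + variant 4 FB rates
  expect_equal(c(v5$alpha_ff, v5$beta_ff), c(v3$alpha_ff, v3$beta_ff))
  expect_equal(c(v5$alpha_fb, v5$beta_fb), c(v4$alpha_fb, v4$beta_fb))
  for (v in 1:5) {
    p <- variant_params(v)
    expect_equal(c(p$tau, p$tau_syn, p$sigma_c, p$n), c(0.030, 1, 45, 37))
  }
  expect_error(variant_params(6), "1..5")
})

test_that("direction kernel rows are normalized, symmetric and delta-limiting", {
  K <- direction_kernel(45, g)
  expect_equal(rowSums(K), rep(1, g$n))
  ## interior symmetry: equal weight at equal direction offsets
  expect_equal(K[19, 19 + 3], K[19, 19 - 3])
  expect_equal(K[10, 10 + 5], K[10, 10 - 5])
  ## narrow-width limit is the identity
  K0 <- direction_kernel(1e-6, g, width_as = "sd")
  expect_equal(K0, diag(g$n), tolerance = 1e-12)
  expect_error(direction_kernel(-1, g), "> 0")
})

test_that("readout weights are mirror images about 0 degrees", {
  w <- readout_weights(g)
  expect_equal(w$g_up, rev(w$g_down))
  expect_equal(which.max(w$g_up), g$n)
})

test_that("drives follow the stated model equations", {
  p <- variant_params(5)
  K <- direction_kernel(p$sigma_c, g, p$kernel_width_as)
  st <- circuit_state(g)
  r <- test_direction_signal(0, g)

  ## lambda = 0: V1 excitation is exactly the filtered input
  p0 <- variant_params("custom", lam = 0)
  d0 <- compute_drives(st, r, p0, g, K)
  expect_equal(d0$i_ex_v1, drop(K %*% r))

  ## silent MT: no modulation, V1 excitation independent of y_fb
  st2 <- st; st2$y_fb <- runif(g$n)
  d1 <- compute_drives(st, r, p, g, K)
  d2 <- compute_drives(st2, r, p, g, K)
  expect_equal(d1$i_mod_v1, rep(0, g$n))
  expect_equal(d1$i_ex_v1, d2$i_ex_v1)

  ## uniform input, uniform state: pool inhibition equals each excitation
  ru <- rep(0.4, g$n)
  du <- compute_drives(st, ru, p, g, K)
  expect_equal(du$i_ex_v1, rep(du$i_inh_v1, g$n))
  expect_equal(du$i_inh_v1, mean(du$i_ex_v1))

  ## membrane potentials act presynaptically only through rectification
  st3 <- st; st3$v_v1 <- rep(-0.5, g$n)
  d3 <- compute_drives(st3, r, p, g, K)
  expect_equal(d3$i_ex_mt, rep(0, g$n))
})

test_that("steady-state formulas match their closed forms", {
  expect_equal(steady_state_membrane(1, 0), 0.5)
  expect_equal(steady_state_membrane(0.3, 0.3), 0)
  expect_gt(steady_state_membrane(1e6, 1), 0.999)
  expect_gt(steady_state_membrane(0, 1e6), -1)
  expect_error(steady_state_membrane(-0.1, 0), ">= 0")

  expect_equal(steady_state_synapse(1, 10, 0), 1)
  expect_equal(steady_state_synapse(0.7, 0, 0.5), 1)
  expect_equal(steady_state_synapse(1.2, 10, 1), 0.1071428571, tolerance = 1e-9)
  expect_equal(steady_state_synapse(0.04, 1.2, 1), 0.0322580645, tolerance = 1e-9)
  expect_error(steady_state_synapse(0, 1.2, 0), "undefined")
})

test_that("a quiescent circuit with zero input is a fixed point of step()", {
  p <- variant_params(5)
  st <- circuit_state(g)
  st2 <- step(st, rep(0, g$n), 0.001, p, g)
  expect_equal(st2$v_v1, st$v_v1)
  expect_equal(st2$v_mt, st$v_mt)
  expect_equal(st2$y_ff, st$y_ff)
  expect_equal(st2$y_fb, st$y_fb)
  expect_equal(st2$t, 0.001)
  expect_error(step(st, rep(0, g$n), 0.01, p, g), "dt")
})

test_that("compiled segment integration reproduces the R reference step", {
  p <- variant_params(5)
  K <- direction_kernel(p$sigma_c, g, p$kernel_width_as)
  sig <- skew_signal_pair(g)$DSK
  stR <- circuit_state(g)
  for (i in 1:150) stR <- step(stR, sig, 0.001, p, g, K)
  stC <- run_segment(circuit_state(g), sig, 0.150, 0.001, p, g, K)
  expect_equal(stC$v_v1, stR$v_v1, tolerance = 1e-13)
  expect_equal(stC$v_mt, stR$v_mt, tolerance = 1e-13)
  expect_equal(stC$y_ff, stR$y_ff, tolerance = 1e-13)
  expect_equal(stC$y_fb, stR$y_fb, tolerance = 1e-13)
  expect_equal(stC$t, stR$t)
})

test_that("segments expose time averages, extrema and trajectories", {
  p <- variant_params(5)
  sig <- skew_signal_pair(g)$DSK
  st0 <- circuit_state(g)
  same <- run_segment(st0, sig, 0, 0.001, p, g)
  expect_equal(same$v_v1, st0$v_v1)
  out <- run_segment(st0, sig, 0.2, 0.001, p, g, record_stride = 50L)
  mr <- attr(out, "mean_rect")
  expect_true(all(mr$v1 >= 0) && all(mr$mt >= 0))
  traj <- attr(out, "trajectory")
  expect_equal(dim(traj), c(4L, 1L + 4L * g$n))
  expect_equal(traj[, 1], c(0.05, 0.10, 0.15, 0.20))
  ## final trajectory row equals the final state
  expect_equal(traj[4, 1 + seq_len(g$n)], out$v_v1, ignore_attr = TRUE)
})

test_that("blank input lets depleted synapses replenish toward 1", {
  p <- variant_params(5)
  sig <- skew_signal_pair(g)$DSK
  adapted <- run_segment(circuit_state(g), sig, 1, 0.001, p, g)
  expect_lt(min(adapted$y_ff), 0.6)
  rested <- run_segment(adapted, rep(0, g$n), 5 / p$alpha_ff, 0.001, p, g)
  expect_gt(min(rested$y_ff), 0.99)
})

test_that("halving the step size changes a 1-s trajectory only at first order", {
  ## forward-Euler halving error is bounded by ~0.1 * (dt * rate) * amplitude
  ## with membrane rates up to (1 + I_ex + I_inh)/tau ~ 60/s and |v| < 0.4,
  ## i.e. about 2e-3 at dt = 1 ms
  p <- variant_params(5)
  sig <- skew_signal_pair(g)$DSK
  a <- run_segment(circuit_state(g), sig, 1, 0.001, p, g)
  b <- run_segment(circuit_state(g), sig, 1, 0.0005, p, g)
  expect_lt(max(abs(a$v_v1 - b$v_v1)), 2e-3)
  expect_lt(max(abs(a$v_mt - b$v_mt)), 2e-3)
  expect_lt(max(abs(a$y_ff - b$y_ff)), 2e-3)
})

test_that("softmax readout is symmetric, temperature-limited and stable", {
  w <- readout_weights(g)
  sym <- test_direction_signal(0, g)  # symmetric about 0
  p <- readout(sym, w, temp = 0.001)
  expect_equal(unname(p["p_up"]), 0.5)
  expect_equal(sum(p), 1)
  up <- test_direction_signal(40, g)
  expect_gt(readout(up, w, 0.001)[["p_up"]], 0.5)
  ## hard-choice limit is numerically safe
  expect_equal(readout(up, w, 1e-12)[["p_up"]], 1)
  ## swapping the channels swaps the probabilities
  swapped <- list(g_up = w$g_down, g_down = w$g_up)
  expect_equal(readout(up, swapped, 0.001)[["p_down"]],
               readout(up, w, 0.001)[["p_up"]])
  expect_error(readout(up, w, 0), "> 0")
})

test_that("mirroring the input mirrors responses and swaps the decision", {
  p <- variant_params(5)
  sig <- skew_signal_pair(g)$DSK
  a <- run_segment(circuit_state(g), sig, 0.3, 0.001, p, g)
  b <- run_segment(circuit_state(g), rev(sig), 0.3, 0.001, p, g)
  expect_equal(b$v_v1, rev(a$v_v1), tolerance = 1e-12)
  expect_equal(b$v_mt, rev(a$v_mt), tolerance = 1e-12)
  expect_equal(b$y_ff, rev(a$y_ff), tolerance = 1e-12)
  w <- readout_weights(g)
  expect_equal(readout(b$v_mt, w, p$temp)[["p_up"]],
               readout(a$v_mt, w, p$temp)[["p_down"]], tolerance = 1e-12)
})

test_that("unadapted probe tuning peaks at the probe direction", {
  p <- variant_params(5)
  pt <- probe_tuning(circuit_state(g), 0, p, probe_duration = 0.15)
  expect_equal(g$angles[which.max(pt$v1[, 1])], 0)
  expect_equal(g$angles[which.max(pt$mt[, 1])], 0)
  expect_equal(max(pt$v1[, 1]), 1)  # max-normalized
})

test_that("interpolated peaks and peak finding behave on known curves", {
  x <- seq(-90, 90, by = 5)
  curve <- exp(-(x - 12)^2 / (2 * 20^2))
  expect_equal(response_peak(curve, x), 12, tolerance = 0.2)
  bim <- exp(-(x + 50)^2 / 200) + 0.7 * exp(-x^2 / 200)
  expect_equal(x[find_peaks(bim, 0.05)], c(-50, 0))
  expect_equal(length(find_peaks(rep(1, 37), 0.05)), 0)
  ## a minor wiggle below the prominence cut is not a peak
  wig <- exp(-(x)^2 / (2 * 30^2)); wig[10] <- wig[10] + 0.01
  expect_equal(x[find_peaks(wig, 0.05)], 0)
})
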