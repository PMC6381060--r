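test_that("skew map matches the closed-form shear and its determinant", {
  ## (0, 100) -> (tan(25 deg) * 100, 100)
  p <- skew_point(c(0, 100), 25)
  expect_equal(p, c(tan(25 * pi / 180) * 100, 100), tolerance = 1e-12)
  expect_equal(p[1], 46.630765815, tolerance = 1e-8)
  expect_equal(det(skew_matrix(25)), 1 - tan(25 * pi / 180)^2,
               tolerance = 1e-12)
  ## composing +psi then -psi scales centered coordinates by (1 - tan^2 psi)
  xy <- cbind(c(10, -30, 5), c(-7, 12, 40))
  back <- skew_point(skew_point(xy, 25), -25)
  expect_equal(back, xy * (1 - tan(25 * pi / 180)^2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(skew_matrix(45), "invertible")
  expect_error(skew_matrix(NA), "finite")
})

test_that("apply_skew is the identity at psi = 0 and rejects bad input", {
  img <- matrix(runif(40 * 40), 40, 40)
  out <- apply_skew(img, 0, crop = NA)
  expect_equal(out, img, tolerance = 1e-12)
  crop <- apply_skew(img, 0)
  expect_equal(dim(crop), rep(floor(40 * 650 / 720), 2))
  skewed <- apply_skew(img, 25)
  expect_true(all(skewed >= min(img) - 1e-12 & skewed <= max(img) + 1e-12))
  bad <- img; bad[3, 3] <- NA
  expect_error(apply_skew(bad, 10), "non-finite")
  expect_error(apply_skew(img, 50), "invertible")
})

test_that("apply_skew moves an off-center point to its forward-mapped pixel", {
  ## pixel coordinates: x rightward, y downward; a spot at (x, y) must land
  ## at (x + tan(psi) y, tan(psi) x + y)
  img <- matrix(0, 101, 101)
  img[51, 81] <- 1  # x = +30, y = 0
  out <- apply_skew(img, 25, crop = NA)
  w <- which(out == max(out), arr.ind = TRUE)[1, ]
  expect_equal(unname(w["col"]), 81)  # x unchanged when y = 0
  expect_equal(unname(w["row"]), 51 + round(tan(25 * pi / 180) * 30))
})

test_that("hanning window has the closed-form radial profile", {
  n <- 129
  w <- hanning_window(n)
  c0 <- (n + 1) / 2
  expect_equal(w[c0, c0], 1)                            # r = 0
  ## radial profile equals cos^2(pi r / N) out to r = N/2 (0.5 at r = N/4)
  r <- 0:63
  expect_equal(w[c0, c0 + r], cos(pi * r / n)^2, tolerance = 1e-12)
  expect_equal(cos(pi * (n / 4) / n)^2, 0.5)
  expect_equal(w[1, 1], 0)                              # corner, r > N/2
  expect_true(all(w >= 0 & w <= 1))
  ## windowing an all-ones image is the mask itself
  expect_equal(matrix(1, n, n) * w, w)
  ## monotone non-increasing along a radius
  profile <- w[c0, c0:(c0 + 64)]
  expect_true(all(diff(profile) <= 1e-12))
  expect_error(hanning_window(0), ">")
})

test_that("dot updates translate by speed * dt and conserve the dot count", {
  f <- dot_field(n_dots = 500, direction = 0, speed = 3, seed = 1)
  f2 <- update_dots(f, dt = 0.01)
  surv <- which(sqrt(rowSums(f$positions^2)) < f$outer_diameter / 2 - 0.05)
  expect_equal(f2$positions[surv, 1] - f$positions[surv, 1],
               rep(0.03, length(surv)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(f2$positions[surv, 2], f$positions[surv, 2])
  expect_equal(nrow(f2$positions), 500)

  up <- update_dots(dot_field(100, direction = 90, seed = 2), dt = 0.02)
  f0 <- dot_field(100, direction = 90, seed = 2)
  surv <- which(sqrt(rowSums(f0$positions^2)) < f0$outer_diameter / 2 - 0.1)
  expect_equal(up$positions[surv, 1], f0$positions[surv, 1])
  expect_equal(up$positions[surv, 2] - f0$positions[surv, 2],
               rep(0.06, length(surv)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(update_dots(f, dt = 0), "> 0")
})

test_that("dots leaving the annulus are repositioned inside it", {
  ## narrow annulus, large step: most dots exit and must be redrawn inside
  f <- dot_field(n_dots = 300, direction = 0, speed = 3,
                 outer_diameter = 2, inner_diameter = 1, seed = 3)
  f2 <- update_dots(f, dt = 0.5, seed = 4)
  r <- sqrt(rowSums(f2$positions^2))
  expect_true(all(r <= 1 + 1e-12 & r >= 0.5 - 1e-12))
  expect_equal(nrow(f2$positions), 300)
  expect_gt(attr(f2, "n_repositioned"), 0)
})

test_that("ensemble mean displacement of surviving dots is speed * dt * u", {
  th <- 30; sp <- 3; dt <- 0.05
  deltas <- matrix(0, 0, 2)
  for (seed in 1:20) {
    f <- dot_field(200, direction = th, speed = sp, seed = seed)
    f2 <- update_dots(f, dt)
    moved <- f2$positions - f$positions
    kept <- rowSums(abs(moved)) < 2 * sp * dt   # exclude repositioned dots
    deltas <- rbind(deltas, moved[kept, ])
  }
  expect_equal(colMeans(deltas),
               sp * dt * c(cos(th * pi / 180), sin(th * pi / 180)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("surrogate movies are deterministic and carry coherent motion", {
  m1 <- synth_movie(n_frames = 8, size = 32, seed = 5)
  m2 <- synth_movie(n_frames = 8, size = 32, seed = 5)
  expect_identical(m1$frames, m2$frames)
  expect_true(all(vapply(m1$frames, function(f) all(f >= 0 & f <= 1),
                         logical(1))))
  ## displacement between consecutive frames matches the requested motion
  m <- synth_movie(n_frames = 3, size = 48, speed = 2, direction_mean = 0,
                   seed = 6)
  expect_equal(oracle_displacement(m$frames[[1]], m$frames[[2]]), c(2, 0))
  up <- synth_movie(n_frames = 3, size = 48, speed = 2, direction_mean = 90,
                    seed = 6)
  expect_equal(oracle_displacement(up$frames[[1]], up$frames[[2]]), c(0, 2))
  expect_error(synth_movie(n_frames = 1), ">= 2")
  expect_error(synth_movie(size = 8), "at least 16")
})

test_that("direction statistics signals match their stated structure", {
  g <- direction_grid()
  dsk <- direction_stats_signal(direction_stats_model("DSK"), g)
  usk <- direction_stats_signal(direction_stats_model("USK"), g)
  unsk <- direction_stats_signal(direction_stats_model("UnSK"), g)
  expect_equal(g$angles[which.max(dsk)], -50)
  expect_equal(g$angles[which.max(usk)], 50)
  expect_equal(g$angles[which.max(unsk)], 0)
  ## USK is the exact mirror of DSK about 0 degrees
  expect_equal(usk, rev(dsk))
  expect_true(all(dsk >= 0) && all(usk >= 0) && all(unsk >= 0))
  expect_true(all(is.finite(c(dsk, usk, unsk))))
  ## DSK is bimodal over the baseline: dominant mode plus horizontal remnant
  expect_equal(g$angles[find_peaks(dsk, 0.05)], c(-50, 0))
})

test_that("test direction signals are symmetric Gaussian bumps on the grid", {
  g <- direction_grid()
  s0 <- test_direction_signal(0, g)
  expect_equal(s0, rev(s0))
  expect_equal(g$angles[which.max(s0)], 0)
  expect_equal(max(s0), 1)
  sp <- test_direction_signal(6.6, g)
  sm <- test_direction_signal(-6.6, g)
  expect_equal(sp, rev(sm))
  s13 <- test_direction_signal(13, g)
  expect_equal(g$angles[which.max(s13)], 15)  # grid node nearest 13
  expect_error(test_direction_signal(95, g), "outside")
})
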