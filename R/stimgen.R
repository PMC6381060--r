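## Stimulus generation: skew (shear) geometric distortion of grayscale
## frames, circular Hanning aperture, random-dot test stimuli, surrogate
## naturalistic movies, and parametric direction-statistics signals.

#' Skew (shear) coordinate map
#'
#' The linear forward map of the skew distortion about the image center:
#' `(x, y) -> (x + tan(psi) * y, tan(psi) * x + y)`. Its determinant is
#' `1 - tan(psi)^2`, so the map is invertible for `|psi| < 45` degrees.
#'
#' @param psi shear angle in degrees.
#' @return `skew_matrix()`: the 2 x 2 forward matrix. `skew_point()`: the
#'   mapped coordinates (rows of `xy` are points `(x, y)`).
#' @examples
#' skew_point(c(0, 100), 25)  # x_d = tan(25 deg) * 100 = 46.63
#' det(skew_matrix(25))       # 1 - tan(25 deg)^2
#' @export
skew_matrix <- function(psi) {
  check_psi(psi)
  t <- tanpi(psi / 180)
  matrix(c(1, t, t, 1), 2, 2)
}

#' @rdname skew_matrix
#' @param xy numeric vector `c(x, y)` or a two-column matrix of points.
#' @export
skew_point <- function(xy, psi) {
  m <- skew_matrix(psi)
  if (is.matrix(xy)) t(m %*% t(xy)) else drop(m %*% xy)
}

check_psi <- function(psi) {
  if (!is.numeric(psi) || length(psi) != 1 || !is.finite(psi))
    stop("'psi' must be a single finite shear angle in degrees")
  if (abs(tanpi(psi / 180)) >= 1)
    stop("skew map is not invertible: |tan(psi)| >= 1 (need |psi| < 45 deg)")
  invisible(psi)
}

#' Apply a skew distortion to a grayscale image
#'
#' Resamples the image under the skew map about the image center using the
#' inverse map with bilinear interpolation (so every output pixel is defined,
#' with no holes), then crops the central square where the sheared edges are
#' removed. Samples falling outside the input are taken from the nearest edge
#' pixel; in the stimulus pipeline these regions are subsequently zeroed by
#' the circular aperture.
#'
#' @param image numeric matrix, grayscale values (finite).
#' @param psi shear angle in degrees, `|psi| < 45`.
#' @param crop output side length in pixels; `NULL` (default) keeps the
#'   central square of `floor(min(dim) * 650/720)` pixels, the proportion
#'   used at full stimulus scale (650 of 720); `NA` disables cropping.
#' @return numeric matrix, the distorted (and cropped) image; values stay in
#'   the input range.
#' @export
apply_skew <- function(image, psi, crop = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix")
  if (any(!is.finite(image))) stop("'image' contains non-finite pixels")
  check_psi(psi)
  nr <- nrow(image); nc <- ncol(image)
  t <- tanpi(psi / 180)
  det <- 1 - t^2
  ## inverse of [[1, t], [t, 1]]
  inv <- matrix(c(1, -t, -t, 1), 2, 2) / det
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  ## output pixel grid in centered pixel coordinates (x right, y down: the
  ## image-matrix convention in which the shear map remaps pixel positions;
  ## an up-skew, psi > 0, then shifts detected motion statistics upward)
  xs <- (seq_len(nc) - cx)
  ys <- (seq_len(nr) - cy)
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  U <- inv[1, 1] * X + inv[1, 2] * Y  # source x
  V <- inv[2, 1] * X + inv[2, 2] * Y  # source y
  col_s <- U + cx
  row_s <- V + cy
  out <- bilinear_sample(image, row_s, col_s)
  if (!is.null(crop) && is.na(crop)) return(out)
  side <- if (is.null(crop)) floor(min(nr, nc) * 650 / 720) else as.integer(crop)
  if (side < 1 || side > min(nr, nc)) stop("invalid 'crop' size")
  r0 <- floor((nr - side) / 2)
  c0 <- floor((nc - side) / 2)
  out[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
}

## Bilinear interpolation with edge replication; row_s/col_s are fractional
## source positions, matrices the size of the output.
bilinear_sample <- function(image, row_s, col_s) {
  nr <- nrow(image); nc <- ncol(image)
  r0 <- pmin(pmax(floor(row_s), 1), nr)
  c0 <- pmin(pmax(floor(col_s), 1), nc)
  r1 <- pmin(r0 + 1, nr)
  c1 <- pmin(c0 + 1, nc)
  fr <- pmin(pmax(row_s - r0, 0), 1)
  fc <- pmin(pmax(col_s - c0, 0), 1)
  idx <- function(r, c) image[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fr) * (1 - fc) * idx(r0, c0) + (1 - fr) * fc * idx(r0, c1) +
    fr * (1 - fc) * idx(r1, c0) + fr * fc * idx(r1, c1)
  matrix(v, nr, nc)
}

#' Circular Hanning aperture mask
#'
#' Raised-cosine weight as a function of the radial distance from the image
#' center: `w(r) = cos^2(pi * r / N)` out to radius `N/2` and 0 beyond, so
#' the center has weight 1 and the weight falls monotonically to 0 at radius
#' `N/2`.
#'
#' @param n window extent `N` in pixels (the mask is `n x n`).
#' @return an `n x n` numeric weight matrix in \[0, 1\].
#' @examples
#' w <- hanning_window(129)
#' w[65, 65]  # 1 at the center
#' @export
hanning_window <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0) stop("'n' must be > 0")
  n <- as.integer(n)
  c0 <- (n + 1) / 2
  d <- seq_len(n) - c0
  r <- sqrt(outer(d^2, d^2, "+"))
  w <- cos(pi * r / n)^2
  w[r > n / 2] <- 0
  w
}

#' Random-dot test stimulus
#'
#' A field of dots placed uniformly inside a circular annulus, moving
#' coherently at a fixed speed along direction `theta` (degrees, positive =
#' upward). Dots that leave the annulus are redrawn uniformly inside it so
#' the dot count is conserved. Geometry defaults follow the psychophysical
#' display: a 17.6-degree aperture with 2000 dots of 0.14 degrees moving at
#' 3 degrees per second.
#'
#' @param n_dots number of dots.
#' @param direction motion direction `theta` in degrees.
#' @param speed dot speed in degrees of visual angle per second.
#' @param outer_diameter,inner_diameter annulus diameters in degrees.
#' @param dot_diameter dot size in degrees (metadata only).
#' @param seed optional integer seed for the initial placement.
#' @return an object of class `dot_field` with a two-column `positions`
#'   matrix (degrees, image center at the origin) and the motion settings.
#' @export
dot_field <- function(n_dots = 2000, direction = 0, speed = 3,
                      outer_diameter = 17.6, inner_diameter = 0,
                      dot_diameter = 0.14, seed = NULL) {
  if (n_dots < 1) stop("'n_dots' must be >= 1")
  if (inner_diameter < 0 || outer_diameter <= inner_diameter)
    stop("need 0 <= inner_diameter < outer_diameter")
  if (!is.null(seed)) set.seed(seed)
  pos <- draw_in_annulus(n_dots, inner_diameter / 2, outer_diameter / 2)
  structure(list(positions = pos, direction = direction, speed = speed,
                 outer_diameter = outer_diameter,
                 inner_diameter = inner_diameter,
                 dot_diameter = dot_diameter, n_dots = as.integer(n_dots)),
            class = "dot_field")
}

draw_in_annulus <- function(n, r_in, r_out) {
  r <- sqrt(runif(n, r_in^2, r_out^2))
  a <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(a), y = r * sin(a))
}

#' Advance a random-dot field by one time step
#'
#' Every dot is translated by `speed * dt` along the field's direction
#' (`(cos theta, sin theta)` in degrees); dots whose centers leave the
#' annulus are repositioned uniformly inside it from the seeded generator.
#' The dot count never changes.
#'
#' @param field a [dot_field()].
#' @param dt time step in seconds (> 0).
#' @param seed optional integer seed controlling the repositioning draws.
#' @return the updated `dot_field`; the number of repositioned dots is
#'   attached as attribute `"n_repositioned"`.
#' @export
update_dots <- function(field, dt, seed = NULL) {
  if (!inherits(field, "dot_field")) stop("'field' must be a dot_field")
  if (field$n_dots < 1 || nrow(field$positions) < 1) stop("empty dot field")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  th <- field$direction * pi / 180
  d <- field$speed * dt
  pos <- field$positions
  pos[, 1] <- pos[, 1] + d * cos(th)
  pos[, 2] <- pos[, 2] + d * sin(th)
  r <- sqrt(rowSums(pos^2))
  out <- r > field$outer_diameter / 2 | r < field$inner_diameter / 2
  if (any(out))
    pos[out, ] <- draw_in_annulus(sum(out), field$inner_diameter / 2,
                                  field$outer_diameter / 2)
  field$positions <- pos
  attr(field, "n_repositioned") <- sum(out)
  field
}

#' Surrogate naturalistic movie
#'
#' Generates a grayscale image sequence with a 1/f-like spatial amplitude
#' spectrum translating coherently, as a desk-scale stand-in for natural
#' movie input: a random-phase 1/f texture is shifted by a subpixel Fourier
#' phase ramp from frame to frame, with the translation direction and speed
#' redrawn every `segment_length` frames (piecewise-coherent motion).
#' Deterministic for a fixed seed.
#'
#' @param n_frames number of frames (>= 2).
#' @param size frame side length in pixels (>= 16).
#' @param speed mean translation speed in pixels per frame.
#' @param direction_mean,direction_sd Normal distribution (degrees) of the
#'   per-segment motion direction; the default concentrates motion around
#'   horizontal, emulating the horizontal dominance of natural sequences.
#' @param speed_sd standard deviation of the per-segment speed.
#' @param segment_length frames per coherent-motion segment.
#' @param spectral_slope exponent of the `1/f^slope` amplitude spectrum.
#' @param frame_rate frames per second (metadata).
#' @param seed integer seed.
#' @return an object of class `image_sequence`: list with `frames` (list of
#'   `size x size` matrices in \[0, 1\]), `frame_rate`, and the per-frame
#'   `directions` and `speeds` actually used.
#' @export
synth_movie <- function(n_frames = 50, size = 64, speed = 1.5,
                        direction_mean = 0, direction_sd = 0, speed_sd = 0,
                        segment_length = 10, spectral_slope = 1,
                        frame_rate = 25, seed = 1) {
  if (n_frames < 2) stop("'n_frames' must be >= 2")
  if (size < 16) stop("'size' must be at least 16 pixels")
  set.seed(seed)
  fx <- fft_freq(size)
  f2 <- sqrt(outer(fx^2, fx^2, "+"))
  amp <- 1 / pmax(f2, fx[2])^spectral_slope  # flat at DC
  phase <- matrix(runif(size^2, 0, 2 * pi), size, size)
  spec <- amp * exp(1i * phase)
  base <- Re(fft(spec, inverse = TRUE)) / size^2
  base <- (base - min(base)) / (max(base) - min(base))
  base_f <- fft(base)

  n_seg <- ceiling(n_frames / segment_length)
  seg_dir <- rnorm(n_seg, direction_mean, direction_sd)
  seg_spd <- pmax(rnorm(n_seg, speed, speed_sd), 0.1)
  dirs <- rep(seg_dir, each = segment_length)[seq_len(n_frames)]
  spds <- rep(seg_spd, each = segment_length)[seq_len(n_frames)]

  ## cumulative displacement; frame k is the base texture shifted by the
  ## running offset (periodic wraparound via the Fourier shift theorem)
  ox <- cumsum(c(0, spds[-n_frames] * cos(dirs[-n_frames] * pi / 180)))
  oy <- cumsum(c(0, spds[-n_frames] * sin(dirs[-n_frames] * pi / 180)))
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames))
    frames[[k]] <- fft_shift_image(base_f, ox[k], oy[k], size)
  structure(list(frames = frames, frame_rate = frame_rate, size = size,
                 directions = dirs, speeds = spds),
            class = "image_sequence")
}

fft_freq <- function(n) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / n
}

## shift an image (given its FFT) by (dx, dy) pixels, x rightward (columns),
## y upward (decreasing row index); periodic boundary
fft_shift_image <- function(image_f, dx, dy, n) {
  f <- fft_freq(n)
  ## rows index y downward; shifting content up by dy = shifting along rows
  ## by -dy
  ramp_r <- exp(-2i * pi * f * (-dy))
  ramp_c <- exp(-2i * pi * f * dx)
  shifted <- image_f * outer(ramp_r, ramp_c)
  out <- Re(fft(shifted, inverse = TRUE)) / n^2
  pmin(pmax(out, 0), 1)
}

#' @export
print.image_sequence <- function(x, ...) {
  cat(sprintf("<image_sequence> %d frames of %d x %d px at %g fps\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$frame_rate))
  invisible(x)
}

#' Apply a skew distortion to every frame of a sequence
#'
#' Convenience wrapper around [apply_skew()] for [synth_movie()] output.
#' @param seq an `image_sequence`.
#' @inheritParams apply_skew
#' @return a new `image_sequence` of cropped, distorted frames.
#' @export
skew_sequence <- function(seq, psi, crop = NULL) {
  if (!inherits(seq, "image_sequence")) stop("'seq' must be an image_sequence")
  seq$frames <- lapply(seq$frames, apply_skew, psi = psi, crop = crop)
  seq$size <- nrow(seq$frames[[1]])
  seq
}

#' Parametric direction-statistics model of the adapting input
#'
#' Describes the pooled motion-direction energy of an adapting image
#' sequence as a broadband baseline plus Gaussian components. The built-in
#' conditions emulate the statistics of naturalistic sequences: un-skewed
#' (`"UnSK"`) input is dominated by horizontal directions (component at 0
#' degrees); down-skew (`"DSK"`) moves the dominant component to -50 degrees
#' and up-skew (`"USK"`) to +50 degrees, each retaining a weaker horizontal
#' remnant so the skewed statistics are bimodal over a broadband floor. USK
#' and DSK are exact mirror images about 0 degrees.
#'
#' @param condition `"UnSK"`, `"USK"` or `"DSK"`.
#' @param baseline uniform broadband energy level (>= 0).
#' @param dominant_amp,dominant_width amplitude and Gaussian SD (degrees) of
#'   the dominant component.
#' @param secondary_amp,secondary_width amplitude and SD of the residual
#'   horizontal component in the skewed conditions.
#' @param dominant_center magnitude (degrees) of the skewed dominant
#'   direction.
#' @return object of class `direction_stats_model` with fields `baseline`,
#'   `components` (matrix with columns `center`, `width`, `amplitude`) and
#'   `condition`.
#' @export
direction_stats_model <- function(condition = c("UnSK", "USK", "DSK"),
                                  baseline = 0.1,
                                  dominant_amp = 1, dominant_width = 12,
                                  secondary_amp = 0.7, secondary_width = 12,
                                  dominant_center = 50) {
  condition <- match.arg(condition)
  if (baseline < 0 || dominant_amp < 0 || secondary_amp < 0)
    stop("baseline and amplitudes must be >= 0")
  comp <- switch(
    condition,
    UnSK = cbind(center = 0, width = dominant_width, amplitude = dominant_amp),
    DSK = cbind(center = c(-dominant_center, 0),
                width = c(dominant_width, secondary_width),
                amplitude = c(dominant_amp, secondary_amp)),
    USK = cbind(center = c(dominant_center, 0),
                width = c(dominant_width, secondary_width),
                amplitude = c(dominant_amp, secondary_amp))
  )
  structure(list(baseline = baseline, components = comp, condition = condition),
            class = "direction_stats_model")
}

#' Evaluate a direction-statistics model on the grid
#'
#' @param model a [direction_stats_model()].
#' @param grid a [direction_grid()].
#' @return non-negative numeric direction signal over the grid.
#' @export
direction_stats_signal <- function(model, grid = direction_grid()) {
  if (!inherits(model, "direction_stats_model"))
    stop("'model' must be a direction_stats_model")
  sig <- rep(model$baseline, grid$n)
  for (i in seq_len(nrow(model$components))) {
    c0 <- model$components[i, "center"]
    w <- model$components[i, "width"]
    a <- model$components[i, "amplitude"]
    sig <- sig + a * exp(-(grid$angles - c0)^2 / (2 * w^2))
  }
  sig
}

#' Pair of adapting direction signals for the two skew conditions
#'
#' @param grid a [direction_grid()].
#' @param ... passed on to [direction_stats_model()].
#' @return list with numeric signals `DSK` and `USK` on the grid.
#' @export
skew_signal_pair <- function(grid = direction_grid(), ...) {
  list(DSK = direction_stats_signal(direction_stats_model("DSK", ...), grid),
       USK = direction_stats_signal(direction_stats_model("USK", ...), grid))
}

#' Direction signal of a random-dot test stimulus
#'
#' A Gaussian bump over the direction grid centered at the test motion
#' direction, with a width (standard deviation) of 15 degrees and a
#' configurable peak amplitude. This is the input the recurrent stage
#' receives during a test interval.
#'
#' @param theta test motion direction in degrees; must lie within the grid
#'   range.
#' @param grid a [direction_grid()].
#' @param width Gaussian standard deviation in degrees.
#' @param amplitude peak amplitude.
#' @return numeric direction signal on the grid.
#' @export
test_direction_signal <- function(theta, grid = direction_grid(), width = 15,
                                  amplitude = 1) {
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta))
    stop("'theta' must be a single finite direction in degrees")
  if (theta < grid$angles[1] || theta > grid$angles[grid$n])
    stop(sprintf("'theta' = %g deg lies outside the grid range [%g, %g]",
                 theta, grid$angles[1], grid$angles[grid$n]))
  amplitude * exp(-(grid$angles - theta)^2 / (2 * width^2))
}
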