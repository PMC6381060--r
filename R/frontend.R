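## Motion front-end: correlation-based (elaborated Reichardt / motion
## energy) detection of local motion from grayscale image sequences,
## divisive center-surround normalization and pooling to the direction
## signal consumed by the recurrent circuit.

#' Front-end filter-bank specification
#'
#' Parameters of the staged front-end: an isotropic difference-of-Gaussians
#' (DoG) retina/LGN filter, an oriented spatial smoothing stage per motion
#' direction, and delayed cross-correlation between consecutive (filtered)
#' frames with opponent subtraction.
#'
#' @param directions motion directions in degrees covered by the detector
#'   bank; defaults to the circuit's [direction_grid()] angles.
#' @param delay temporal delay in frames between the correlated samples
#'   (>= 1).
#' @param lgn_center_sigma,lgn_surround_sigma DoG standard deviations in
#'   pixels.
#' @param shift correlation displacement in pixels (the detector's preferred
#'   displacement per `delay` frames).
#' @param oriented_sigma SD (pixels) of the oriented smoothing applied along
#'   the axis orthogonal to each motion direction; 0 disables the stage.
#' @return object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(directions = direction_grid()$angles,
                             delay = 1L, lgn_center_sigma = 1,
                             lgn_surround_sigma = 2, shift = 1,
                             oriented_sigma = 2) {
  if (delay < 1) stop("'delay' must be at least 1 frame")
  if (lgn_center_sigma <= 0 || lgn_surround_sigma <= lgn_center_sigma)
    stop("need 0 < lgn_center_sigma < lgn_surround_sigma")
  structure(list(directions = directions, delay = as.integer(delay),
                 lgn_center_sigma = lgn_center_sigma,
                 lgn_surround_sigma = lgn_surround_sigma,
                 shift = shift, oriented_sigma = oriented_sigma),
            class = "filter_bank_spec")
}

#' Local motion energy from an image sequence
#'
#' For every spatial location, frame pair and direction, computes an
#' opponent Reichardt correlation: frames are DoG filtered (LGN stage) and
#' smoothed along the orientation orthogonal to the probed direction
#' (oriented stage), then the two detector arms are correlated with the
#' delay on opposite sides,
#' `f_t(x) * f_{t+d}(x + s u) - f_t(x + s u) * f_{t+d}(x)` with `u` the unit
#' vector of the probed direction and `s` the preferred displacement, and
#' the result is half-wave rectified. A time-constant sequence therefore
#' yields exactly zero energy. Spatial shifts use the Fourier shift theorem
#' (periodic boundary), so the stage is deterministic and exactly
#' mirror-equivariant.
#'
#' @param seq an `image_sequence` (see [synth_movie()]) or a list of
#'   equally-sized numeric matrices.
#' @param spec a [filter_bank_spec()].
#' @return object of class `local_motion_field`: list with `energy`, a 4-D
#'   array `[row, col, time, direction]` of non-negative energies, and
#'   `directions`.
#' @export
erd_local_motion <- function(seq, spec = filter_bank_spec()) {
  frames <- if (inherits(seq, "image_sequence")) seq$frames else seq
  if (!is.list(frames) || length(frames) <= spec$delay)
    stop("sequence must be longer than the temporal delay")
  dims <- dim(frames[[1]])
  if (any(dims < 8)) stop("frames are smaller than the filter support")
  if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1))))
    stop("all frames must share dimensions")
  n <- dims[1]
  if (dims[1] != dims[2]) stop("square frames are required by the FFT stages")

  ## frequency responses of the Gaussian stages; f in cycles/pixel, so a
  ## Gaussian of SD sigma pixels has transfer exp(-2 pi^2 sigma^2 |f|^2)
  f <- fft_freq(n)
  F2 <- outer(f^2, f^2, "+")
  gauss_tf <- function(sigma) exp(-2 * pi^2 * sigma^2 * F2)
  dog <- gauss_tf(spec$lgn_center_sigma) - gauss_tf(spec$lgn_surround_sigma)

  frames_f <- lapply(frames, function(fr) fft(fr) * dog)

  nt <- length(frames) - spec$delay
  nd <- length(spec$directions)
  energy <- array(0, dim = c(n, n, nt, nd))
  for (j in seq_len(nd)) {
    th <- spec$directions[j] * pi / 180
    ux <- cos(th); uy <- sin(th)
    ## oriented smoothing along the axis orthogonal to motion:
    ## Gaussian in the (-sin, cos) direction, in the frequency domain
    if (spec$oriented_sigma > 0) {
      ## frequency component along the orthogonal axis (-uy, ux); rows index
      ## y downward, so f_y enters with a sign flip
      fy <- outer(-f, rep(1, n))
      fx <- outer(rep(1, n), f)
      fo <- -uy * fx + ux * fy
      otf <- exp(-2 * pi^2 * spec$oriented_sigma^2 * fo^2)
    } else otf <- 1
    ## sampling ramp: s(x) = img(x + s u)
    ramp <- shift_tf(f, -spec$shift * ux, -spec$shift * uy, n)
    for (k in seq_len(nt)) {
      cur <- frames_f[[k]] * otf
      nxt <- frames_f[[k + spec$delay]] * otf
      a <- Re(fft(cur, inverse = TRUE)) / n^2
      b <- Re(fft(nxt, inverse = TRUE)) / n^2
      a_s <- Re(fft(cur * ramp, inverse = TRUE)) / n^2
      b_s <- Re(fft(nxt * ramp, inverse = TRUE)) / n^2
      energy[, , k, j] <- pmax(a * b_s - a_s * b, 0)
    }
  }
  structure(list(energy = energy, directions = spec$directions),
            class = "local_motion_field")
}

## Fourier-domain translation by (dx, dy) pixels (x rightward along columns,
## y upward, i.e. toward smaller row indices).
shift_tf <- function(f, dx, dy, n) {
  ramp_r <- exp(-2i * pi * f * (-dy))
  ramp_c <- exp(-2i * pi * f * dx)
  outer(ramp_r, ramp_c)
}

#' Divisive center-surround normalization of a local motion field
#'
#' Each local energy is divided by `eps + ` the mean energy in a square
#' spatial surround, pooled across all directions at that frame, a standard
#' divisive-normalization pool. A spatially and directionally uniform field
#' therefore maps to a constant, and overall contrast scaling is largely
#' divided out once the pool dominates `eps`.
#'
#' @param field a `local_motion_field`.
#' @param surround side length in pixels of the square pooling window.
#' @param eps_frac `eps` as a fraction of the field's mean energy (guards
#'   empty pools); an absolute floor of `1e-12` is applied for all-zero
#'   fields.
#' @return a `local_motion_field` of bounded, non-negative normalized
#'   responses.
#' @export
center_surround_normalize <- function(field, surround = 9, eps_frac = 1e-3) {
  if (!inherits(field, "local_motion_field"))
    stop("'field' must be a local_motion_field")
  e <- field$energy
  if (any(e < 0)) stop("input energies must be non-negative")
  d <- dim(e)
  n <- d[1]
  eps <- max(eps_frac * mean(e), 1e-12)
  ## box filter in the frequency domain, periodic boundary
  box <- matrix(0, n, n)
  half <- floor(surround / 2)
  ix <- c(seq_len(half + 1), seq(n - half + 1, n))
  if (surround >= n) ix <- seq_len(n)
  box[ix, ix] <- 1 / length(ix)^2
  box_f <- fft(box)
  out <- e
  for (k in seq_len(d[3])) {
    pool_in <- apply(e[, , k, , drop = FALSE], c(1, 2), mean)
    pool <- Re(fft(fft(pool_in) * Conj(box_f), inverse = TRUE)) / n^2
    pool <- pmax(pool, 0)
    for (j in seq_len(d[4]))
      out[, , k, j] <- e[, , k, j] / (eps + pool)
  }
  field$energy <- out
  field
}

#' Pool a local motion field to a direction signal
#'
#' Averages the energy over space and time per direction, the input the
#' recurrent V1-MT stage consumes.
#'
#' @param field a `local_motion_field`.
#' @param grid a [direction_grid()]; the field's directions must match the
#'   grid angles.
#' @return non-negative numeric direction signal on the grid.
#' @export
pool_to_direction_signal <- function(field, grid = direction_grid()) {
  if (!inherits(field, "local_motion_field"))
    stop("'field' must be a local_motion_field")
  if (length(field$energy) == 0) stop("empty motion field")
  if (length(field$directions) != grid$n ||
      max(abs(field$directions - grid$angles)) > 1e-9)
    stop("field directions do not match the grid")
  apply(field$energy, 4, mean)
}
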