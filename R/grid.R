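#' Direction preference grid
#'
#' The discrete set of motion-direction preferences shared by every unit in
#' the two model areas. The default places 37 direction-tuned units uniformly
#' on the half circle from -90 (downward) to +90 degrees (upward) in steps of
#' 5 degrees, so that the decision channels centered at +/-90 degrees fall on
#' grid endpoints. Positive angles are upward motion components.
#'
#' @param n number of direction-tuned units (odd, so that 0 degrees is on the
#'   grid).
#' @param span two-element numeric, the inclusive angular range in degrees;
#'   must be symmetric about 0.
#' @return an object of class `direction_grid`: a list with elements
#'   `angles` (degrees, strictly increasing), `n` and `spacing`.
#' @examples
#' g <- direction_grid()
#' g$n            # 37
#' range(g$angles)
#' @export
direction_grid <- function(n = 37L, span = c(-90, 90)) {
  n <- as.integer(n)
  if (n < 3L) stop("direction grid needs at least 3 units")
  if (length(span) != 2L || span[1] >= span[2])
    stop("'span' must be an increasing range")
  if (abs(span[1] + span[2]) > 1e-12)
    stop("'span' must be symmetric about 0 degrees")
  angles <- seq(span[1], span[2], length.out = n)
  structure(
    list(angles = angles, n = n, spacing = angles[2] - angles[1]),
    class = "direction_grid"
  )
}

#' @export
print.direction_grid <- function(x, ...) {
  cat(sprintf("<direction_grid> %d units, %.4g to %.4g deg (spacing %.4g)\n",
              x$n, x$angles[1], x$angles[x$n], x$spacing))
  invisible(x)
}

is_direction_grid <- function(x) inherits(x, "direction_grid")

check_signal <- function(signal, grid, what = "direction signal") {
  if (!is.numeric(signal) || length(signal) != grid$n)
    stop(sprintf("%s must be a numeric vector of length %d (one value per grid direction)",
                 what, grid$n))
  if (any(!is.finite(signal)))
    stop(sprintf("%s contains non-finite values", what))
  invisible(signal)
}

## Convert a "width" given in degrees to a Gaussian standard deviation.
## Three conventions coexist in the tuning-curve literature: "span" reads a
## width as the full tuning extent (+/- 2 SD, so sd = width / 4), "fwhm" as
## the full width at half maximum, and "sd" as the standard deviation
## itself. The direction kernel defaults to "span" (a 45-degree receptive
## field covering +/- 22.5 degrees); the decision channels and the
## test-stimulus signal use "sd".
width_to_sd <- function(width, width_as = c("span", "fwhm", "sd")) {
  switch(match.arg(width_as),
         span = width / 4,
         fwhm = width / (2 * sqrt(2 * log(2))),
         sd = width)
}
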