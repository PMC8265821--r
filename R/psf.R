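#' Airy point-spread-function kernel on a supersampled grid
#'
#' Intensity pattern `(2 J1(v)/v)^2` with `v = 3.8317 * r / r0`, where `r0`
#' is the first-dark-ring radius (`psf_diameter / 2`).  The kernel is
#' truncated at the third dark ring (radius `2.655 * r0`) and normalized to
#' unit sum, so convolving point emitters with it conserves expected
#' electrons up to field-edge clipping.
#'
#' @param psf_diameter first-dark-ring diameter in nm (see [psf_diameter()]).
#' @param grid_step supersampled pixel size in nm.
#' @param shape `"airy"` (default) or `"gaussian"`: the Gaussian switch uses
#'   a sigma of `0.42 * lambda / (2 NA)` equivalent width (`0.21 *
#'   psf_diameter / 1.22`), a common approximation when speed matters.
#' @return a square odd-sized numeric matrix summing to 1.
#' @export
psf_kernel <- function(psf_diameter, grid_step, shape = c("airy", "gaussian")) {
  shape <- match.arg(shape)
  stopifnot(psf_diameter > 0, grid_step > 0)
  r0 <- psf_diameter / 2                  # first zero, nm
  r3 <- r0 * 10.1735 / 3.8317             # third zero, nm
  half <- ceiling(r3 / grid_step)
  ax <- (-half:half) * grid_step
  r <- sqrt(outer(ax^2, ax^2, "+"))
  if (shape == "airy") {
    v <- 3.8317 * r / r0
    k <- matrix(1, nrow(r), ncol(r))
    nz <- v > 0
    k[nz] <- (2 * besselJ(v[nz], 1) / v[nz])^2
    k[r > r3] <- 0
  } else {
    sigma <- 0.21 * psf_diameter / 1.22
    k <- exp(-r^2 / (2 * sigma^2))
    k[r > r3] <- 0
  }
  k / sum(k)
}
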