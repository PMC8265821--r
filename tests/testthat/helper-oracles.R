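# Independent oracles used across the suite.

# Principal-axis angle (degrees, axial, [-90, 90)) of an image from its
# second central moments; the brute-force orientation oracle.  y axis is
# flipped so positive angles are counter-clockwise on screen.
second_moment_angle <- function(img) {
  img <- pmax(img, 0)
  rc <- expand.grid(r = seq_len(nrow(img)) - 1, c = seq_len(ncol(img)) - 1)
  w <- as.numeric(img) / sum(img)
  cx <- sum(w * rc$c)
  cy <- sum(w * rc$r)
  mu20 <- sum(w * (rc$c - cx)^2)
  mu02 <- sum(w * (rc$r - cy)^2)
  mu11 <- sum(w * (rc$c - cx) * -(rc$r - cy))
  a <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  ((a + 90) %% 180) - 90
}

# smallest axial (period-180) distance between two angles in degrees
axial_diff <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}

# noiseless background-free two-tag fixture at the field centre
noiseless_fixture <- function(theta, sep = 300, config = sim_config(),
                              anchor = NULL) {
  ss <- config$supersample_factor
  if (is.null(anchor))
    anchor <- c(config$field_size[2] * ss / 2, config$field_size[1] * ss / 2)
  spec <- monomer_spec(anchor, 2L, orientation = theta, separation = sep)
  render_expected(spec, config) - config$mean_background
}

noiseless_single_fixture <- function(config = sim_config(), anchor = NULL) {
  ss <- config$supersample_factor
  if (is.null(anchor))
    anchor <- c(config$field_size[2] * ss / 2, config$field_size[1] * ss / 2)
  render_expected(monomer_spec(anchor, 1L), config) - config$mean_background
}
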