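#' Simulation configuration
#'
#' Defaults encode the imaging conditions of the study: 25 x 25 camera-pixel
#' patches at 107.5 nm/pixel (6.45-um pitch, 60x), rendered on a grid
#' supersampled 10x, blurred by the Airy PSF of the 530-nm emission through
#' the NA-1.45 objective (first dark ring 445.9 nm), ~2000 signal electrons
#' per fluorophore per 5-s exposure (from the default photon budget), mean
#' background 100 electrons/pixel, read noise 6 electrons RMS.  Two-tag
#' separations are uniform on 150-300 nm; orientations are drawn on the
#' 15-degree grid (12 axial values) in `"discrete"` mode or uniformly on
#' \[-90, 90) in `"continuous"` mode.
#'
#' @param field_size integer (rows, cols) of the camera-pixel patch.
#' @param supersample_factor integer supersampling of the rendering grid.
#' @param pixel_size sample-plane camera pixel size, nm.
#' @param psf_diameter first-dark-ring PSF diameter, nm.
#' @param signal_electrons expected electrons per fluorophore per exposure.
#'   The default bypasses the absolute radiometric chain (whose source
#'   radiance is configurable) with the value the default [photon_budget()]
#'   produces, keeping peak pixel counts comfortably above the 175-count
#'   detection threshold.
#' @param mean_background mean background electrons per pixel.
#' @param read_noise_rms read noise, electrons RMS (applied after the Poisson
#'   draw as rounded zero-mean Gaussian, clipped at zero).
#' @param separation_range two-tag separation interval, nm.
#' @param orientation_mode `"discrete"` (15-degree grid) or `"continuous"`.
#' @param psf_shape `"airy"` or `"gaussian"` (see [psf_kernel()]).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(field_size = c(25, 25), supersample_factor = 10,
                       pixel_size = 107.5, psf_diameter = 445.93,
                       signal_electrons = 2000, mean_background = 100,
                       read_noise_rms = 6, separation_range = c(150, 300),
                       orientation_mode = c("discrete", "continuous"),
                       psf_shape = "airy") {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(length(field_size) == 2L, all(field_size >= 5),
            supersample_factor >= 1, pixel_size > 0, psf_diameter > 0,
            signal_electrons >= 0, mean_background >= 0, read_noise_rms >= 0,
            length(separation_range) == 2L,
            separation_range[1] > 0,
            separation_range[1] <= separation_range[2])
  cfg <- structure(list(field_size = as.integer(field_size),
                        supersample_factor = as.integer(supersample_factor),
                        pixel_size = pixel_size, psf_diameter = psf_diameter,
                        signal_electrons = signal_electrons,
                        mean_background = mean_background,
                        read_noise_rms = read_noise_rms,
                        separation_range = separation_range,
                        orientation_mode = orientation_mode,
                        psf_shape = psf_shape),
                   class = "sim_config")
  # PSF support (third dark ring) must fit around the central-third anchor box
  margin_px <- (2.655 * psf_diameter / 2 + separation_range[2]) / pixel_size
  if (min(field_size) / 3 + margin_px > min(field_size))
    stop("field too small to contain the PSF support around a monomer")
  cfg
}

#' Ground truth for one simulated monomer
#'
#' @param anchor numeric (x, y) position of the first fluorophore in
#'   supersampled pixels (0-based, x = column, y = row, origin top-left).
#' @param n_tags 1 or 2.
#' @param orientation axial angle in degrees in \[-90, 90\] (NA when
#'   `n_tags = 1`); positive counter-clockwise from the horizontal axis.
#' @param separation tag separation in nm (NA when `n_tags = 1`).
#' @return an object of class `monomer_spec`.
#' @export
monomer_spec <- function(anchor, n_tags, orientation = NA_real_,
                         separation = NA_real_) {
  stopifnot(length(anchor) == 2L, n_tags %in% c(1L, 2L))
  if (n_tags == 2L) {
    stopifnot(is.finite(orientation), orientation >= -90, orientation <= 90,
              is.finite(separation), separation > 0)
  }
  structure(list(anchor = as.numeric(anchor), n_tags = as.integer(n_tags),
                 orientation = orientation, separation = separation),
            class = "monomer_spec")
}

#' Map orientation and tag count to the 13-class label
#'
#' Classes 0-11 are 15-degree axial orientation bins covering \[-90, 90)
#' (bin b is centred on `-90 + 15 b` degrees, the grid the discrete sampler
#' draws from; -90 and +90 are identified).  Class 12 is the single-tag
#' ("singularity") class, whose orientation is undefined.
#'
#' @param orientation degrees (ignored for single tags).
#' @param n_tags 1 or 2.
#' @return integer label in 0..12.
#' @export
orientation_to_class <- function(orientation, n_tags = 2L) {
  out <- integer(length(orientation))
  single <- n_tags == 1L
  out[single] <- 12L
  th <- orientation[!single]
  out[!single] <- as.integer(round((th + 90) / 15)) %% 12L
  out
}

#' Representative orientation of a class
#' @param class integer label 0..11 (class 12 returns NA).
#' @return degrees in \[-90, 90).
#' @export
class_to_orientation <- function(class) {
  ifelse(class == 12L, NA_real_, -90 + 15 * as.numeric(class))
}

# positions of all tags of a monomer, (x, y) in supersampled pixels
tag_positions <- function(spec, config) {
  ss_step <- config$pixel_size / config$supersample_factor
  pos <- matrix(spec$anchor, nrow = 1)
  if (spec$n_tags == 2L) {
    th <- spec$orientation * pi / 180
    d <- spec$separation / ss_step
    # y axis points down, positive angles counter-clockwise
    pos <- rbind(pos, spec$anchor + d * c(cos(th), -sin(th)))
  }
  pos
}

#' Draw one random monomer
#'
#' The anchor fluorophore is uniform over the central third of the field;
#' for a double tag the separation is Uniform(150, 300) nm and the
#' orientation follows the configured mode (discrete 15-degree grid or
#' continuous).  Uses the current R random stream.
#'
#' @param config a [sim_config()].
#' @param n_tags force 1 or 2 tags; `NULL` (default) draws 2 with
#'   probability 12/13 (the balanced-corpus class proportions).
#' @return a [monomer_spec()].
#' @export
sample_monomer <- function(config, n_tags = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ss <- config$supersample_factor
  nr <- config$field_size[1] * ss
  nc <- config$field_size[2] * ss
  anchor <- c(runif(1, nc / 3, 2 * nc / 3), runif(1, nr / 3, 2 * nr / 3))
  if (is.null(n_tags)) n_tags <- if (runif(1) < 12 / 13) 2L else 1L
  if (n_tags == 1L) return(monomer_spec(anchor, 1L))
  sep <- runif(1, config$separation_range[1], config$separation_range[2])
  th <- if (config$orientation_mode == "discrete") {
    -90 + 15 * sample.int(12L, 1L) - 15   # {-90, -75, ..., 75}
  } else {
    runif(1, -90, 90)
  }
  monomer_spec(anchor, 2L, orientation = th, separation = sep)
}

# sum supersample x supersample blocks of a matrix down to camera pixels
bin_supersampled <- function(m, factor) {
  if (factor == 1L) return(m)
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  a <- colSums(array(m, dim = c(factor, nr, ncol(m))))   # nr x (nc*factor)
  t(colSums(array(t(a), dim = c(factor, nc, nr))))       # nr x nc
}

#' Render the expected (noiseless) camera image
#'
#' Places unit impulses of weight `signal_electrons` at each tag position on
#' the supersampled grid, convolves with the unit-sum PSF kernel (impulse
#' placement makes this an exact kernel translation), bin-sums down to
#' camera resolution, and adds the mean background.
#'
#' @param specs a [monomer_spec()] or list of them.
#' @param config a [sim_config()].
#' @param kernel optional precomputed [psf_kernel()] (recomputed otherwise).
#' @return numeric matrix (rows x cols camera pixels) of expected electrons.
#' @export
render_expected <- function(specs, config, kernel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(specs, "monomer_spec")) specs <- list(specs)
  ss <- config$supersample_factor
  nr <- config$field_size[1] * ss
  nc <- config$field_size[2] * ss
  if (is.null(kernel))
    kernel <- psf_kernel(config$psf_diameter, config$pixel_size / ss,
                         shape = config$psf_shape)
  half <- (nrow(kernel) - 1L) %/% 2L
  canvas <- matrix(0, nr, nc)
  for (spec in specs) {
    for (i in seq_len(spec$n_tags)) {
      p <- tag_positions(spec, config)[i, ]
      cx <- as.integer(round(p[1])); cy <- as.integer(round(p[2]))
      # kernel footprint, clipped at the field edge (0-based coords)
      r0 <- max(cy - half, 0L); r1 <- min(cy + half, nr - 1L)
      c0 <- max(cx - half, 0L); c1 <- min(cx + half, nc - 1L)
      if (r0 > r1 || c0 > c1)
        stop("monomer tag outside the field")
      kr <- (r0 - cy + half + 1L):(r1 - cy + half + 1L)
      kc <- (c0 - cx + half + 1L):(c1 - cx + half + 1L)
      canvas[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] <-
        canvas[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] +
        config$signal_electrons * kernel[kr, kc]
    }
  }
  bin_supersampled(canvas, ss) + config$mean_background
}

#' Apply Poisson shot noise (and optional read noise) to an expected image
#'
#' Each pixel is an independent Poisson draw with the pixel's expected
#' electron count as rate.  If `read_noise_rms > 0`, rounded zero-mean
#' Gaussian read noise is added afterwards and the result clipped at zero.
#' Uses the current R random stream.
#'
#' @param expected non-negative numeric matrix of expected electrons.
#' @param read_noise_rms electrons RMS (default 0).
#' @return integer matrix of simulated counts.
#' @export
apply_shot_noise <- function(expected, read_noise_rms = 0) {
  if (any(expected < 0)) stop("expected image must be non-negative")
  n <- length(expected)
  counts <- rpois(n, lambda = as.numeric(expected))
  if (read_noise_rms > 0)
    counts <- pmax(counts + round(rnorm(n, 0, read_noise_rms)), 0)
  matrix(as.integer(counts), nrow(expected), ncol(expected))
}

#' Generate a labeled synthetic dataset
#'
#' One monomer per image.  Class balance is uniform over the 13 classes
#' within rounding (classes 0-11: double tags at the class's grid
#' orientation in discrete mode, or uniform within the class's bin in
#' continuous mode; class 12: single tag).  The stored `counts` have the
#' mean background subtracted and are clipped at zero, as done before
#' classification; the raw frames are kept in `raw`.  The dataset is a pure
#' function of (config, seed).
#'
#' @param n_samples number of images (>= 13).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param keep_raw keep the unsubtracted frames (default TRUE).
#' @return an object of class `monomer_dataset`: list with `counts` (integer
#'   matrix, one column-major-flattened image per row), `raw`,
#'   `labels` (integer 0..12), `truth` (data.frame: n_tags, orientation_deg,
#'   separation_nm, anchor_x, anchor_y), `config`, `seed`.
#' @export
generate_dataset <- function(n_samples, config = sim_config(), seed = 1,
                             keep_raw = TRUE) {
  stopifnot(n_samples >= 13)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  npx <- prod(config$field_size)
  ss <- config$supersample_factor
  kernel <- psf_kernel(config$psf_diameter, config$pixel_size / ss,
                       shape = config$psf_shape)
  base <- n_samples %/% 13L
  labels <- c(rep(0:12, base), seq_len(n_samples %% 13L) - 1L)
  labels <- sample(labels)

  counts <- matrix(0L, n_samples, npx)
  raw <- if (keep_raw) matrix(0L, n_samples, npx) else NULL
  truth <- data.frame(n_tags = integer(n_samples),
                      orientation_deg = numeric(n_samples),
                      separation_nm = numeric(n_samples),
                      anchor_x = numeric(n_samples),
                      anchor_y = numeric(n_samples))
  for (i in seq_len(n_samples)) {
    lab <- labels[i]
    if (lab == 12L) {
      spec <- sample_monomer(config, n_tags = 1L)
    } else {
      spec <- sample_monomer(config, n_tags = 2L)
      th <- if (config$orientation_mode == "discrete") {
        class_to_orientation(lab)
      } else {
        runif(1, -90 + 15 * lab - 7.5, -90 + 15 * lab + 7.5)
      }
      if (th < -90) th <- th + 180
      spec$orientation <- th
    }
    expected <- render_expected(spec, config, kernel = kernel)
    frame <- apply_shot_noise(expected, config$read_noise_rms)
    if (keep_raw) raw[i, ] <- as.integer(frame)
    counts[i, ] <- as.integer(round(pmax(frame - config$mean_background, 0)))
    truth$n_tags[i] <- spec$n_tags
    truth$orientation_deg[i] <- if (spec$n_tags == 2L) spec$orientation else NA_real_
    truth$separation_nm[i] <- if (spec$n_tags == 2L) spec$separation else NA_real_
    truth$anchor_x[i] <- spec$anchor[1]
    truth$anchor_y[i] <- spec$anchor[2]
  }
  structure(list(counts = counts, raw = raw, labels = as.integer(labels),
                 truth = truth, config = config, seed = as.integer(seed)),
            class = "monomer_dataset")
}

#' @export
print.monomer_dataset <- function(x, ...) {
  cat(sprintf("<monomer_dataset: %d images of %dx%d px, seed %d>\n",
              nrow(x$counts), x$config$field_size[1], x$config$field_size[2],
              x$seed))
  print(table(label = x$labels))
  invisible(x)
}

#' Extract one image of a dataset as a matrix
#' @param dataset a `monomer_dataset`.
#' @param i image index.
#' @param raw return the unsubtracted frame instead of the
#'   background-subtracted counts.
#' @return integer matrix (rows x cols).
#' @export
get_image <- function(dataset, i, raw = FALSE) {
  src <- if (raw) dataset$raw else dataset$counts
  if (raw && is.null(src)) stop("raw frames were not kept for this dataset")
  matrix(src[i, ], dataset$config$field_size[1], dataset$config$field_size[2])
}
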