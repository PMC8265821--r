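#' Read grayscale count frames from a TIFF file
#'
#' Single- or multi-page 8/16-bit grayscale TIFF; page order is preserved.
#' Color or floating-point TIFFs are rejected (convert to integer grayscale
#' counts first).
#'
#' @param path path to the TIFF file.
#' @return list of integer matrices, one per page.
#' @export
read_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L)
      stop("page ", i, " is not grayscale; convert to single-channel counts")
    if (!is.integer(p) && any(p != round(p)))
      stop("page ", i, " holds floating-point samples; expected integer counts")
    matrix(as.integer(p), nrow(p), ncol(p))
  })
}

#' Write count frames to a 16-bit grayscale TIFF
#'
#' @param frames an integer matrix or list of them (counts in 0..65535;
#'   larger counts are rejected, being far above the camera's full-well
#'   regime).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  scaled <- lapply(frames, function(f) {
    if (any(f < 0)) stop("counts must be non-negative")
    if (any(f > 65535)) stop("counts above 65535 cannot be stored as 16-bit")
    matrix(as.numeric(f) / 65535, nrow(f), ncol(f))
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

# tiff::readTIFF(as.is=TRUE) rescaling counterpart used by read_dataset
read_counts_tiff <- function(path) {
  read_frames(path)[[1]]
}

#' Write a labeled dataset to a directory of TIFFs with a CSV manifest
#'
#' One 16-bit grayscale TIFF per image (background-subtracted counts), plus
#' `manifest.csv` with the fixed columns `filename`, `label`,
#' `orientation_deg`, `separation_nm`, `n_tags`, `seed`, and a
#' `config.yaml` snapshot sufficient to regenerate the dataset.
#'
#' @param dataset a `monomer_dataset`.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory (default FALSE).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("directory ", dir, " is not empty; use force = TRUE to overwrite")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(dataset$counts)
  files <- sprintf("sample_%05d.tif", seq_len(n))
  for (i in seq_len(n)) {
    write_frames(get_image(dataset, i), file.path(dir, files[i]))
  }
  manifest <- data.frame(filename = files, label = dataset$labels,
                         orientation_deg = dataset$truth$orientation_deg,
                         separation_nm = dataset$truth$separation_nm,
                         n_tags = dataset$truth$n_tags,
                         seed = dataset$seed)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  write_config(c(unclass(dataset$config), list(seed = dataset$seed)),
               file.path(dir, "config.yaml"))
  invisible(mpath)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return a `monomer_dataset` (without raw frames).
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  cfg_list <- read_config(file.path(dir, "config.yaml"))
  config <- as_sim_config(cfg_list)
  n <- nrow(manifest)
  counts <- matrix(0L, n, prod(config$field_size))
  for (i in seq_len(n))
    counts[i, ] <- as.integer(read_counts_tiff(file.path(dir, manifest$filename[i])))
  truth <- data.frame(n_tags = manifest$n_tags,
                      orientation_deg = manifest$orientation_deg,
                      separation_nm = manifest$separation_nm,
                      anchor_x = NA_real_, anchor_y = NA_real_)
  structure(list(counts = counts, raw = NULL,
                 labels = as.integer(manifest$label), truth = truth,
                 config = config,
                 seed = as.integer(manifest$seed[1])),
            class = "monomer_dataset")
}

#' Write a configuration list as YAML
#' @param config a named list (e.g. an unclassed [sim_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a YAML configuration
#' @param path path to a YAML file.
#' @return a named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Coerce a plain list to a [sim_config()]
#' @param x named list of `sim_config` fields (unknown fields are ignored).
#' @return a `sim_config`.
#' @export
as_sim_config <- function(x) {
  defaults <- formals(sim_config)
  keep <- intersect(names(x), names(defaults))
  do.call(sim_config, x[keep])
}
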