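# Raster, checkpoint and configuration I/O.
#
# Masks are stored losslessly as single-channel indexed rasters: 8-bit PNG
# (label = value * 255) when c <= 256, 16-bit single-channel TIFF when
# c > 256. Images are stored as PNG with intensities in [0, 1]. Row-major,
# origin top-left, 0-based labels throughout.

#' Write / read an integer mask raster
#'
#' @param mask an integer matrix or [MaskImage-class].
#' @param path output path; `.png` for up to 256 classes, `.tif`/`.tiff`
#'   for more.
#' @return `writeMaskFile` returns `path` invisibly; `readMaskFile`
#'   returns an integer matrix.
#' @export
writeMaskFile <- function(mask, path) {
  m <- asMaskMatrix(mask)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(m) > 255L)
      stop("PNG masks support at most 256 classes; use a 16-bit TIFF")
    png::writePNG(m / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  } else stop("unsupported mask format: .", ext)
  invisible(path)
}

#' @rdname writeMaskFile
#' @export
readMaskFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") png::readPNG(path) * 255
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) * 65535
         else stop("unsupported mask format: .", ext)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  matrix(as.integer(round(raw)), nrow(raw), ncol(raw))
}

readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported image format: .", ext)
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Load a paired images/masks directory
#'
#' Expects `path/images/` and `path/masks/` with matching basenames (PNG or
#' TIFF). Image intensities are rescaled to [0, 1] by the raster reader;
#' masks are validated against `nClasses` when given.
#'
#' @param path dataset directory.
#' @param nClasses expected class count; inferred as `max(label) + 1` when
#'   `NULL`.
#' @return a labelled [SegDataset-class].
#' @export
loadDatasetDir <- function(path, nClasses = NULL) {
  imgDir <- file.path(path, "images")
  mskDir <- file.path(path, "masks")
  if (!dir.exists(imgDir) || !dir.exists(mskDir))
    stop("dataset directory must contain images/ and masks/: ", path)
  imgFiles <- sort(list.files(imgDir, pattern = "\\.(png|tif|tiff)$",
                              ignore.case = TRUE))
  if (length(imgFiles) == 0L) stop("no images found under ", imgDir)
  mskFiles <- sort(list.files(mskDir, pattern = "\\.(png|tif|tiff)$",
                              ignore.case = TRUE))
  ib <- tools::file_path_sans_ext(imgFiles)
  mb <- tools::file_path_sans_ext(mskFiles)
  missing <- setdiff(ib, mb)
  if (length(missing))
    stop("missing mask(s) for: ", paste(missing, collapse = ", "))
  images <- setNames(lapply(file.path(imgDir, imgFiles), readImageFile), ib)
  masks <- setNames(lapply(
    file.path(mskDir, mskFiles[match(ib, mb)]), readMaskFile), ib)
  mx <- max(vapply(masks, max, 0L))
  if (is.null(nClasses)) nClasses <- mx + 1L
  if (mx >= nClasses)
    stop(sprintf("mask label %d out of range for %d classes", mx, nClasses))
  segDataset(images, masks, nClasses = nClasses)
}

#' Write a synthetic dataset to disk
#'
#' Generates the dataset of `spec` and writes `images/` and `masks/` PNG
#' directories plus a `manifest.csv` (filename, split) under `dir`. A
#' fraction `valFrac` of the images (the tail of the generation order) is
#' marked `val`, the rest `pool`.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#' @param valFrac fraction assigned to the validation split.
#' @return the manifest data.frame, invisibly.
#' @export
simulateToDir <- function(spec, dir, valFrac = 0.2) {
  ds <- generateDataset(spec)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- datasetIds(ds)
  nVal <- round(valFrac * length(ids))
  split <- rep("pool", length(ids))
  if (nVal > 0) split[(length(ids) - nVal + 1L):length(ids)] <- "val"
  for (i in seq_along(ids)) {
    png::writePNG(ds@images[[i]][, , 1],
                  file.path(dir, "images", paste0(ids[i], ".png")))
    writeMaskFile(ds@masks[[i]],
                  file.path(dir, "masks", paste0(ids[i], ".png")))
  }
  manifest <- data.frame(filename = paste0(ids, ".png"), split = split)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write a probability or variance map as a multi-channel TIFF
#'
#' Class-probability maps (H, W, c) are written one channel per class;
#' plain H x W matrices (e.g. predictive-variance maps, whose values for
#' probabilities never exceed 1/4) as single-channel. Values are stored in
#' 16 bits over [0, 1].
#'
#' @param x a [ProbMap-class], (H, W, c) array, or numeric matrix with
#'   values in [0, 1].
#' @param path output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
writeProbMapFile <- function(x, path) {
  if (is(x, "ProbMap")) x <- probValues(x)
  if (min(x) < 0 || max(x) > 1) stop("values must lie in [0, 1]")
  tiff::writeTIFF(x, path, bits.per.sample = 16L)
  invisible(path)
}

#' Checkpoint a model to a single file
#'
#' Serializes the full parameter set and running statistics with R's native
#' serialization; a save/load round trip reproduces deterministic forward
#' passes bit-identically.
#'
#' @param model a [UNetModel-class].
#' @param path checkpoint file path.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns the [UNetModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "UNetModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  model <- readRDS(path)
  if (!is(model, "UNetModel")) stop("not a model checkpoint: ", path)
  model
}

.runConfigDefaults <- list(
  depth = 3L, base_filters = 16L, n_classes = 2L, in_channels = 1L,
  variant = "maxpool_dropout", dropout_rate = 0.5, use_batchnorm = TRUE,
  lr = 0.001, batch_size = 4L, max_epochs = 60L, patience = 5L,
  acquisition = "committee_jsd", k = 2L, iterations = 15L,
  initial_size = 2L, subsample_size = NULL, T = 20L,
  mc_batchnorm = FALSE, seed = 1L, data_dir = NULL, out_dir = NULL)

#' Read / write a run configuration
#'
#' A run configuration is a flat YAML mapping of architecture, training and
#' active-learning parameters; unknown keys are rejected, missing keys take
#' the package defaults. Every run writes its fully resolved configuration
#' next to its results, so a results directory is self-describing.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return named list of resolved parameters.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .runConfigDefaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  cfg
}

#' @param cfg a resolved configuration list.
#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

modelConfigFromRun <- function(cfg) {
  modelConfig(depth = cfg$depth, baseFilters = cfg$base_filters,
              nClasses = cfg$n_classes, inChannels = cfg$in_channels,
              variant = cfg$variant, dropoutRate = cfg$dropout_rate,
              useBatchnorm = cfg$use_batchnorm)
}
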