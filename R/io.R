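#' Read a grayscale image from PNG or TIFF
#'
#' Bit depth is preserved: 8-bit files give `dtype_max = 255`, 16-bit
#' files `dtype_max = 65535`, and intensities are returned on that native
#' integer scale. Multi-channel inputs are converted to luminance
#' (Rec. 709 weights) with a warning.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A [gray_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image '%s': file does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    dat <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop(sprintf(
                      "cannot read '%s' as PNG: %s", path, conditionMessage(e)),
                      call. = FALSE))
    info <- attr(dat, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else if (ext %in% c("tif", "tiff")) {
    dat <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) stop(sprintf(
                      "cannot read '%s' as TIFF: %s", path,
                      conditionMessage(e)), call. = FALSE))
    bits <- attr(dat, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(dat) > 255) 16L else 8L
  } else {
    stop(sprintf("unsupported image format '%s' for '%s' (use PNG or TIFF)",
                 ext, path), call. = FALSE)
  }
  dmax <- 2^bits - 1
  if (length(dim(dat)) == 3) {
    nch <- dim(dat)[3]
    warning(sprintf("'%s' has %d channels; converting to luminance",
                    path, nch), call. = FALSE)
    wts <- if (nch >= 3) c(0.2126, 0.7152, 0.0722) else rep(1 / nch, nch)
    g <- matrix(0, dim(dat)[1], dim(dat)[2])
    for (ch in seq_along(wts)) g <- g + wts[ch] * dat[, , ch]
    dat <- g
  }
  # readPNG scales to [0, 1]; readTIFF(as.is) keeps integers
  if (ext == "png") dat <- dat * dmax
  gray_image(matrix(as.numeric(dat), nrow(dat), ncol(dat)), dtype_max = dmax)
}

#' Write a grayscale image to PNG (8-bit) or TIFF (8/16-bit)
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- if (inherits(image, "gray_image")) image else
    gray_image(image, dtype_max = if (max(image) > 255) 65535 else 255)
  ext <- tolower(tools::file_ext(path))
  scaled <- img$pixels / img$dtype_max
  if (ext == "png") {
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    bits <- if (img$dtype_max > 255) 16L else 8L
    tiff::writeTIFF(scaled, path, bits.per.sample = bits)
  } else {
    stop(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Write a label map as a raw-index 8-bit PNG
#'
#' Cluster labels are stored as raw 0-based indices (label 1 becomes
#' pixel value 0), machine-readable rather than visually scaled. Use
#' `colorize = TRUE` to additionally write a contrast-stretched
#' visualization next to it (suffix `_vis.png`).
#'
#' @param labels integer matrix of 1-based cluster labels (at most 256
#'   clusters).
#' @param path output PNG path.
#' @param colorize also write a scaled visualization (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, colorize = FALSE) {
  if (min(labels) < 1 || max(labels) > 256) {
    stop("labels must be 1-based cluster indices (<= 256)", call. = FALSE)
  }
  png::writePNG((labels - 1) / 255, path)
  if (colorize) {
    vis <- (labels - min(labels)) / max(1, max(labels) - min(labels))
    png::writePNG(vis, sub("\\.png$", "_vis.png", path))
  }
  invisible(path)
}

#' Read a raw-index label PNG back to 1-based labels
#'
#' @param path PNG written by [write_labels()].
#' @return Integer matrix of 1-based labels.
#' @export
read_labels <- function(path) {
  img <- read_image(path)
  matrix(as.integer(round(img$pixels)) + 1L, nrow(img$pixels),
         ncol(img$pixels))
}

#' Write a JSON report for a segmentation run
#'
#' The report carries everything needed to reproduce and audit a run:
#' the method, configuration (including the seed), iteration count,
#' convergence flag, objective trace, per-iteration membership deltas,
#' final cluster centers and optional evaluation metrics.
#'
#' @param result a `segmentation_result`.
#' @param path output `.json` path.
#' @param metrics optional named numeric vector (e.g. from
#'   [seg_indices()]).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, metrics = NULL) {
  cfg <- result$config
  if (inherits(cfg, "ifcm_config")) cfg <- unclass(cfg)
  cfg <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  rep <- list(
    method = result$method,
    config = cfg,
    iterations = result$iterations,
    converged = result$converged,
    objective_trace = result$objective_trace,
    membership_deltas = result$membership_deltas,
    centers = result$centers
  )
  if (!is.null(metrics)) rep$metrics <- as.list(metrics)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a flat YAML configuration into an [ifcm_config()]
#'
#' Recognized keys mirror the CLI flags: `clusters`, `m`, `eta`,
#' `max_iter`, `seed`, `use_ifs`, `use_transfer`, `use_similarity`,
#' `center_power_m`, `generator.family`, `generator.param`,
#' `transfer.radius`, `transfer.eps`, `transfer.subsample`,
#' `transfer.median_radius`, `similarity.mode`,
#' `similarity.window_radius`, `similarity.scale_floor`,
#' `similarity.scale_mode`. Dotted keys may also be written as nested
#' YAML mappings.
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file's values.
#' @return An [ifcm_config()].
#' @export
read_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (nm in names(raw)) {
    if (is.list(raw[[nm]])) {
      for (sub in names(raw[[nm]])) flat[[paste(nm, sub, sep = ".")]] <-
          raw[[nm]][[sub]]
    } else flat[[nm]] <- raw[[nm]]
  }
  flat <- utils::modifyList(flat, list(...))
  pick <- function(key, default) if (!is.null(flat[[key]])) flat[[key]] else default
  gen <- generator_params(pick("generator.family", "sugeno"),
                          pick("generator.param", 2))
  tr <- guided_filter_params(pick("transfer.radius", 3),
                             pick("transfer.eps", 0.01),
                             pick("transfer.subsample", 1),
                             pick("transfer.median_radius", 1))
  sim <- list(mode = pick("similarity.mode", "direct"),
              window_radius = pick("similarity.window_radius", 1),
              scale_floor = pick("similarity.scale_floor", 1e-12),
              scale_mode = pick("similarity.scale_mode", "printed"),
              distance = pick("similarity.distance", "gray"))
  if (is.null(flat$clusters)) {
    stop("config must set `clusters`", call. = FALSE)
  }
  ifcm_config(clusters = flat$clusters,
              m = pick("m", 2), eta = pick("eta", 1e-5),
              max_iter = pick("max_iter", 100), seed = pick("seed", 1),
              use_ifs = pick("use_ifs", TRUE),
              use_transfer = pick("use_transfer", TRUE),
              use_similarity = pick("use_similarity", TRUE),
              generator = gen, transfer = tr, similarity = sim,
              center_power_m = pick("center_power_m", TRUE),
              init = pick("init", "centers"))
}
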