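#' Read a classified label image (TIFF or PNG)
#'
#' Reads a single-channel 8- or 16-bit integer label image; pixel values
#' are taken verbatim as class codes. If a JSON sidecar `<path>.json`
#' exists with an object mapping codes to names, it is attached as
#' `class_names`.
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param resolution pixel size in physical units.
#' @param nodata_code optional nodata class code.
#' @return a [categorical_raster()].
#' @export
read_label_image <- function(path, resolution = 1.0, nodata_code = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  values <- switch(ext,
    tif = , tiff = {
      img <- tiff::readTIFF(path, as.is = TRUE)
      .flatten_channel(img, path)
    },
    png = {
      img <- png::readPNG(path)
      img <- .flatten_channel(img, path)
      # readPNG rescales to [0, 1]; recover the 8- or 16-bit integer codes
      v8 <- img * 255
      if (max(abs(v8 - round(v8))) < 1e-6) round(v8) else round(img * 65535)
    },
    stop("unsupported label image format: .", ext))
  storage.mode(values) <- "integer"
  sidecar <- paste0(path, ".json")
  class_names <- if (file.exists(sidecar)) {
    unlist(jsonlite::read_json(sidecar))
  } else NULL
  categorical_raster(values, resolution = resolution,
                     nodata_code = nodata_code, class_names = class_names)
}

.flatten_channel <- function(img, path) {
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L &&
        !all(img[, , 1] == img[, , dim(img)[3]])) {
      stop("multi-channel image is not a label map: ", path)
    }
    img <- img[, , 1L]
  }
  img
}

#' Write a label image
#'
#' Writes class codes as a single-channel label image — 16-bit TIFF, or
#' 8-bit PNG (so PNG labels must stay below 256) — such that
#' `read_label_image()` round-trips the raster exactly. `NA` (nodata)
#' pixels are written as code 0, so choose a nodata code that is not a
#' class when round-tripping masked rasters.
#'
#' @param raster a [categorical_raster()].
#' @param path output path (`.tif`, `.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_label_image <- function(raster, path) {
  stopifnot(inherits(raster, "categorical_raster"))
  v <- raster$values
  v[is.na(v)] <- 0L
  if (max(v) > 65535L) stop("class codes exceed 16-bit range")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L,
                                   compression = "none"),
    png = {
      if (max(v) > 255L) stop("PNG label images support codes up to 255")
      png::writePNG(v / 255, path)
    },
    stop("unsupported label image format: .", ext))
  invisible(path)
}

#' Read a point pattern from a CSV table
#'
#' Expects columns `x`, `y` and optionally `mark`. The window defaults to
#' the bounding box of the points (with a zero-margin fallback for a
#' degenerate range).
#'
#' @param path CSV path.
#' @param window optional [pp_window()]; if `NULL`, the bounding box.
#' @return a [point_pattern()].
#' @export
read_points_csv <- function(path, window = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(tab))) {
    stop("malformed point CSV ", path, ": expected columns x,y[,mark]")
  }
  if (is.null(window)) {
    pad <- function(lo, hi) if (hi > lo) c(lo, hi) else c(lo - 0.5, hi + 0.5)
    xr <- pad(min(tab$x), max(tab$x)); yr <- pad(min(tab$y), max(tab$y))
    window <- pp_window(xr[1], xr[2], yr[1], yr[2])
  }
  point_pattern(tab$x, tab$y, window,
                marks = if ("mark" %in% names(tab)) tab$mark else NULL)
}

#' Write a point pattern to CSV
#'
#' Canonical formatting (`x,y[,mark]`, 17 significant digits — enough to
#' represent a double exactly) so write-then-read round-trips are exact
#' and repeated write-read-write cycles are byte-stable.
#'
#' @param pp a [point_pattern()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(pp, path) {
  stopifnot(inherits(pp, "point_pattern"))
  tab <- data.frame(x = sprintf("%.17g", pp$x), y = sprintf("%.17g", pp$y))
  if (!is.null(pp$marks)) tab$mark <- pp$marks
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- ImageJ ROI format ----------------------------------------------------

#' Read an ImageJ .roi annotation
#'
#' Minimal parser for the binary ImageJ ROI format covering the
#' annotation types the framework consumes: multi-point sets (point
#' picks of portal tracts, central veins, MFB nuclei) and
#' polygon/polyline/freehand traces (vessel circumferences). ImageJ's
#' integer pixel coordinates are converted to physical coordinates by the
#' package pixel-centre convention (`+ 0.5`).
#'
#' @param path path to a `.roi` file.
#' @return list with `type` (`"point"`, `"polyline"` or `"polygon"`),
#'   `x`, `y`, `name`.
#' @export
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout") {
    stop("malformed ROI file ", path, ": missing 'Iout' magic at offset 0")
  }
  u16 <- function(off) {  # big-endian unsigned short at 0-based offset
    as.integer(raw[off + 1L]) * 256L + as.integer(raw[off + 2L])
  }
  s16 <- function(off) {
    v <- u16(off); if (v >= 32768L) v - 65536L else v
  }
  type_code <- as.integer(raw[7L])
  top <- s16(8L); left <- s16(10L)
  n <- u16(16L)
  type <- switch(as.character(type_code),
    "0" = "polygon", "3" = "polyline", "4" = "polyline", "5" = "polyline",
    "7" = "polygon", "10" = "point",
    stop("unsupported ROI type code ", type_code, " in ", path))
  if (n < 1L) stop("ROI ", path, " contains no coordinates")
  base <- 64L
  xs <- vapply(seq_len(n), function(i) s16(base + 2L * (i - 1L)), integer(1))
  ys <- vapply(seq_len(n), function(i) s16(base + 2L * n + 2L * (i - 1L)),
               integer(1))
  list(type = type,
       x = left + xs + 0.5,
       y = top + ys + 0.5,
       name = tools::file_path_sans_ext(basename(path)))
}

#' Write a minimal ImageJ .roi annotation
#'
#' Inverse of [read_imagej_roi()] for point sets and
#' polylines/polygons, sufficient for round-trip interchange with ImageJ
#' (coordinates are truncated to the integer pixel grid, as in the
#' format).
#'
#' @param x,y pixel-centre coordinates (converted back to integer pixel
#'   coordinates by `floor`).
#' @param path output `.roi` path.
#' @param type `"point"`, `"polyline"` or `"polygon"`.
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(x, y, path, type = c("point", "polyline",
                                                  "polygon")) {
  type <- match.arg(type)
  xi <- as.integer(floor(x)); yi <- as.integer(floor(y))
  left <- min(xi); top <- min(yi)
  n <- length(xi)
  type_code <- switch(type, point = 10L, polyline = 5L, polygon = 0L)
  be16 <- function(v) {
    v <- as.integer(v) %% 65536L
    as.raw(c(v %/% 256L, v %% 256L))
  }
  header <- c(charToRaw("Iout"), be16(227L),
              as.raw(type_code), as.raw(0L),
              be16(top), be16(left),
              be16(max(yi) + 1L), be16(max(xi) + 1L),
              be16(n))
  header <- c(header, as.raw(rep(0L, 64L - length(header))))
  coords <- c(unlist(lapply(xi - left, be16)),
              unlist(lapply(yi - top, be16)))
  writeBin(c(header, coords), path)
  invisible(path)
}

#' Read a set of ImageJ ROIs from a .zip archive
#'
#' @param path path to a `.zip` of `.roi` files (as saved by the ImageJ
#'   ROI manager).
#' @return list of [read_imagej_roi()] results, ordered by file name.
#' @export
read_imagej_roi_zip <- function(path) {
  exdir <- tempfile("roizip")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
  if (length(files) == 0L) stop("no .roi entries in ", path)
  lapply(files, read_imagej_roi)
}

#' Collect point ROIs into a point pattern
#'
#' @param rois list of ROIs from [read_imagej_roi_zip()] (or a single ROI
#'   list); non-point ROIs are rejected.
#' @param window a [pp_window()] (e.g. [raster_window()] of the source
#'   image).
#' @return a [point_pattern()].
#' @export
rois_to_pattern <- function(rois, window) {
  if (!is.null(rois$type)) rois <- list(rois)
  types <- vapply(rois, `[[`, "", "type")
  if (any(types != "point")) {
    stop("expected point ROIs, found: ", paste(unique(types), collapse = ", "))
  }
  point_pattern(unlist(lapply(rois, `[[`, "x")),
                unlist(lapply(rois, `[[`, "y")), window)
}

# ---- centroid extraction --------------------------------------------------

#' Extract centroids of rounded structures of one class
#'
#' The follicle-style extractor: select one class of the raster, convert
#' to a binary mask, fill interior holes, find connected components
#' (8-connectivity), keep components that are large
#' (`area >= min_area_px`) and rounded (circularity
#' `4 pi A / P^2 >= min_circularity`), and return their area centroids as
#' a point pattern in the raster's full-extent window.
#'
#' @param raster a [categorical_raster()].
#' @param class_code class to extract (must be present).
#' @param min_area_px minimum component area in pixels (default 50).
#' @param min_circularity minimum circularity in `[0, 1]` (default 0.4;
#'   a 1-pixel-wide line scores far below this).
#' @return a [point_pattern()] of centroids (empty, with a warning, when
#'   no component survives).
#' @export
extract_class_centroids <- function(raster, class_code, min_area_px = 50,
                                    min_circularity = 0.4) {
  stopifnot(inherits(raster, "categorical_raster"))
  v <- raster$values
  if (!class_code %in% raster_classes(raster)) {
    stop("class ", class_code, " not present in raster")
  }
  mask <- !is.na(v) & v == class_code
  mask <- .fill_holes(mask)
  bin <- categorical_raster(matrix(ifelse(mask, 1L, NA_integer_),
                                   nrow(v), ncol(v)) ,
                            resolution = raster$resolution)
  lab <- tryCatch(label_patches(bin, connectivity = 8),
                  error = function(e) NULL)
  win <- raster_window(raster)
  if (is.null(lab)) {
    warning("no pixels of class ", class_code, " after masking")
    return(point_pattern(numeric(0), numeric(0), win))
  }
  perim <- .patch_perimeters(lab$patch_ids, length(lab$patch_class))
  area <- lab$patch_size
  circ <- 4 * pi * area / perim^2
  keep <- which(area >= min_area_px & circ >= min_circularity)
  if (length(keep) == 0L) {
    warning("no component passed the area/circularity filters")
    return(point_pattern(numeric(0), numeric(0), win))
  }
  res <- raster$resolution
  cx <- numeric(length(keep)); cy <- numeric(length(keep))
  ids <- lab$patch_ids
  nr <- nrow(ids)
  for (i in seq_along(keep)) {
    px <- which(ids == keep[i])
    col <- (px - 1L) %/% nr + 1L
    row <- (px - 1L) %% nr + 1L
    cx[i] <- mean(col - 0.5) * res
    cy[i] <- mean(row - 0.5) * res
  }
  point_pattern(cx, cy, win)
}

# fill interior holes of a binary mask: background components not
# touching the image border become foreground (4-connectivity for the
# background, the dual of 8-connected foreground)
.fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- matrix(ifelse(mask, NA_integer_, 1L), nr, nc)
  if (!anyNA(bg) || all(is.na(bg))) return(mask)
  lab <- label_patches(categorical_raster(bg), connectivity = 4)
  ids <- lab$patch_ids
  border_ids <- unique(c(ids[1, ], ids[nr, ], ids[, 1], ids[, nc]))
  border_ids <- border_ids[border_ids > 0L]
  mask | (ids > 0L & !(ids %in% border_ids))
}

# ---- pipeline -------------------------------------------------------------

#' Run the end-to-end landscape/point-pattern pipeline
#'
#' Orchestrates, from a configuration list: label images -> patch
#' labelling -> class/landscape/complexity metric CSVs, and point CSVs ->
#' summary indices and function estimate CSVs. A JSON manifest recording
#' the configuration, the seeds used and every output file is written to
#' the output directory, making a run reproducible bit-for-bit.
#'
#' @param config list (or path to a JSON file) with optional elements:
#'   `rasters` (named character vector/list of label-image paths),
#'   `points` (named list of point CSV paths), `window` (list
#'   `x_min, x_max, y_min, y_max`; required for `points`), `out_dir`,
#'   `connectivity` (default 8), `fn` (summary function for point
#'   inputs, default `"L"`), `correction`, `n_sim` (envelope simulations,
#'   default 0 = none), `seed` (default 1).
#' @return list with `manifest` (path) and `outputs` (character vector),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("rasters", "points", "window", "out_dir", "connectivity",
             "fn", "correction", "n_sim", "seed", "resolution")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conn <- config$connectivity %||% 8
  seed <- as.integer(config$seed %||% 1L)
  fn <- config$fn %||% "L"
  outputs <- character(0)

  for (nm in names(config$rasters)) {
    raster <- read_label_image(config$rasters[[nm]],
                               resolution = config$resolution %||% 1.0)
    lab <- label_patches(raster, conn)
    base <- file.path(out_dir, nm)
    write_metrics_csv(class_metrics(lab, raster), "class", nm,
                      paste0(base, "_class_metrics.csv"))
    write_metrics_csv(landscape_level_metrics(lab, raster), "landscape",
                      nm, paste0(base, "_landscape_metrics.csv"))
    cx <- as.data.frame(complexity_metrics(adjacency_counts(raster)))
    write_metrics_csv(cx, "landscape", nm,
                      paste0(base, "_complexity_metrics.csv"))
    outputs <- c(outputs, paste0(base, c("_class_metrics.csv",
                                         "_landscape_metrics.csv",
                                         "_complexity_metrics.csv")))
  }

  for (nm in names(config$points)) {
    win <- if (!is.null(config$window)) {
      do.call(pp_window, config$window[c("x_min", "x_max",
                                         "y_min", "y_max")])
    } else NULL
    pp <- read_points_csv(config$points[[nm]], window = win)
    base <- file.path(out_dir, nm)
    ss <- summary_stats(pp)
    idx <- data.frame(metric = c("n", "intensity", "mean_nn_distance",
                                 "clark_evans", "hopkins_skellam"),
                      value = c(ss$n, ss$intensity, ss$mean_nn_distance,
                                clark_evans(pp),
                                hopkins_skellam(pp, rng_seed = seed)))
    utils::write.csv(idx, paste0(base, "_indices.csv"), row.names = FALSE)
    est_path <- paste0(base, "_", fn, ".csv")
    n_sim <- config$n_sim %||% 0
    if (n_sim >= 2) {
      env <- csr_envelope(pp, which = fn, n_sim = n_sim, kind = "global",
                          rng_seed = seed, correction = config$correction)
      utils::write.csv(data.frame(r = env$r, value = env$obs,
                                  lo = env$lo, hi = env$hi),
                       est_path, row.names = FALSE)
    } else {
      val <- .eval_summary_fn(pp, fn, default_r_grid(pp$window, 128L),
                              config$correction)
      utils::write.csv(data.frame(r = default_r_grid(pp$window, 128L),
                                  value = val),
                       est_path, row.names = FALSE)
    }
    outputs <- c(outputs, paste0(base, "_indices.csv"), est_path)
  }

  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = config, seed = seed, outputs = outputs,
         package_version = as.character(utils::packageVersion("histoscape"))),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs <- c(outputs, manifest)
  invisible(list(manifest = manifest, outputs = outputs))
}
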