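#' Categorical raster (classified histology image)
#'
#' A `categorical_raster` is the in-memory form of a classified histology
#' image: a 2D grid of integer class codes ("the histological landscape"),
#' e.g. nuclei / cytoplasm / vascular channels, or cells / stroma / colloid /
#' space. Class codes need not be contiguous. Pixels equal to `nodata_code`
#' (or `NA`) lie outside the tissue and are excluded from every metric.
#'
#' Coordinate convention, used throughout the package: pixel `(row, col)`
#' (1-based, row 1 at the top) has centre `(x = col - 0.5, y = row - 0.5)`;
#' the image occupies the window `[0, ncol] x [0, nrow]` with y increasing
#' downward. `resolution` is the pixel edge length in physical units
#' (defaults to 1, i.e. lengths in pixels and areas in pixels squared).
#'
#' @param values integer matrix of class codes (`NA` allowed for nodata).
#' @param resolution pixel edge length in physical units; must be `> 0`.
#' @param nodata_code optional integer; pixels with this value are treated
#'   as nodata (converted to `NA` internally).
#' @param class_names optional named character vector mapping class codes
#'   (as names) to human-readable class names.
#' @return object of class `categorical_raster` with elements `values`
#'   (integer matrix, `NA` = nodata), `resolution` and `class_names`.
#' @examples
#' r <- categorical_raster(matrix(c(1, 1, 1, 2), 2, 2))
#' class_proportions(r)
#' @export
categorical_raster <- function(values, resolution = 1.0, nodata_code = NULL,
                               class_names = NULL) {
  if (!is.matrix(values)) {
    stop("`values` must be a matrix of integer class codes")
  }
  storage.mode(values) <- "integer"
  if (!is.null(nodata_code)) {
    values[values == as.integer(nodata_code)] <- NA_integer_
  }
  if (all(is.na(values))) {
    stop("empty landscape: raster contains no non-nodata pixel")
  }
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      !is.finite(resolution) || resolution <= 0) {
    stop("`resolution` must be a single positive number")
  }
  if (any(values < 0L, na.rm = TRUE)) {
    stop("class codes must be non-negative integers")
  }
  structure(
    list(values = values, resolution = as.numeric(resolution),
         class_names = class_names),
    class = "categorical_raster"
  )
}

#' @export
print.categorical_raster <- function(x, ...) {
  v <- x$values
  cat("categorical_raster: ", nrow(v), " x ", ncol(v),
      " pixels, resolution ", x$resolution, "\n", sep = "")
  p <- class_proportions(x)
  cat("classes:", paste0(names(p), " (", sprintf("%.1f%%", 100 * p), ")",
                         collapse = ", "), "\n")
  if (anyNA(v)) cat("nodata pixels:", sum(is.na(v)), "\n")
  invisible(x)
}

#' Raster classes present
#' @param raster a [categorical_raster()].
#' @return sorted integer vector of class codes present.
#' @export
raster_classes <- function(raster) {
  sort(unique(as.vector(raster$values[!is.na(raster$values)])))
}

#' Observation window spanned by a raster
#'
#' Full-extent rectangular window of the raster in physical units, per the
#' package pixel-centre convention (origin at the top-left corner).
#' @param raster a [categorical_raster()].
#' @return a [pp_window()].
#' @export
raster_window <- function(raster) {
  res <- raster$resolution
  pp_window(0, ncol(raster$values) * res, 0, nrow(raster$values) * res)
}

#' Label patches (connected same-class regions)
#'
#' Partitions the raster into patches: maximal connected sets of pixels
#' sharing one class, the unit of landscape-ecology analysis. Connectivity
#' defaults to 8 (queen); adjacency-based metrics always use the
#' 4-neighbour rule regardless of this choice.
#'
#' @param raster a [categorical_raster()].
#' @param connectivity 4 or 8.
#' @return object of class `patch_labeling`: list with `patch_ids` (integer
#'   matrix, 0 = nodata), `patch_class` (integer vector indexed by patch id),
#'   `patch_size` (pixel counts), `connectivity`.
#' @export
label_patches <- function(raster, connectivity = 8) {
  stopifnot(inherits(raster, "categorical_raster"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)  # column-major pixel index
  ok <- !is.na(v)

  edge_pairs <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)  # linear indices, never [row, col]
    # keep pairs where both pixels are data and share a class
    keep <- ok[a] & ok[b] & v[a] == v[b]
    keep[is.na(keep)] <- FALSE
    cbind(a[keep], b[keep])
  }
  pairs <- list()
  if (nc > 1L) pairs <- c(pairs, list(edge_pairs(idx[, -nc], idx[, -1L])))
  if (nr > 1L) pairs <- c(pairs, list(edge_pairs(idx[-nr, ], idx[-1L, ])))
  if (connectivity == 8L && nr > 1L && nc > 1L) {
    pairs <- c(pairs, list(edge_pairs(idx[-nr, -nc], idx[-1L, -1L])))  # \
    pairs <- c(pairs, list(edge_pairs(idx[-1L, -nc], idx[-nr, -1L])))  # /
  }
  pairs <- do.call(rbind, pairs)

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    g <- igraph::add_edges(g, t(pairs))
  }
  memb <- igraph::components(g)$membership
  memb[!ok] <- NA

  # dense ids from 1 in row-major first-occurrence order (deterministic)
  rowmajor <- as.vector(t(matrix(memb, nr, nc)))
  first <- rowmajor[!is.na(rowmajor)]
  relabel <- integer(max(memb, na.rm = TRUE))
  relabel[unique(first)] <- seq_along(unique(first))
  ids <- matrix(0L, nr, nc)
  ids[ok] <- relabel[memb[ok]]

  np <- max(ids)
  patch_class <- integer(np)
  patch_class[ids[ok]] <- v[ok]
  patch_size <- tabulate(ids[ok], nbins = np)

  structure(
    list(patch_ids = ids, patch_class = patch_class,
         patch_size = patch_size, connectivity = connectivity),
    class = "patch_labeling"
  )
}

#' @export
print.patch_labeling <- function(x, ...) {
  cat("patch_labeling:", length(x$patch_class), "patches,",
      length(unique(x$patch_class)), "classes, connectivity",
      x$connectivity, "\n")
  invisible(x)
}

#' Class adjacency counts (4-neighbour, double-count convention)
#'
#' Counts ordered pairs of 4-adjacent pixels by class: `counts[i, j]` is the
#' number of ordered neighbour pairs `(a, b)` with `class(a) = i`,
#' `class(b) = j`. Every unordered edge contributes twice, so the matrix is
#' symmetric (the FRAGSTATS double-count convention). Pairs touching nodata
#' are excluded. This co-occurrence matrix underlies the aggregation,
#' contagion and complexity metrics.
#'
#' @param raster a [categorical_raster()].
#' @return object of class `adjacency_counts`: integer matrix with dimnames
#'   equal to the class codes present.
#' @export
adjacency_counts <- function(raster) {
  stopifnot(inherits(raster, "categorical_raster"))
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  classes <- raster_classes(raster)
  m <- length(classes)
  f <- function(x) factor(x, levels = classes)
  counts <- matrix(0L, m, m, dimnames = list(classes, classes))
  add <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) return()
    tab <- table(f(a[keep]), f(b[keep]))
    counts <<- counts + unclass(tab) + t(unclass(tab))
  }
  if (nc > 1L) add(v[, -nc], v[, -1L])
  if (nr > 1L) add(v[-nr, ], v[-1L, ])
  storage.mode(counts) <- "integer"
  structure(counts, class = c("adjacency_counts", "matrix"))
}

#' Class proportions of a raster
#'
#' Proportion of pixels in each class among non-nodata (and, optionally,
#' masked-in) pixels — the simplest information a classified image yields.
#'
#' @param raster a [categorical_raster()].
#' @param mask optional logical matrix of the same shape; only `TRUE` pixels
#'   are counted (emulating e.g. an "all_tissue" mask).
#' @return named numeric vector of proportions (names = class codes),
#'   summing to 1.
#' @export
class_proportions <- function(raster, mask = NULL) {
  stopifnot(inherits(raster, "categorical_raster"))
  v <- raster$values
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(v))) {
      stop("`mask` must be a logical matrix with the raster's dimensions")
    }
    v <- v[mask]
  }
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no pixels selected")
  tab <- table(v)
  p <- as.numeric(tab) / length(v)
  names(p) <- names(tab)
  p
}
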