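#' Rectangular observation window
#'
#' Point-pattern analyses in this package operate in a rectangular window
#' (in practice the largest rectangle common to a set of classified
#' images), in the same physical units as the point coordinates.
#'
#' @param x_min,x_max,y_min,y_max window limits; `x_max > x_min`,
#'   `y_max > y_min`.
#' @return object of class `pp_window`.
#' @export
pp_window <- function(x_min, x_max, y_min, y_max) {
  if (!(x_max > x_min && y_max > y_min)) {
    stop("window must satisfy x_max > x_min and y_max > y_min")
  }
  structure(list(x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max),
            class = "pp_window")
}

#' @export
print.pp_window <- function(x, ...) {
  cat(sprintf("window [%g, %g] x [%g, %g]\n",
              x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

window_area <- function(w) (w$x_max - w$x_min) * (w$y_max - w$y_min)
window_sides <- function(w) c(w$x_max - w$x_min, w$y_max - w$y_min)

# distance from each point to the window boundary
border_distance <- function(pp) {
  w <- pp$window
  pmin(pp$x - w$x_min, w$x_max - pp$x, pp$y - w$y_min, w$y_max - pp$y)
}

#' Spatial point pattern
#'
#' A set of annotated feature locations (follicle centroids, portal tracts,
#' central veins, myofibroblast nuclei, ...) inside a rectangular window,
#' with optional marks.
#'
#' @param x,y numeric coordinate vectors of equal length.
#' @param window a [pp_window()]; all points must lie inside or on its
#'   boundary.
#' @param marks optional vector of per-point labels (e.g. `"portal"`,
#'   `"central"`).
#' @return object of class `point_pattern` with elements `x`, `y`,
#'   `window`, `marks`, `n`.
#' @export
point_pattern <- function(x, y, window, marks = NULL) {
  stopifnot(inherits(window, "pp_window"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("point coordinates must be finite")
  if (length(x) > 0 &&
      (any(x < window$x_min) || any(x > window$x_max) ||
       any(y < window$y_min) || any(y > window$y_max))) {
    stop("all points must lie inside or on the window boundary")
  }
  if (!is.null(marks) && length(marks) != length(x)) {
    stop("`marks` must have one entry per point")
  }
  structure(list(x = x, y = y, window = window, marks = marks,
                 n = length(x)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("point_pattern:", x$n, "points in")
  print(x$window)
  if (!is.null(x$marks)) {
    cat("marks:", paste(utils::head(sort(unique(x$marks)), 5),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a point pattern by mark
#' @param pp a [point_pattern()].
#' @param mark mark value to keep.
#' @return a [point_pattern()] of the matching points in the same window.
#' @export
subset_marks <- function(pp, mark) {
  stopifnot(inherits(pp, "point_pattern"))
  if (is.null(pp$marks)) stop("pattern has no marks")
  keep <- pp$marks == mark
  point_pattern(pp$x[keep], pp$y[keep], pp$window, pp$marks[keep])
}

# full pairwise distance matrix (diagonal Inf) and NN distances
pp_pairdist <- function(pp) {
  d <- as.matrix(stats::dist(cbind(pp$x, pp$y)))
  diag(d) <- Inf
  d
}

pp_nndist <- function(pp) {
  if (pp$n < 2L) return(rep(NA_real_, pp$n))
  apply(pp_pairdist(pp), 1L, min)
}

#' Basic point-pattern summaries
#'
#' Intensity (points per unit area) and crude mean nearest-neighbour
#' distance — the simplest measures of a spatial point pattern.
#'
#' @param pp a [point_pattern()].
#' @return list with `n`, `intensity`, `mean_nn_distance` (`NA`, flagged
#'   undefined, when `n < 2`).
#' @export
summary_stats <- function(pp) {
  stopifnot(inherits(pp, "point_pattern"))
  list(n = pp$n,
       intensity = pp$n / window_area(pp$window),
       mean_nn_distance = if (pp$n >= 2L) mean(pp_nndist(pp)) else NA_real_)
}

#' Clark-Evans aggregation index
#'
#' Ratio of the observed mean nearest-neighbour distance to its expectation
#' `1 / (2 sqrt(lambda))` under complete spatial randomness (CSR) at the
#' same intensity. Values below 1 suggest clustering, above 1
#' ordering/dispersal. The default is the uncorrected (naive) index; the
#' Donnelly edge correction adjusts the CSR expectation for the window
#' perimeter and is approximately unbiased in rectangles.
#'
#' @param pp a [point_pattern()] with at least 2 points.
#' @param correction `"none"` (default) or `"donnelly"`.
#' @return the index (single number).
#' @export
clark_evans <- function(pp, correction = c("none", "donnelly")) {
  stopifnot(inherits(pp, "point_pattern"))
  correction <- match.arg(correction)
  if (pp$n < 2L) stop("Clark-Evans index needs at least 2 points")
  a <- window_area(pp$window)
  n <- pp$n
  obs <- mean(pp_nndist(pp))
  expected <- switch(correction,
    none = 0.5 * sqrt(a / n),
    donnelly = {
      per <- 2 * sum(window_sides(pp$window))
      0.5 * sqrt(a / n) + (0.0514 + 0.041 / sqrt(n)) * per / n
    })
  obs / expected
}

#' Hopkins-Skellam index
#'
#' Compares event-to-event nearest-neighbour distances with distances from
#' uniformly random sample locations to the nearest event:
#' `sum(d_event^2) / sum(d_sample^2)` over equal counts. Under CSR the
#' index is about 1; clustering shrinks event NN distances, giving values
#' below 1; dispersal gives values above 1.
#'
#' @param pp a [point_pattern()] with at least 2 points.
#' @param n_sample_points number of uniform sample locations (defaults to
#'   the number of events).
#' @param rng_seed integer seed for the sample locations.
#' @return the index (single number).
#' @export
hopkins_skellam <- function(pp, n_sample_points = pp$n, rng_seed = 1L) {
  stopifnot(inherits(pp, "point_pattern"))
  if (pp$n < 2L) stop("Hopkins-Skellam index needs at least 2 points")
  if (n_sample_points < 1L) stop("n_sample_points must be >= 1")
  nn_event <- pp_nndist(pp)
  if (all(nn_event == 0)) {
    warning("all points coincide; index degenerate (0)")
    return(0)
  }
  w <- pp$window
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(rng_seed))
  sx <- stats::runif(n_sample_points, w$x_min, w$x_max)
  sy <- stats::runif(n_sample_points, w$y_min, w$y_max)
  d_sample <- .cross_nn1(sx, sy, pp$x, pp$y)
  # equal counts in both sums: resample event distances if counts differ
  if (n_sample_points != pp$n) {
    idx <- sample.int(pp$n, n_sample_points, replace = n_sample_points > pp$n)
    nn_event <- nn_event[idx]
  }
  sum(nn_event^2) / sum(d_sample^2)
}

# distance from each (x, y) to the nearest of (tx, ty), chunked
.cross_nn1 <- function(x, y, tx, ty, chunk = 2048L) {
  n <- length(x)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    dx <- outer(x[i0:i1], tx, "-")
    dy <- outer(y[i0:i1], ty, "-")
    out[i0:i1] <- sqrt(.rowMins(dx * dx + dy * dy))
  }
  out
}

.rowMins <- function(m) do.call(pmin, as.data.frame(m))

# preserve caller RNG state around seeded Monte-Carlo operations
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
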