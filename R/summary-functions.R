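#' Default r grid for summary functions
#'
#' The standard rule: `n_r` values from 0 to a quarter of the shorter
#' window side.
#' @param window a [pp_window()].
#' @param n_r number of grid points (default 512).
#' @return increasing numeric vector starting at 0.
#' @export
default_r_grid <- function(window, n_r = 512L) {
  seq(0, min(window_sides(window)) / 4, length.out = n_r)
}

.new_fn_estimate <- function(name, r, value, correction, n_points,
                             theo = NULL, extra = NULL) {
  out <- c(list(name = name, r = r, value = value, correction = correction,
                n_points = n_points, theo = theo), extra)
  class(out) <- "fn_estimate"
  out
}

#' @export
print.fn_estimate <- function(x, ...) {
  cat(sprintf("%s-function estimate (%s correction), %d points, r in [0, %g]\n",
              x$name, x$correction, x$n_points, max(x$r)))
  invisible(x)
}

#' Ripley's K function
#'
#' Second-moment summary of a point pattern. The estimator is
#' `K(r) = |W| / (n (n - 1)) * sum_{i != j} e_ij * 1[d_ij <= r]` with
#' edge-correction weights `e_ij`:
#'
#' * `"none"` — `e_ij = 1` (negatively biased near the boundary);
#' * `"translation"` — `e_ij = |W| / ((a - |dx|)(b - |dy|))` for a
#'   rectangle with sides `a`, `b` (default; valid for all rectangles);
#' * `"isotropic"` — Ripley's weight, the reciprocal fraction of the
#'   circle through the pair that lies inside the window (rectangles
#'   only; r is truncated at half the shorter side, with a warning, where
#'   the weight is unstable);
#' * `"border"` — reduced-sample estimator using only points at least `r`
#'   from the boundary.
#'
#' Under CSR, `K(r) = pi r^2`, so the centred L function
#' `L(r) - r = sqrt(K / pi) - r` is zero; clustering plots above zero and
#' regularity/dispersal below.
#'
#' @param pp a [point_pattern()] with at least 2 points.
#' @param r_grid increasing grid of distances starting at 0 (default
#'   [default_r_grid()]).
#' @param correction one of `"none"`, `"border"`, `"translation"`,
#'   `"isotropic"`.
#' @return an `fn_estimate` with fields `r`, `value` and the theoretical
#'   CSR curve `theo = pi r^2`.
#' @export
k_function <- function(pp, r_grid = default_r_grid(pp$window),
                       correction = c("translation", "none", "border",
                                      "isotropic")) {
  stopifnot(inherits(pp, "point_pattern"))
  correction <- match.arg(correction)
  if (pp$n < 2L) stop("K function needs at least 2 points")
  if (r_grid[1] != 0 || is.unsorted(r_grid, strictly = FALSE)) {
    stop("r_grid must be increasing and start at 0")
  }
  sides <- window_sides(pp$window)
  if (correction == "isotropic" && max(r_grid) > min(sides) / 2) {
    warning("isotropic correction truncated at half the shorter side")
    r_grid <- r_grid[r_grid <= min(sides) / 2]
  }
  a <- window_area(pp$window)
  n <- pp$n
  d <- pp_pairdist(pp)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dij <- d[pairs]

  value <- switch(correction,
    none = {
      .k_accumulate(dij, rep(2, length(dij)), r_grid) * a / (n * (n - 1))
    },
    translation = {
      dx <- abs(pp$x[pairs[, 1]] - pp$x[pairs[, 2]])
      dy <- abs(pp$y[pairs[, 1]] - pp$y[pairs[, 2]])
      e <- a / ((sides[1] - dx) * (sides[2] - dy))
      .k_accumulate(dij, 2 * e, r_grid) * a / (n * (n - 1))
    },
    isotropic = {
      e1 <- .ripley_weight(pp$x[pairs[, 1]], pp$y[pairs[, 1]], dij, pp$window)
      e2 <- .ripley_weight(pp$x[pairs[, 2]], pp$y[pairs[, 2]], dij, pp$window)
      .k_accumulate(dij, e1 + e2, r_grid) * a / (n * (n - 1))
    },
    border = {
      b <- border_distance(pp)
      counts <- vapply(r_grid, function(r) {
        keep <- b >= r
        if (!any(keep)) return(NA_real_)
        mean(rowSums(d[keep, , drop = FALSE] <= r))
      }, numeric(1))
      counts * a / (n - 1)
    })
  .new_fn_estimate("K", r_grid, value, correction, n,
                   theo = pi * r_grid^2)
}

# sum of weights for pairs with d <= r, for each r (sorted accumulation)
.k_accumulate <- function(dij, w, r_grid) {
  o <- order(dij)
  cs <- c(0, cumsum(w[o]))
  idx <- findInterval(r_grid, dij[o])
  cs[idx + 1L]
}

# Ripley's isotropic edge-correction weight for circles centred at (x, y)
# with radius r in a rectangular window: 1 / (interior fraction of the
# circumference). Valid for r < half the shorter side.
.ripley_weight <- function(x, y, r, w) {
  d_l <- x - w$x_min; d_r <- w$x_max - x
  d_b <- y - w$y_min; d_t <- w$y_max - y
  ang <- function(d) 2 * acos(pmin(1, d / r))       # arc outside one edge
  corner <- function(d1, d2) {                      # overlap at a corner
    pmax(0, acos(pmin(1, d1 / r)) + acos(pmin(1, d2 / r)) - pi / 2)
  }
  exterior <- ang(d_l) + ang(d_r) + ang(d_b) + ang(d_t) -
    corner(d_l, d_b) - corner(d_l, d_t) - corner(d_r, d_b) - corner(d_r, d_t)
  frac <- 1 - exterior / (2 * pi)
  1 / pmax(frac, .Machine$double.eps)
}

#' Ripley's L function
#'
#' Variance-stabilised transform `L(r) = sqrt(K(r) / pi)`; under CSR
#' `L(r) = r`, so the centred form `L(r) - r` plots CSR as a horizontal
#' line through zero.
#'
#' @inheritParams k_function
#' @param centred if `TRUE`, `value` is `L(r) - r` (and `theo` is 0).
#' @return an `fn_estimate` (name `"L"`).
#' @export
l_function <- function(pp, r_grid = default_r_grid(pp$window),
                       correction = c("translation", "none", "border",
                                      "isotropic"),
                       centred = FALSE) {
  k <- k_function(pp, r_grid, correction)
  l <- sqrt(k$value / pi)
  .new_fn_estimate("L", k$r, if (centred) l - k$r else l, k$correction,
                   k$n_points, theo = if (centred) rep(0, length(k$r)) else k$r,
                   extra = list(centred = centred))
}

#' Empty-space (F), nearest-neighbour (G) and J functions
#'
#' `F(r)` is the CDF of the distance from an arbitrary location in the
#' window to the nearest point, estimated over a regular lattice of test
#' locations; `G(r)` is the CDF of the point-to-nearest-other-point
#' distance; `J(r) = (1 - G(r)) / (1 - F(r))`, reported only where
#' `F(r) < 1`. Under CSR `J` is identically 1; clustering pushes `J`
#' below 1 and regularity above.
#'
#' Edge corrections: `"reduced_sample"` (border; the default) retains at
#' distance `r` only test locations/points at least `r` from the window
#' boundary; `"km"` is the Kaplan-Meier estimator treating the boundary
#' distance as a censoring time.
#'
#' @param pp a [point_pattern()] (at least 1 point for F, 2 for G).
#' @param r_grid increasing grid from 0; default spans a quarter of the
#'   shorter window side.
#' @param correction `"reduced_sample"` or `"km"`.
#' @param grid_spacing spacing of the F test-location lattice; default
#'   `min(side) / 128`.
#' @return list with elements `F`, `G`, `J`, each an `fn_estimate`
#'   (`J$value` is `NA` where `F = 1`).
#' @export
empty_space_functions <- function(pp, r_grid = default_r_grid(pp$window),
                                  correction = c("reduced_sample", "km"),
                                  grid_spacing = NULL) {
  stopifnot(inherits(pp, "point_pattern"))
  correction <- match.arg(correction)
  if (pp$n < 1L) stop("F/G/J need a non-empty pattern")
  w <- pp$window
  sides <- window_sides(w)
  if (is.null(grid_spacing)) grid_spacing <- min(sides) / 128

  # F: regular lattice of test locations (cell centres)
  gx <- seq(w$x_min + grid_spacing / 2, w$x_max, by = grid_spacing)
  gy <- seq(w$y_min + grid_spacing / 2, w$y_max, by = grid_spacing)
  gxy <- expand.grid(x = gx, y = gy)
  d_empty <- .cross_nn1(gxy$x, gxy$y, pp$x, pp$y)
  b_empty <- pmin(gxy$x - w$x_min, w$x_max - gxy$x,
                  gxy$y - w$y_min, w$y_max - gxy$y)
  f_val <- .edge_corrected_cdf(d_empty, b_empty, r_grid, correction)
  f_est <- .new_fn_estimate("F", r_grid, f_val, correction, pp$n)

  g_est <- NULL
  if (pp$n >= 2L) {
    d_nn <- pp_nndist(pp)
    b_pts <- border_distance(pp)
    g_val <- .edge_corrected_cdf(d_nn, b_pts, r_grid, correction)
    g_est <- .new_fn_estimate("G", r_grid, g_val, correction, pp$n)
  }

  j_est <- NULL
  if (!is.null(g_est)) {
    j_val <- ifelse(!is.na(f_val) & f_val < 1,
                    (1 - g_est$value) / (1 - f_val), NA_real_)
    j_est <- .new_fn_estimate("J", r_grid, j_val, correction, pp$n,
                              theo = rep(1, length(r_grid)))
  }
  list(F = f_est, G = g_est, J = j_est)
}

# edge-corrected empirical CDF of distances d with censoring distances b
.edge_corrected_cdf <- function(d, b, r_grid, correction) {
  if (correction == "reduced_sample") {
    vapply(r_grid, function(r) {
      keep <- b >= r
      if (!any(keep)) return(NA_real_)
      mean(d[keep] <= r)
    }, numeric(1))
  } else {
    obs <- pmin(d, b)
    event <- d <= b
    fit <- survival::survfit(survival::Surv(obs, event) ~ 1)
    s <- stats::stepfun(fit$time, c(1, fit$surv))(r_grid)
    pmin(pmax(1 - s, 0), 1)
  }
}
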