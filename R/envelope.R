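#' Simulate a homogeneous Poisson (CSR) pattern with fixed n
#'
#' Internal helper: n points placed uniformly in the window (a binomial
#' process, the conditional form of CSR used for envelope simulation).
#' @noRd
.runif_pattern <- function(n, window) {
  point_pattern(stats::runif(n, window$x_min, window$x_max),
                stats::runif(n, window$y_min, window$y_max), window)
}

# evaluate a named summary function on a fixed grid, returning values
.eval_summary_fn <- function(pp, which, r_grid, correction = NULL,
                             grid_spacing = NULL) {
  switch(which,
    K = k_function(pp, r_grid,
                   correction = correction %||% "translation")$value,
    L = l_function(pp, r_grid,
                   correction = correction %||% "translation",
                   centred = TRUE)$value,
    F = empty_space_functions(pp, r_grid,
                              correction = correction %||% "reduced_sample",
                              grid_spacing = grid_spacing)$F$value,
    G = empty_space_functions(pp, r_grid,
                              correction = correction %||% "reduced_sample",
                              grid_spacing = grid_spacing)$G$value,
    J = empty_space_functions(pp, r_grid,
                              correction = correction %||% "reduced_sample",
                              grid_spacing = grid_spacing)$J$value,
    stop("unknown summary function: ", which)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo CSR envelope for a summary function
#'
#' Simulates `n_sim` CSR patterns with the same number of points in the
#' same window, computes the chosen summary function with the same
#' estimator and correction, and returns envelope bands together with the
#' empirical curve.
#'
#' * `kind = "pointwise"`: rank envelopes at each r — the k-th smallest
#'   and k-th largest simulated value with `k = ceiling(alpha/2 *
#'   (n_sim + 1))` (for `n_sim = 99`, `alpha = 0.05`: the 3rd lowest and
#'   highest).
#' * `kind = "global"`: maximum-deviation envelopes — the band is the
#'   simulation mean plus/minus the `ceiling((1 - alpha) * (n_sim + 1))`-th
#'   smallest of the simulated maximum absolute deviations from that mean,
#'   giving simultaneous coverage across the whole r range.
#'
#' @param pp a [point_pattern()] with at least 2 points.
#' @param which one of `"K"`, `"L"`, `"F"`, `"G"`, `"J"` (`"L"` is the
#'   centred `L(r) - r`).
#' @param n_sim number of CSR simulations (at least 2; 99 is
#'   conventional).
#' @param kind `"pointwise"` or `"global"`.
#' @param rng_seed integer seed; identical seeds give identical envelopes.
#' @param r_grid common r grid (default [default_r_grid()] with 128
#'   points).
#' @param correction estimator correction (defaults: translation for K/L,
#'   reduced-sample for F/G/J).
#' @param alpha envelope level (default 0.05).
#' @param grid_spacing F test-lattice spacing passed through to
#'   [empty_space_functions()].
#' @return object of class `csr_envelope`: list with `r`, `obs`, `lo`,
#'   `hi`, `sim_mean`, `which`, `kind`, `n_sim`, `alpha`.
#' @export
csr_envelope <- function(pp, which = c("L", "K", "F", "G", "J"),
                         n_sim = 99L, kind = c("pointwise", "global"),
                         rng_seed = 1L,
                         r_grid = default_r_grid(pp$window, 128L),
                         correction = NULL, alpha = 0.05,
                         grid_spacing = NULL) {
  stopifnot(inherits(pp, "point_pattern"))
  which <- match.arg(which)
  kind <- match.arg(kind)
  if (pp$n < 2L) stop("envelope needs at least 2 points")
  if (n_sim < 2L) stop("n_sim must be at least 2")

  obs <- .eval_summary_fn(pp, which, r_grid, correction, grid_spacing)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(rng_seed))
  sims <- vapply(seq_len(n_sim), function(i) {
    .eval_summary_fn(.runif_pattern(pp$n, pp$window), which, r_grid,
                     correction, grid_spacing)
  }, numeric(length(r_grid)))

  if (kind == "pointwise") {
    k <- ceiling(alpha / 2 * (n_sim + 1))
    k <- max(1L, min(k, n_sim))
    lo <- apply(sims, 1L, function(v) sort(v)[k])
    hi <- apply(sims, 1L, function(v) sort(v, decreasing = TRUE)[k])
    sim_mean <- rowMeans(sims)
  } else {
    sim_mean <- rowMeans(sims)
    dev <- apply(sims, 2L, function(v) max(abs(v - sim_mean), na.rm = TRUE))
    k <- min(ceiling((1 - alpha) * (n_sim + 1)), n_sim)
    crit <- sort(dev)[k]
    lo <- sim_mean - crit
    hi <- sim_mean + crit
  }
  structure(list(r = r_grid, obs = obs, lo = lo, hi = hi,
                 sim_mean = sim_mean, which = which, kind = kind,
                 n_sim = n_sim, alpha = alpha),
            class = "csr_envelope")
}

#' @export
print.csr_envelope <- function(x, ...) {
  cat(sprintf("%s %s CSR envelope (%d simulations, alpha %.2f)\n",
              x$kind, x$which, x$n_sim, x$alpha))
  out <- sum(x$obs < x$lo | x$obs > x$hi, na.rm = TRUE)
  cat("observed curve outside the band at", out, "of",
      sum(!is.na(x$obs)), "r values\n")
  invisible(x)
}

#' Studentized permutation test for grouped point patterns
#'
#' Tests whether two or more groups of point patterns share the same
#' summary-function behaviour. Each pattern is reduced to its empirical
#' summary function on a common r grid; the test statistic is
#' \deqn{T = \sum_{i < j} \int \frac{(\bar f_i(r) - \bar f_j(r))^2}
#'   {s_i^2(r)/m_i + s_j^2(r)/m_j} \, dr}
#' (trapezoid quadrature, group means \eqn{\bar f}, between-pattern
#' variances \eqn{s^2} floored at 1e-12), and the p-value is obtained by
#' permuting pattern-to-group assignments with the add-one convention
#' `p = (1 + #(T* >= T)) / (1 + n_permutations)`.
#'
#' @param groups list of groups, each a list of [point_pattern()]s
#'   (at least 2 groups with at least 2 patterns each).
#' @param which summary function: `"L"` (centred), `"F"`, `"G"` or `"J"`.
#' @param r_grid common r grid; default from the first pattern's window
#'   (64 points).
#' @param n_permutations number of random permutations (999 is
#'   conventional).
#' @param rng_seed integer seed for the permutations.
#' @param correction estimator correction forwarded to the summary
#'   function.
#' @return object of class `group_test`: list with `statistic`, `p_value`,
#'   `n_permutations`, `groups` (labels and sizes), `which`.
#' @export
studentized_permutation_test <- function(groups,
                                         which = c("L", "F", "G", "J"),
                                         r_grid = NULL,
                                         n_permutations = 999L,
                                         rng_seed = 1L,
                                         correction = NULL) {
  which <- match.arg(which)
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 patterns (variance undefined)")
  }
  pats <- unlist(groups, recursive = FALSE)
  if (is.null(r_grid)) {
    r_grid <- default_r_grid(pats[[1]]$window, 64L)
  }
  curves <- vapply(pats, .eval_summary_fn, numeric(length(r_grid)),
                   which = which, r_grid = r_grid, correction = correction)
  # J can be NA at large r where F saturates; restrict to fully observed r
  ok <- rowSums(is.na(curves)) == 0L
  if (sum(ok) < 2L) stop("summary functions undefined over the r grid")
  curves <- curves[ok, , drop = FALSE]
  r_use <- r_grid[ok]
  g_idx <- rep(seq_along(groups), sizes)

  stat <- function(assign) .studentized_T(curves, assign, r_use)
  observed <- stat(g_idx)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(rng_seed))
  perm_T <- vapply(seq_len(n_permutations),
                   function(i) stat(sample(g_idx)), numeric(1))
  p <- (1 + sum(perm_T >= observed)) / (1 + n_permutations)
  structure(list(statistic = observed, p_value = p,
                 n_permutations = n_permutations,
                 groups = data.frame(group = names(groups) %||%
                                       as.character(seq_along(groups)),
                                     size = as.integer(sizes)),
                 which = which, r = r_use, perm_statistics = perm_T),
            class = "group_test")
}

#' Combined grouped test across several summary functions
#'
#' Aggregated variant of [studentized_permutation_test()]: the statistic
#' is the sum of the per-function studentized statistics over the
#' requested summary functions, with one shared set of group-label
#' permutations. This is a labelled convenience for "are the groups
#' different by any of L, F, G, J taken together"; it is not claimed to
#' equal any single-function statistic.
#'
#' @inheritParams studentized_permutation_test
#' @param which character vector of summary functions to combine.
#' @return a `group_test` (with `which` the concatenated function names
#'   and `per_function` holding the observed per-function statistics).
#' @export
combined_permutation_test <- function(groups, which = c("L", "G", "J"),
                                      r_grid = NULL,
                                      n_permutations = 999L,
                                      rng_seed = 1L, correction = NULL) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 patterns (variance undefined)")
  }
  pats <- unlist(groups, recursive = FALSE)
  if (is.null(r_grid)) r_grid <- default_r_grid(pats[[1]]$window, 64L)
  curve_sets <- lapply(which, function(fn) {
    curves <- vapply(pats, .eval_summary_fn, numeric(length(r_grid)),
                     which = fn, r_grid = r_grid, correction = correction)
    ok <- rowSums(is.na(curves)) == 0L
    list(curves = curves[ok, , drop = FALSE], r = r_grid[ok])
  })
  g_idx <- rep(seq_along(groups), sizes)
  stat <- function(assign) {
    vapply(curve_sets,
           function(cs) .studentized_T(cs$curves, assign, cs$r),
           numeric(1))
  }
  obs_per_fn <- stat(g_idx)
  observed <- sum(obs_per_fn)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(rng_seed))
  perm_T <- vapply(seq_len(n_permutations),
                   function(i) sum(stat(sample(g_idx))), numeric(1))
  p <- (1 + sum(perm_T >= observed)) / (1 + n_permutations)
  structure(list(statistic = observed, p_value = p,
                 n_permutations = n_permutations,
                 groups = data.frame(group = names(groups) %||%
                                       as.character(seq_along(groups)),
                                     size = as.integer(sizes)),
                 which = paste(which, collapse = "+"),
                 per_function = stats::setNames(obs_per_fn, which),
                 perm_statistics = perm_T),
            class = "group_test")
}

.studentized_T <- function(curves, g_idx, r) {
  gs <- sort(unique(g_idx))
  means <- sapply(gs, function(g) rowMeans(curves[, g_idx == g, drop = FALSE]))
  vars <- sapply(gs, function(g) {
    apply(curves[, g_idx == g, drop = FALSE], 1L, stats::var)
  })
  m <- vapply(gs, function(g) sum(g_idx == g), numeric(1))
  total <- 0
  for (i in seq_along(gs)[-length(gs)]) {
    for (j in seq((i + 1), length(gs))) {
      denom <- pmax(vars[, i] / m[i] + vars[, j] / m[j], 1e-12)
      integrand <- (means[, i] - means[, j])^2 / denom
      total <- total + .trapz(r, integrand)
    }
  }
  total
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("studentized permutation test (%s function): T = %.4f, p = %.4g (%d permutations)\n",
              x$which, x$statistic, x$p_value, x$n_permutations))
  print(x$groups)
  invisible(x)
}

#' Voronoi tessellation and Stienen diagram of a point pattern
#'
#' The Voronoi cell of a point is the region of the window closer to that
#' point than to any other point; cells are computed by clipping the
#' window rectangle with the perpendicular-bisector half-planes and
#' together tile the window exactly. The Stienen diagram draws around each
#' point a circle of diameter equal to its nearest-neighbour distance;
#' circles extending beyond the window are flagged (conventionally not
#' plotted).
#'
#' @param pp a [point_pattern()] with at least 2 points.
#' @return list with `cells` (list of polygon data.frames `x`, `y`),
#'   `cell_areas`, and `stienen` (data.frame `x`, `y`, `radius`,
#'   `crosses_boundary`).
#' @export
voronoi_stienen <- function(pp) {
  stopifnot(inherits(pp, "point_pattern"))
  if (pp$n < 2L) stop("Voronoi/Stienen need at least 2 points")
  w <- pp$window
  rect <- list(x = c(w$x_min, w$x_max, w$x_max, w$x_min),
               y = c(w$y_min, w$y_min, w$y_max, w$y_max))
  cells <- lapply(seq_len(pp$n), function(i) {
    poly <- rect
    for (j in seq_len(pp$n)[-i]) {
      # half-plane of points nearer to i than to j
      nx <- pp$x[j] - pp$x[i]; ny <- pp$y[j] - pp$y[i]
      mx <- (pp$x[i] + pp$x[j]) / 2; my <- (pp$y[i] + pp$y[j]) / 2
      poly <- .clip_halfplane(poly, nx, ny, nx * mx + ny * my)
      if (length(poly$x) == 0L) break
    }
    poly
  })
  areas <- vapply(cells, function(p) .polygon_area(p$x, p$y), numeric(1))
  nn <- pp_nndist(pp)
  radius <- nn / 2
  crosses <- border_distance(pp) < radius
  list(cells = cells, cell_areas = areas,
       stienen = data.frame(x = pp$x, y = pp$y, radius = radius,
                            crosses_boundary = crosses))
}

# Sutherland-Hodgman clip of polygon by half-plane {p : n . p <= c}
.clip_halfplane <- function(poly, nx, ny, cval) {
  n <- length(poly$x)
  if (n == 0L) return(poly)
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly$x[i]; y1 <- poly$y[i]; x2 <- poly$x[j]; y2 <- poly$y[j]
    in1 <- nx * x1 + ny * y1 <= cval
    in2 <- nx * x2 + ny * y2 <= cval
    if (in1) { xs <- c(xs, x1); ys <- c(ys, y1) }
    if (in1 != in2) {
      t <- (cval - nx * x1 - ny * y1) / (nx * (x2 - x1) + ny * (y2 - y1))
      xs <- c(xs, x1 + t * (x2 - x1)); ys <- c(ys, y1 + t * (y2 - y1))
    }
  }
  list(x = xs, y = ys)
}

.polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
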