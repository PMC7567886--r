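#' k nearest cross-distances between two point patterns
#'
#' For each point of `from_pp`, the `k` smallest Euclidean distances to
#' points of `to_pp`, in ascending order (e.g. each central vein's
#' distances to its 6 nearest portal tracts).
#'
#' @param from_pp,to_pp [point_pattern()]s.
#' @param k number of neighbours; `to_pp` must have at least `k` points.
#' @return numeric matrix with one row per `from_pp` point and `k`
#'   ascending columns.
#' @export
cross_knn_distances <- function(from_pp, to_pp, k) {
  stopifnot(inherits(from_pp, "point_pattern"),
            inherits(to_pp, "point_pattern"))
  k <- as.integer(k)
  if (to_pp$n < k) {
    stop(sprintf("target pattern has %d points but k = %d (deficit %d)",
                 to_pp$n, k, k - to_pp$n))
  }
  t(vapply(seq_len(from_pp$n), function(i) {
    d <- sqrt((to_pp$x - from_pp$x[i])^2 + (to_pp$y - from_pp$y[i])^2)
    sort(d, partial = k)[seq_len(k)]
  }, numeric(k)))
}

#' Hexagon-paradigm lobule size estimation
#'
#' Models each hepatic lobule as a regular hexagon with the central vein
#' at its centre and portal tracts at the vertices. For each central vein,
#' the mean `r` of the distances to the 6 nearest portal tracts is taken
#' as the hexagon circumradius and the lobule area computed as
#' `(3 * sqrt(3) / 2) * r^2`.
#'
#' @param centrals [point_pattern()] of central veins.
#' @param portals [point_pattern()] of portal tracts (at least 6 points).
#' @return data.frame with one row per central vein: `central_id`,
#'   `d1`..`d6` (ascending distances), `r` (their mean), `area`.
#' @export
lobule_areas <- function(centrals, portals) {
  if (portals$n < 6L) {
    stop(sprintf("need at least 6 portal tracts (have %d)", portals$n))
  }
  d <- cross_knn_distances(centrals, portals, 6L)
  r <- rowMeans(d)
  out <- data.frame(central_id = seq_len(centrals$n))
  colnames(d) <- paste0("d", 1:6)
  out <- cbind(out, d)
  out$r <- r
  out$area <- (3 * sqrt(3) / 2) * r^2
  out
}

#' Shortest distance from points to a closed polyline ring
#'
#' Minimum Euclidean distance from each point to any segment of the ring
#' (e.g. myofibroblast nuclei to the annotated central-vein
#' circumference). Points inside the ring get their distance to the
#' boundary, not zero.
#'
#' @param points data.frame or list with `x`, `y`, or a [point_pattern()].
#' @param ring data.frame or list with `x`, `y` vertices of a closed
#'   polyline (the closing segment last-to-first is implied; at least 3
#'   vertices).
#' @return numeric vector of distances.
#' @export
point_to_ring_distance <- function(points, ring) {
  px <- points$x; py <- points$y
  rx <- ring$x; ry <- ring$y
  if (length(rx) < 3L) stop("ring needs at least 3 vertices")
  if (all(rx == rx[1]) && all(ry == ry[1])) {
    stop("degenerate ring: all vertices coincide")
  }
  n <- length(rx)
  j <- c(seq(2L, n), 1L)
  ax <- rx; ay <- ry; bx <- rx[j]; by <- ry[j]
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  vapply(seq_along(px), function(i) {
    t <- ((px[i] - ax) * ex + (py[i] - ay) * ey) / pmax(len2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    qx <- ax + t * ex; qy <- ay + t * ey
    sqrt(min((px[i] - qx)^2 + (py[i] - qy)^2))
  }, numeric(1))
}

#' Area centroid of a closed ring
#'
#' Polygon centroid by the shoelace formula. If the ring encloses
#' (numerically) zero area, falls back to the vertex mean with a warning.
#'
#' @param ring data.frame or list with `x`, `y` vertices.
#' @return named numeric vector `c(x, y)`.
#' @export
ring_centroid <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  j <- c(seq(2L, n), 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * max(1, sum(x^2 + y^2))) {
    warning("ring encloses zero area; using vertex mean as centroid")
    return(c(x = mean(x), y = mean(y)))
  }
  c(x = sum((x + x[j]) * cross) / (6 * a),
    y = sum((y + y[j]) * cross) / (6 * a))
}

#' Polar angles of points about a centre
#'
#' Angle of each point about `center`, in degrees in `[0, 360)`, in the
#' standard mathematical orientation after undoing the raster y-flip:
#' due east is 0 deg and due north (up in the image) is 90 deg. Because
#' raster y increases downward, this is `atan2(-dy, dx)` on raw image
#' coordinates.
#'
#' @param points data.frame or list with `x`, `y`.
#' @param center numeric length-2 `(x, y)`.
#' @param flip_y set `FALSE` if the coordinates already have y increasing
#'   upward.
#' @return numeric vector of angles in degrees.
#' @export
polar_angles <- function(points, center, flip_y = TRUE) {
  dx <- points$x - center[[1]]
  dy <- points$y - center[[2]]
  if (flip_y) dy <- -dy
  at <- which(dx == 0 & dy == 0)
  if (length(at) > 0L) {
    stop("point(s) at the centre: index ", paste(at, collapse = ", "))
  }
  (atan2(dy, dx) * 180 / pi) %% 360
}

#' Circular kernel density of angles
#'
#' Wrapped (circular) Gaussian kernel density estimate of a sample of
#' angles, evaluated on a 1-degree grid over `[0, 360)` and integrating
#' to 1 over the circle. The wrapped estimator avoids the 0/360 boundary
#' artefacts of a linear KDE. The angle of peak density, `phi_peak`, is
#' the grid argmax.
#'
#' @param angles numeric vector of angles in degrees (at least 2).
#' @param bandwidth kernel standard deviation in degrees; default
#'   Silverman's rule on the angle sample.
#' @return list with `phi` (grid, degrees), `density` (per degree),
#'   `phi_peak`, `bandwidth`.
#' @export
angular_density <- function(angles, bandwidth = NULL) {
  if (length(angles) < 2L) stop("need at least 2 angles")
  a <- angles %% 360
  if (is.null(bandwidth)) bandwidth <- max(stats::bw.nrd0(a), 1e-6)
  grid <- 0:359
  # wrap the sample into the three adjacent periods
  rep3 <- c(a - 360, a, a + 360)
  dens <- vapply(grid, function(g) {
    sum(stats::dnorm(g, mean = rep3, sd = bandwidth))
  }, numeric(1)) / length(a)
  dens <- dens / sum(dens)  # normalise on the 1-degree grid
  list(phi = grid, density = dens, phi_peak = grid[which.max(dens)],
       bandwidth = bandwidth)
}

#' Scar field: myofibroblasts around a central vein
#'
#' Bundles myofibroblast (MFB) nuclear positions with the annotated vein
#' circumference and derives the per-cell geometry used in scar-axis
#' analysis: shortest distance `d` to the vein ring, polar angle `phi`
#' about the ring centroid, and the angle of peak angular density
#' `phi_peak`.
#'
#' @param mfb data.frame or list with `x`, `y` of MFB nuclei.
#' @param ring data.frame or list with `x`, `y` of the vein circumference
#'   polyline.
#' @param bandwidth angular KDE bandwidth in degrees (default Silverman).
#' @param flip_y passed to [polar_angles()].
#' @return object of class `scar_field`: list with `mfb` (data.frame
#'   `x`, `y`), `ring`, `centroid`, `d`, `phi`, `phi_peak`, `bandwidth`.
#' @export
scar_field <- function(mfb, ring, bandwidth = NULL, flip_y = TRUE) {
  centroid <- ring_centroid(ring)
  d <- point_to_ring_distance(mfb, ring)
  phi <- polar_angles(mfb, centroid, flip_y = flip_y)
  ad <- angular_density(phi, bandwidth)
  structure(list(mfb = data.frame(x = mfb$x, y = mfb$y),
                 ring = data.frame(x = ring$x, y = ring$y),
                 centroid = centroid, d = d, phi = phi,
                 phi_peak = ad$phi_peak, bandwidth = ad$bandwidth,
                 flip_y = flip_y),
            class = "scar_field")
}

#' @export
print.scar_field <- function(x, ...) {
  cat(sprintf("scar_field: %d MFB cells, phi_peak = %g deg, median d = %.3g\n",
              nrow(x$mfb), x$phi_peak, stats::median(x$d)))
  invisible(x)
}

#' Rotate a scar field so the density peak sits at 90 degrees
#'
#' Shifts every polar angle by `(90 - phi_peak) mod 360`, the angular
#' equivalent of rotating all MFBs about the vein centroid so fields from
#' different images can be aggregated. Pairwise angular differences and
#' all radial distances are preserved.
#'
#' @param field a [scar_field()].
#' @param bandwidth angular KDE bandwidth for re-estimating the peak.
#' @return the aligned `scar_field` (with `shift_applied` recording the
#'   rotation in degrees).
#' @export
align_to_peak <- function(field, bandwidth = NULL) {
  stopifnot(inherits(field, "scar_field"))
  shift <- (90 - field$phi_peak) %% 360
  phi <- (field$phi + shift) %% 360
  ad <- angular_density(phi, bandwidth %||% field$bandwidth)
  field$phi <- phi
  field$phi_peak <- ad$phi_peak
  field$shift_applied <- shift
  field
}

#' Least-squares sine fit to an angular density
#'
#' Fits `f(phi) = A * sin(2 * pi * phi / P + phi0) + C` to an angular
#' density (or any curve on a full 0-360 degree grid) with the amplitude,
#' period, phase and offset all free. To avoid local minima the fit is
#' multi-started from period seeds 360, 180 and 120 degrees (each with a
#' linear least-squares warm start for the remaining parameters) and the
#' best-RSS fit returned. A fitted period near 180 degrees indicates
#' axial (bipolar) symmetry of the density.
#'
#' @param phi grid of angles in degrees.
#' @param density density values on the grid.
#' @param period_starts period seeds in degrees.
#' @return object of class `axial_sine_fit`: list with `amplitude`
#'   (>= 0), `period` (degrees), `phase` (degrees, in `[0, 360)`),
#'   `offset`, `rss`, `fitted`, and `period_identifiable` (`FALSE` when
#'   the amplitude is negligible relative to the density scale).
#' @export
fit_axial_sine <- function(phi, density, period_starts = c(360, 180, 120)) {
  stopifnot(length(phi) == length(density), length(phi) >= 8L)
  if (stats::sd(density) < .Machine$double.eps * max(1, abs(mean(density)))) {
    # constant density: zero amplitude, period not identifiable
    return(structure(list(amplitude = 0, period = period_starts[1],
                          phase = 0, offset = mean(density), rss = 0,
                          fitted = rep(mean(density), length(phi)),
                          period_identifiable = FALSE),
                     class = "axial_sine_fit"))
  }
  best <- NULL
  for (p0 in period_starts) {
    # linear warm start at fixed period: density ~ a sin + b cos + C
    s <- sin(2 * pi * phi / p0); co <- cos(2 * pi * phi / p0)
    lmfit <- stats::lm(density ~ s + co)
    a <- stats::coef(lmfit)[["s"]]; b <- stats::coef(lmfit)[["co"]]
    start <- list(A = sqrt(a^2 + b^2), P = p0,
                  phi0 = atan2(b, a), C = stats::coef(lmfit)[[1]])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        density ~ A * sin(2 * pi * phi / P + phi0) + C,
        start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      co_f <- stats::coef(fit)
      best <- list(A = co_f[["A"]], P = abs(co_f[["P"]]),
                   phi0 = co_f[["phi0"]], C = co_f[["C"]], rss = rss,
                   fitted = stats::fitted(fit))
    }
  }
  if (is.null(best)) {
    stop("sine fit failed to converge from all period starts ",
         paste(period_starts, collapse = ", "))
  }
  # canonical form: non-negative amplitude, phase in [0, 360)
  if (best$A < 0) {
    best$A <- -best$A
    best$phi0 <- best$phi0 + pi
  }
  identifiable <- best$A > 0.05 * max(stats::sd(density), .Machine$double.eps)
  structure(list(amplitude = best$A, period = best$P,
                 phase = (best$phi0 * 180 / pi) %% 360,
                 offset = best$C, rss = best$rss, fitted = best$fitted,
                 period_identifiable = identifiable),
            class = "axial_sine_fit")
}

#' @export
print.axial_sine_fit <- function(x, ...) {
  cat(sprintf("sine fit: amplitude %.4g, period %.1f deg, phase %.1f deg, offset %.4g, rss %.3g\n",
              x$amplitude, x$period, x$phase, x$offset, x$rss))
  if (!x$period_identifiable) cat("(amplitude negligible: period not identifiable)\n")
  invisible(x)
}

#' Radial density of cell-to-vein distances
#'
#' Gaussian kernel density (Silverman bandwidth) of the distance sample
#' on `[0, max(d)]`, with reflection at zero (distances cannot be
#' negative) and renormalisation so the density integrates to 1 on the
#' interval. A mode near zero is the signature of an MFB gradient highest
#' at the central vein.
#'
#' @param d numeric vector of distances (at least 2).
#' @param n grid size (default 512).
#' @return list with `x`, `density`, `mode`, `quartiles` (25/50/75% of
#'   the sample), `bandwidth`.
#' @export
radial_density <- function(d, n = 512L) {
  if (length(d) < 2L) stop("need at least 2 distances")
  if (max(d) == min(d)) {
    # degenerate spike: all mass at the common value
    x <- seq(0, max(max(d), .Machine$double.eps), length.out = n)
    dens <- rep(0, n)
    dens[which.min(abs(x - d[1]))] <- 1 / (x[2] - x[1])
    return(list(x = x, density = dens, mode = d[1],
                quartiles = stats::quantile(d, c(.25, .5, .75)),
                bandwidth = 0))
  }
  bw <- stats::bw.nrd0(d)
  kd <- stats::density(c(d, -d), bw = bw, from = 0, to = max(d), n = n)
  dens <- 2 * kd$y           # reflection at zero
  step <- kd$x[2] - kd$x[1]
  dens <- dens / (sum(dens) * step)
  list(x = kd$x, density = dens, mode = kd$x[which.max(dens)],
       quartiles = stats::quantile(d, c(.25, .5, .75)), bandwidth = bw)
}

#' Bootstrap Kolmogorov-Smirnov test
#'
#' Two-sample KS statistic `D` (sup-difference of empirical CDFs,
#' tie-tolerant) with a bootstrap p-value: both groups are resampled with
#' replacement from the pooled sample and `p = (1 + #(D* >= D)) /
#' (1 + n_boot)`.
#'
#' @param a,b numeric samples (non-empty).
#' @param n_boot number of bootstrap resamples (default 999).
#' @param rng_seed integer seed.
#' @return list with `D`, `p_value`, `n_boot`.
#' @export
ks_boot <- function(a, b, n_boot = 999L, rng_seed = 1L) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  d_obs <- .ks_D(a, b)
  pool <- c(a, b)
  na <- length(a); nb <- length(b)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(rng_seed))
  d_star <- vapply(seq_len(n_boot), function(i) {
    .ks_D(sample(pool, na, replace = TRUE), sample(pool, nb, replace = TRUE))
  }, numeric(1))
  list(D = d_obs, p_value = (1 + sum(d_star >= d_obs)) / (1 + n_boot),
       n_boot = n_boot)
}

.ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pts)
  fb <- stats::ecdf(b)(pts)
  max(abs(fa - fb))
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test (Satterthwaite degrees of freedom), the
#' package-wide two-group comparison for normally distributed summaries
#' such as per-case lobule areas. Thin wrapper over [stats::t.test()].
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need at least 2 values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    stop("both samples have zero variance; t statistic undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}
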