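#' Synthetic clumpy categorical raster
#'
#' Emulates a classified histology tile with controllable spatial
#' aggregation. An iid Gaussian noise field is smoothed with a separable
#' Gaussian kernel whose radius grows with `clumpiness`, then thresholded
#' at the class-weight quantiles, so marginal class proportions track
#' `class_weights` while spatial clumping tracks `clumpiness`.
#' `clumpiness = 0` gives iid labels. (A blur-and-threshold construction,
#' not the modified-random-clusters algorithm: simpler, deterministic and
#' sufficient for monotone metric behaviour.)
#'
#' @param shape integer vector `c(rows, cols)`, at least 8 x 8.
#' @param n_classes number of classes (codes `1..n_classes`).
#' @param clumpiness in `[0, 1]`; smoothing sd is
#'   `clumpiness * min(shape) / 8` pixels.
#' @param class_weights target class proportions (must sum to 1; default
#'   equal).
#' @param seed integer seed; identical configurations give identical
#'   rasters.
#' @param resolution pixel size passed to [categorical_raster()].
#' @return a [categorical_raster()].
#' @export
gen_clumpy_raster <- function(shape, n_classes = 3L, clumpiness = 0.5,
                              class_weights = NULL, seed = 1L,
                              resolution = 1.0) {
  shape <- as.integer(shape)
  if (any(shape < 8L)) stop("shape must be at least 8 x 8")
  if (clumpiness < 0 || clumpiness > 1) stop("clumpiness must be in [0, 1]")
  if (is.null(class_weights)) class_weights <- rep(1 / n_classes, n_classes)
  if (length(class_weights) != n_classes) {
    stop("class_weights must have one entry per class")
  }
  if (abs(sum(class_weights) - 1) > 1e-8) {
    stop("class_weights must sum to 1")
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  field <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  sigma <- clumpiness * min(shape) / 8
  if (sigma > 0) field <- .gauss_smooth(field, sigma)
  cuts <- stats::quantile(field, probs = cumsum(class_weights),
                          names = FALSE, type = 7)
  cuts[n_classes] <- Inf
  codes <- matrix(findInterval(field, c(-Inf, utils::head(cuts, -1)),
                               rightmost.closed = FALSE),
                  shape[1], shape[2])
  categorical_raster(codes, resolution = resolution)
}

# separable Gaussian smoothing with edge renormalisation
.gauss_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  smooth_1d <- function(nsize) {
    # banded convolution matrix with renormalised edge rows
    k <- matrix(0, nsize, nsize)
    for (off in -half:half) {
      idx <- seq_len(nsize)
      keep <- idx + off >= 1L & idx + off <= nsize
      k[cbind(idx[keep], idx[keep] + off)] <- kern[off + half + 1L]
    }
    k / rowSums(k)
  }
  kr <- smooth_1d(nrow(m))
  kc <- smooth_1d(ncol(m))
  kr %*% m %*% t(kc)
}

#' Synthetic point processes (CSR, clustered, inhibited)
#'
#' * `poisson`: homogeneous Poisson process — `N ~ Poisson(lambda |W|)`
#'   uniform points (the CSR null model).
#' * `matern_cluster`: Matern cluster process — Poisson parents of
#'   intensity `kappa` in the window dilated by `R`, each with
#'   `Poisson(mu)` offspring uniform in a disc of radius `R`, clipped to
#'   the window.
#' * `inhibition`: simple sequential inhibition — uniform proposals
#'   accepted only at hard-core distance `>= h` from all accepted points,
#'   until `n` points or the attempt budget is exhausted (then a partial
#'   pattern with a warning).
#'
#' @param kind `"poisson"`, `"matern_cluster"` or `"inhibition"`.
#' @param window a [pp_window()].
#' @param params named list: `lambda` (poisson); `kappa`, `mu`, `R`
#'   (matern_cluster); `n`, `h`, optionally `max_attempts` (inhibition).
#' @param seed integer seed.
#' @return a [point_pattern()].
#' @export
gen_point_process <- function(kind = c("poisson", "matern_cluster",
                                       "inhibition"),
                              window, params, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(window, "pp_window"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  sides <- window_sides(window)
  switch(kind,
    poisson = {
      lambda <- params$lambda
      if (is.null(lambda) || lambda <= 0) stop("poisson needs lambda > 0")
      n <- stats::rpois(1, lambda * window_area(window))
      .runif_pattern(n, window)
    },
    matern_cluster = {
      kappa <- params$kappa; mu <- params$mu; R <- params$R
      if (any(c(kappa, mu, R) <= 0)) stop("kappa, mu, R must be > 0")
      # parents in the R-dilated window so edge clusters are not lost
      dil <- pp_window(window$x_min - R, window$x_max + R,
                       window$y_min - R, window$y_max + R)
      np <- stats::rpois(1, kappa * window_area(dil))
      pxp <- stats::runif(np, dil$x_min, dil$x_max)
      pyp <- stats::runif(np, dil$y_min, dil$y_max)
      xs <- numeric(0); ys <- numeric(0)
      for (i in seq_len(np)) {
        m <- stats::rpois(1, mu)
        if (m == 0) next
        rr <- R * sqrt(stats::runif(m))
        th <- stats::runif(m, 0, 2 * pi)
        xs <- c(xs, pxp[i] + rr * cos(th))
        ys <- c(ys, pyp[i] + rr * sin(th))
      }
      keep <- xs >= window$x_min & xs <= window$x_max &
        ys >= window$y_min & ys <= window$y_max
      point_pattern(xs[keep], ys[keep], window)
    },
    inhibition = {
      n <- params$n; h <- params$h
      if (is.null(n) || is.null(h) || h <= 0) stop("inhibition needs n and h > 0")
      if (h >= min(sides)) stop("inhibition radius must be below the window scale")
      max_attempts <- params$max_attempts %||% (100L * n)
      xs <- numeric(0); ys <- numeric(0)
      attempts <- 0L
      while (length(xs) < n && attempts < max_attempts) {
        attempts <- attempts + 1L
        cx <- stats::runif(1, window$x_min, window$x_max)
        cy <- stats::runif(1, window$y_min, window$y_max)
        if (length(xs) == 0L ||
            min((xs - cx)^2 + (ys - cy)^2) >= h^2) {
          xs <- c(xs, cx); ys <- c(ys, cy)
        }
      }
      if (length(xs) < n) {
        warning(sprintf("inhibition reached %d of %d points within the attempt budget",
                        length(xs), n))
      }
      point_pattern(xs, ys, window)
    })
}

#' Synthetic jittered lobular lattice
#'
#' Emulates the classical hepatic microarchitecture: central veins on a
#' triangular lattice with spacing `s`, portal tracts at the vertices of
#' the corresponding hexagonal (honeycomb) cells — each vertex shared by
#' adjacent lobules and generated once — with iid Gaussian jitter of sd
#' `sigma` applied to every point. The construction's true lobule area,
#' `(3 sqrt(3) / 2) * (s / sqrt(3))^2 = (sqrt(3) / 2) s^2`, is returned
#' as ground truth.
#'
#' Central veins are kept only where their full vertex ring fits inside
#' the window, so with `sigma = 0` every central has its own 6 vertices
#' as exactly its 6 nearest portals. Jittered points falling outside the
#' window are dropped.
#'
#' @param window a [pp_window()].
#' @param spacing centre-to-centre lobule spacing `s` (must be below half
#'   the shorter window side).
#' @param jitter_sd jitter sd `sigma` (warns when `sigma >= s / 2`).
#' @param seed integer seed.
#' @return list with `centrals`, `portals` ([point_pattern()]s),
#'   `true_area`, `spacing`, `jitter_sd`.
#' @export
gen_lobular_lattice <- function(window, spacing, jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(window, "pp_window"))
  sides <- window_sides(window)
  if (spacing >= min(sides) / 2) {
    stop("spacing must be below half the shorter window side")
  }
  if (jitter_sd >= spacing / 2) {
    warning("jitter sd >= spacing / 2: lobule identity may overlap")
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  s <- spacing
  rv <- s / sqrt(3)                     # hexagon circumradius
  row_h <- s * sqrt(3) / 2
  rows <- seq(window$y_min - s, window$y_max + s, by = row_h)
  cx <- list(); cy <- list()
  for (k in seq_along(rows)) {
    off <- if (k %% 2 == 0) s / 2 else 0
    xs <- seq(window$x_min - s + off, window$x_max + s, by = s)
    cx[[k]] <- xs; cy[[k]] <- rep(rows[k], length(xs))
  }
  cx <- unlist(cx); cy <- unlist(cy)
  # vertices: 6 per central at circumradius, angles 30, 90, ..., 330 deg
  ang <- (seq(30, 330, by = 60)) * pi / 180
  vx <- as.vector(outer(rv * cos(ang), cx, "+"))
  vy <- as.vector(outer(rv * sin(ang), cy, "+"))
  vkey <- paste(round(vx, 6), round(vy, 6))
  dup <- duplicated(vkey)
  vx <- vx[!dup]; vy <- vy[!dup]

  # centrals whose vertex ring fits inside the window
  margin <- rv + 1e-9
  ck <- cx >= window$x_min + margin & cx <= window$x_max - margin &
    cy >= window$y_min + margin & cy <= window$y_max - margin
  cx <- cx[ck]; cy <- cy[ck]

  if (jitter_sd > 0) {
    cx <- cx + stats::rnorm(length(cx), sd = jitter_sd)
    cy <- cy + stats::rnorm(length(cy), sd = jitter_sd)
    vx <- vx + stats::rnorm(length(vx), sd = jitter_sd)
    vy <- vy + stats::rnorm(length(vy), sd = jitter_sd)
  }
  inw <- function(x, y) x >= window$x_min & x <= window$x_max &
    y >= window$y_min & y <= window$y_max
  keep_c <- inw(cx, cy); keep_v <- inw(vx, vy)
  list(centrals = point_pattern(cx[keep_c], cy[keep_c], window),
       portals = point_pattern(vx[keep_v], vy[keep_v], window),
       true_area = (3 * sqrt(3) / 2) * rv^2,
       spacing = spacing, jitter_sd = jitter_sd)
}

#' Synthetic bipolar scar field
#'
#' Emulates a pericentral scar: a circular vein ring at the origin and
#' MFB cells whose polar angles follow an axial bimodal mixture with
#' modes at `axis_deg` and `axis_deg + 180` (weights `w` and `1 - w`,
#' wrapped-normal components of concentration `kappa`, i.e. angular sd
#' `1 / sqrt(kappa)` radians; `kappa = 0` gives uniform angles) and whose
#' radial distances from the ring are `Exponential` with decay scale
#' `1 / radial_decay`. Ground truth (`axis_deg`, `w`, `kappa`,
#' `radial_decay`) is attached.
#'
#' @param n_cells number of MFB cells (at least 10).
#' @param vein_radius vein ring radius.
#' @param axis_deg planted dominant axis, degrees.
#' @param bipolar_concentration concentration `kappa >= 0`.
#' @param radial_decay exponential rate of distance from the ring.
#' @param w weight of the dominant mode (`>= 0.5`).
#' @param seed integer seed.
#' @param ring_vertices number of ring polyline vertices.
#' @return a [scar_field()] with attribute `truth`.
#' @export
gen_scar_field <- function(n_cells = 200L, vein_radius = 1,
                           axis_deg = 90, bipolar_concentration = 10,
                           radial_decay = 2, w = 0.7, seed = 1L,
                           ring_vertices = 120L) {
  if (n_cells < 10L) stop("n_cells must be at least 10")
  if (bipolar_concentration < 0) stop("concentration kappa must be >= 0")
  if (w < 0.5 || w > 1) stop("dominant-mode weight w must be in [0.5, 1]")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  th <- seq(0, 2 * pi, length.out = ring_vertices + 1L)[-(ring_vertices + 1L)]
  ring <- data.frame(x = vein_radius * cos(th), y = vein_radius * sin(th))
  if (bipolar_concentration == 0) {
    phi <- stats::runif(n_cells, 0, 360)
  } else {
    sd_deg <- (1 / sqrt(bipolar_concentration)) * 180 / pi
    mode <- ifelse(stats::runif(n_cells) < w, axis_deg, axis_deg + 180)
    phi <- (mode + stats::rnorm(n_cells, sd = sd_deg)) %% 360
  }
  d <- stats::rexp(n_cells, rate = radial_decay)
  rad <- vein_radius + d
  # generator works in mathematical orientation (y up); scar_field is
  # built with flip_y = FALSE accordingly
  mfb <- data.frame(x = rad * cos(phi * pi / 180),
                    y = rad * sin(phi * pi / 180))
  sf <- scar_field(mfb, ring, flip_y = FALSE)
  attr(sf, "truth") <- list(axis_deg = axis_deg, w = w,
                            kappa = bipolar_concentration,
                            radial_decay = radial_decay,
                            vein_radius = vein_radius)
  sf
}
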