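#' Patch-level landscape metrics
#'
#' Per-patch metrics of the "area and edge" and "aggregation" families:
#' area, perimeter, shape index and Euclidean nearest-neighbour distance.
#'
#' Perimeter counts raster cell edges on the patch boundary, including
#' edges against nodata and the image border, scaled by the resolution.
#' The shape index is the raster-adjusted `0.25 * perimeter / sqrt(area)`
#' (1 for a square patch). ENN is the shortest edge-to-edge distance
#' between pixel centres of the patch and the nearest other patch of the
#' same class; it is `NA` (undefined) when the class has a single patch.
#'
#' @param labeling a [label_patches()] result derived from `raster`.
#' @param raster the [categorical_raster()] the labeling was derived from.
#' @return data.frame with one row per patch: `patch_id`, `class`,
#'   `area`, `perimeter`, `shape_index`, `enn`.
#' @export
patch_metrics <- function(labeling, raster) {
  stopifnot(inherits(labeling, "patch_labeling"),
            inherits(raster, "categorical_raster"))
  ids <- labeling$patch_ids
  np <- length(labeling$patch_class)
  res <- raster$resolution

  area_px <- labeling$patch_size
  perim_px <- .patch_perimeters(ids, np)
  area <- area_px * res^2
  perim <- perim_px * res
  shape <- 0.25 * perim / sqrt(area)
  enn <- .patch_enn(ids, labeling$patch_class, res)

  data.frame(patch_id = seq_len(np), class = labeling$patch_class,
             area = area, perimeter = perim, shape_index = shape,
             enn = enn)
}

# boundary edge count per patch: 4 minus number of same-patch 4-neighbours
.patch_perimeters <- function(ids, np) {
  nr <- nrow(ids); nc <- ncol(ids)
  shared <- integer(np)  # same-patch interior edges, single count
  tally <- function(a, b) {
    same <- a > 0L & a == b
    if (any(same)) {
      t <- tabulate(a[same], nbins = np)
      shared <<- shared + t
    }
  }
  if (nc > 1L) tally(ids[, -nc], ids[, -1L])
  if (nr > 1L) tally(ids[-nr, ], ids[-1L, ])
  sizes <- tabulate(ids[ids > 0L], nbins = np)
  4L * sizes - 2L * shared
}

# nearest same-class other patch, edge-to-edge over boundary pixel centres
.patch_enn <- function(ids, patch_class, res) {
  np <- length(patch_class)
  enn <- rep(NA_real_, np)
  if (np < 2L) return(enn)
  nr <- nrow(ids); nc <- ncol(ids)
  # boundary pixels: at least one 4-neighbour (or border) outside the patch
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- ids
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  boundary <- core > 0L &
    (pad[1:nr, 2:(nc + 1L)] != core | pad[3:(nr + 2L), 2:(nc + 1L)] != core |
       pad[2:(nr + 1L), 1:nc] != core | pad[2:(nr + 1L), 3:(nc + 2L)] != core)
  which_b <- which(boundary)
  bid <- core[which_b]
  bx <- ((which_b - 1L) %/% nr + 1L) - 0.5   # col - 0.5
  by <- ((which_b - 1L) %% nr + 1L) - 0.5    # row - 0.5
  for (cl in unique(patch_class)) {
    patches <- which(patch_class == cl)
    if (length(patches) < 2L) next
    sel <- bid %in% patches
    px <- bx[sel]; py <- by[sel]; pid <- bid[sel]
    d <- .pairwise_dist(cbind(px, py))
    same <- outer(pid, pid, "==")
    d[same] <- Inf
    dmin <- apply(d, 1L, min)
    for (p in patches) enn[p] <- min(dmin[pid == p]) * res
  }
  enn
}

.pairwise_dist <- function(xy) {
  as.matrix(stats::dist(xy))
}

#' Class-level landscape metrics
#'
#' Per-class metrics of the "area and edge" and "aggregation" families:
#'
#' * `pland` — percentage of the landscape occupied by the class;
#' * `np` — number of patches; `pd` — patches per unit area;
#' * `lpi` — largest patch index (% of landscape in the largest patch);
#' * `te` — total edge involving the class (boundary edges of its pixels,
#'   including against nodata and the image border); `ed` — edge density;
#' * `area_mn` — mean patch area;
#' * `ai` — aggregation index, `100 * g_ii / max_g_ii`, where `g_ii` is the
#'   observed number of like adjacencies (single count) and `max_g_ii`
#'   follows the standard largest-integer-square construction. `NA` for a
#'   single-pixel class (no adjacency possible).
#'
#' @inheritParams patch_metrics
#' @return data.frame with one row per class present in the raster.
#' @export
class_metrics <- function(labeling, raster) {
  stopifnot(inherits(labeling, "patch_labeling"),
            inherits(raster, "categorical_raster"))
  v <- raster$values
  res <- raster$resolution
  classes <- raster_classes(raster)
  n_data <- sum(!is.na(v))
  total_area <- n_data * res^2
  adj <- adjacency_counts(raster)

  rows <- lapply(classes, function(cl) {
    in_cl <- !is.na(v) & v == cl
    a_px <- sum(in_cl)
    patches <- which(labeling$patch_class == cl)
    sizes <- labeling$patch_size[patches]
    gii <- adj[as.character(cl), as.character(cl)] / 2  # single count
    max_gii <- .max_like_adjacencies(a_px)
    # boundary edges of class-cl pixels: 4 per pixel minus shared like edges
    te_px <- 4L * a_px - 2L * gii
    data.frame(
      class = cl,
      pland = 100 * a_px / n_data,
      np = length(patches),
      pd = length(patches) / total_area,
      lpi = 100 * max(sizes) / n_data,
      te = te_px * res,
      ed = te_px * res / total_area,
      area_mn = mean(sizes) * res^2,
      ai = if (max_gii > 0) 100 * gii / max_gii else NA_real_
    )
  })
  do.call(rbind, rows)
}

# largest-integer-square construction for the maximum number of like
# adjacencies (single count) among A pixels
.max_like_adjacencies <- function(a_px) {
  n <- floor(sqrt(a_px))
  m <- a_px - n^2
  if (m == 0) {
    2 * n * (n - 1)
  } else if (m <= n) {
    2 * n * (n - 1) + 2 * m - 1
  } else {
    2 * n * (n - 1) + 2 * m - 2
  }
}

#' Landscape-level metrics
#'
#' Whole-landscape metrics of the "area and edge", "aggregation" and
#' "diversity" families: patch count `np`, total (inter-class) edge `te`
#' and edge density `ed`, mean patch area `area_mn`, largest patch index
#' `lpi`, Shannon diversity `shdi`, Shannon evenness `shei`, Simpson
#' diversity `sidi`, area-weighted aggregation index `ai`, and contagion
#' `contag` (FRAGSTATS adjacency-probability form).
#'
#' `te` counts interior 4-neighbour edges whose two pixels differ in class
#' (single count), scaled by resolution. `shei` and `contag` are undefined
#' (`NA`) for a single-class landscape.
#'
#' @inheritParams patch_metrics
#' @return one-row data.frame.
#' @export
landscape_level_metrics <- function(labeling, raster) {
  stopifnot(inherits(labeling, "patch_labeling"),
            inherits(raster, "categorical_raster"))
  v <- raster$values
  res <- raster$resolution
  n_data <- sum(!is.na(v))
  total_area <- n_data * res^2
  p <- as.numeric(class_proportions(raster))
  m <- length(p)
  adj <- adjacency_counts(raster)

  # inter-class interior edges, single count
  te_px <- (sum(adj) - sum(diag(adj))) / 2
  shdi <- -sum(p * log(p))
  shei <- if (m > 1) shdi / log(m) else NA_real_
  sidi <- 1 - sum(p^2)

  cm <- class_metrics(labeling, raster)
  w <- cm$pland / sum(cm$pland[!is.na(cm$ai)])
  ai <- if (all(is.na(cm$ai))) NA_real_ else
    sum(cm$ai * w, na.rm = TRUE)

  contag <- .contagion(adj, p)

  data.frame(
    np = length(labeling$patch_class),
    te = te_px * res,
    ed = te_px * res / total_area,
    area_mn = mean(labeling$patch_size) * res^2,
    lpi = 100 * max(labeling$patch_size) / n_data,
    shdi = shdi,
    shei = shei,
    sidi = sidi,
    ai = ai,
    contag = contag
  )
}

# FRAGSTATS contagion from the double-count adjacency matrix and class
# proportions; NA for single-class landscapes
.contagion <- function(adj, p) {
  m <- length(p)
  if (m < 2) return(NA_real_)
  g <- unclass(adj)
  rs <- rowSums(g)
  if (any(rs == 0)) return(NA_real_)
  q <- p * (g / rs)           # P_i * g_ik / sum_k g_ik
  q <- as.vector(q)
  q <- q[q > 0]
  100 * (1 + sum(q * log(q)) / (2 * log(m)))
}

#' Information-theoretic landscape complexity metrics
#'
#' The four holistic complexity measures of a categorical landscape,
#' computed in bits from the normalised 4-neighbour class co-occurrence
#' distribution `p(i, j)` and its marginals:
#'
#' * `marginal` — entropy H(x) of the row-marginal class distribution
#'   (thematic complexity);
#' * `joint` — entropy H(x, y) of the co-occurrence distribution (overall
#'   spatio-thematic complexity);
#' * `conditional` — H(y|x) = joint − marginal (configurational
#'   complexity);
#' * `mutual_information` — I(x, y) = marginal − conditional (aggregation
#'   of the landscape beyond what class abundances imply); and
#' * `relative_mutual_information` — I/H(x), in `[0, 1]`, `NA` when the
#'   marginal entropy is zero (single-class landscape).
#'
#' @param adjacency an [adjacency_counts()] matrix.
#' @return list with elements `marginal`, `conditional`, `joint`,
#'   `mutual_information`, `relative_mutual_information` (bits).
#' @export
complexity_metrics <- function(adjacency) {
  stopifnot(inherits(adjacency, "adjacency_counts"))
  g <- unclass(adjacency)
  total <- sum(g)
  if (total == 0) stop("degenerate landscape: no pixel adjacencies")
  pij <- g / total
  pi_ <- rowSums(pij)
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  marginal <- h(pi_)
  joint <- h(as.vector(pij))
  conditional <- joint - marginal
  mi <- marginal - conditional
  list(
    marginal = marginal,
    conditional = conditional,
    joint = joint,
    mutual_information = mi,
    relative_mutual_information =
      if (marginal > 0) mi / marginal else NA_real_
  )
}

#' Write metric tables as a tidy long CSV
#'
#' Serialises patch-, class- or landscape-level metric tables to the long
#' format `(case_id, level, id, metric, value)`, appending when the file
#' already holds tables from other images.
#'
#' @param table data.frame from [patch_metrics()], [class_metrics()] or
#'   [landscape_level_metrics()] (or a one-row data.frame of
#'   [complexity_metrics()] values).
#' @param level one of `"patch"`, `"class"`, `"landscape"`.
#' @param case_id identifier of the analysed image.
#' @param path output CSV path.
#' @param append append to an existing file (default `FALSE`).
#' @return the long-format data.frame, invisibly.
#' @export
write_metrics_csv <- function(table, level, case_id, path, append = FALSE) {
  level <- match.arg(level, c("patch", "class", "landscape"))
  id_col <- switch(level, patch = "patch_id", class = "class",
                   landscape = NULL)
  if (is.list(table) && !is.data.frame(table)) {
    table <- as.data.frame(table)
  }
  ids <- if (!is.null(id_col) && id_col %in% names(table)) {
    table[[id_col]]
  } else rep(1L, nrow(table))
  metric_cols <- setdiff(names(table), c("patch_id", "class"))
  long <- do.call(rbind, lapply(metric_cols, function(mc) {
    data.frame(case_id = case_id, level = level, id = ids, metric = mc,
               value = as.numeric(table[[mc]]))
  }))
  utils::write.table(long, path, sep = ",", row.names = FALSE,
                     col.names = !append || !file.exists(path),
                     append = append && file.exists(path), qmethod = "double")
  invisible(long)
}
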