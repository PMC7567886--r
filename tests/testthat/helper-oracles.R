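# Independent brute-force oracles: naive enumeration implementations kept
# deliberately separate from the package internals.

# flood-fill patch labelling by pixel-at-a-time queue
oracle_label_patches <- function(values, connectivity = 8) {
  nr <- nrow(values); nc <- ncol(values)
  ids <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, ]
  }
  next_id <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (is.na(values[r0, c0]) || ids[r0, c0] != 0L) next
    next_id <- next_id + 1L
    queue <- list(c(r0, c0))
    ids[r0, c0] <- next_id
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        rr <- cur[1] + nbrs[k, 1]; cc <- cur[2] + nbrs[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !is.na(values[rr, cc]) && ids[rr, cc] == 0L &&
            values[rr, cc] == values[cur[1], cur[2]]) {
          ids[rr, cc] <- next_id
          queue <- c(queue, list(c(rr, cc)))
        }
      }
    }
  }
  ids
}

# ordered 4-neighbour class pair counts by explicit loop
oracle_adjacency <- function(values) {
  classes <- sort(unique(as.vector(values[!is.na(values)])))
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  nr <- nrow(values); nc <- ncol(values)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(values[r, c])) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          !is.na(values[rr, cc])) {
        i <- as.character(values[r, c]); j <- as.character(values[rr, cc])
        m[i, j] <- m[i, j] + 1L
      }
    }
  }
  m
}

# per-patch area/perimeter by pixel loops
oracle_patch_table <- function(values, connectivity = 8) {
  ids <- oracle_label_patches(values, connectivity)
  np <- max(ids)
  nr <- nrow(values); nc <- ncol(values)
  area <- integer(np); perim <- integer(np)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    id <- ids[r, c]
    if (id == 0L) next
    area[id] <- area[id] + 1L
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      outside <- rr < 1 || rr > nr || cc < 1 || cc > nc || ids[rr, cc] != id
      if (outside) perim[id] <- perim[id] + 1L
    }
  }
  list(ids = ids, area = area, perimeter = perim)
}

# entropies by direct summation over the co-occurrence table
oracle_complexity <- function(values) {
  adj <- oracle_adjacency(values)
  p <- adj / sum(adj)
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  marginal <- h(rowSums(p))
  joint <- h(as.vector(p))
  list(marginal = marginal, joint = joint,
       conditional = joint - marginal,
       mutual_information = 2 * marginal - joint)
}

# uncorrected Ripley K by explicit double loop over ordered pairs
oracle_k_uncorrected <- function(x, y, area, r_grid) {
  n <- length(x)
  vapply(r_grid, function(r) {
    count <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= r) {
        count <- count + 1
      }
    }
    area * count / (n * (n - 1))
  }, numeric(1))
}

# small random raster fixture
random_raster <- function(nr, nc, n_classes, seed) {
  set.seed(seed)
  categorical_raster(matrix(sample.int(n_classes, nr * nc, replace = TRUE),
                            nr, nc))
}
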