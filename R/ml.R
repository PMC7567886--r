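#' Assemble landscape-metric features for one classified image
#'
#' Computes the landscape-level, class-level ("aggregation" and "area and
#' edge" families) and complexity metrics of a raster and flattens them
#' into a single feature row for case-level machine learning. Undefined
#' metrics (e.g. evenness of a single-class landscape) propagate as `NA`
#' and are handled by [filter_features()].
#'
#' @param raster a [categorical_raster()].
#' @param case_id case identifier.
#' @param label optional diagnosis label for the row.
#' @param connectivity patch connectivity (default 8).
#' @return one-row data.frame: `case_id`, optional `label`, and named
#'   numeric features (`ls_*` landscape level, `cl<code>_*` class level,
#'   `cx_*` complexity).
#' @export
landscape_features <- function(raster, case_id, label = NULL,
                               connectivity = 8) {
  lab <- label_patches(raster, connectivity)
  ls <- landscape_level_metrics(lab, raster)
  cl <- class_metrics(lab, raster)
  cx <- complexity_metrics(adjacency_counts(raster))
  row <- data.frame(case_id = case_id)
  if (!is.null(label)) row$label <- label
  for (nm in names(ls)) row[[paste0("ls_", nm)]] <- ls[[nm]]
  for (i in seq_len(nrow(cl))) {
    for (nm in setdiff(names(cl), "class")) {
      row[[paste0("cl", cl$class[i], "_", nm)]] <- cl[[nm]][i]
    }
  }
  for (nm in names(cx)) row[[paste0("cx_", nm)]] <- cx[[nm]]
  row
}

#' Split cases into training and test sets
#'
#' Random split by `case_id` so paired regions (e.g. lesional and
#' non-lesional rows of one case) never straddle the split, stratified by
#' the case-level label profile.
#'
#' @param table feature data.frame with columns `case_id` and `label`.
#' @param train_fraction fraction of cases assigned to training (default
#'   0.8).
#' @param rng_seed integer seed; identical seeds give identical splits.
#' @return list with `train` and `test` data.frames (disjoint case ids).
#' @export
split_cases <- function(table, train_fraction = 0.8, rng_seed = 1L) {
  stopifnot(all(c("case_id", "label") %in% names(table)))
  cases <- unique(table$case_id)
  profile <- vapply(cases, function(cid) {
    paste(sort(unique(table$label[table$case_id == cid])), collapse = "+")
  }, character(1))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(rng_seed))
  train_cases <- character(0)
  for (pr in unique(profile)) {
    grp <- cases[profile == pr]
    n_train <- round(train_fraction * length(grp))
    train_cases <- c(train_cases, as.character(sample(grp, n_train)))
  }
  train <- table[as.character(table$case_id) %in% train_cases, , drop = FALSE]
  test <- table[!as.character(table$case_id) %in% train_cases, , drop = FALSE]
  for (side in list(train, test)) {
    if (!all(unique(table$label) %in% side$label)) {
      stop("a label class is absent from one side of the split; ",
           "adjust train_fraction or add cases")
    }
  }
  list(train = train, test = test)
}

#' Fit the feature filter and normalising transform on training data
#'
#' The three-step feature pipeline, fitted on training rows only:
#'
#' 1. drop features that are `NA` anywhere or near-zero variance
#'    (frequency ratio of the two most common values > 19 and unique-value
#'    fraction < 10%, via [caret::nearZeroVar()]);
#' 2. per-feature rank-based inverse-normal transform (mapping training
#'    ranks to normal scores; applied to new data by interpolation of the
#'    fitted mapping, never refitted);
#' 3. greedy correlation filter dropping one member of every pair with
#'    `|r| > 0.75` (the member with the larger mean absolute correlation,
#'    via [caret::findCorrelation()]; ties broken by column order).
#'
#' @param train_table data.frame with `case_id`, optional `label`, and
#'   numeric features.
#' @param cor_cutoff correlation threshold (default 0.75).
#' @return list with `table` (filtered, transformed training data) and
#'   `transform` (a `feature_transform` to apply to new data).
#' @export
filter_features <- function(train_table, cor_cutoff = 0.75) {
  meta_cols <- intersect(c("case_id", "label"), names(train_table))
  feats <- setdiff(names(train_table), meta_cols)
  x <- train_table[, feats, drop = FALSE]
  # step 0/1: undefined metrics and near-zero variance
  keep <- vapply(x, function(col) is.numeric(col) && !anyNA(col), logical(1))
  x <- x[, keep, drop = FALSE]
  if (ncol(x) > 0) {
    nzv <- caret::nearZeroVar(x, freqCut = 19, uniqueCut = 10)
    if (length(nzv) > 0) x <- x[, -nzv, drop = FALSE]
  }
  if (ncol(x) == 0) stop("all features removed by the variance filter")
  # step 2: rank-based inverse-normal transform fitted on train
  maps <- lapply(x, function(col) {
    n <- length(col)
    sorted <- sort(col)
    scores <- stats::qnorm((seq_len(n) - 0.5) / n)
    list(sorted = sorted, scores = scores)
  })
  xt <- as.data.frame(Map(.apply_int_map, x, maps))
  # step 3: correlation filter on the transformed features
  if (ncol(xt) > 1) {
    cm <- stats::cor(as.matrix(xt))
    drop_idx <- caret::findCorrelation(cm, cutoff = cor_cutoff, exact = FALSE)
    if (length(drop_idx) > 0) xt <- xt[, -drop_idx, drop = FALSE]
  }
  if (ncol(xt) == 0) stop("all features removed by the correlation filter")
  transform <- structure(list(features = names(xt),
                              maps = maps[names(xt)],
                              cor_cutoff = cor_cutoff),
                         class = "feature_transform")
  out <- cbind(train_table[, meta_cols, drop = FALSE], xt)
  list(table = out, transform = transform)
}

.apply_int_map <- function(col, map) {
  # monotone interpolation of the fitted rank -> normal-score mapping;
  # values beyond the training range take the extreme scores
  stats::approx(map$sorted, map$scores, xout = col, rule = 2,
                ties = "ordered")$y
}

#' Apply a fitted feature transform to new data
#'
#' Reapplies (never refits) the transform from [filter_features()]:
#' selects the retained features and maps each through the training
#' inverse-normal mapping.
#'
#' @param transform a `feature_transform`.
#' @param table data.frame containing at least the transform's features.
#' @return data.frame with meta columns plus transformed features.
#' @export
apply_feature_filter <- function(transform, table) {
  stopifnot(inherits(transform, "feature_transform"))
  missing <- setdiff(transform$features, names(table))
  if (length(missing) > 0) {
    stop("table lacks features: ", paste(missing, collapse = ", "))
  }
  meta_cols <- intersect(c("case_id", "label"), names(table))
  xt <- as.data.frame(Map(.apply_int_map,
                          table[, transform$features, drop = FALSE],
                          transform$maps))
  cbind(table[, meta_cols, drop = FALSE], xt)
}

#' Train a random-forest diagnostic classifier
#'
#' Bagged decision-tree ensemble (`sqrt(p)` candidate features per split)
#' over a filtered feature table with a binary label, retaining per-tree
#' structures and in-bag records for variable-importance introspection.
#' The conventional forest size is 10,000 trees; tests and examples use
#' fewer for speed.
#'
#' @param train_table filtered data.frame with `label` plus numeric
#'   features (a `case_id` column is ignored for fitting).
#' @param n_trees number of trees (default 10000).
#' @param rng_seed integer seed; identical seed and data give an
#'   identical forest.
#' @return object of class `forest_model`: list with the fitted
#'   [randomForest::randomForest] (`fit`), `features`, `positive` (the
#'   second factor level, treated as the positive class).
#' @export
train_forest <- function(train_table, n_trees = 10000L, rng_seed = 1L) {
  stopifnot("label" %in% names(train_table))
  y <- factor(train_table$label)
  if (nlevels(y) != 2L) stop("label must have exactly 2 classes")
  feats <- setdiff(names(train_table), c("case_id", "label"))
  x <- as.matrix(train_table[, feats, drop = FALSE])
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(rng_seed))
  fit <- randomForest::randomForest(
    x = x, y = y, ntree = as.integer(n_trees),
    importance = TRUE, keep.forest = TRUE, keep.inbag = TRUE)
  structure(list(fit = fit, features = feats, positive = levels(y)[2L],
                 n_trees = as.integer(n_trees)),
            class = "forest_model")
}

#' Evaluate a forest on held-out cases
#'
#' Sweeps the predicted positive-class probability over thresholds to
#' build the ROC table, computes AUC by the trapezoid rule over all
#' distinct thresholds, and reports F1 per threshold and the
#' F1-maximising threshold.
#'
#' @param model a [train_forest()] model.
#' @param test_table data.frame with `label` and the model's features
#'   (must be disjoint from training cases).
#' @return object of class `eval_report`: list with `roc` (data.frame
#'   `threshold`, `tpr`, `fpr`, `f1`), `auc` (`NA` when the test labels
#'   are single-class), `best_threshold`, `max_f1`, `prob`.
#' @export
evaluate <- function(model, test_table) {
  stopifnot(inherits(model, "forest_model"),
            "label" %in% names(test_table))
  x <- as.matrix(test_table[, model$features, drop = FALSE])
  prob <- stats::predict(model$fit, x, type = "prob")[, model$positive]
  truth <- factor(test_table$label,
                  levels = levels(model$fit$y))
  pos <- truth == model$positive
  if (length(unique(pos)) < 2L) {
    warning("single-class test labels: AUC undefined")
    return(structure(list(roc = NULL, auc = NA_real_,
                          best_threshold = NA_real_, max_f1 = NA_real_,
                          prob = prob),
                     class = "eval_report"))
  }
  thresholds <- sort(unique(c(0, prob, 1)))
  roc <- do.call(rbind, lapply(thresholds, function(th) {
    pred <- prob >= th
    tp <- sum(pred & pos); fp <- sum(pred & !pos)
    fn <- sum(!pred & pos)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- tp / (tp + fn)
    f1 <- if (!is.na(prec) && prec + rec > 0) 2 * prec * rec / (prec + rec)
      else 0
    data.frame(threshold = th, tpr = rec, fpr = fp / sum(!pos), f1 = f1)
  }))
  fx <- c(roc$fpr, 0, 1); fy <- c(roc$tpr, 0, 1)
  o <- order(fx, fy)
  auc <- .trapz(fx[o], fy[o])
  best <- which.max(roc$f1)
  structure(list(roc = roc, auc = auc,
                 best_threshold = roc$threshold[best],
                 max_f1 = roc$f1[best], prob = prob),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("forest evaluation: AUC = %.3f, max F1 = %.3f at threshold %.2f\n",
              x$auc, x$max_f1, x$best_threshold))
  invisible(x)
}

#' Variable importance of a trained forest
#'
#' Per-feature importance measures assembled from the forest internals:
#'
#' * `accuracy_decrease` — mean decrease of out-of-bag prediction
#'   accuracy when the feature is permuted;
#' * `gini_decrease` — total decrease in Gini node impurity from splits
#'   on the feature;
#' * `mean_min_depth` — mean, over trees, of the minimal depth at which
#'   the feature splits (root = 0); trees not using the feature
#'   contribute that tree's maximal depth + 1;
#' * `n_nodes` — number of split nodes using the feature; `n_root` —
#'   number of trees whose root splits on it;
#' * `p_value_nodes` — one-sided binomial p-value for `n_nodes` against
#'   uniform-random split-variable choice (an approximation: the null
#'   ignores the per-split candidate subsampling).
#'
#' @param model a [train_forest()] model.
#' @param pairwise if `TRUE`, also return the simplified pairwise
#'   interaction table: counts of parent-child split co-occurrence of
#'   feature pairs within trees.
#' @return data.frame with one row per feature (and attribute
#'   `pairwise` when requested), sorted by `mean_min_depth`.
#' @export
variable_importance <- function(model, pairwise = FALSE) {
  stopifnot(inherits(model, "forest_model"))
  imp <- randomForest::importance(model$fit)
  feats <- model$features
  p <- length(feats)
  n_nodes <- integer(p); n_root <- integer(p)
  depth_sum <- numeric(p); names(depth_sum) <- feats
  pair_counts <- new.env(parent = emptyenv())
  total_splits <- 0L
  ntree <- model$fit$ntree
  for (k in seq_len(ntree)) {
    tr <- randomForest::getTree(model$fit, k, labelVar = FALSE)
    split_var <- tr[, "split var"]
    is_split <- split_var > 0L
    total_splits <- total_splits + sum(is_split)
    n_nodes <- n_nodes + tabulate(split_var[is_split], nbins = p)
    if (is_split[1L]) {
      n_root[split_var[1L]] <- n_root[split_var[1L]] + 1L
    }
    # node depths by walking daughters from the root
    depth <- rep(NA_real_, nrow(tr))
    depth[1L] <- 0
    for (nd in seq_len(nrow(tr))) {
      if (is_split[nd]) {
        depth[tr[nd, "left daughter"]] <- depth[nd] + 1
        depth[tr[nd, "right daughter"]] <- depth[nd] + 1
      }
    }
    max_depth <- max(depth, na.rm = TRUE)
    mind <- tapply(depth[is_split], split_var[is_split], min)
    tree_min <- rep(max_depth + 1, p)
    tree_min[as.integer(names(mind))] <- mind
    depth_sum <- depth_sum + tree_min
    if (pairwise) {
      for (nd in which(is_split)) {
        for (dght in tr[nd, c("left daughter", "right daughter")]) {
          if (dght > 0L && is_split[dght]) {
            key <- paste(feats[split_var[nd]], feats[split_var[dght]],
                         sep = ">")
            pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
          }
        }
      }
    }
  }
  p_nodes <- stats::pbinom(n_nodes - 1L, total_splits, 1 / p,
                           lower.tail = FALSE)
  out <- data.frame(
    feature = feats,
    accuracy_decrease = imp[feats, "MeanDecreaseAccuracy"],
    gini_decrease = imp[feats, "MeanDecreaseGini"],
    mean_min_depth = depth_sum / ntree,
    n_nodes = n_nodes,
    n_root = n_root,
    p_value_nodes = p_nodes,
    row.names = NULL)
  out <- out[order(out$mean_min_depth), ]
  if (pairwise) {
    keys <- ls(pair_counts)
    pw <- if (length(keys) > 0) {
      parts <- strsplit(keys, ">", fixed = TRUE)
      pw <- data.frame(parent = vapply(parts, `[`, "", 1L),
                       child = vapply(parts, `[`, "", 2L),
                       count = vapply(keys, function(k) pair_counts[[k]],
                                      integer(1)),
                       row.names = NULL)
      pw[order(-pw$count), ]
    } else NULL
    attr(out, "pairwise") <- pw
  }
  out
}

#' k-means clustering of cases
#'
#' Standardises the features and runs Lloyd's k-means with multiple
#' restarts (unsupervised segregation of cases by diagnosis, typically
#' with `k = 2`).
#'
#' @param feature_table data.frame with `case_id` and numeric features
#'   (a `label` column, if present, is excluded from clustering).
#' @param k number of clusters (`k <=` number of cases).
#' @param rng_seed integer seed.
#' @param n_start number of random restarts (default 10).
#' @return list with `assignments` (named by case_id), `centers`,
#'   `within_ss` (total within-cluster sum of squares).
#' @export
kmeans_cases <- function(feature_table, k = 2L, rng_seed = 1L,
                         n_start = 10L) {
  feats <- setdiff(names(feature_table), c("case_id", "label"))
  x <- as.matrix(feature_table[, feats, drop = FALSE])
  if (k > nrow(x)) stop("k must not exceed the number of cases")
  sds <- apply(x, 2L, stats::sd)
  x <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(rng_seed))
  km <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_start, iter.max = 100L,
                  algorithm = "Lloyd"))
  assignments <- km$cluster
  if ("case_id" %in% names(feature_table)) {
    names(assignments) <- feature_table$case_id
  }
  list(assignments = assignments, centers = km$centers,
       within_ss = km$tot.withinss)
}
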