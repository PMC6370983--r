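# Stratified 3-fold CV and the semi-exhaustive feature-subset search ranked
# by mean CV AUC.

#' Stratified k-fold assignment
#'
#' Within each class, samples are shuffled by a seeded generator and dealt
#' round-robin to folds, so per-fold class counts differ by at most one.
#' Deterministic given (label order, seed); the caller's RNG state is left
#' untouched.
#'
#' @param labels 0/1 (or small integer) class labels.
#' @param n_folds number of folds (default 3).
#' @param seed integer seed.
#' @return A `fold_assignment` list with `fold` (0-based fold index per
#'   sample), `n_folds` and `seed`.
#' @export
stratified_kfold <- function(labels, n_folds = 3L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop_named("stratified_kfold: n_folds must be >= 2")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds) {
        stop_named("stratified_kfold: class '%s' has %d samples, fewer than %d folds",
                   cl, length(idx), n_folds)
      }
      perm <- idx[sample.int(length(idx))]
      fold[perm] <- rep_len(0:(n_folds - 1L), length(perm))
    }
  })
  structure(list(fold = fold, n_folds = n_folds, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Number of feature subsets of sizes min_size..max_size
#'
#' The closed-form binomial sum `sum(choose(p, m))` for `m` in
#' `min_size..max_size`, evaluated in exact integer arithmetic.
#'
#' @param p pool size; `min_size`, `max_size` the size range.
#' @param min_size,max_size subset size bounds.
#' @return The exact count as a double (integer-valued).
#' @export
count_subsets <- function(p, min_size = 1L, max_size = 5L) {
  if (min_size < 1L || max_size < min_size || max_size > p) {
    stop_named("count_subsets: need 1 <= min_size <= max_size <= p")
  }
  sum(choose(p, min_size:max_size))
}

#' Enumerate feature subsets
#'
#' All sorted index subsets of sizes `min_size..max_size` of `1..p`, emitted
#' in size order then lexicographic order within size, each exactly once.
#' Intended for small pools; the search itself enumerates per size
#' internally.
#'
#' @inheritParams count_subsets
#' @return List of integer vectors.
#' @export
enumerate_subsets <- function(p, min_size = 1L, max_size = 5L) {
  count_subsets(p, min_size, max_size)  # validates bounds
  out <- list()
  for (m in min_size:max_size) {
    cm <- utils::combn(p, m)
    out <- c(out, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
  }
  out
}

# Per-fold normalized design matrices: normalization is fit on the training
# rows of each fold and applied to all rows, so test rows never influence
# the fit (no leakage).
fold_views <- function(X, folds) {
  lapply(0:(folds$n_folds - 1L), function(f) {
    te <- which(folds$fold == f)
    tr <- which(folds$fold != f)
    params <- fit_normalization(X[tr, , drop = FALSE])
    list(Xn = apply_normalization(X, params), train = tr, test = te)
  })
}

#' Evaluate one feature subset by stratified cross-validation
#'
#' For each fold: fit per-feature normalization on the training rows, score
#' the held-out rows with the correlation-distance KNN, and compute the fold
#' ROC AUC plus threshold metrics. The mean over folds is the ranking
#' quantity of the search.
#'
#' @param X numeric feature matrix (rows = lesions, columns = the 38 panel
#'   features).
#' @param y integer 0/1 task labels.
#' @param subset integer feature column indices (1-based, panel order).
#' @param folds a [stratified_kfold()] assignment.
#' @param cfg a [knn_config()].
#' @return A `subset_result` list: `subset`, `fold_auc`, `mean_auc`,
#'   `accuracy`, `sensitivity`, `specificity` (fold means).
#' @export
evaluate_subset <- function(X, y, subset, folds, cfg = knn_config()) {
  X <- as.matrix(X)
  subset <- sort(unique(as.integer(subset)))
  if (any(subset < 1L) || any(subset > ncol(X))) {
    stop_named("evaluate_subset: subset indices outside 1..%d", ncol(X))
  }
  views <- fold_views(X[, subset, drop = FALSE],
                      folds)
  per_fold <- lapply(views, function(v) {
    if (length(unique(y[v$test])) < 2L) {
      stop_named("evaluate_subset: fold has single-class test labels; AUC undefined")
    }
    sc <- knn_scores(v$Xn[v$train, , drop = FALSE], y[v$train],
                     v$Xn[v$test, , drop = FALSE], k = cfg$k)
    evaluate_scores(sc, y[v$test], cfg$threshold)
  })
  agg <- mean_over_folds(per_fold)
  structure(list(subset = subset,
                 fold_auc = vapply(per_fold, `[[`, 0, "auc"),
                 mean_auc = agg$auc,
                 accuracy = agg$accuracy,
                 sensitivity = agg$sensitivity,
                 specificity = agg$specificity),
            class = "subset_result")
}

#' Semi-exhaustive feature-subset search
#'
#' Evaluates every subset of sizes `min_size..max_size` of the feature pool
#' by mean CV AUC and ranks them descending; ties are broken by smaller
#' subset size, then lexicographic subset order, so the ranking is a total
#' order independent of evaluation order. The default engine is a compiled
#' kernel; `engine = "r"` runs the pure-R reference route.
#'
#' @param X feature matrix; `y` 0/1 task labels.
#' @param y integer 0/1 task labels.
#' @param folds a [stratified_kfold()] assignment (one fixed assignment is
#'   reused across all subsets).
#' @param min_size,max_size subset size range (defaults 1 and 5).
#' @param cfg a [knn_config()].
#' @param top_n number of top-ranked subsets returned with full metrics.
#' @param engine `"cpp"` (compiled) or `"r"` (reference implementation).
#' @param progress print per-size progress lines.
#' @return A `search_result` list: `ranked` (data.frame of the top
#'   subsets), `n_evaluated`, `min_size`, `max_size`, `seed`.
#' @export
semi_exhaustive_search <- function(X, y, folds, min_size = 1L, max_size = 5L,
                                   cfg = knn_config(), top_n = 100L,
                                   engine = c("cpp", "r"), progress = FALSE) {
  engine <- match.arg(engine)
  X <- as.matrix(X)
  p <- ncol(X)
  n_total <- count_subsets(p, min_size, max_size)
  views <- fold_views(X, folds)
  if (length(unique(folds$fold)) != folds$n_folds) {
    stop_named("semi_exhaustive_search: empty fold in assignment")
  }

  sizes <- min_size:max_size
  best <- list()  # per size: mean AUC vector + combn matrix kept lazily
  all_mean <- vector("list", length(sizes))
  combs <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    m <- sizes[si]
    cm <- utils::combn(p, m)
    combs[[si]] <- cm
    if (engine == "cpp") {
      aucs <- eval_subsets_cpp(
        lapply(views, function(v) list(Xn = v$Xn,
                                       train = v$train - 1L,
                                       test = v$test - 1L)),
        as.integer(y), cm - 1L, cfg$k)
      all_mean[[si]] <- rowMeans(aucs)
    } else {
      all_mean[[si]] <- vapply(seq_len(ncol(cm)), function(j) {
        evaluate_subset(X, y, cm[, j], folds, cfg)$mean_auc
      }, 0)
    }
    if (progress) {
      message(sprintf("  size %d: %d subsets evaluated", m, ncol(cm)))
    }
  }

  # Global ranking key: (-mean AUC, size, lexicographic index within size).
  key_size <- rep(sizes, vapply(all_mean, length, 0L))
  key_idx <- unlist(lapply(all_mean, seq_along))
  key_auc <- unlist(all_mean)
  ord <- order(-key_auc, key_size, key_idx)
  keep <- ord[seq_len(min(top_n, length(ord)))]

  col_names <- colnames(X) %||% paste0("f", seq_len(p))
  rows <- lapply(seq_along(keep), function(r) {
    gi <- keep[r]
    si <- match(key_size[gi], sizes)
    sub <- combs[[si]][, key_idx[gi]]
    res <- evaluate_subset(X, y, sub, folds, cfg)
    data.frame(rank = r,
               subset_indices = paste(sub, collapse = "+"),
               subset_names = paste(col_names[sub], collapse = "+"),
               size = length(sub),
               mean_auc = res$mean_auc,
               fold1_auc = res$fold_auc[1],
               fold2_auc = res$fold_auc[2],
               fold3_auc = if (length(res$fold_auc) >= 3) res$fold_auc[3] else NA_real_,
               accuracy = res$accuracy,
               sensitivity = res$sensitivity,
               specificity = res$specificity,
               stringsAsFactors = FALSE)
  })
  ranked <- do.call(rbind, rows)
  ranked$subset <- lapply(keep, function(gi) {
    si <- match(key_size[gi], sizes)
    combs[[si]][, key_idx[gi]]
  })
  structure(list(ranked = ranked, n_evaluated = n_total,
                 min_size = min_size, max_size = max_size,
                 seed = folds$seed, k = cfg$k),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search: %s subsets (sizes %d-%d), best mean AUC %.3f [%s]>\n",
              format(x$n_evaluated, big.mark = ","), x$min_size, x$max_size,
              x$ranked$mean_auc[1], x$ranked$subset_names[1]))
  invisible(x)
}

#' Zone-level analysis: one search per one-vs-rest task
#'
#' Filters the feature table to the zone (PZ uses the DWI-derived lesions;
#' TZAFS pools TZ and AFS lesions, which are graded alike), then runs the
#' semi-exhaustive search for each of the five Grade Group tasks with one
#' seeded fold assignment per task.
#'
#' @param features feature table from [cohort_features()] (columns
#'   `patient_id, lesion_id, zone, gg` + the 38 panel features).
#' @param zone `"PZ"` or `"TZAFS"`.
#' @param cfg named list of search settings: `min_size`, `max_size`,
#'   `n_folds`, `k`, `threshold`, `top_n`, `seed`, `engine`, plus optional
#'   `feature_pool` (integer panel indices restricting the searched pool).
#' @return A `zone_analysis` list with per-task `search_result`s and a
#'   `summary` data.frame of best subsets.
#' @export
run_zone_analysis <- function(features, zone = c("PZ", "TZAFS"), cfg = list()) {
  zone <- match.arg(zone)
  rows <- if (zone == "PZ") features$zone == "PZ" else features$zone %in% c("TZ", "AFS")
  if (!any(rows)) stop_named("run_zone_analysis: no lesions in zone %s", zone)
  df <- features[rows, , drop = FALSE]
  pool <- sort(unique(cfg$feature_pool %||% seq_len(38L)))
  X <- as.matrix(df[, feature_names()[pool], drop = FALSE])
  knn <- knn_config(cfg$k %||% 5L, cfg$threshold %||% 0.5)
  n_folds <- cfg$n_folds %||% 3L
  seed <- cfg$seed %||% 17L
  max_size <- min(cfg$max_size %||% 5L, length(pool))
  min_size <- cfg$min_size %||% 1L

  tasks <- binary_tasks()
  results <- list()
  for (ti in seq_along(tasks)) {
    task <- tasks[[ti]]
    y <- task_labels(task, df$gg)
    folds <- stratified_kfold(y, n_folds = n_folds,
                              seed = derive_seed(seed, ti))
    res <- semi_exhaustive_search(
      X, y, folds, min_size = min_size, max_size = max_size,
      cfg = knn, top_n = cfg$top_n %||% 100L,
      engine = cfg$engine %||% "cpp",
      progress = isTRUE(cfg$progress))
    # report subsets in 38-panel indexing even when the pool is restricted
    res$ranked$subset <- lapply(res$ranked$subset, function(s) pool[s])
    res$ranked$subset_indices <- vapply(res$ranked$subset, paste, "",
                                        collapse = "+")
    results[[task$name]] <- res
  }
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    top <- results[[nm]]$ranked[1, ]
    data.frame(zone = zone, task = nm,
               best_subset = top$subset_indices,
               best_subset_names = top$subset_names,
               mean_auc = top$mean_auc, accuracy = top$accuracy,
               sensitivity = top$sensitivity, specificity = top$specificity,
               n_pos = sum(task_labels(nm, df$gg)),
               n = nrow(df), stringsAsFactors = FALSE)
  }))
  structure(list(zone = zone, results = results, summary = summary,
                 n_lesions = nrow(df)),
            class = "zone_analysis")
}
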