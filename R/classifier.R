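# Binary KNN with per-feature z-score normalization and correlation
# distance; one-vs-rest assembly over the five Grade Group tasks.

#' The five one-vs-rest Grade Group tasks
#'
#' GG1, GG2, GG1+2, GG3 and GG4+5 versus the remaining groups, in that
#' declared order (also the tie-break order for [ovr_assign()]).
#'
#' @return Named list of tasks, each with `name` and `positive_groups`.
#' @export
binary_tasks <- function() {
  list(
    GG1_vs_rest  = list(name = "GG1_vs_rest",  positive_groups = 1L),
    GG2_vs_rest  = list(name = "GG2_vs_rest",  positive_groups = 2L),
    GG12_vs_rest = list(name = "GG12_vs_rest", positive_groups = c(1L, 2L)),
    GG3_vs_rest  = list(name = "GG3_vs_rest",  positive_groups = 3L),
    GG45_vs_rest = list(name = "GG45_vs_rest", positive_groups = c(4L, 5L))
  )
}

#' Binary labels for a task
#'
#' @param task one element of [binary_tasks()] or its name.
#' @param gg integer vector of Grade Groups (1..5).
#' @return Integer 0/1 vector (1 = positive group).
#' @export
task_labels <- function(task, gg) {
  if (is.character(task)) task <- binary_tasks()[[task]]
  if (is.null(task)) stop_named("task_labels: unknown task")
  as.integer(gg %in% task$positive_groups)
}

#' KNN configuration
#'
#' @param k number of neighbours (default 5).
#' @param threshold score threshold for the binary operating point
#'   (default 0.5; `score >= threshold` is called positive).
#' @return A `knn_config` list.
#' @export
knn_config <- function(k = 5L, threshold = 0.5) {
  k <- as.integer(k)
  if (k < 1L) stop_named("knn_config: k must be >= 1")
  if (threshold < 0 || threshold > 1) stop_named("knn_config: threshold must lie in [0, 1]")
  structure(list(k = k, threshold = threshold), class = "knn_config")
}

#' Fit per-feature z-score normalization on training rows
#'
#' Population (1/N) standard deviations; a constant column gets sd 0 and is
#' mapped to all-zero by [apply_normalization()].
#'
#' @param train numeric training matrix (rows = samples).
#' @return List with `mean` and `sd` per column.
#' @export
fit_normalization <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stop_named("fit_normalization: empty training set")
  mu <- colMeans(train)
  sd <- sqrt(colMeans(sweep(train, 2, mu)^2))
  list(mean = mu, sd = sd)
}

#' Apply fitted normalization parameters
#'
#' @param x numeric matrix with the same columns as the training matrix.
#' @param params from [fit_normalization()].
#' @return Normalized matrix; constant training columns become 0.
#' @export
apply_normalization <- function(x, params) {
  x <- as.matrix(x)
  out <- sweep(x, 2, params$mean)
  sd <- ifelse(params$sd > 0, params$sd, 1)
  out <- sweep(out, 2, sd, "/")
  out[, params$sd == 0] <- 0
  out
}

#' Correlation distance between two feature vectors
#'
#' `d = 1 - r` with `r` the Pearson correlation of `u` and `v` across the
#' selected features, so `d` lies in `[0, 2]`. If either vector has zero
#' variance, `d` is defined as 1.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return Distance in `[0, 2]`.
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v)) stop_named("correlation_distance: length mismatch (%d vs %d)", length(u), length(v))
  if (length(u) < 2L) stop_named("correlation_distance: vectors must have length >= 2")
  du <- u - mean(u); dv <- v - mean(v)
  su <- sqrt(sum(du^2)); sv <- sqrt(sum(dv^2))
  if (su == 0 || sv == 0) return(1)
  1 - sum(du * dv) / (su * sv)
}

# Distance matrix between test rows and training rows on the selected
# feature subspace. Pearson correlation distance for >= 2 features (zero
# variance rows fall back to d = 1); absolute difference for a single
# feature, where Pearson correlation is undefined.
knn_distances <- function(Xtr, Xte) {
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  m <- ncol(Xtr)
  if (m == 1L) {
    return(abs(outer(Xte[, 1L], Xtr[, 1L], "-")))
  }
  # All sums are accumulated feature-by-feature in plain double precision
  # (no BLAS matmul, no long-double rowSums) so the floating-point rounding
  # matches the compiled search kernel bit-for-bit; with few features the
  # routes would otherwise differ in the last ulp and break distance ties
  # differently.
  center_sd <- function(X) {
    mu <- 0
    for (c in seq_len(m)) mu <- mu + X[, c]
    mu <- mu / m
    cx <- X - mu
    ss <- 0
    for (c in seq_len(m)) ss <- ss + cx[, c]^2
    list(c = cx, s = sqrt(ss))
  }
  tr <- center_sd(Xtr); te <- center_sd(Xte)
  ctr <- tr$c; cte <- te$c; str <- tr$s; ste <- te$s
  num <- matrix(0, nrow(Xte), nrow(Xtr))
  for (c in seq_len(m)) num <- num + cte[, c] %o% ctr[, c]
  den <- ste %o% str
  d <- matrix(1, nrow(Xte), nrow(Xtr))
  ok <- den > 0
  d[ok] <- 1 - num[ok] / den[ok]
  d
}

#' KNN probability scores for test rows
#'
#' For each test row, the fraction of positive labels among its `k`
#' nearest training rows by correlation distance; distance ties are broken
#' by ascending training-row index, making scores fully deterministic.
#' Inputs are expected to be normalized with train-fitted parameters.
#'
#' @param Xtr normalized training matrix; `ytr` its 0/1 labels.
#' @param ytr integer 0/1 training labels.
#' @param Xte normalized test matrix (or a single vector).
#' @param k number of neighbours, `k <= nrow(Xtr)`.
#' @return Numeric scores in `[0, 1]`, one per test row.
#' @export
knn_scores <- function(Xtr, ytr, Xte, k = 5L) {
  Xtr <- as.matrix(Xtr)
  if (is.null(dim(Xte))) Xte <- matrix(Xte, nrow = 1L)
  Xte <- as.matrix(Xte)
  k <- as.integer(k)
  if (k > nrow(Xtr)) stop_named("knn_scores: k = %d exceeds training size %d", k, nrow(Xtr))
  if (length(ytr) != nrow(Xtr)) stop_named("knn_scores: label/row mismatch")
  d <- knn_distances(Xtr, Xte)
  apply(d, 1L, function(dr) {
    nb <- order(dr, seq_along(dr))[seq_len(k)]
    mean(ytr[nb])
  })
}

#' KNN score for a single test vector
#'
#' @inheritParams knn_scores
#' @param x normalized test feature vector.
#' @param cfg a [knn_config()].
#' @return Score in `[0, 1]`.
#' @export
knn_score <- function(Xtr, ytr, x, cfg = knn_config()) {
  knn_scores(Xtr, ytr, matrix(x, nrow = 1L), k = cfg$k)[1L]
}

#' One-vs-rest label assignment
#'
#' The task with the maximal probability score wins; exact ties go to the
#' earliest task in the declared order (GG1, GG2, GG1+2, GG3, GG4+5).
#'
#' @param scores numeric vector, one score per task.
#' @param tasks ordered task list (default [binary_tasks()]).
#' @return The winning task's name.
#' @export
ovr_assign <- function(scores, tasks = binary_tasks()) {
  if (length(scores) == 0L) stop_named("ovr_assign: empty score list")
  if (length(scores) != length(tasks)) stop_named("ovr_assign: %d scores for %d tasks", length(scores), length(tasks))
  tasks[[which.max(scores)]]$name
}

#' Binarize a probability score
#'
#' `score >= threshold` is positive (the boundary counts as positive).
#'
#' @param score numeric score(s) in `[0, 1]`.
#' @param threshold decision threshold in `[0, 1]`, default 0.5.
#' @return Integer 0/1 prediction(s).
#' @export
binarize <- function(score, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop_named("binarize: threshold must lie in [0, 1]")
  as.integer(score >= threshold)
}
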