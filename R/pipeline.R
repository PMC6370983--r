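# End-to-end orchestration: cohort -> features -> per-zone task searches ->
# report, plus deployment-style classification of unseen fragments.

#' Default pipeline configuration
#'
#' All settings of an end-to-end run in one plain list (serializable to
#' YAML): cohort source, preprocessing, feature, classifier and search
#' parameters, and the master seed every random draw derives from.
#'
#' @param seed master seed (default 17).
#' @return Named list of settings.
#' @export
default_config <- function(seed = 17L) {
  list(
    mode = "synthetic",          # "synthetic" or "features"
    features_csv = NULL,         # used when mode = "features"
    seed = as.integer(seed),
    zones = c("PZ", "TZAFS"),
    target_spacing = 0.5,        # mm, in-plane working resolution
    roi_size = 61L,
    gray_levels = 128L,
    k = 5L,
    threshold = 0.5,
    n_folds = 3L,
    min_size = 1L,
    max_size = 5L,
    top_n = 100L,
    engine = "cpp",
    feature_pool = NULL          # optional restriction of the 38-panel pool
  )
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg[names(user)] <- user
  cfg
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, extracts the 38-feature table, runs the
#' semi-exhaustive search for each one-vs-rest task in each requested zone,
#' and writes `features.csv`, per-task ranked-subset CSVs, `summary.csv`,
#' `summary.json` and a machine-readable `manifest.json` echoing the full
#' configuration. Re-running with the same config reproduces all outputs
#' byte-identically.
#'
#' @param config list from [default_config()] / [read_config()].
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @return Invisibly, a list with `features`, `analyses`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  full <- default_config()
  full[names(config)] <- config
  config <- full

  if (config$mode == "synthetic") {
    cohort <- generate_cohort(synthetic_cohort_spec(seed = config$seed),
                              size = config$roi_size)
    features <- cohort_features(cohort, G = config$gray_levels)
  } else if (config$mode == "features") {
    if (is.null(config$features_csv)) stop_named("run_pipeline: mode 'features' needs features_csv")
    if (!file.exists(config$features_csv)) {
      stop_named("run_pipeline: feature table %s does not exist", config$features_csv)
    }
    features <- utils::read.csv(config$features_csv, stringsAsFactors = FALSE)
    miss <- setdiff(c("patient_id", "lesion_id", "zone", "gg", feature_names()),
                    names(features))
    if (length(miss)) {
      stop_named("run_pipeline: %s is missing column(s): %s",
                 config$features_csv, paste(miss, collapse = ", "))
    }
  } else {
    stop_named("run_pipeline: unknown mode '%s'", config$mode)
  }

  search_cfg <- config[c("min_size", "max_size", "n_folds", "k", "threshold",
                         "top_n", "seed", "engine", "feature_pool")]
  analyses <- lapply(config$zones, function(z) {
    run_zone_analysis(features, zone = z, cfg = search_cfg)
  })
  names(analyses) <- config$zones
  summary <- do.call(rbind, lapply(analyses, `[[`, "summary"))
  rownames(summary) <- NULL

  manifest <- list(
    package = "zonegrade",
    version = as.character(utils::packageVersion("zonegrade")),
    config = config[!vapply(config, is.null, TRUE)],
    seed = config$seed,
    n_lesions = nrow(features),
    n_task_searches = nrow(summary),
    n_subsets_per_search = count_subsets(
      length(config$feature_pool %||% seq_len(38L)),
      config$min_size, config$max_size)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    # full %.17g precision so a run restarted from the exported table
    # reproduces every downstream number exactly
    fchr <- features
    for (nm in feature_names()) fchr[[nm]] <- sprintf("%.17g", fchr[[nm]])
    utils::write.csv(fchr, file.path(out_dir, "features.csv"),
                     row.names = FALSE, quote = FALSE)
    for (z in names(analyses)) {
      for (task in names(analyses[[z]]$results)) {
        ranked <- analyses[[z]]$results[[task]]$ranked
        ranked$subset <- NULL
        utils::write.csv(ranked,
                         file.path(out_dir, sprintf("ranked_%s_%s.csv", z, task)),
                         row.names = FALSE)
      }
    }
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    best <- stats::setNames(as.list(summary$mean_auc),
                            paste(summary$zone, summary$task, sep = "."))
    jsonlite::write_json(best, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  invisible(list(features = features, analyses = analyses, summary = summary,
                 manifest = manifest))
}

#' Train deployable one-vs-rest models for a zone
#'
#' Freezes, per task, the best subset found by the zone analysis together
#' with normalization parameters fitted on (and the normalized features of)
#' the full zone cohort, ready for [classify_unseen()].
#'
#' @param features feature table ([cohort_features()] layout).
#' @param zone_analysis a `zone_analysis` from [run_zone_analysis()].
#' @param cfg a [knn_config()].
#' @param G gray levels used at feature extraction (stored for reuse).
#' @return An `ovr_models` list.
#' @export
train_ovr_models <- function(features, zone_analysis, cfg = knn_config(),
                             G = 128L) {
  zone <- zone_analysis$zone
  rows <- if (zone == "PZ") features$zone == "PZ" else features$zone %in% c("TZ", "AFS")
  df <- features[rows, , drop = FALSE]
  X <- as.matrix(df[, feature_names(), drop = FALSE])
  models <- lapply(names(zone_analysis$results), function(task) {
    sub <- zone_analysis$results[[task]]$ranked$subset[[1]]
    params <- fit_normalization(X[, sub, drop = FALSE])
    list(task = task, subset = sub,
         params = params,
         Xn = apply_normalization(X[, sub, drop = FALSE], params),
         y = task_labels(task, df$gg))
  })
  names(models) <- names(zone_analysis$results)
  structure(list(zone = zone, models = models, cfg = cfg, G = G),
            class = "ovr_models")
}

#' Classify an unseen lesion fragment
#'
#' Extracts the 38-feature panel, scores the fragment with each task's KNN
#' model and assigns the label of the highest-scoring task ([ovr_assign()]
#' tie rule).
#'
#' @param models an `ovr_models` from [train_ovr_models()].
#' @param fragment a [roi_fragment()].
#' @return List with `label` (winning task name) and named `scores`.
#' @export
classify_unseen <- function(models, fragment) {
  stopifnot(inherits(models, "ovr_models"))
  fv <- extract_features(fragment, G = models$G)
  scores <- vapply(models$models, function(m) {
    x <- apply_normalization(matrix(fv[m$subset], nrow = 1L), m$params)
    knn_scores(m$Xn, m$y, x, k = models$cfg$k)
  }, 0)
  list(label = ovr_assign(scores, binary_tasks()[names(models$models)]),
       scores = scores)
}
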