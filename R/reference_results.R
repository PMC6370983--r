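# Published reference results for the clinical cohort.

#' Reference per-task AUCs of the original clinical analysis
#'
#' Mean 3-fold CV ROC AUCs per one-vs-rest Grade Group task reported for
#' the zonal bpMRI models trained on the PROSTATEx-challenge training
#' cohort (peripheral zone from high-b-value DWI, TZ+AFS from T2W). The
#' clinical images cannot ship with the package, so these serve as fixed
#' reference values for aggregate arithmetic — e.g. the overall zone means
#' of 0.92 (PZ) and 0.87 (TZ+AFS) — not as quantities this package
#' recomputes.
#'
#' @return Data.frame with columns `zone`, `task`, `auc`.
#' @export
reference_task_aucs <- function() {
  tasks <- names(binary_tasks())
  rbind(
    data.frame(zone = "PZ", task = tasks,
               auc = c(0.87, 0.88, 0.96, 0.98, 0.91)),
    data.frame(zone = "TZAFS", task = tasks,
               auc = c(0.85, 0.89, 0.83, 0.94, 0.86))
  )
}
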