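# Replicate-level evaluation: Power, MEs and the confusion-matrix rates of
# the verification stage (TPR, SPC, ACC, FDR), with the published
# degenerate-denominator conventions.

#' Classify a detection result against the simulation truth
#'
#' The classification universe is the candidate set carried into stage two:
#' a candidate is a "disease model" only when its SNP columns equal the
#' causal set exactly (partial overlap counts as non-disease). TP/FN count
#' disease-model candidates that did / did not pass the significance
#' threshold; FP/TN count non-disease candidates. A causal model absent from
#' the candidates contributes nothing to the confusion counts — it only
#' lowers stage-1 power via `found`.
#'
#' @param result An `epi_result` from [epi_run()] / [epi_verify()].
#' @param truth A `sim_truth` (see [generate_dataset()]).
#' @return A one-row data.frame: `TP`, `FP`, `TN`, `FN`, `found`,
#'   `significant_found`, `evaluations`.
#' @export
classify_outcomes <- function(result, truth) {
  truth_id <- paste(sort(truth$causal_column_indices), collapse = ",")
  ids <- result$tested$combo_id
  if (is.null(ids)) stop("result carries no candidate identities")
  sig <- result$tested$significant
  is_truth <- ids == truth_id
  tp <- sum(is_truth & sig)
  fn <- sum(is_truth & !sig)
  fp <- sum(!is_truth & sig)
  tn <- sum(!is_truth & !sig)
  found <- isTRUE(result$found) || any(is_truth)
  evaluations <- if (isTRUE(result$found) && !is.na(result$mes))
    result$mes else result$evaluations_used
  data.frame(TP = tp, FP = fp, TN = tn, FN = fn, found = found,
             significant_found = tp > 0L, evaluations = evaluations)
}

#' Summarize a batch of replicate outcomes
#'
#' @param outcomes A data.frame of rows from [classify_outcomes()], one per
#'   replicate (optionally with a `runtime` column).
#' @return A list of class `batch_evaluation`: `power_stage1` (fraction of
#'   replicates whose causal model reached the candidate set),
#'   `power_stage2` (fraction where it also passed the threshold), pooled
#'   `tpr`, `spc`, `acc`, `fdr` (SPC = 0 when FP+TN = 0 and FDR = 0 when
#'   TP+FP = 0, by convention; TPR likewise 0 when TP+FN = 0), `mes` (mean
#'   evaluations until first hit, or the budget for misses),
#'   `runtime_mean`, and the raw `per_replicate` table.
#' @export
summarize_batch <- function(outcomes) {
  if (nrow(outcomes) < 1L) stop("need at least one replicate")
  tp <- sum(outcomes$TP); fp <- sum(outcomes$FP)
  tn <- sum(outcomes$TN); fn <- sum(outcomes$FN)
  rate <- function(num, den) if (den == 0L) 0 else num / den
  structure(
    list(power_stage1 = mean(outcomes$found),
         power_stage2 = mean(outcomes$significant_found),
         tpr = rate(tp, tp + fn),
         spc = rate(tn, fp + tn),
         acc = rate(tp + tn, tp + tn + fn + fp),
         fdr = rate(fp, tp + fp),
         mes = mean(outcomes$evaluations),
         runtime_mean = if ("runtime" %in% names(outcomes))
           mean(outcomes$runtime) else NA_real_,
         confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
         per_replicate = outcomes),
    class = "batch_evaluation")
}

#' @export
print.batch_evaluation <- function(x, ...) {
  cat("batch_evaluation over", nrow(x$per_replicate), "replicates\n")
  cat(sprintf("  Power (stage 1 / stage 2): %.3f / %.3f\n",
              x$power_stage1, x$power_stage2))
  cat(sprintf("  TPR %.3f  SPC %.3f  ACC %.3f  FDR %.3f\n",
              x$tpr, x$spc, x$acc, x$fdr))
  cat(sprintf("  MEs %.1f\n", x$mes))
  invisible(x)
}
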