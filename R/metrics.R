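#' @title Evaluation indices
#' @name metrics
#' @description Protein-level evaluation of signal-peptide calls: the
#'   Matthews correlation coefficient, the transmembrane false-positive
#'   rate, and precision/recall/F1, plus the tally that produces them.
NULL

#' Construct confusion counts
#'
#' Signal peptide is the positive class. `FP_TM` counts the subset of
#' false positives that are transmembrane proteins and `N_TM` the total
#' number of transmembrane negatives, so `FP_TM / N_TM` is the
#' transmembrane false-positive rate.
#'
#' @param TP,TN,FP,FN Non-negative integers.
#' @param FP_TM Transmembrane proteins miscalled as signal peptides;
#'   at most `FP` and at most `N_TM`.
#' @param N_TM Total transmembrane negatives.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN, FP_TM = 0L, N_TM = 0L) {
  vals <- c(TP = TP, TN = TN, FP = FP, FN = FN,
            FP_TM = FP_TM, N_TM = N_TM)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (FP_TM > FP || FP_TM > N_TM)
    stop("FP_TM must not exceed FP or N_TM", call. = FALSE)
  structure(as.list(vals), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$TP, " TN=", x$TN, " FP=", x$FP,
      " FN=", x$FN, " FP_TM=", x$FP_TM, "/", x$N_TM, "\n", sep = "")
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with 0
#' returned when any factor of the denominator is 0 (the usual
#' convention for degenerate tallies).
#'
#' @param counts A [confusion_counts()].
#' @return A value in \[-1, 1\].
#' @export
mcc <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

#' Transmembrane false-positive rate
#'
#' `FP_TM / N_TM`: the fraction of transmembrane negatives miscalled as
#' signal peptides. Returns 0 when there are no transmembrane proteins.
#'
#' @param counts A [confusion_counts()].
#' @return A value in \[0, 1\].
#' @export
fpr_tm <- function(counts) {
  if (counts$N_TM == 0) return(0)
  counts$FP_TM / counts$N_TM
}

#' Precision, recall and F1
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and
#' `f1 = 2*TP/(2*TP+FN+FP)` (equal to the harmonic mean of precision
#' and recall). Each index is defined as 0 when its denominator is 0.
#'
#' @param counts A [confusion_counts()].
#' @return A named list with `precision`, `recall` and `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  FN <- as.numeric(counts$FN)
  precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  recall <- if (TP + FN == 0) 0 else TP / (TP + FN)
  f1 <- if (2 * TP + FN + FP == 0) 0 else 2 * TP / (2 * TP + FN + FP)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Full metric report from confusion counts
#'
#' @param counts A [confusion_counts()].
#' @return A named list: `mcc`, `fpr_tm`, `precision`, `recall`, `f1`
#'   (all as fractions; multiply by 100 for the conventional percent
#'   presentation).
#' @export
metric_report <- function(counts) {
  prf <- precision_recall_f1(counts)
  list(mcc = mcc(counts), fpr_tm = fpr_tm(counts),
       precision = prf$precision, recall = prf$recall, f1 = prf$f1)
}

#' Evaluate sequence-level calls against truth flags
#'
#' Tallies the confusion counts over all records, with signal peptide as
#' the positive class; `FP_TM`/`N_TM` are tallied over the records
#' flagged as transmembrane negatives.
#'
#' @param truth A data frame with columns `id`, `true_is_sp`,
#'   `true_is_tm` -- or a list of labeled [protein_record()]s /
#'   encoded samples carrying those flags.
#' @param calls A data frame with columns `id` and `is_sp` (e.g. from
#'   [predict_records()]), or a logical vector aligned with `truth`.
#' @return A list with `counts` (a [confusion_counts()]) and `metrics`
#'   (a [metric_report()]).
#' @export
evaluate_predictions <- function(truth, calls) {
  if (!is.data.frame(truth)) {
    truth <- do.call(rbind, lapply(truth, function(r) {
      if (inherits(r, "protein_record")) {
        tt <- record_truth(r)
        data.frame(id = r$id, true_is_sp = tt$is_sp, true_is_tm = tt$is_tm,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(id = r$source_id, true_is_sp = r$true_is_sp,
                   true_is_tm = r$true_is_tm, stringsAsFactors = FALSE)
      }
    }))
  }
  if (is.logical(calls)) {
    if (length(calls) != nrow(truth))
      stop("calls length differs from number of records", call. = FALSE)
    calls <- data.frame(id = truth$id, is_sp = calls,
                        stringsAsFactors = FALSE)
  }
  if (!setequal(truth$id, calls$id) || anyDuplicated(truth$id) ||
      anyDuplicated(calls$id))
    stop("truth and calls must carry the same unique ids", call. = FALSE)
  if (any(is.na(truth$true_is_sp)))
    stop("records without labels cannot be evaluated", call. = FALSE)
  pred <- calls$is_sp[match(truth$id, calls$id)]
  pos <- truth$true_is_sp
  tm <- truth$true_is_tm
  counts <- confusion_counts(
    TP = sum(pos & pred), TN = sum(!pos & !pred),
    FP = sum(!pos & pred), FN = sum(pos & !pred),
    FP_TM = sum(tm & pred), N_TM = sum(tm))
  list(counts = counts, metrics = metric_report(counts))
}
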