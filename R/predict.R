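#' @title Sequence-level calls from per-residue probabilities
#' @name predict
#' @description The consecutive-residue threshold rule that turns a
#'   96 x 3 probability matrix into a whole-sequence signal-peptide call,
#'   and the per-residue segmentation.
NULL

#' Construct a decision configuration
#'
#' @param threshold Probability threshold in (0, 1); the call uses a
#'   strict `>` comparison. Treated as a hyper-parameter and selected by
#'   nested cross validation in the full protocol.
#' @param window Number of consecutive residues that must all exceed the
#'   threshold (default 4).
#' @param statistic Within-window statistic: `"min"` (default; every
#'   residue in the window must clear the threshold) or `"mean"`.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(threshold = 0.5, window = 4L,
                            statistic = c("min", "mean")) {
  statistic <- match.arg(statistic)
  window <- as.integer(window)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (window < 1L || window > INPUT_LEN)
    stop("window must be in 1..96", call. = FALSE)
  structure(list(threshold = threshold, window = window,
                 statistic = statistic), class = "decision_config")
}

window_scores <- function(s, window, statistic) {
  n <- length(s) - window + 1L
  fun <- if (statistic == "min") min else mean
  vapply(seq_len(n), function(i) fun(s[i:(i + window - 1L)]), numeric(1))
}

#' Call signal-peptide status from a probability matrix
#'
#' The sequence is called a signal peptide when the S-channel
#' probability of some `window` consecutive residues clears the
#' threshold. With the default `"min"` statistic the score is the
#' maximum over all windows of the within-window minimum S probability,
#' and the call is `score > threshold` (strict).
#'
#' @param probs 96 x 3 probability matrix, channel order (S, T, N).
#' @param cfg A [decision_config()].
#' @return A list with `is_sp` (logical) and `score` (in \[0, 1\]).
#' @export
call_signal_peptide <- function(probs, cfg = decision_config()) {
  if (!is.matrix(probs) || ncol(probs) != 3L)
    stop("probs must be a matrix with 3 columns (S, T, N)", call. = FALSE)
  if (cfg$window > nrow(probs))
    stop("window exceeds the number of positions", call. = FALSE)
  score <- max(window_scores(probs[, 1L], cfg$window, cfg$statistic))
  list(is_sp = score > cfg$threshold, score = score)
}

#' Per-residue segmentation from a probability matrix
#'
#' Labels each position by its argmax channel, breaking ties by the
#' priority S > T > N, and reports the end of the leading S run (the
#' predicted cleavage position, 1-based) when the sequence starts in S.
#'
#' @param probs 96 x 3 probability matrix, channel order (S, T, N).
#' @return A list with `residue_labels` (length-96 string over {S,T,N})
#'   and `sp_end` (1-based last residue of the leading S run, or `NA`
#'   when position 1 is not S).
#' @export
segment_probs <- function(probs) {
  if (!is.matrix(probs) || ncol(probs) != 3L)
    stop("probs must be a matrix with 3 columns (S, T, N)", call. = FALSE)
  cls <- max.col(probs, ties.method = "first")  # column order = priority
  labels <- LABEL_ALPHABET[cls]
  sp_end <- NA_integer_
  if (labels[1] == "S") {
    r <- rle(labels)
    sp_end <- r$lengths[1]
  }
  list(residue_labels = paste(labels, collapse = ""), sp_end = sp_end)
}

#' Predict sequence-level calls for a set of records
#'
#' Runs the model over every record and applies the decision rule and
#' segmentation.
#'
#' @param model A `sigunet_model` or `sigunet_fit`.
#' @param records List of [protein_record()] objects (or already-encoded
#'   samples from [encode_records()]).
#' @param cfg A [decision_config()].
#' @return A data frame with one row per record: `id`, `score`, `is_sp`,
#'   `sp_end` (1-based, `NA` when no leading S run) and `residue_labels`.
#' @export
predict_records <- function(model, records, cfg = decision_config()) {
  samples <- if (length(records) > 0L &&
                 inherits(records[[1]], "encoded_sample"))
    records else encode_records(records)
  probs <- predict_probs_batch(model, samples)
  rows <- lapply(seq_along(samples), function(i) {
    call <- call_signal_peptide(probs[[i]], cfg)
    seg <- segment_probs(probs[[i]])
    data.frame(id = samples[[i]]$source_id, score = call$score,
               is_sp = call$is_sp, sp_end = seg$sp_end,
               residue_labels = seg$residue_labels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
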