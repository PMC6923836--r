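#' @title Nested cross validation with inner-model ensembling
#' @name nested_cv_protocol
#' @description Outer k-fold evaluation whose hyper-parameters (network
#'   configuration and decision threshold) are chosen by an inner
#'   (k-1)-fold loop on each outer training set; the k-1 inner models of
#'   the selected candidate predict the outer test partition and their
#'   probability matrices are averaged before the decision rule. The
#'   outer test partition is never used for any selection decision.
NULL

#' Construct a cross-validation plan
#'
#' @param hyper_grid List of candidates, each a list with `net_config`
#'   (a [network_config()]) and `threshold` (decision threshold).
#' @param k Outer fold count (default 5); each outer fold runs k-1 inner
#'   folds over the k-1 training partitions.
#' @param selection_metric Inner selection metric; `"mcc"`.
#' @param seed Seed for the stratified fold assignment.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(hyper_grid, k = 5L, selection_metric = "mcc",
                    seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (!is.list(hyper_grid) || length(hyper_grid) == 0L)
    stop("hyper_grid must be a non-empty list", call. = FALSE)
  ok <- vapply(hyper_grid, function(cand)
    is.list(cand) && inherits(cand$net_config, "network_config") &&
      is.numeric(cand$threshold), logical(1))
  if (!all(ok))
    stop("each candidate needs a net_config and a threshold",
         call. = FALSE)
  selection_metric <- match.arg(selection_metric, "mcc")
  structure(list(k = k, hyper_grid = hyper_grid,
                 selection_metric = selection_metric,
                 seed = as.integer(seed)), class = "cv_plan")
}

sample_class <- function(s) {
  if (isTRUE(s$true_is_sp)) "sp" else if (isTRUE(s$true_is_tm)) "tm"
  else "other"
}

# Stratified partition: within each protein-level class, a seeded
# shuffle dealt round-robin into k folds, so rare classes reach every
# fold. Returns a list of k disjoint index vectors covering 1..n.
stratified_folds <- function(samples, k, seed) {
  set.seed(seed)
  cls <- vapply(samples, sample_class, character(1))
  parts <- vector("list", k)
  for (cl in unique(cls)) {
    idx <- sample(which(cls == cl))
    for (j in seq_along(idx)) {
      f <- ((j - 1L) %% k) + 1L
      parts[[f]] <- c(parts[[f]], idx[j])
    }
  }
  parts
}

truth_frame <- function(samples) {
  data.frame(id = vapply(samples, `[[`, character(1), "source_id"),
             true_is_sp = vapply(samples, `[[`, logical(1), "true_is_sp"),
             true_is_tm = vapply(samples, `[[`, logical(1), "true_is_tm"),
             stringsAsFactors = FALSE)
}

calls_from_probs <- function(probs_list, threshold, window = 4L) {
  vapply(probs_list, function(p)
    call_signal_peptide(p, decision_config(threshold, window))$is_sp,
    logical(1))
}

#' Run nested cross validation
#'
#' For each outer fold the k-1 training partitions serve as the inner
#' folds: every hyper-parameter candidate is trained k-1 times (each
#' inner fold once as validation set) and scored by the mean
#' inner-validation MCC at the candidate's threshold. The winning
#' candidate's k-1 inner models are then applied to the outer test
#' partition, their probability matrices are arithmetically averaged,
#' and the decision rule is applied to the average. Ties in the inner
#' score are broken by smaller [count_parameters()], then by smaller
#' threshold.
#'
#' @param samples List of labeled encoded samples ([encode_records()]);
#'   at least `k` of them.
#' @param plan A [cv_plan()].
#' @param train_cfg A [train_config()] shared by all fits.
#' @param train_fun Training backend,
#'   `function(train, val, net_config, train_cfg)`; defaults to
#'   [train_model()]. Swappable for stub models in tests.
#' @param predict_fun Prediction backend,
#'   `function(fit, samples)` returning a list of 96 x 3 probability
#'   matrices; defaults to the package's batched forward pass.
#' @param verbose Print per-fold progress.
#' @return An object of class `nested_cv_result`: per-fold details
#'   (test ids, inner scores, selected candidate, averaged probability
#'   matrices, calls) plus the aggregate confusion counts and metric
#'   report over the union of outer test partitions.
#' @export
nested_cv <- function(samples, plan, train_cfg = train_config(),
                      train_fun = NULL, predict_fun = NULL,
                      verbose = FALSE) {
  if (length(samples) < plan$k)
    stop("need at least k samples", call. = FALSE)
  if (is.null(train_fun)) train_fun <- train_model
  if (is.null(predict_fun))
    predict_fun <- function(fit, s) predict_probs_batch(fit, s)

  n_cand <- length(plan$hyper_grid)
  parts <- stratified_folds(samples, plan$k, plan$seed)
  ids <- vapply(samples, `[[`, character(1), "source_id")
  folds <- vector("list", plan$k)

  for (f in seq_len(plan$k)) {
    test_idx <- parts[[f]]
    inner_parts <- parts[-f]
    n_inner <- length(inner_parts)

    # leakage guard: outer test ids never enter inner training/validation
    stopifnot(length(intersect(test_idx, unlist(inner_parts))) == 0L)

    inner_scores <- matrix(NA_real_, n_inner, n_cand)
    test_probs <- vector("list", n_cand)  # [[cand]][[inner]] -> list
    for (j in seq_len(n_cand)) {
      cand <- plan$hyper_grid[[j]]
      test_probs[[j]] <- vector("list", n_inner)
      for (v in seq_len(n_inner)) {
        val_idx <- inner_parts[[v]]
        tr_idx <- unlist(inner_parts[-v])
        fit <- train_fun(samples[tr_idx], samples[val_idx],
                         cand$net_config, train_cfg)
        val_probs <- predict_fun(fit, samples[val_idx])
        calls <- calls_from_probs(val_probs, cand$threshold)
        ev <- evaluate_predictions(truth_frame(samples[val_idx]), calls)
        inner_scores[v, j] <- ev$metrics$mcc
        test_probs[[j]][[v]] <- predict_fun(fit, samples[test_idx])
      }
    }

    mean_scores <- colMeans(inner_scores)
    n_params <- vapply(plan$hyper_grid, function(cand)
      count_parameters(cand$net_config), numeric(1))
    thresholds <- vapply(plan$hyper_grid, `[[`, numeric(1), "threshold")
    best <- order(-mean_scores, n_params, thresholds)[1]

    # average the k-1 inner models' probabilities on the outer test set
    avg_probs <- lapply(seq_along(test_idx), function(i)
      Reduce(`+`, lapply(test_probs[[best]], `[[`, i)) / n_inner)
    calls <- calls_from_probs(avg_probs,
                              plan$hyper_grid[[best]]$threshold)
    if (verbose)
      message(sprintf(
        "fold %d/%d: candidate %d selected (mean inner MCC %.3f)",
        f, plan$k, best, mean_scores[best]))
    folds[[f]] <- list(test_ids = ids[test_idx], test_idx = test_idx,
                       inner_scores = inner_scores,
                       mean_scores = mean_scores,
                       selected = best,
                       selected_candidate = plan$hyper_grid[[best]],
                       n_models = n_inner,
                       avg_probs = avg_probs, calls = calls)
  }

  all_idx <- unlist(lapply(folds, `[[`, "test_idx"))
  all_calls <- unlist(lapply(folds, `[[`, "calls"))
  agg <- evaluate_predictions(truth_frame(samples[all_idx]), all_calls)
  structure(list(folds = folds, counts = agg$counts,
                 metrics = agg$metrics, plan = plan),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  m <- x$metrics
  cat("<nested_cv_result> k=", x$plan$k, ", ",
      length(x$plan$hyper_grid), " candidate(s)\n", sep = "")
  cat(sprintf("  MCC %.1f%%  FPR_TM %.1f%%  Precision %.1f%%  Recall %.1f%%  F1 %.1f%%\n",
              100 * m$mcc, 100 * m$fpr_tm, 100 * m$precision,
              100 * m$recall, 100 * m$f1))
  invisible(x)
}
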