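# Stub training backend: "training" records a constant probability
# matrix determined by the training ids, so ensembling arithmetic and
# data-flow can be checked by hand.
stub_backend <- function(constant_by_call = NULL) {
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  calls$train_ids <- list()
  calls$val_ids <- list()
  train_fun <- function(train, val, net_config, train_cfg) {
    calls$n <- calls$n + 1L
    calls$train_ids[[calls$n]] <-
      vapply(train, `[[`, character(1), "source_id")
    calls$val_ids[[calls$n]] <-
      vapply(val, `[[`, character(1), "source_id")
    s <- if (is.null(constant_by_call)) 0.5 else
      constant_by_call[[((calls$n - 1L) %% length(constant_by_call)) + 1L]]
    list(stub_s = s)
  }
  predict_fun <- function(fit, samples) {
    lapply(samples, function(s)
      cbind(S = rep(fit$stub_s, 96), T = (1 - fit$stub_s) / 2,
            N = (1 - fit$stub_s) / 2))
  }
  list(train_fun = train_fun, predict_fun = predict_fun, calls = calls)
}

one_candidate <- function(threshold = 0.5) {
  list(list(net_config = tiny_config(), threshold = threshold))
}

test_that("outer partitions are disjoint, cover the data, and never leak into inner folds", {
  samples <- tiny_samples(40, 30, 30, seed = 41)
  backend <- stub_backend()
  res <- nested_cv(samples, cv_plan(one_candidate(0.4), k = 5, seed = 2),
                   train_config(max_epochs = 1, patience = 1),
                   train_fun = backend$train_fun,
                   predict_fun = backend$predict_fun)
  all_ids <- vapply(samples, `[[`, character(1), "source_id")
  test_ids <- unlist(lapply(res$folds, `[[`, "test_ids"))
  expect_setequal(test_ids, all_ids)
  expect_equal(anyDuplicated(test_ids), 0L)

  # each outer fold is scored by exactly k-1 = 4 models
  expect_true(all(vapply(res$folds, `[[`, integer(1), "n_models") == 4L))

  # leakage freedom: inner train/val ids never contain outer test ids
  fold_sizes <- vapply(res$folds, function(f) length(f$test_ids),
                       integer(1))
  calls_per_fold <- backend$calls$n / 5L
  for (f in seq_len(5L)) {
    outer_ids <- res$folds[[f]]$test_ids
    idx <- ((f - 1L) * calls_per_fold + 1L):(f * calls_per_fold)
    for (ci in idx) {
      expect_length(intersect(outer_ids, backend$calls$train_ids[[ci]]), 0L)
      expect_length(intersect(outer_ids, backend$calls$val_ids[[ci]]), 0L)
    }
  }
})

test_that("stratification places every class in every fold", {
  samples <- tiny_samples(20, 15, 15, seed = 43)
  parts <- sigunet:::stratified_folds(samples, 5L, seed = 3L)
  cls <- vapply(samples, sigunet:::sample_class, character(1))
  for (p in parts) expect_setequal(unique(cls[p]), c("sp", "tm", "other"))
})

test_that("averaged test predictions equal the hand-computed mean of inner-model constants", {
  samples <- tiny_samples(10, 5, 5, seed = 47)
  consts <- list(0.2, 0.4, 0.6, 0.8)  # one per inner model, cycling
  backend <- stub_backend(constant_by_call = consts)
  res <- nested_cv(samples, cv_plan(one_candidate(0.3), k = 5, seed = 2),
                   train_config(max_epochs = 1, patience = 1),
                   train_fun = backend$train_fun,
                   predict_fun = backend$predict_fun)
  expected <- mean(unlist(consts))  # 4 inner models -> one full cycle
  for (f in res$folds) {
    for (p in f$avg_probs) {
      expect_equal(unique(p[, 1]), expected)
      expect_true(all(abs(rowSums(p) - 1) < 1e-5))
    }
  }
})

test_that("hyper-parameter selection maximizes mean inner MCC with documented tie-breaks", {
  samples <- tiny_samples(10, 5, 5, seed = 53)
  # constant S-probability 0.5 everywhere: threshold 0.4 calls all
  # positive (MCC 0), threshold 0.6 calls all negative (MCC 0) -- a tie
  # broken by the smaller threshold among equal-size networks
  backend <- stub_backend()
  grid <- list(list(net_config = tiny_config(), threshold = 0.6),
               list(net_config = tiny_config(), threshold = 0.4))
  res <- nested_cv(samples, cv_plan(grid, k = 5, seed = 2),
                   train_config(max_epochs = 1, patience = 1),
                   train_fun = backend$train_fun,
                   predict_fun = backend$predict_fun)
  for (f in res$folds) {
    expect_equal(f$selected_candidate$threshold, 0.4)
    expect_equal(dim(f$inner_scores), c(4L, 2L))
  }
})

test_that("plan validation rejects degenerate inputs", {
  expect_error(cv_plan(list()), "non-empty")
  expect_error(cv_plan(one_candidate(), k = 1), "k must be")
  samples <- tiny_samples(2, 1, 1, seed = 3)
  expect_error(nested_cv(samples[1:3],
                         cv_plan(one_candidate(), k = 5)),
               "at least k")
})

test_that("aggregate metrics are recomputed consistently from the pooled calls", {
  samples <- tiny_samples(12, 6, 6, seed = 59)
  backend <- stub_backend(constant_by_call = list(0.9))
  res <- nested_cv(samples, cv_plan(one_candidate(0.5), k = 4, seed = 7),
                   train_config(max_epochs = 1, patience = 1),
                   train_fun = backend$train_fun,
                   predict_fun = backend$predict_fun)
  # constant 0.9 > 0.5 everywhere: every protein is called positive
  expect_equal(res$counts$TP, 12)
  expect_equal(res$counts$FP, 12)
  expect_equal(res$counts$FP_TM, 6)
  expect_equal(res$counts$N_TM, 6)
  expect_equal(res$metrics$mcc, mcc(res$counts))
  expect_equal(res$metrics$fpr_tm, 1)
})
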