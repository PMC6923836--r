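#' @title Training with amino-acid-level cross entropy
#' @name training
#' @description The per-residue cross-entropy loss, a seeded first-order
#'   training loop with early stopping on validation loss, and model
#'   checkpointing helpers.
NULL

#' Construct a training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (samples).
#' @param max_epochs Upper bound on training epochs.
#' @param patience Epochs without validation-loss improvement before
#'   stopping; must not exceed `max_epochs`.
#' @param seed Integer seed controlling weight initialization and batch
#'   shuffling; identical seeds give identical fits.
#' @param mask_padding If `TRUE`, positions beyond the true sequence
#'   length are excluded from the loss. Off by default: padded positions
#'   carry class N and contribute to the fixed 96-term sum.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 200L, patience = 10L, seed = 1L,
                         mask_padding = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  batch_size <- as.integer(batch_size)
  max_epochs <- as.integer(max_epochs)
  patience <- as.integer(patience)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (max_epochs < 1L) stop("max_epochs must be >= 1", call. = FALSE)
  if (patience < 1L || patience > max_epochs)
    stop("patience must be in 1..max_epochs", call. = FALSE)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 seed = as.integer(seed), mask_padding = mask_padding),
            class = "train_config")
}

#' Per-residue cross-entropy loss for one sample
#'
#' `-sum_{i=1..96} sum_{j in (S,T,N)} y_ij * ln(h_ij)`, with
#' probabilities clipped to `[1e-7, 1]` before the logarithm. When
#' `n_valid` is given, only the first `n_valid` positions (the real,
#' non-padding residues) enter the sum.
#'
#' @param y 96 x 3 one-hot label matrix.
#' @param h 96 x 3 probability matrix (rows sum to 1).
#' @param n_valid Optional number of non-padding positions to keep.
#' @return A non-negative scalar; 0 exactly when `h` puts probability 1
#'   on the true class everywhere (up to clipping).
#' @export
sigunet_loss <- function(y, h, n_valid = NULL) {
  if (!is.matrix(y) || !is.matrix(h) || !all(dim(y) == dim(h)) ||
      ncol(y) != 3L)
    stop("y and h must both be 96 x 3 matrices", call. = FALSE)
  keep <- seq_len(if (is.null(n_valid)) nrow(y) else min(n_valid, nrow(y)))
  h <- pmin(pmax(h, 1e-7), 1)
  -sum(y[keep, ] * log(h[keep, ]))
}

# Adam update, in place on `layers`; `state` holds first/second moments.
adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g[[nm]]
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] +
        (1 - beta2) * g[[nm]]^2
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * (state$m[[i]][[nm]] / c1) /
          (sqrt(state$v[[i]][[nm]] / c2) + eps)
    }
  }
  layers
}

# Mean per-sample cross-entropy of stacked predictions P vs labels Y
# ((B*96) x 3 each); `valid` is an optional logical row mask.
batch_loss <- function(P, Y, B, valid = NULL) {
  Pc <- pmin(pmax(P, 1e-7), 1)
  ll <- -rowSums(Y * log(Pc))
  if (!is.null(valid)) ll <- ll * valid
  sum(ll) / B
}

eval_loss <- function(layers, X, Y, n, valid = NULL, chunk = 256L) {
  total <- 0
  for (start in seq.int(1L, n, chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    rows <- rep((idx - 1L) * INPUT_LEN, each = INPUT_LEN) +
      rep.int(seq_len(INPUT_LEN), length(idx))
    P <- forward_net(layers, X[rows, , drop = FALSE], length(idx))$out
    total <- total + batch_loss(P, Y[rows, , drop = FALSE], 1L,
                                if (is.null(valid)) NULL else valid[rows])
  }
  total / n
}

stack_samples <- function(samples, field) {
  do.call(rbind, lapply(samples, `[[`, field))
}

valid_mask <- function(samples) {
  unlist(lapply(samples, function(s)
    seq_len(INPUT_LEN) <= s$n_valid), use.names = FALSE)
}

#' Train a network with early stopping
#'
#' Minimizes the batch-averaged per-residue cross entropy
#' ([sigunet_loss()]) with Adam, monitoring the validation loss after
#' every epoch and keeping the weights of the best validation epoch.
#' Training stops once the validation loss has failed to improve for
#' `patience` consecutive epochs. All randomness (weight initialization,
#' batch shuffling) derives from `train_cfg$seed`, so identical inputs
#' and configuration reproduce the fit exactly.
#'
#' @param train,val Non-empty lists of labeled encoded samples (see
#'   [encode_records()]); every sample must carry `y`.
#' @param net_config A [network_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `sigunet_fit`: `model` (weights from the
#'   best validation epoch), `history` (data frame of per-epoch train and
#'   validation losses) and `best_epoch`.
#' @export
train_model <- function(train, val, net_config,
                        train_cfg = train_config(), verbose = FALSE) {
  if (length(train) == 0L || length(val) == 0L)
    stop("train and val must be non-empty", call. = FALSE)
  if (any(vapply(c(train, val), function(s) is.null(s$y), logical(1))))
    stop("all samples must carry label matrices y", call. = FALSE)

  set.seed(train_cfg$seed)
  model <- build_network(net_config)
  layers <- model$layers

  n_tr <- length(train)
  Xtr <- stack_samples(train, "x")
  Ytr <- stack_samples(train, "y")
  Xva <- stack_samples(val, "x")
  Yva <- stack_samples(val, "y")
  vtr <- if (train_cfg$mask_padding) valid_mask(train) else NULL
  vva <- if (train_cfg$mask_padding) valid_mask(val) else NULL

  state <- new.env(parent = emptyenv())
  state$m <- lapply(layers, function(ly) lapply(ly$params, function(p) p * 0))
  state$v <- state$m

  best_val <- Inf
  best_layers <- layers
  best_epoch <- 0L
  wait <- 0L
  t_step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  for (epoch in seq_len(train_cfg$max_epochs)) {
    perm <- sample.int(n_tr)
    epoch_loss <- 0
    for (start in seq.int(1L, n_tr, train_cfg$batch_size)) {
      bidx <- perm[start:min(start + train_cfg$batch_size - 1L, n_tr)]
      B <- length(bidx)
      rows <- rep((bidx - 1L) * INPUT_LEN, each = INPUT_LEN) +
        rep.int(seq_len(INPUT_LEN), B)
      Xb <- Xtr[rows, , drop = FALSE]
      Yb <- Ytr[rows, , drop = FALSE]
      vb <- if (is.null(vtr)) NULL else vtr[rows]

      fw <- forward_net(layers, Xb, B, want_caches = TRUE)
      epoch_loss <- epoch_loss + batch_loss(fw$out, Yb, 1L, vb)
      dZ <- (fw$out - Yb) / B
      if (!is.null(vb)) dZ <- dZ * vb
      grads <- backward_net(layers, fw$caches, dZ, B)
      t_step <- t_step + 1L
      layers <- adam_step(layers, grads, state,
                          train_cfg$learning_rate, t_step)
    }
    train_loss <- epoch_loss / n_tr
    val_loss <- eval_loss(layers, Xva, Yva, length(val), vva)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f",
                      epoch, train_loss, val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_layers <- layers
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$patience) break
    }
  }

  model$layers <- best_layers
  structure(list(model = model, history = history,
                 best_epoch = best_epoch, best_val_loss = best_val),
            class = "sigunet_fit")
}

#' @export
print.sigunet_fit <- function(x, ...) {
  cat("<sigunet_fit> ", nrow(x$history), " epochs, best epoch ",
      x$best_epoch, " (val loss ", sprintf("%.4f", x$best_val_loss),
      ")\n", sep = "")
  invisible(x)
}

#' Save a trained model
#'
#' Writes the weights to `<path>` (RDS) and a JSON sidecar
#' `<path>.json` recording the network configuration.
#'
#' @param model A `sigunet_model` or `sigunet_fit`.
#' @param path Output path for the weight file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "sigunet_fit")) model <- model$model
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the weight file.
#' @return A `sigunet_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sigunet_model"))
    stop("not a sigunet model checkpoint: ", path, call. = FALSE)
  model
}
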