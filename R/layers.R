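# Internal numerical engine for the 1D U-Net.
#
# A batch of B sequences of length L with C channels is a (B*L) x C
# matrix whose rows are sample-blocked: rows 1..L are sample 1, rows
# L+1..2L are sample 2, and so on. Convolutions are im2col + one BLAS
# matrix product; gradients are exact (verified against finite
# differences in the test suite).

.shift_cache <- new.env(parent = emptyenv())

# Y[i] = X[i + d] within each length-L sample block, zero outside.
shift_rows <- function(X, d, L, B) {
  if (d == 0L) return(X)
  key <- paste(L, B, d, sep = "_")
  idx <- .shift_cache[[key]]
  if (is.null(idx)) {
    pos <- rep.int(seq_len(L), B)
    dest <- which(pos + d >= 1L & pos + d <= L)
    idx <- list(dest = dest, src = dest + d)
    .shift_cache[[key]] <- idx
  }
  Y <- matrix(0, nrow(X), ncol(X))
  Y[idx$dest, ] <- X[idx$src, , drop = FALSE]
  Y
}

# (B*L) x C -> (B*L) x (k*C), offset blocks ordered -p..p.
im2col <- function(X, k, L, B) {
  if (k == 1L) return(X)
  p <- (k - 1L) %/% 2L
  do.call(cbind, lapply(seq.int(-p, p), function(d) shift_rows(X, d, L, B)))
}

add_bias <- function(Y, b) Y + matrix(b, nrow(Y), length(b), byrow = TRUE)

# Forward pass. Returns list(out, caches): `out` is the (B*96) x 3
# probability matrix; `caches` holds per-layer intermediates for
# backward_net() when want_caches = TRUE.
forward_net <- function(layers, X, B, want_caches = FALSE) {
  L <- INPUT_LEN
  skips <- list()
  caches <- if (want_caches) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      Xcol <- im2col(X, ly$k, L, B)
      Z <- add_bias(Xcol %*% ly$params$W, ly$params$b)
      A <- if (ly$act == "relu") pmax(Z, 0) else Z
      if (want_caches)
        caches[[i]] <- list(Xcol = Xcol, L = L,
                            mask = if (ly$act == "relu") Z > 0 else NULL)
      X <- A
    } else if (ly$type == "push_skip") {
      skips[[length(skips) + 1L]] <- X
      if (want_caches) caches[[i]] <- list(L = L)
    } else if (ly$type == "pool") {
      odd <- seq.int(1L, B * L, 2L)
      Xo <- X[odd, , drop = FALSE]
      Xe <- X[odd + 1L, , drop = FALSE]
      if (ly$pool == "average") {
        A <- (Xo + Xe) / 2
        if (want_caches) caches[[i]] <- list(L = L)
      } else {
        M <- Xo >= Xe
        A <- Xo * M + Xe * (1 - M)
        if (want_caches) caches[[i]] <- list(L = L, mask = M)
      }
      L <- L %/% 2L
      X <- A
    } else if (ly$type == "upconv") {
      Z1 <- add_bias(X %*% ly$params$W1, ly$params$b)
      Z2 <- add_bias(X %*% ly$params$W2, ly$params$b)
      A <- matrix(0, 2L * nrow(X), ly$cout)
      odd <- seq.int(1L, nrow(A), 2L)
      A[odd, ] <- Z1
      A[odd + 1L, ] <- Z2
      mask <- A > 0
      A <- pmax(A, 0)
      if (want_caches) caches[[i]] <- list(Xin = X, L = L, mask = mask)
      L <- 2L * L
      X <- A
    } else if (ly$type == "concat") {
      skip <- skips[[length(skips)]]
      skips[[length(skips)]] <- NULL
      if (want_caches) caches[[i]] <- list(L = L, n_dec = ncol(X))
      X <- cbind(X, skip)
    } else if (ly$type == "softmax") {
      mx <- do.call(pmax, lapply(seq_len(ncol(X)), function(j) X[, j]))
      E <- exp(X - mx)
      X <- E / rowSums(E)
      if (want_caches) caches[[i]] <- list(L = L)
    }
  }
  list(out = X, caches = caches)
}

# Backward pass from dZ, the gradient at the input of the softmax layer
# (for cross-entropy on softmax outputs this is (P - Y) / batch_scale).
# Returns a list of per-layer gradient lists parallel to `layers`.
backward_net <- function(layers, caches, dZ, B) {
  grads <- vector("list", length(layers))
  skip_grads <- list()
  dX <- dZ
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "softmax") {
      # gradient already combined with the cross-entropy loss
      next
    } else if (ly$type == "conv") {
      if (!is.null(cc$mask)) dX <- dX * cc$mask
      grads[[i]] <- list(W = crossprod(cc$Xcol, dX), b = colSums(dX))
      dXcol <- dX %*% t(ly$params$W)
      if (ly$k == 1L) {
        dX <- dXcol
      } else {
        p <- (ly$k - 1L) %/% 2L
        cin <- ly$cin
        dX <- matrix(0, nrow(dXcol), cin)
        for (j in seq_len(ly$k)) {
          d <- j - 1L - p
          blk <- dXcol[, ((j - 1L) * cin + 1L):(j * cin), drop = FALSE]
          dX <- dX + shift_rows(blk, -d, cc$L, B)
        }
      }
    } else if (ly$type == "pool") {
      L_in <- cc$L
      dA <- matrix(0, B * L_in, ncol(dX))
      odd <- seq.int(1L, B * L_in, 2L)
      if (ly$pool == "average") {
        dA[odd, ] <- dX / 2
        dA[odd + 1L, ] <- dX / 2
      } else {
        dA[odd, ] <- dX * cc$mask
        dA[odd + 1L, ] <- dX * (1 - cc$mask)
      }
      dX <- dA
    } else if (ly$type == "push_skip") {
      g <- skip_grads[[length(skip_grads)]]
      skip_grads[[length(skip_grads)]] <- NULL
      dX <- dX + g
    } else if (ly$type == "upconv") {
      dX <- dX * cc$mask
      odd <- seq.int(1L, nrow(dX), 2L)
      d1 <- dX[odd, , drop = FALSE]
      d2 <- dX[odd + 1L, , drop = FALSE]
      grads[[i]] <- list(W1 = crossprod(cc$Xin, d1),
                         W2 = crossprod(cc$Xin, d2),
                         b = colSums(d1) + colSums(d2))
      dX <- d1 %*% t(ly$params$W1) + d2 %*% t(ly$params$W2)
    } else if (ly$type == "concat") {
      n_dec <- cc$n_dec
      skip_grads[[length(skip_grads) + 1L]] <-
        dX[, (n_dec + 1L):ncol(dX), drop = FALSE]
      dX <- dX[, seq_len(n_dec), drop = FALSE]
    }
  }
  grads
}

#' Per-residue class probabilities for one encoded sequence
#'
#' @param model A model from [build_network()] or the `$model` of a
#'   [train_model()] fit.
#' @param x A 96 x 20 input matrix (see [encode_sequence()]).
#' @return A 96 x 3 matrix of class probabilities, columns (S, T, N);
#'   every row sums to 1.
#' @export
predict_probs <- function(model, x) {
  if (inherits(model, "sigunet_fit")) model <- model$model
  if (!is.matrix(x) || nrow(x) != INPUT_LEN || ncol(x) != 20L)
    stop("x must be a 96 x 20 matrix", call. = FALSE)
  P <- forward_net(model$layers, x, 1L)$out
  colnames(P) <- LABEL_ALPHABET
  P
}

# Batched prediction: list of encoded samples (or raw 96x20 matrices)
# -> list of 96 x 3 probability matrices.
predict_probs_batch <- function(model, samples, chunk = 256L) {
  if (inherits(model, "sigunet_fit")) model <- model$model
  xs <- lapply(samples, function(s) if (is.matrix(s)) s else s$x)
  n <- length(xs)
  out <- vector("list", n)
  for (start in seq.int(1L, n, chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    X <- do.call(rbind, xs[idx])
    P <- forward_net(model$layers, X, length(idx))$out
    for (j in seq_along(idx)) {
      M <- P[((j - 1L) * INPUT_LEN + 1L):(j * INPUT_LEN), , drop = FALSE]
      colnames(M) <- LABEL_ALPHABET
      out[[idx[j]]] <- M
    }
  }
  out
}
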