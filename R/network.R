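#' @title The SigUNet architecture family
#' @name network
#' @description Fully convolutional 1D encoder--decoder networks that map a
#'   96 x 20 one-hot sequence matrix to a 96 x 3 per-residue class
#'   probability matrix. No fully connected layers: every operation is a
#'   length-preserving convolution, a size-2 pooling, a size-2 stride-2
#'   transposed convolution, or a per-position softmax.
NULL

#' Construct a network configuration
#'
#' The encoder has `depth` levels, each with `convs_per_level`
#' length-preserving 1D convolutions (ReLU) followed by a size-2 pooling;
#' a bottleneck level; and a mirrored decoder using size-2 stride-2
#' transposed convolutions with skip concatenation of the same-resolution
#' encoder output. A final 1x1 convolution maps to 3 channels with a
#' per-position softmax.
#'
#' Channel counts follow `schedule`: `"linear"` starts from `m` and
#' increases by `n` after each pooling (the SigUNet schedule), `"doubling"`
#' starts from 64 and doubles after each pooling (the original U-Net
#' schedule, used by the U-Net-1D ablation baseline).
#'
#' @param m First-level channel count (linear schedule).
#' @param n Channel increment per level (linear schedule).
#' @param depth Number of pooling steps; 96 must be divisible by 2^depth.
#' @param kernel_size Odd convolution width.
#' @param convs_per_level Convolutions per resolution level.
#' @param pooling `"average"` (SigUNet default) or `"max"`.
#' @param schedule `"linear"` or `"doubling"`.
#' @param variant Label for the configuration family: `"sigunet"`,
#'   `"sigunet_light"` or `"unet1d"`.
#' @return An object of class `network_config`.
#' @seealso [sigunet_config()], [sigunet_light_config()], [unet1d_config()]
#'   for the repository-default instances.
#' @export
network_config <- function(m = 24L, n = 24L, depth = 3L, kernel_size = 3L,
                           convs_per_level = 2L,
                           pooling = c("average", "max"),
                           schedule = c("linear", "doubling"),
                           variant = c("sigunet", "sigunet_light",
                                       "unet1d")) {
  pooling <- match.arg(pooling)
  schedule <- match.arg(schedule)
  variant <- match.arg(variant)
  m <- as.integer(m); n <- as.integer(n); depth <- as.integer(depth)
  kernel_size <- as.integer(kernel_size)
  convs_per_level <- as.integer(convs_per_level)
  if (m < 1L) stop("m must be a positive integer", call. = FALSE)
  if (n < 0L) stop("n must be a non-negative integer", call. = FALSE)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (INPUT_LEN %% (2L^depth) != 0L)
    stop("96 must be divisible by 2^depth (got depth = ", depth, ")",
         call. = FALSE)
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be an odd positive integer", call. = FALSE)
  if (convs_per_level < 1L)
    stop("convs_per_level must be >= 1", call. = FALSE)
  structure(list(m = m, n = n, depth = depth, kernel_size = kernel_size,
                 convs_per_level = convs_per_level, pooling = pooling,
                 schedule = schedule, variant = variant),
            class = "network_config")
}

#' Repository-default SigUNet configuration
#'
#' Linear channel schedule m = 24, n = 24, depth 3, kernel 3, two
#' convolutions per level, average pooling.
#' @param ... Overrides passed to [network_config()].
#' @return A `network_config`.
#' @export
sigunet_config <- function(...) {
  args <- list(m = 24L, n = 24L, depth = 3L, kernel_size = 3L,
               convs_per_level = 2L, pooling = "average",
               schedule = "linear", variant = "sigunet")
  do.call(network_config, utils::modifyList(args, list(...)))
}

#' Repository-default SigUNet-light configuration
#'
#' The reduced model: m = 20, n = 20, otherwise as [sigunet_config()].
#' @param ... Overrides passed to [network_config()].
#' @return A `network_config`.
#' @export
sigunet_light_config <- function(...) {
  args <- list(m = 20L, n = 20L, depth = 3L, kernel_size = 3L,
               convs_per_level = 2L, pooling = "average",
               schedule = "linear", variant = "sigunet_light")
  do.call(network_config, utils::modifyList(args, list(...)))
}

#' U-Net-1D ablation baseline configuration
#'
#' Doubling channel schedule (64, 128, ...) with max pooling, as in the
#' original U-Net, in one dimension.
#' @param depth Number of pooling steps (default 3).
#' @param ... Further overrides passed to [network_config()].
#' @return A `network_config`.
#' @export
unet1d_config <- function(depth = 3L, ...) {
  args <- list(m = 64L, n = 0L, depth = depth, kernel_size = 3L,
               convs_per_level = 2L, pooling = "max",
               schedule = "doubling", variant = "unet1d")
  do.call(network_config, utils::modifyList(args, list(...)))
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config> ", x$variant, ": depth ", x$depth,
      ", kernel ", x$kernel_size, ", ", x$convs_per_level,
      " conv/level, ", x$pooling, " pooling, ", x$schedule,
      " schedule", sep = "")
  if (x$schedule == "linear") cat(" (m=", x$m, ", n=", x$n, ")", sep = "")
  cat("; ", format(count_parameters(x), big.mark = ","),
      " trainable weights\n", sep = "")
  invisible(x)
}

#' Channel count at a resolution level
#'
#' @param config A [network_config()].
#' @param level Integer level, 0 (input resolution) up to `depth`
#'   (bottleneck).
#' @return The channel count: `m + level * n` for the linear schedule,
#'   `64 * 2^level` for the doubling schedule.
#' @export
channel_schedule <- function(config, level) {
  level <- as.integer(level)
  if (level < 0L || level > config$depth)
    stop("level must be in 0..depth (= ", config$depth, ")", call. = FALSE)
  switch(config$schedule,
         linear = config$m + level * config$n,
         doubling = 64L * 2L^level)
}

# Architecture walk shared by count_parameters() and build_network():
# calls f(type, cin, cout, k) for every weighted layer in execution order.
walk_layers <- function(config, f) {
  k <- config$kernel_size
  cin <- 20L
  for (level in 0:(config$depth - 1L)) {
    ch <- channel_schedule(config, level)
    for (i in seq_len(config$convs_per_level)) {
      f("conv", cin, ch, k); cin <- ch
    }
    f("pool", cin, cin, 2L)
  }
  ch <- channel_schedule(config, config$depth)
  for (i in seq_len(config$convs_per_level)) {
    f("conv", cin, ch, k); cin <- ch
  }
  for (level in (config$depth - 1L):0) {
    ch <- channel_schedule(config, level)
    f("upconv", cin, ch, 2L)
    f("concat", ch, 2L * ch, 0L)
    cin <- 2L * ch
    for (i in seq_len(config$convs_per_level)) {
      f("conv", cin, ch, k); cin <- ch
    }
  }
  f("final", cin, 3L, 1L)
  invisible(NULL)
}

#' Count trainable weights in closed form
#'
#' Sums `kernel_size * c_in * c_out + c_out` per convolution,
#' `2 * c_in * c_out + c_out` per transposed convolution and
#' `c_in * 3 + 3` for the final 1x1 layer. Equals the exhaustive
#' enumeration of the built model's weight arrays (see [n_parameters()]).
#'
#' @param config A [network_config()].
#' @return Total number of trainable weights.
#' @export
count_parameters <- function(config) {
  total <- 0
  walk_layers(config, function(type, cin, cout, k) {
    total <<- total + switch(type,
      conv = k * cin * cout + cout,
      upconv = 2 * cin * cout + cout,
      final = cin * cout + cout,
      0)
  })
  total
}

#' Enumerate the trainable weights of a built model
#'
#' The brute-force companion of [count_parameters()]: walks every weight
#' array actually allocated in the model and sums its length.
#'
#' @param model A model from [build_network()].
#' @return Total number of trainable weights.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(ly)
    sum(vapply(ly$params, length, numeric(1))), numeric(1)))
}

# He-uniform initialization: U(-sqrt(6/fan_in), +sqrt(6/fan_in)).
he_uniform <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a network from a configuration
#'
#' Allocates and He-uniform-initializes all weight arrays. Draws from the
#' current RNG stream; call `set.seed()` first for reproducible weights.
#'
#' @param config A [network_config()].
#' @return An object of class `sigunet_model`: the configuration plus a
#'   list of layer objects (weights and per-layer metadata). Apply it with
#'   [predict_probs()].
#' @export
build_network <- function(config) {
  layers <- list()
  walk_layers(config, function(type, cin, cout, k) {
    ly <- switch(type,
      conv = list(type = "conv", k = k, cin = cin, cout = cout,
                  act = "relu",
                  params = list(W = he_uniform(k * cin, cout, k * cin),
                                b = rep(0, cout))),
      pool = list(type = "pool", pool = config$pooling, params = list()),
      upconv = list(type = "upconv", cin = cin, cout = cout,
                    params = list(W1 = he_uniform(cin, cout, cin),
                                  W2 = he_uniform(cin, cout, cin),
                                  b = rep(0, cout))),
      concat = list(type = "concat", params = list()),
      final = list(type = "conv", k = 1L, cin = cin, cout = cout,
                   act = "linear",
                   params = list(W = he_uniform(cin, cout, cin),
                                 b = rep(0, cout))))
    # a skip push precedes every pooling step
    if (type == "pool")
      layers[[length(layers) + 1L]] <<- list(type = "push_skip",
                                             params = list())
    layers[[length(layers) + 1L]] <<- ly
  })
  layers[[length(layers) + 1L]] <- list(type = "softmax", params = list())
  structure(list(config = config, layers = layers),
            class = "sigunet_model")
}

#' @export
print.sigunet_model <- function(x, ...) {
  cat("<sigunet_model> ", x$config$variant, ", ",
      format(n_parameters(x), big.mark = ","),
      " trainable weights, input 96 x 20, output 96 x 3\n", sep = "")
  invisible(x)
}
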