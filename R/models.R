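#' WideResNet configuration
#'
#' Describes a member of the WRN family: depth `d` with `(d - 4) / 6`
#' pre-activation residual blocks per group at widths `16k / 32k / 64k`,
#' in a 1-D (raw time series) or 2-D (image representation) realization.
#' Convolutions are bias-free with kernel 3 (3x3 in 2-D), normalization
#' layers are affine, and the single classifier layer carries a bias; the
#' parameter count is therefore independent of the input size thanks to
#' global average pooling.
#'
#' @param depth network depth; `(depth - 4)` must be divisible by 6
#'   (16, 28, 40, ...).
#' @param width width multiplier `k` (>= 1).
#' @param dim `"1d"` or `"2d"`.
#' @param in_channels input channels (3 for a tri-axial accelerometer).
#' @param n_classes output classes.
#' @param input_size expected spatial input: a length (1-D) or `c(H, W)`
#'   (2-D). Informational; forward passes accept any size.
#' @return Object of class `wrn_config`.
#' @export
wrn_config <- function(depth, width, dim = c("1d", "2d"), in_channels = 3,
                       n_classes = 14, input_size = NULL) {
  dim <- match.arg(dim)
  if (depth < 10 || (depth - 4) %% 6 != 0)
    stop("depth must satisfy (depth - 4) %% 6 == 0; got ", depth, call. = FALSE)
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  if (in_channels < 1 || n_classes < 2)
    stop("in_channels and n_classes must be positive (>= 2 classes)",
         call. = FALSE)
  if (is.null(input_size)) input_size <- if (dim == "1d") 500L else c(64L, 64L)
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 dim = dim, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size)),
            class = "wrn_config")
}

#' @export
print.wrn_config <- function(x, ...) {
  cat(sprintf("<wrn_config> WRN%d-%d (%s), %d ch -> %d classes\n",
              x$depth, x$width, x$dim, x$in_channels, x$n_classes))
  invisible(x)
}

config_equal <- function(a, b) {
  identical(a[c("depth", "width", "dim", "in_channels", "n_classes")],
            b[c("depth", "width", "dim", "in_channels", "n_classes")])
}

#' Build a WideResNet
#'
#' Instantiates the compiled network and initializes its weights: He
#' normal (fan-out mode) for convolutions, gamma 1 / beta 0 for
#' normalization, and uniform `+-1/sqrt(fan_in)` for the classifier.
#' Initialization draws come from R's RNG, so a seed makes the build
#' reproducible.
#'
#' @param cfg a [wrn_config()].
#' @param seed optional integer seed for the initializer.
#' @return Object of class `wrn_network` (holds an external pointer; use
#'   [checkpoint()] for a persistable snapshot).
#' @export
build_wrn <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "wrn_config"))
  ptr <- .wrn_create(cfg$depth, cfg$width, if (cfg$dim == "1d") 1L else 2L,
                     cfg$in_channels, cfg$n_classes)
  net <- structure(list(ptr = ptr, config = cfg), class = "wrn_network")
  if (!is.null(seed)) set.seed(seed)
  lay <- .wrn_layout(ptr)
  v <- numeric(.wrn_n_params(ptr))
  for (i in seq_len(nrow(lay))) {
    idx <- lay$offset[i]:(lay$offset[i] + lay$size[i] - 1)
    v[idx] <- switch(lay$type[i],
      conv = rnorm(lay$size[i]) * sqrt(2 / lay$fan_out[i]),
      bn_gamma = 1,
      bn_beta = 0,
      fc_w = runif(lay$size[i], -1, 1) / sqrt(lay$fan_in[i]),
      fc_b = runif(lay$size[i], -1, 1) / sqrt(lay$fan_in[i]))
  }
  .wrn_set_params(ptr, v)
  net
}

#' @export
print.wrn_network <- function(x, ...) {
  cat(sprintf("<wrn_network> WRN%d-%d (%s), %s trainable parameters\n",
              x$config$depth, x$config$width, x$config$dim,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param net a `wrn_network` or a [wrn_config()] (a config is built
#'   transiently).
#' @param millions return the count in millions rounded to 2 decimals.
#' @return integer count (or numeric, when `millions = TRUE`).
#' @export
count_params <- function(net, millions = FALSE) {
  if (inherits(net, "wrn_config")) net <- build_wrn(net)
  stopifnot(inherits(net, "wrn_network"))
  n <- .wrn_n_params(net$ptr)
  if (millions) round(n / 1e6, 2) else n
}

#' Two-teacher compression ratio
#'
#' `100 * S / (T1 + T2)` per cent, from exact parameter counts: how large
#' the deployed student is relative to the combined capacity of the
#' raw-signal teacher and the image-representation teacher it distills
#' from.
#'
#' @param student,teacher1,teacher2 networks, configs, or raw counts.
#' @param digits decimals to round to (default 2).
#' @return percentage.
#' @export
compression_ratio <- function(student, teacher1, teacher2, digits = 2) {
  as_count <- function(x)
    if (is.numeric(x)) x else count_params(x)
  s <- as_count(student); t1 <- as_count(teacher1); t2 <- as_count(teacher2)
  if (s <= 0 || t1 <= 0 || t2 <= 0)
    stop("parameter counts must be positive", call. = FALSE)
  round(100 * s / (t1 + t2), digits)
}

#' Flatten / load the trainable parameter vector
#'
#' The whole network is one flat double vector in a fixed layout, which is
#' what the weight-space diagnostics (interpolation curves) operate on.
#' `load_params` requires an exact length match and returns the network
#' invisibly.
#'
#' @param net a `wrn_network`.
#' @param v numeric vector of length [count_params()].
#' @return `flatten_params`: numeric vector.
#' @export
flatten_params <- function(net) {
  stopifnot(inherits(net, "wrn_network"))
  .wrn_get_params(net$ptr)
}

#' @rdname flatten_params
#' @export
load_params <- function(net, v) {
  stopifnot(inherits(net, "wrn_network"))
  .wrn_set_params(net$ptr, as.numeric(v))
  invisible(net)
}

#' Linear interpolation between two weight vectors
#'
#' `(1 - eta) * x_a + eta * x_b` elementwise. `eta = 0` and `eta = 1`
#' reproduce the endpoints; values outside `[0, 1]` extrapolate along the
#' same line (the interpolation diagnostics use `eta` in `[-1, 2]`).
#'
#' @param x_a,x_b equal-length numeric vectors.
#' @param eta interpolation coefficient.
#' @return numeric vector.
#' @export
interpolate_params <- function(x_a, x_b, eta) {
  if (length(x_a) != length(x_b))
    stop("weight vectors differ in length", call. = FALSE)
  (1 - eta) * x_a + eta * x_b
}

# (C, S1, S2, N)-ordered batch vector from stored window/image arrays
batch_input <- function(xall, idx) {
  d <- dim(xall)
  if (length(d) == 3) {            # (C, L, N) -> dims C, L, 1, B
    xb <- xall[, , idx, drop = FALSE]
    list(x = as.numeric(xb), dims = c(d[1], d[2], 1L, length(idx)))
  } else {                         # (C, H, W, N)
    xb <- xall[, , , idx, drop = FALSE]
    list(x = as.numeric(xb), dims = c(d[1], d[2], d[3], length(idx)))
  }
}

# canonical (channel-first, sample-last) layouts for the engine
input_array <- function(x) {
  if (inherits(x, "window_set")) return(aperm(x$windows, c(2, 3, 1)))
  if (inherits(x, "image_set")) return(aperm(x$pixels, c(2, 3, 4, 1)))
  if (is.array(x) && length(dim(x)) == 3) return(aperm(x, c(2, 3, 1)))
  if (is.array(x) && length(dim(x)) == 4) return(aperm(x, c(2, 3, 4, 1)))
  stop("expected a window_set, image_set, or 3-/4-d array", call. = FALSE)
}

n_samples_of <- function(xall) {
  d <- dim(xall)
  d[length(d)]
}

forward_batches <- function(net, xall, batch_size = 256, mode = 0L,
                            features = FALSE) {
  n <- n_samples_of(xall)
  out <- NULL
  for (b in seq(1, n, by = batch_size)) {
    idx <- b:min(b + batch_size - 1, n)
    bi <- batch_input(xall, idx)
    part <- if (features) .wrn_features(net$ptr, bi$x, bi$dims)
            else .wrn_forward(net$ptr, bi$x, bi$dims, as.integer(mode), FALSE)
    out <- rbind(out, part)
  }
  out
}

#' Logits / penultimate features for a dataset
#'
#' Runs the network in evaluation mode (frozen normalization statistics)
#' over the given windows or images.
#'
#' @param net a `wrn_network` or `wrn_checkpoint`.
#' @param x a `window_set`, `image_set`, or array (`N x C x L` /
#'   `N x C x H x W`).
#' @param batch_size forward batch size.
#' @return `predict_logits`: `N x n_classes` matrix; `network_features`:
#'   `N x n_features` matrix of global-average-pooled activations.
#' @export
predict_logits <- function(net, x, batch_size = 256) {
  net <- as_network(net)
  forward_batches(net, input_array(x), batch_size, mode = 0L)
}

#' @rdname predict_logits
#' @export
network_features <- function(net, x, batch_size = 256) {
  net <- as_network(net)
  forward_batches(net, input_array(x), batch_size, features = TRUE)
}

#' Persistable snapshot of a network
#'
#' A checkpoint bundles the configuration, the flat trainable parameter
#' vector and the normalization running statistics; it survives
#' `saveRDS()` across sessions, unlike the live network object.
#'
#' @param net a `wrn_network`.
#' @param meta optional provenance list.
#' @return Object of class `wrn_checkpoint`.
#' @export
checkpoint <- function(net, meta = list()) {
  stopifnot(inherits(net, "wrn_network"))
  structure(list(config = net$config, params = .wrn_get_params(net$ptr),
                 running = .wrn_get_running(net$ptr), meta = meta),
            class = "wrn_checkpoint")
}

#' Restore a network from a checkpoint
#'
#' Builds a fresh network (or loads into `into`) and installs the stored
#' weights and running statistics. Loading into an existing network
#' validates configuration equality first.
#'
#' @param ckpt a `wrn_checkpoint`.
#' @param into optional existing `wrn_network` of identical configuration.
#' @return A `wrn_network`.
#' @export
restore_network <- function(ckpt, into = NULL) {
  stopifnot(inherits(ckpt, "wrn_checkpoint"))
  net <- if (is.null(into)) build_wrn(ckpt$config) else into
  if (!config_equal(net$config, ckpt$config))
    stop("checkpoint configuration does not match the target network",
         call. = FALSE)
  .wrn_set_params(net$ptr, ckpt$params)
  .wrn_set_running(net$ptr, ckpt$running)
  net
}

as_network <- function(x) {
  if (inherits(x, "wrn_network")) return(x)
  if (inherits(x, "wrn_checkpoint")) return(restore_network(x))
  stop("expected a wrn_network or wrn_checkpoint", call. = FALSE)
}

#' @export
print.wrn_checkpoint <- function(x, ...) {
  cat(sprintf("<wrn_checkpoint> WRN%d-%d (%s), %d parameters\n",
              x$config$depth, x$config$width, x$config$dim,
              length(x$params)))
  invisible(x)
}

#' Save / load checkpoints
#' @param ckpt a `wrn_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "wrn_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "wrn_checkpoint"))
    stop("file does not contain a checkpoint", call. = FALSE)
  ckpt
}

#' Informational FLOP accounting
#'
#' Multiply-accumulate count of one forward pass at the configured input
#' size (one MAC per kernel tap per output element, plus the classifier).
#' Reported for orientation only; FLOP conventions vary between papers, so
#' this number is not used as a fidelity check anywhere.
#'
#' @param cfg a [wrn_config()].
#' @return list with `macs` and `flops` (= 2 * macs).
#' @export
count_flops <- function(cfg) {
  stopifnot(inherits(cfg, "wrn_config"))
  two_d <- cfg$dim == "2d"
  sp <- if (two_d) cfg$input_size else c(cfg$input_size[1], 1L)
  k <- if (two_d) 9 else 3
  n_blk <- (cfg$depth - 4) / 6
  widths <- c(16, 32, 64) * cfg$width
  conv_out <- function(sp, stride) ceiling(sp / stride)
  macs <- 0
  # stem
  macs <- macs + cfg$in_channels * 16 * k * prod(sp)
  prev <- 16
  for (g in 1:3) {
    for (b in 1:n_blk) {
      cin <- if (b == 1) prev else widths[g]
      stride <- if (b == 1 && g > 1) 2 else 1
      spo <- conv_out(sp, stride)
      macs <- macs + cin * widths[g] * k * prod(spo) +
        widths[g] * widths[g] * k * prod(spo)
      if (cin != widths[g] || stride != 1)
        macs <- macs + cin * widths[g] * prod(spo)
      sp <- spo
    }
    prev <- widths[g]
  }
  macs <- macs + widths[3] * cfg$n_classes
  list(macs = macs, flops = 2 * macs)
}
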