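#' Classification report for a network on labeled windows
#'
#' Argmax-of-logits prediction; reports accuracy in percent, macro-averaged
#' F1 (per-class harmonic mean of precision and recall, averaged with
#' equal class weight -- the informative choice under class imbalance), the
#' confusion matrix (rows = true class, columns = predicted), and
#' per-class recall.
#'
#' @param net a `wrn_network` or `wrn_checkpoint`.
#' @param x a `window_set`/`image_set` or array of inputs.
#' @param labels optional 0-based labels (taken from `x` when absent).
#' @return Object of class `irkd_eval`.
#' @export
evaluate_network <- function(net, x, labels = NULL) {
  labels <- as.integer(labels %||% x$labels)
  if (length(labels) == 0) stop("empty test set", call. = FALSE)
  net <- as_network(net)
  logits <- predict_logits(net, x)
  if (nrow(logits) != length(labels))
    stop("label count does not match input count", call. = FALSE)
  pred <- max.col(logits, ties.method = "first") - 1L
  K <- net$config$n_classes
  conf <- matrix(0L, K, K, dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  for (i in seq_along(labels)) {
    conf[labels[i] + 1L, pred[i] + 1L] <- conf[labels[i] + 1L, pred[i] + 1L] + 1L
  }
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = 100 * sum(tp) / length(labels),
                 macro_f1 = mean(f1), confusion = conf,
                 per_class_recall = rec),
            class = "irkd_eval")
}

#' @export
print.irkd_eval <- function(x, ...) {
  cat(sprintf("<irkd_eval> accuracy %.2f%%, macro-F1 %.4f (%d classes)\n",
              x$accuracy, x$macro_f1, nrow(x$confusion)))
  invisible(x)
}

#' Corruption specification
#'
#' Joint test-time corruption: one contiguous segment of
#' `round(missing_fraction * T)` time steps, at a seeded uniform-random
#' start, is zeroed across all channels ("continuous missing segment"),
#' and i.i.d. Gaussian noise of SD `noise_sd` is added to every sample.
#' Presets: level1 = (0.15, 0.06), level2 = (0.22, 0.09),
#' level3 = (0.30, 0.12).
#'
#' @param level preset name, or `NULL` to give `missing_fraction` /
#'   `noise_sd` directly.
#' @param missing_fraction fraction of time steps removed, in `[0, 1)`.
#' @param noise_sd Gaussian SD (>= 0), in units of the stored signal.
#' @return Object of class `corruption_spec`.
#' @export
corruption_spec <- function(level = NULL, missing_fraction = 0,
                            noise_sd = 0) {
  presets <- list(level1 = c(0.15, 0.06), level2 = c(0.22, 0.09),
                  level3 = c(0.30, 0.12))
  if (!is.null(level)) {
    level <- match.arg(level, names(presets))
    missing_fraction <- presets[[level]][1]
    noise_sd <- presets[[level]][2]
  } else level <- "custom"
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(missing_fraction = missing_fraction, noise_sd = noise_sd,
                 level_name = level), class = "corruption_spec")
}

#' Apply test-time corruption to windows
#'
#' Deterministic given the seed, so every model under comparison can be
#' evaluated on the identical corrupted test set.
#'
#' @param x a [window_set()] or `N x C x L` array.
#' @param spec a [corruption_spec()].
#' @param seed integer seed.
#' @return same type as `x`.
#' @export
corrupt_windows <- function(x, spec, seed = 1) {
  stopifnot(inherits(spec, "corruption_spec"))
  ws <- inherits(x, "window_set")
  w <- if (ws) x$windows else x
  d <- dim(w); n <- d[1]; Tn <- d[3]
  set.seed(seed)
  seg <- round(spec$missing_fraction * Tn)
  for (i in seq_len(n)) {
    if (seg > 0) {
      start <- sample.int(Tn - seg + 1, 1)
      w[i, , start:(start + seg - 1)] <- 0
    }
    if (spec$noise_sd > 0)
      w[i, , ] <- w[i, , ] + rnorm(d[2] * Tn, 0, spec$noise_sd)
  }
  if (ws) window_set(w, x$labels, x$subject_ids,
                     c(x$meta, list(corruption = spec$level_name)))
  else w
}

#' Re-estimate normalization running statistics
#'
#' One pass over the given inputs in accumulation mode: every batch's
#' per-channel mean and variance are averaged with equal weight and
#' installed as the running statistics (interpolated weight vectors carry
#' meaningless interpolated statistics, so the interpolation diagnostics
#' re-estimate them).
#'
#' @param net a `wrn_network`.
#' @param x inputs (`window_set`, `image_set`, or array).
#' @param batch_size pass batch size.
#' @return the network, invisibly.
#' @export
reestimate_bn <- function(net, x, batch_size = 64) {
  stopifnot(inherits(net, "wrn_network"))
  xall <- input_array(x)
  n <- n_samples_of(xall)
  .wrn_bn_accum_reset(net$ptr)
  for (b in seq(1, n, by = batch_size)) {
    idx <- b:min(b + batch_size - 1, n)
    bi <- batch_input(xall, idx)
    .wrn_forward(net$ptr, bi$x, bi$dims, 2L, FALSE)
    .wrn_bn_accum_add(net$ptr)
  }
  .wrn_bn_accum_finalize(net$ptr)
  invisible(net)
}

#' Accuracy along the line between two weight vectors
#'
#' Evaluates the network with parameters `(1 - eta) x_a + eta x_b` over a
#' grid of `eta`, re-estimating normalization statistics on the training
#' inputs at each point (set `reestimate = FALSE` to instead interpolate
#' the stored running statistics; that mode reproduces the endpoint
#' checkpoints exactly at `eta = 0` and `eta = 1`). A flat, high curve
#' means the two solutions lie in a connected low-loss region; a deep
#' valley means they sit in different basins.
#'
#' @param ckpt_a,ckpt_b `wrn_checkpoint`s of identical configuration.
#' @param train_set,test_set [window_set()]s used for re-estimation and
#'   evaluation.
#' @param eta_grid interpolation coefficients (default `seq(-1, 2, 0.25)`).
#' @param reestimate re-estimate normalization statistics per point.
#' @return data.frame with columns `eta`, `train_acc`, `test_acc`.
#' @export
parametric_curve <- function(ckpt_a, ckpt_b, train_set, test_set,
                             eta_grid = seq(-1, 2, by = 0.25),
                             reestimate = TRUE) {
  stopifnot(inherits(ckpt_a, "wrn_checkpoint"),
            inherits(ckpt_b, "wrn_checkpoint"))
  if (!config_equal(ckpt_a$config, ckpt_b$config))
    stop("checkpoints have different architectures", call. = FALSE)
  net <- build_wrn(ckpt_a$config)
  xtr <- input_array(train_set)
  xte <- input_array(test_set)
  out <- data.frame()
  for (eta in eta_grid) {
    load_params(net, interpolate_params(ckpt_a$params, ckpt_b$params, eta))
    if (reestimate) {
      reestimate_bn(net, train_set)
    } else {
      .wrn_set_running(net$ptr, interpolate_params(ckpt_a$running,
                                                   ckpt_b$running, eta))
    }
    tr <- accuracy_pct(max.col(forward_batches(net, xtr), ties.method = "first") - 1L,
                       train_set$labels)
    te <- accuracy_pct(max.col(forward_batches(net, xte), ties.method = "first") - 1L,
                       test_set$labels)
    out <- rbind(out, data.frame(eta = eta, train_acc = tr, test_acc = te))
  }
  out
}

#' V-measure between true labels and a clustering
#'
#' Harmonic mean of homogeneity (each cluster holds one class) and
#' completeness (each class sits in one cluster), both defined through
#' conditional entropies of the label/cluster contingency table.
#' Invariant to cluster relabeling; 1 when clusters reproduce the classes,
#' near 0 for random assignment.
#'
#' @param truth,pred equal-length label vectors (any codes).
#' @return value in `[0, 1]`.
#' @export
v_measure <- function(truth, pred) {
  n <- length(truth)
  stopifnot(length(pred) == n, n > 0)
  tab <- table(truth, pred) / n
  pc <- rowSums(tab); pk <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hc <- ent(pc); hk <- ent(pk)
  hck <- -sum(tab[tab > 0] *
                log(tab[tab > 0] / rep(pk, each = nrow(tab))[tab > 0]))
  hkc <- -sum(tab[tab > 0] *
                log(tab[tab > 0] / rep(pc, times = ncol(tab))[tab > 0]))
  h <- if (hc == 0) 1 else 1 - hck / hc
  c <- if (hk == 0) 1 else 1 - hkc / hk
  if (h + c == 0) 0 else 2 * h * c / (h + c)
}

#' Exact t-SNE embedding
#'
#' Small O(n^2) implementation of t-distributed stochastic neighbour
#' embedding (perplexity-calibrated Gaussian affinities, early
#' exaggeration, momentum gradient descent), sufficient for the few
#' hundred test windows the clustering diagnostics visualize.
#'
#' @param x numeric matrix, one observation per row.
#' @param dims output dimensionality (default 2).
#' @param perplexity neighbourhood size (capped at `(n - 1) / 3`).
#' @param max_iter gradient steps.
#' @param seed integer seed for the initial layout.
#' @return `n x dims` matrix.
#' @export
tsne_embed <- function(x, dims = 2, perplexity = 30, max_iter = 500,
                       seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  d2 <- as.matrix(stats::dist(x))^2
  # per-point bandwidths by bisection on the entropy
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  G <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 12 else 1
    mom <- if (iter <= 250) 0.5 else 0.8
    qd <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(qd) <- 0
    Q <- pmax(qd / sum(qd), 1e-12)
    W <- (ex * P - Q) * qd
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- pmax(0.01, ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8))
    G <- mom * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Clustering quality of learned features (V-score)
#'
#' Embeds penultimate-layer features with 2-D t-SNE, clusters the
#' embedding with seeded k-means (`k` = number of classes), and scores the
#' clustering against the true labels with the V-measure. This is the
#' package's concrete pathway for judging homogeneity/completeness of the
#' representation a trained student has learned; the clustering step is a
#' modelling choice, documented as such.
#'
#' @param features `n x d` feature matrix (see [network_features()]).
#' @param labels true labels.
#' @param k number of clusters (>= 2; default: number of distinct labels).
#' @param seed integer seed for t-SNE and k-means.
#' @param use_tsne set to `FALSE` to cluster the raw features directly.
#' @return value in `[0, 1]`.
#' @export
v_score <- function(features, labels, k = length(unique(labels)), seed = 1,
                    use_tsne = TRUE) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  emb <- if (use_tsne) tsne_embed(features, seed = seed) else as.matrix(features)
  set.seed(seed)
  km <- kmeans(emb, centers = k, nstart = 10, iter.max = 100)
  v_measure(labels, km$cluster)
}

#' Accuracy across the two-teacher balance
#'
#' Runs an independent two-teacher distillation per `alpha` per seed and
#' summarizes mean and SD of the final evaluation accuracy.
#'
#' @param alphas numeric vector of balance values in `[0, 1]`.
#' @param seeds integer vector; one run per (alpha, seed).
#' @param student_cfg,tcfg,train_set,eval_set,ir_train as in
#'   [train_network()].
#' @param teacher1,teacher2 frozen teacher checkpoints.
#' @param lambda,tau objective weights.
#' @param anneal_checkpoint optional annealing initializer.
#' @return data.frame `(alpha, mean_acc, sd_acc)` with the per-run table in
#'   attribute `"runs"`.
#' @export
alpha_sweep <- function(alphas, seeds, student_cfg, teacher1, teacher2,
                        tcfg, train_set, eval_set, ir_train,
                        lambda = 0.7, tau = 4, anneal_checkpoint = NULL) {
  if (any(alphas < 0 | alphas > 1))
    stop("alpha values must lie in [0, 1]", call. = FALSE)
  runs <- data.frame()
  for (a in alphas) for (s in seeds) {
    dcfg <- distill_config("kd_multi", lambda = lambda, tau = tau, alpha = a,
                           teacher1 = teacher1, teacher2 = teacher2,
                           anneal = !is.null(anneal_checkpoint),
                           anneal_checkpoint = anneal_checkpoint, seed = s)
    fit <- train_network(student_cfg, dcfg, tcfg, train_set, eval_set,
                         ir_train = ir_train)
    runs <- rbind(runs, data.frame(
      alpha = a, seed = s,
      acc = fit$history$eval_acc[nrow(fit$history)]))
  }
  out <- do.call(rbind, lapply(split(runs, runs$alpha), function(g) {
    data.frame(alpha = g$alpha[1], mean_acc = mean(g$acc),
               sd_acc = if (nrow(g) > 1) sd(g$acc) else 0)
  }))
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  out
}
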