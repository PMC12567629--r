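#' Optimizer and schedule configuration
#'
#' SGD with Nesterov-free momentum and L2 weight decay. The learning rate
#' is piecewise constant: `lr0` until the early drop epoch, times
#' `drop_factor` from there on, and additionally times `late_factor` at
#' every positive multiple of `late_every` epochs (default
#' `floor(epochs / 3)`).
#'
#' @param epochs total training epochs.
#' @param batch_size minibatch size.
#' @param momentum SGD momentum.
#' @param weight_decay L2 coefficient.
#' @param lr0 initial learning rate.
#' @param drop_epoch epoch of the early decay.
#' @param drop_factor early decay factor.
#' @param late_every period of the late decays; `NULL` means
#'   `floor(epochs / 3)`.
#' @param late_factor late decay factor.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 64, momentum = 0.9,
                         weight_decay = 1e-4, lr0 = 0.05, drop_epoch = 10,
                         drop_factor = 0.2, late_every = NULL,
                         late_factor = 0.1) {
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be positive",
                                         call. = FALSE)
  if (lr0 <= 0) stop("lr0 must be > 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, lr0 = lr0,
                 drop_epoch = as.integer(drop_epoch),
                 drop_factor = drop_factor,
                 late_every = as.integer(late_every %||% (epochs %/% 3)),
                 late_factor = late_factor),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param cfg a [train_config()].
#' @return numeric learning rate.
#' @export
lr_at_epoch <- function(epoch, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  lr <- cfg$lr0
  if (epoch >= cfg$drop_epoch) lr <- lr * cfg$drop_factor
  if (cfg$late_every > 0) lr <- lr * cfg$late_factor^(epoch %/% cfg$late_every)
  lr
}

#' Distillation run configuration
#'
#' Fully determines a student training run given a seed: the strategy
#' (plain cross-entropy training, single-teacher, or two-teacher
#' distillation), the loss weights, the frozen teacher checkpoints, and
#' optionally an annealing checkpoint whose weights initialize the student
#' in place of random initialization.
#'
#' @param strategy `"scratch"`, `"kd_single"`, or `"kd_multi"`.
#' @param lambda cross-entropy vs distillation balance in `[0, 1]`.
#' @param tau distillation temperature (> 0).
#' @param alpha teacher balance in `[0, 1]` (two-teacher runs only).
#' @param teacher1 checkpoint of the 1-D raw-series teacher (or `NULL`).
#' @param teacher2 checkpoint of the 2-D image-representation teacher (or
#'   `NULL`).
#' @param anneal logical; initialize from `anneal_checkpoint`.
#' @param anneal_checkpoint a `wrn_checkpoint` trained from scratch with
#'   the student's architecture (see [anneal_initialize()]).
#' @param seed integer seed for initialization and batch order.
#' @return Object of class `distill_config`.
#' @export
distill_config <- function(strategy = c("scratch", "kd_single", "kd_multi"),
                           lambda = 0.7, tau = 4, alpha = 0.5,
                           teacher1 = NULL, teacher2 = NULL,
                           anneal = FALSE, anneal_checkpoint = NULL,
                           seed = 1) {
  strategy <- match.arg(strategy)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  n_teachers <- sum(!is.null(teacher1), !is.null(teacher2))
  if (strategy == "kd_multi" && n_teachers != 2)
    stop("kd_multi requires both teacher1 and teacher2", call. = FALSE)
  if (strategy == "kd_single" && n_teachers != 1)
    stop("kd_single requires exactly one teacher", call. = FALSE)
  if (anneal && is.null(anneal_checkpoint))
    stop("anneal = TRUE requires anneal_checkpoint", call. = FALSE)
  structure(list(strategy = strategy, lambda = lambda, tau = tau,
                 alpha = alpha, teacher1 = teacher1, teacher2 = teacher2,
                 anneal = anneal, anneal_checkpoint = anneal_checkpoint,
                 seed = as.integer(seed)),
            class = "distill_config")
}

accuracy_pct <- function(pred, labels) 100 * mean(pred == labels)

#' Train a student (scratch, single-, or two-teacher distillation)
#'
#' Teachers are frozen: their logits over the training set are computed
#' once in evaluation mode and reused every epoch, so a distillation run
#' cannot alter them. The raw-series teacher consumes `train_set` itself;
#' the image teacher consumes `ir_train`, which must hold the image
#' representation of the same windows in the same order. Each epoch runs
#' seeded shuffled minibatch SGD with the [train_config()] schedule and
#' records loss components and accuracies.
#'
#' @param student_cfg [wrn_config()] of the (1-D) student.
#' @param dcfg a [distill_config()].
#' @param tcfg a [train_config()].
#' @param train_set,eval_set [window_set()]s of raw windows.
#' @param ir_train optional `image_set` aligned index-wise with
#'   `train_set` (required when `teacher2` is present).
#' @param teacher_logits optional `list(t1 =, t2 =)` of precomputed teacher
#'   logit matrices over `train_set` (teachers are frozen, so identical
#'   runs can share them instead of re-running the teachers' forward
#'   passes).
#' @param verbose print per-epoch progress.
#' @return Object of class `irkd_fit`: list with `checkpoint` (final),
#'   `best` (highest evaluation accuracy, earliest epoch on ties), and
#'   `history` (one row per epoch: lr, loss components, accuracies).
#' @export
train_network <- function(student_cfg, dcfg, tcfg, train_set, eval_set,
                          ir_train = NULL, teacher_logits = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(student_cfg, "wrn_config"),
            inherits(dcfg, "distill_config"), inherits(tcfg, "train_config"),
            inherits(train_set, "window_set"),
            inherits(eval_set, "window_set"))
  use_t1 <- dcfg$strategy != "scratch" && !is.null(dcfg$teacher1)
  use_t2 <- dcfg$strategy != "scratch" && !is.null(dcfg$teacher2)
  n <- dim(train_set$windows)[1]

  # frozen-teacher logits, computed once in evaluation mode
  lt1 <- teacher_logits$t1
  lt2 <- teacher_logits$t2
  if (use_t1 && is.null(lt1)) lt1 <- predict_logits(dcfg$teacher1, train_set)
  if (use_t2 && is.null(lt2)) {
    if (is.null(ir_train))
      stop("teacher2 is set but ir_train (its image inputs) is missing",
           call. = FALSE)
    if (dim(ir_train$pixels)[1] != n)
      stop("ir_train must pair index-wise with train_set", call. = FALSE)
    lt2 <- predict_logits(dcfg$teacher2, ir_train)
  }
  if (use_t1 && nrow(lt1) != n || use_t2 && nrow(lt2) != n)
    stop("teacher logits must pair index-wise with train_set", call. = FALSE)

  set.seed(dcfg$seed)
  net <- build_wrn(student_cfg)          # seeded random init
  if (dcfg$anneal) {
    if (!config_equal(dcfg$anneal_checkpoint$config, student_cfg))
      stop("anneal checkpoint architecture differs from the student",
           call. = FALSE)
    restore_network(dcfg$anneal_checkpoint, into = net)
    .wrn_reset_state(net$ptr)            # fresh momentum + running stats
    .wrn_set_running(net$ptr, dcfg$anneal_checkpoint$running)
  }

  xtr <- input_array(train_set)
  xev <- input_array(eval_set)
  lam <- if (dcfg$strategy == "scratch") 0 else dcfg$lambda
  alp <- if (dcfg$strategy == "kd_multi") dcfg$alpha else 0

  hist <- data.frame()
  best <- NULL; best_acc <- -Inf
  for (ep in seq_len(tcfg$epochs) - 1L) {
    lr <- lr_at_epoch(ep, tcfg)
    ord <- sample.int(n)
    ep_ce <- ep_k1 <- ep_k2 <- 0; nb <- 0
    correct <- 0
    for (b in seq(1, n, by = tcfg$batch_size)) {
      idx <- ord[b:min(b + tcfg$batch_size - 1, n)]
      bi <- batch_input(xtr, idx)
      logits <- .wrn_forward(net$ptr, bi$x, bi$dims, 1L, TRUE)
      yb <- train_set$labels[idx]
      g <- distill_logit_grad(logits, yb,
                              if (use_t1) lt1[idx, , drop = FALSE],
                              if (use_t2) lt2[idx, , drop = FALSE],
                              lambda = lam, alpha = alp, tau = dcfg$tau)
      .wrn_backward(net$ptr, g)
      .wrn_sgd_step(net$ptr, lr, tcfg$momentum, tcfg$weight_decay)
      ep_ce <- ep_ce + ce_loss(logits, yb)
      if (use_t1 && lam > 0)
        ep_k1 <- ep_k1 + kd_loss(lt1[idx, , drop = FALSE], logits, dcfg$tau)
      if (use_t2 && lam > 0)
        ep_k2 <- ep_k2 + kd_loss(lt2[idx, , drop = FALSE], logits, dcfg$tau)
      correct <- correct + sum(max.col(logits, ties.method = "first") - 1L == yb)
      nb <- nb + 1
    }
    ev_logits <- forward_batches(net, xev)
    ev_acc <- accuracy_pct(max.col(ev_logits, ties.method = "first") - 1L, eval_set$labels)
    hist <- rbind(hist, data.frame(
      epoch = ep, lr = lr, loss_ce = ep_ce / nb, loss_kd_t1 = ep_k1 / nb,
      loss_kd_t2 = ep_k2 / nb, train_acc = 100 * correct / n,
      eval_acc = ev_acc))
    if (ev_acc > best_acc) {             # strict: ties keep the earliest
      best_acc <- ev_acc
      best <- checkpoint(net, meta = list(epoch = ep, eval_acc = ev_acc))
    }
    if (verbose)
      message(sprintf("epoch %3d lr %.5f ce %.4f kd1 %.4f kd2 %.4f train %.2f eval %.2f",
                      ep, lr, ep_ce / nb, ep_k1 / nb, ep_k2 / nb,
                      100 * correct / n, ev_acc))
  }
  structure(list(
    checkpoint = checkpoint(net, meta = list(strategy = dcfg$strategy,
                                             seed = dcfg$seed,
                                             final_eval_acc = ev_acc)),
    best = best, history = hist), class = "irkd_fit")
}

#' @export
print.irkd_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<irkd_fit> %d epochs; final eval %.2f%%, best eval %.2f%% (epoch %d)\n",
              nrow(h), h$eval_acc[nrow(h)], x$best$meta$eval_acc,
              x$best$meta$epoch))
  invisible(x)
}

#' Annealing initialization: scratch-pretrain the student
#'
#' Trains a model with the student's exact architecture from scratch on
#' the raw series with cross-entropy only, under the full training
#' schedule. The resulting checkpoint initializes subsequent distillation
#' runs in place of random weights, which narrows the representational gap
#' to the image-teacher and stabilizes early distillation.
#'
#' @param student_cfg a 1-D [wrn_config()].
#' @param train_set,eval_set [window_set()]s.
#' @param tcfg a [train_config()].
#' @param seed integer seed.
#' @return The final `wrn_checkpoint` of the scratch run (with the fit in
#'   attribute `"fit"`).
#' @export
anneal_initialize <- function(student_cfg, train_set, eval_set, tcfg,
                              seed = 1) {
  if (student_cfg$dim != "1d")
    stop("the annealing student must be a 1-D network", call. = FALSE)
  fit <- train_network(student_cfg,
                       distill_config("scratch", seed = seed),
                       tcfg, train_set, eval_set)
  ck <- fit$checkpoint
  ck$meta$anneal <- TRUE
  attr(ck, "fit") <- fit
  ck
}
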