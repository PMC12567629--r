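#' Run a declarative distillation experiment
#'
#' Executes the full protocol from one configuration: simulate (or load)
#' the dataset, convert image representations, train the two teachers,
#' optionally scratch-pretrain the annealing initializer, distill the
#' student once per seed, and evaluate. Every stage artifact (teacher
#' checkpoints, image caches, annealing checkpoints, per-run histories) is
#' written under `output_dir` keyed by a hash of the stage configuration,
#' so re-running an unchanged experiment is a cache hit and re-running a
#' modified one recomputes only the affected stages.
#'
#' @param config a nested list (or path to a YAML file) with blocks
#'   `dataset` (`train` / `test` [synthetic_spec()] argument lists, or
#'   `train_dir` / `test_dir` paths), `representation` (`kind`,
#'   [window_to_image()] options), `models` (`teacher1` / `teacher2` /
#'   `student` [wrn_config()] argument lists), `distill` (`strategy`,
#'   `lambda`, `tau`, `alpha`, `anneal`), `train` ([train_config()]
#'   arguments), `seeds` (integer vector) and `output_dir`.
#' @param verbose print stage progress.
#' @return list with `summary` (one row: mean and SD of final student
#'   accuracy over seeds), `runs`, and artifact paths; also written to
#'   `output_dir` as CSV plus a JSON manifest of config hashes.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir %||% stop("config needs output_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- as.integer(config$seeds %||% stop("config needs seeds", call. = FALSE))
  if (length(seeds) == 0) stop("seeds must be non-empty", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  dist_block <- config$distill %||% list()
  strategy <- dist_block$strategy %||% "kd_multi"
  m <- config$models %||% stop("config needs a models block", call. = FALSE)
  # fail fast on inconsistent teacher blocks, before any training
  if (strategy == "kd_multi" && (is.null(m$teacher1) || is.null(m$teacher2)))
    stop("kd_multi requires models$teacher1 and models$teacher2", call. = FALSE)
  if (strategy == "kd_single" &&
      sum(!is.null(m$teacher1), !is.null(m$teacher2)) != 1)
    stop("kd_single requires exactly one teacher model block", call. = FALSE)

  manifest <- list()
  stage <- function(name, cfg, producer) {
    key <- content_hash(cfg)
    path <- file.path(out_dir, paste0(name, "_", substr(key, 1, 12), ".rds"))
    manifest[[name]] <<- list(hash = key, path = path)
    if (file.exists(path)) {
      say("stage %s: cache hit", name)
      return(readRDS(path))
    }
    say("stage %s: computing", name)
    val <- tryCatch(producer(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    saveRDS(val, path)
    val
  }

  ds_cfg <- config$dataset %||% stop("config needs a dataset block", call. = FALSE)
  data <- stage("dataset", ds_cfg, function() {
    if (!is.null(ds_cfg$train_dir)) {
      list(train = read_window_set(ds_cfg$train_dir),
           test = read_window_set(ds_cfg$test_dir))
    } else {
      list(train = generate_activity_dataset(do.call(synthetic_spec, ds_cfg$train)),
           test = generate_activity_dataset(do.call(synthetic_spec, ds_cfg$test)))
    }
  })

  rep_cfg <- config$representation %||% list(kind = "gaf")
  student_cfg <- do.call(wrn_config, m$student)
  tcfg <- do.call(train_config, config$train %||% list())
  base_seed <- seeds[1]

  use_t2 <- !is.null(m$teacher2) && strategy != "scratch" &&
    !(strategy == "kd_single" && is.null(m$teacher2))
  use_t1 <- !is.null(m$teacher1) && strategy != "scratch"

  ir_train <- NULL
  t1 <- t2 <- NULL
  if (use_t1) {
    t1_cfg <- do.call(wrn_config, m$teacher1)
    t1 <- stage("teacher1", list(m$teacher1, ds_cfg, config$train, base_seed),
                function() {
      train_network(t1_cfg, distill_config("scratch", seed = base_seed),
                    tcfg, data$train, data$test)$checkpoint
    })
  }
  if (use_t2) {
    ir_train <- stage("ir_train", list(ds_cfg, rep_cfg), function() {
      do.call(windows_to_images, c(list(data$train), rep_cfg[names(rep_cfg) != "kind"],
                                   list(kind = rep_cfg$kind %||% "gaf")))
    })
    ir_test <- stage("ir_test", list(ds_cfg, rep_cfg, "test"), function() {
      do.call(windows_to_images, c(list(data$test), rep_cfg[names(rep_cfg) != "kind"],
                                   list(kind = rep_cfg$kind %||% "gaf")))
    })
    t2_cfg <- do.call(wrn_config, m$teacher2)
    t2 <- stage("teacher2", list(m$teacher2, ds_cfg, rep_cfg, config$train,
                                 base_seed), function() {
      train_image_teacher(t2_cfg, ir_train, ir_test, data$train$labels,
                          data$test$labels, tcfg, base_seed)
    })
  }

  anneal_ck <- NULL
  if (isTRUE(dist_block$anneal)) {
    anneal_ck <- lapply(seeds, function(s)
      stage(paste0("anneal_seed", s),
            list(m$student, ds_cfg, config$train, s), function() {
        anneal_initialize(student_cfg, data$train, data$test, tcfg, seed = s)
      }))
    names(anneal_ck) <- as.character(seeds)
  }

  runs <- data.frame()
  for (s in seeds) {
    fit <- stage(paste0("student_seed", s),
                 list(config[setdiff(names(config), "output_dir")], s),
                 function() {
      dcfg <- distill_config(strategy,
                             lambda = dist_block$lambda %||% 0.7,
                             tau = dist_block$tau %||% 4,
                             alpha = dist_block$alpha %||% 0.5,
                             teacher1 = t1, teacher2 = t2,
                             anneal = isTRUE(dist_block$anneal),
                             anneal_checkpoint = anneal_ck[[as.character(s)]],
                             seed = s)
      train_network(student_cfg, dcfg, tcfg, data$train, data$test,
                    ir_train = ir_train)
    })
    write.csv(fit$history,
              file.path(out_dir, sprintf("history_seed%d.csv", s)),
              row.names = FALSE)
    runs <- rbind(runs, data.frame(
      seed = s, final_acc = fit$history$eval_acc[nrow(fit$history)],
      best_acc = fit$best$meta$eval_acc))
  }
  summary <- data.frame(
    strategy = strategy, n_seeds = length(seeds),
    mean_acc = mean(runs$final_acc),
    sd_acc = if (nrow(runs) > 1) sd(runs$final_acc) else 0)
  write.csv(runs, file.path(out_dir, "runs.csv"), row.names = FALSE)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  list(summary = summary, runs = runs, manifest = manifest,
       output_dir = out_dir)
}

# scratch-train a 2-D teacher on image representations
train_image_teacher <- function(cfg, ir_train, ir_eval, labels_train,
                                labels_eval, tcfg, seed, verbose = FALSE) {
  train_network_images(cfg, tcfg, ir_train, labels_train, ir_eval,
                       labels_eval, seed, verbose)
}

train_network_images <- function(cfg, tcfg, ir_train, labels_train, ir_eval,
                                 labels_eval, seed, verbose = FALSE,
                                 eval_every = 5) {
  set.seed(seed)
  net <- build_wrn(cfg)
  xtr <- input_array(ir_train)
  xev <- input_array(ir_eval)
  n <- n_samples_of(xtr)
  hist <- data.frame()
  for (ep in seq_len(tcfg$epochs) - 1L) {
    lr <- lr_at_epoch(ep, tcfg)
    ord <- sample.int(n)
    correct <- 0; ep_ce <- 0; nb <- 0
    for (b in seq(1, n, by = tcfg$batch_size)) {
      idx <- ord[b:min(b + tcfg$batch_size - 1, n)]
      bi <- batch_input(xtr, idx)
      logits <- .wrn_forward(net$ptr, bi$x, bi$dims, 1L, TRUE)
      yb <- labels_train[idx]
      g <- distill_logit_grad(logits, yb, lambda = 0)
      .wrn_backward(net$ptr, g)
      .wrn_sgd_step(net$ptr, lr, tcfg$momentum, tcfg$weight_decay)
      ep_ce <- ep_ce + ce_loss(logits, yb)
      correct <- correct + sum(max.col(logits, ties.method = "first") - 1L == yb)
      nb <- nb + 1
    }
    ev <- if (ep %% eval_every == 0 || ep == tcfg$epochs - 1L)
      accuracy_pct(max.col(forward_batches(net, xev), ties.method = "first") - 1L, labels_eval)
    else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, loss_ce = ep_ce / nb,
                                   train_acc = 100 * correct / n,
                                   eval_acc = ev))
    if (verbose)
      message(sprintf("epoch %3d lr %.5f ce %.4f train %.2f eval %.2f",
                      ep, lr, ep_ce / nb, 100 * correct / n, ev))
  }
  ck <- checkpoint(net, meta = list(seed = seed, final_eval_acc = ev))
  attr(ck, "history") <- hist
  ck
}

#' Architecture report for the teacher/student pairings
#'
#' Builds every teacher pairing of the 14-class, 3-channel configuration
#' (WRN16-1, WRN16-3, WRN28-1, WRN28-3 in 1-D and 2-D) together with the
#' 1-D WRN16-1 student, and reports exact trainable-parameter counts (in
#' millions, 2 decimals) and the two-teacher compression ratios.
#'
#' @param n_classes,in_channels dataset shape (defaults 14 classes, 3
#'   channels).
#' @return data.frame, one row per teacher architecture.
#' @export
table1_report <- function(n_classes = 14, in_channels = 3) {
  student_n <- count_params(wrn_config(16, 1, "1d", in_channels, n_classes))
  rows <- lapply(list(c(16, 1), c(16, 3), c(28, 1), c(28, 3)), function(dw) {
    n1 <- count_params(wrn_config(dw[1], dw[2], "1d", in_channels, n_classes))
    n2 <- count_params(wrn_config(dw[1], dw[2], "2d", in_channels, n_classes))
    data.frame(teacher = sprintf("WRN%d-%d", dw[1], dw[2]),
               params_1d_M = round(n1 / 1e6, 2),
               params_2d_M = round(n2 / 1e6, 2),
               student_M = round(student_n / 1e6, 2),
               compression_pct = compression_ratio(student_n, n1, n2))
  })
  do.call(rbind, rows)
}

#' Run a strategy grid (distillation suite)
#'
#' Executes [run_experiment()] once per strategy (each in its own
#' subdirectory of `output_dir`, with stage caching inside) and binds the
#' per-strategy mean/SD summaries into one comparison table.
#'
#' @param config as in [run_experiment()], with `distill$strategy` a
#'   character vector of strategies to compare.
#' @param verbose print stage progress.
#' @return data.frame of per-strategy summaries (attribute `"results"`
#'   holds the full per-run outputs).
#' @export
distill_suite <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  strategies <- config$distill$strategy %||% c("scratch", "kd_multi")
  out_root <- config$output_dir
  results <- lapply(strategies, function(st) {
    cfg <- config
    cfg$distill$strategy <- st
    cfg$output_dir <- file.path(out_root, st)
    run_experiment(cfg, verbose = verbose)
  })
  summary <- do.call(rbind, lapply(results, `[[`, "summary"))
  write.csv(summary, file.path(out_root, "suite_summary.csv"),
            row.names = FALSE)
  attr(summary, "results") <- results
  summary
}
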