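make_constant_net <- function(cfg, class0 = 0L) {
  # zero all weights, then bias the classifier toward one class
  net <- build_wrn(cfg, seed = 1)
  v <- rep(0, count_params(net))
  lay <- irkd:::.wrn_layout(net$ptr)
  fb <- lay[lay$type == "fc_b", ]
  v[fb$offset + class0] <- 10
  load_params(net, v)
  net
}

test_that("evaluation reports exact metrics for degenerate predictors", {
  cfg <- tiny_wrn(n_classes = 2)
  ds <- tiny_dataset(n_classes = 2, windows_per_class = 10)
  net <- make_constant_net(cfg, class0 = 0L)
  ev <- evaluate_network(net, ds)
  expect_equal(ev$accuracy, 50)
  expect_equal(ev$macro_f1, 1 / 3)   # F1 = (2/3 + 0) / 2
  expect_equal(unname(ev$confusion[, 1]), c(10, 10))
  expect_equal(unname(ev$per_class_recall), c(1, 0))
  expect_error(evaluate_network(net, ds, labels = integer(0)), "empty")
})

test_that("confusion rows conserve class counts and evaluation ignores sample order", {
  ds <- tiny_dataset(windows_per_class = 8)
  net <- build_wrn(tiny_wrn(), seed = 4)
  ev <- evaluate_network(net, ds)
  expect_equal(unname(rowSums(ev$confusion)),
               as.vector(table(factor(ds$labels, levels = 0:2))))
  perm <- sample(dim(ds$windows)[1])
  ev2 <- evaluate_network(net, subset_window_set(ds, perm))
  expect_equal(ev2$accuracy, ev$accuracy)
  expect_equal(ev2$macro_f1, ev$macro_f1)
})

test_that("corruption zeroes exactly the preset segment length and recovers the noise scale", {
  expect_equal(round(corruption_spec("level1")$missing_fraction * 500), 75)
  expect_equal(round(corruption_spec("level2")$missing_fraction * 500), 110)
  expect_equal(round(corruption_spec("level3")$missing_fraction * 500), 150)

  w <- array(1, c(20, 2, 500))
  out <- corrupt_windows(w, corruption_spec(missing_fraction = 0.15,
                                            noise_sd = 0), seed = 2)
  zeroed <- apply(out == 0, 1, function(m) sum(m[1, ]))
  expect_true(all(zeroed == 75))
  # the segment is contiguous and shared across channels
  i <- which(out[1, 1, ] == 0)
  expect_equal(i, seq(min(i), min(i) + 74))
  expect_equal(which(out[1, 2, ] == 0), i)

  # identity corruption
  expect_identical(corrupt_windows(w, corruption_spec(missing_fraction = 0,
                                                      noise_sd = 0)), w)

  # noise SD estimated on the untouched region, 100 windows
  s <- 0.06
  w2 <- array(0, c(100, 1, 500))
  out2 <- corrupt_windows(w2, corruption_spec(missing_fraction = 0.15,
                                              noise_sd = s), seed = 3)
  set.seed(3)  # replay the generator's draw order to recover segment starts
  starts <- integer(100)
  for (i in 1:100) {
    starts[i] <- sample.int(500 - 75 + 1, 1)
    rnorm(500)
  }
  sds <- vapply(1:100, function(i)
    sd(out2[i, 1, -(starts[i]:(starts[i] + 74))]), 0)
  expect_lt(abs(mean(sds) - s) / s, 0.05)

  expect_error(corruption_spec(missing_fraction = 1), "missing_fraction")
})

test_that("interpolation curves reproduce checkpoint accuracies exactly at the endpoints", {
  tr <- tiny_dataset(seed = 61)
  te <- tiny_dataset(seed = 62, windows_per_class = 4, subject_offset = 4)
  cfg <- tiny_wrn()
  tc <- tiny_train_config(epochs = 2)
  ck_a <- train_network(cfg, distill_config("scratch", seed = 1), tc, tr, te)$checkpoint
  ck_b <- train_network(cfg, distill_config("scratch", seed = 2), tc, tr, te)$checkpoint
  curve <- parametric_curve(ck_a, ck_b, tr, te, eta_grid = c(0, 0.5, 1),
                            reestimate = FALSE)
  expect_equal(curve$test_acc[1], evaluate_network(ck_a, te)$accuracy)
  expect_equal(curve$test_acc[3], evaluate_network(ck_b, te)$accuracy)
  # identical endpoints give a flat line
  flat <- parametric_curve(ck_a, ck_a, tr, te, eta_grid = c(0, 0.5, 1),
                           reestimate = FALSE)
  expect_true(all(flat$test_acc == flat$test_acc[1]))
  # default grid covers [-1, 2] in steps of 0.25
  expect_equal(nrow(parametric_curve(ck_a, ck_a, tr, te,
                                     eta_grid = seq(-1, 2, 0.25),
                                     reestimate = FALSE)), 13)
  other <- train_network(wrn_config(16, 2, "1d", 2, 3, 64),
                         distill_config("scratch", seed = 1), tc, tr,
                         te)$checkpoint
  expect_error(parametric_curve(ck_a, other, tr, te), "architecture")
})

test_that("normalization re-estimation reproduces large-batch statistics behaviour", {
  tr <- tiny_dataset(seed = 71, windows_per_class = 16)
  net <- build_wrn(tiny_wrn(), seed = 3)
  before <- irkd:::.wrn_get_running(net$ptr)
  reestimate_bn(net, tr, batch_size = 16)
  after <- irkd:::.wrn_get_running(net$ptr)
  expect_false(identical(before, after))
  # re-running the same pass is idempotent
  reestimate_bn(net, tr, batch_size = 16)
  expect_identical(after, irkd:::.wrn_get_running(net$ptr))
})

test_that("the V-measure has its defining fixed points and invariances", {
  y <- rep(0:2, each = 20)
  expect_equal(v_measure(y, y), 1)
  relab <- c(5, 9, 7)[y + 1]
  expect_equal(v_measure(y, relab), 1)
  set.seed(2)
  rand <- sample(0:9, 6000, replace = TRUE)
  truth <- rep(0:2, 2000)
  expect_lt(v_measure(truth, rand), 0.05)
  # merging all clusters: completeness 1, homogeneity 0 -> score 0
  expect_equal(v_measure(y, rep(1, 60)), 0)
})

test_that("the V-score pipeline scores separable features high and is seed-stable", {
  set.seed(5)
  n <- 60
  labs <- rep(0:2, each = n / 3)
  feats <- matrix(rnorm(n * 8, sd = 0.15), n, 8) + labs * 2
  v <- v_score(feats, labs, k = 3, seed = 1)
  expect_gt(v, 0.9)
  expect_identical(v, v_score(feats, labs, k = 3, seed = 1))
  expect_error(v_score(feats, labs, k = 1), "k")
  v_raw <- v_score(feats, labs, k = 3, seed = 1, use_tsne = FALSE)
  expect_gt(v_raw, 0.9)
})

test_that("the alpha sweep emits one aggregated row per balance value", {
  tr <- tiny_dataset(seed = 81)
  te <- tiny_dataset(seed = 82, windows_per_class = 4, subject_offset = 4)
  cfg <- tiny_wrn()
  tc <- tiny_train_config(epochs = 1)
  t1 <- train_network(cfg, distill_config("scratch", seed = 1), tc, tr, te)$checkpoint
  ir_tr <- windows_to_images(tr, kind = "gaf", resolution = 16)
  ir_te <- windows_to_images(te, kind = "gaf", resolution = 16)
  t2 <- irkd:::train_image_teacher(
    tiny_wrn("2d", in_channels = 2, input_size = c(16, 16)),
    ir_tr, ir_te, tr$labels, te$labels, tc, seed = 2)
  sw <- alpha_sweep(c(0.3, 0.7), seeds = 1, student_cfg = cfg,
                    teacher1 = t1, teacher2 = t2, tcfg = tc,
                    train_set = tr, eval_set = te, ir_train = ir_tr)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$alpha, c(0.3, 0.7))
  expect_equal(sw$sd_acc, c(0, 0))
  runs <- attr(sw, "runs")
  expect_equal(sw$mean_acc, runs$acc[match(sw$alpha, runs$alpha)])
  expect_error(alpha_sweep(c(-0.1), 1, cfg, t1, t2, tc, tr, te, ir_tr),
               "alpha")
})
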