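test_that("the learning-rate schedule follows the early drop plus periodic decay rule", {
  tc <- train_config(epochs = 200)
  expect_equal(lr_at_epoch(0, tc), 0.05)
  expect_equal(lr_at_epoch(9, tc), 0.05)
  expect_equal(lr_at_epoch(10, tc), 0.01)
  # with t = 200 the decay period is 66: drops at 66, 132, 198
  expect_equal(lr_at_epoch(65, tc), 0.01)
  expect_equal(lr_at_epoch(66, tc), 0.001)
  expect_equal(lr_at_epoch(140, tc), 1e-4)
  expect_equal(lr_at_epoch(198, tc), 1e-5)
  # full enumeration: piecewise constant, non-increasing
  lrs <- vapply(0:199, lr_at_epoch, 0, cfg = tc)
  expect_true(all(diff(lrs) <= 0))
})

test_that("distillation configs enforce the teacher-count invariants", {
  ck <- checkpoint(build_wrn(tiny_wrn(), seed = 1))
  expect_error(distill_config("kd_multi", teacher1 = ck), "both")
  expect_error(distill_config("kd_single"), "exactly one")
  expect_error(distill_config("kd_single", teacher1 = ck, teacher2 = ck),
               "exactly one")
  expect_error(distill_config("scratch", anneal = TRUE), "anneal_checkpoint")
  expect_silent(distill_config("kd_single", teacher2 = ck))
})

test_that("training is reproducible and a zero distillation weight reproduces the scratch trajectory", {
  tr <- tiny_dataset(seed = 31)
  te <- tiny_dataset(seed = 32, windows_per_class = 4, subject_offset = 4)
  cfg <- tiny_wrn()
  tc <- tiny_train_config(epochs = 2)

  fit_a <- train_network(cfg, distill_config("scratch", seed = 5), tc, tr, te)
  fit_b <- train_network(cfg, distill_config("scratch", seed = 5), tc, tr, te)
  expect_identical(fit_a$checkpoint$params, fit_b$checkpoint$params)
  expect_identical(fit_a$history, fit_b$history)
  fit_c <- train_network(cfg, distill_config("scratch", seed = 6), tc, tr, te)
  expect_false(identical(fit_a$checkpoint$params, fit_c$checkpoint$params))

  t1 <- fit_a$checkpoint
  t2 <- irkd:::train_image_teacher(
    tiny_wrn("2d", in_channels = 2, input_size = c(16, 16)),
    windows_to_images(tr, kind = "gaf", resolution = 16),
    windows_to_images(te, kind = "gaf", resolution = 16),
    tr$labels, te$labels, tc, seed = 9)
  ir_tr <- windows_to_images(tr, kind = "gaf", resolution = 16)
  fit_kd0 <- train_network(cfg,
                           distill_config("kd_multi", lambda = 0,
                                          teacher1 = t1, teacher2 = t2,
                                          seed = 5),
                           tc, tr, te, ir_train = ir_tr)
  expect_identical(fit_kd0$checkpoint$params, fit_a$checkpoint$params)
})

test_that("teachers stay frozen through a distillation run and history tracks all components", {
  tr <- tiny_dataset(seed = 41)
  te <- tiny_dataset(seed = 42, windows_per_class = 4, subject_offset = 4)
  cfg <- tiny_wrn()
  tc <- tiny_train_config(epochs = 2)
  t1 <- train_network(cfg, distill_config("scratch", seed = 1), tc, tr, te)$checkpoint
  t2 <- irkd:::train_image_teacher(
    tiny_wrn("2d", in_channels = 2, input_size = c(16, 16)),
    windows_to_images(tr, kind = "gaf", resolution = 16),
    windows_to_images(te, kind = "gaf", resolution = 16),
    tr$labels, te$labels, tc, seed = 2)
  t1_before <- t1$params
  t2_before <- t2$params
  ir_tr <- windows_to_images(tr, kind = "gaf", resolution = 16)
  fit <- train_network(cfg,
                       distill_config("kd_multi", lambda = 0.7, alpha = 0.3,
                                      teacher1 = t1, teacher2 = t2, seed = 3),
                       tc, tr, te, ir_train = ir_tr)
  expect_identical(t1$params, t1_before)
  expect_identical(t2$params, t2_before)
  h <- fit$history
  expect_equal(nrow(h), 2)
  expect_true(all(c("epoch", "lr", "loss_ce", "loss_kd_t1", "loss_kd_t2",
                    "train_acc", "eval_acc") %in% names(h)))
  expect_true(all(is.finite(h$eval_acc)))
  expect_true(all(h$loss_kd_t1 > 0) && all(h$loss_kd_t2 > 0))
  expect_error(train_network(cfg,
                             distill_config("kd_multi", teacher1 = t1,
                                            teacher2 = t2, seed = 3),
                             tc, tr, te),
               "ir_train")
})

test_that("annealing initialization hands the student the scratch weights at epoch zero", {
  tr <- tiny_dataset(seed = 51)
  te <- tiny_dataset(seed = 52, windows_per_class = 4, subject_offset = 4)
  cfg <- tiny_wrn()
  tc <- tiny_train_config(epochs = 2)
  ann <- anneal_initialize(cfg, tr, te, tc, seed = 11)
  expect_s3_class(ann, "wrn_checkpoint")
  expect_true(ann$meta$anneal)
  ann2 <- anneal_initialize(cfg, tr, te, tc, seed = 11)
  expect_identical(ann$params, ann2$params)

  t1 <- train_network(cfg, distill_config("scratch", seed = 1), tc, tr,
                      te)$checkpoint
  # zero-epoch distillation run: the returned weights are the initializer's
  fit0 <- train_network(cfg,
                        distill_config("kd_single", teacher1 = t1,
                                       anneal = TRUE, anneal_checkpoint = ann,
                                       seed = 12),
                        train_config(epochs = 1, batch_size = 16,
                                     lr0 = 1e-12),
                        tr, te)
  drift <- max(abs(fit0$checkpoint$params - ann$params))
  expect_lt(drift, 1e-6)
  # without annealing the start is the seeded random initializer instead
  fit_r <- train_network(cfg,
                         distill_config("kd_single", teacher1 = t1,
                                        seed = 12),
                         train_config(epochs = 1, batch_size = 16,
                                      lr0 = 1e-12),
                         tr, te)
  set.seed(12)
  ref <- flatten_params(build_wrn(cfg))
  expect_lt(max(abs(fit_r$checkpoint$params - ref)), 1e-6)
  # architecture mismatch is rejected before any training
  other <- wrn_config(16, 2, "1d", 2, 3, 64)
  expect_error(train_network(other,
                             distill_config("kd_single", teacher1 = t1,
                                            anneal = TRUE,
                                            anneal_checkpoint = ann,
                                            seed = 1),
                             tc, tr, te),
               "architecture|match|differs")
})
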