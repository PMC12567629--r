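# The scaled-down distillation study shared by the acceptance assertions:
# 5 activity classes, 3 channels, 500-sample windows, 200 windows/class for
# training (16 subjects) and 50/class for testing (4 held-out subjects),
# noise SD 0.3; WRN16-1 teachers (1-D raw, 2-D GASF) trained 30 epochs;
# WRN16-1 students distilled 30 epochs with lambda 0.7, tau 4, alpha 0.3
# over three seeds. Computed once and reused by every assertion that needs
# it.

.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!is.null(.study_cache$res)) return(.study_cache$res)

  train_set <- generate_activity_dataset(synthetic_spec(
    n_classes = 5, n_subjects = 16, windows_per_class = 200, channels = 3,
    window_length = 500, sample_rate = 100, noise_sd = 0.3, seed = 101))
  test_set <- generate_activity_dataset(synthetic_spec(
    n_classes = 5, n_subjects = 4, windows_per_class = 50, channels = 3,
    window_length = 500, sample_rate = 100, noise_sd = 0.3, seed = 102,
    subject_offset = 16))

  tc <- train_config(epochs = 30)
  student_cfg <- wrn_config(16, 1, "1d", 3, 5, 500)
  teacher2_cfg <- wrn_config(16, 1, "2d", 3, 5, c(64, 64))
  seeds <- 1:3

  teacher1 <- train_network(student_cfg, distill_config("scratch", seed = 11),
                            tc, train_set, test_set)$checkpoint
  ir_train <- windows_to_images(train_set, kind = "gaf")
  ir_test <- windows_to_images(test_set, kind = "gaf")
  teacher2 <- irkd:::train_image_teacher(teacher2_cfg, ir_train, ir_test,
                                         train_set$labels, test_set$labels,
                                         tc, seed = 12)
  lt <- list(t1 = predict_logits(teacher1, train_set),
             t2 = predict_logits(teacher2, ir_train))

  scratch <- lapply(seeds, function(s)
    anneal_initialize(student_cfg, train_set, test_set, tc, seed = s))
  kdm <- lapply(seeds, function(s)
    train_network(student_cfg,
                  distill_config("kd_multi", lambda = 0.7, tau = 4,
                                 alpha = 0.3, teacher1 = teacher1,
                                 teacher2 = teacher2, anneal = TRUE,
                                 anneal_checkpoint = scratch[[s]], seed = s),
                  tc, train_set, test_set, ir_train = ir_train,
                  teacher_logits = lt))

  scratch_acc <- vapply(scratch, function(ck) {
    h <- attr(ck, "fit")$history
    h$eval_acc[nrow(h)]
  }, 0)
  kdm_acc <- vapply(kdm, function(f) f$history$eval_acc[nrow(f$history)], 0)

  etas <- c(0, 0.25, 0.5, 0.75, 1)
  curve_ann <- parametric_curve(strip_fit(scratch[[1]]), kdm[[1]]$checkpoint,
                                train_set, test_set, eta_grid = etas)
  curve_indep <- parametric_curve(strip_fit(scratch[[1]]),
                                  strip_fit(scratch[[2]]),
                                  train_set, test_set, eta_grid = etas)

  levels <- c("clean", "level1", "level2", "level3")
  corr_acc <- sapply(levels, function(lv) {
    ts <- if (lv == "clean") test_set
          else corrupt_windows(test_set, corruption_spec(lv), seed = 424242)
    vapply(kdm, function(f) evaluate_network(f$checkpoint, ts)$accuracy, 0)
  })

  .study_cache$res <- list(
    scratch_acc = scratch_acc, kdm_acc = kdm_acc,
    curve_ann = curve_ann, curve_indep = curve_indep,
    corr_acc = corr_acc)
  .study_cache$res
}

strip_fit <- function(ck) {
  attr(ck, "fit") <- NULL
  ck
}
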