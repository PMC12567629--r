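test_that("networks produce logits of the contracted shape in both dimensionalities", {
  net1 <- build_wrn(wrn_config(16, 1, "1d", 3, 14, 500), seed = 1)
  x <- array(rnorm(2 * 3 * 100), c(2, 3, 100))
  expect_equal(dim(predict_logits(net1, x)), c(2, 14))

  net2 <- build_wrn(wrn_config(16, 1, "2d", 3, 14, c(32, 32)), seed = 1)
  xi <- array(rnorm(2 * 3 * 32 * 32), c(2, 3, 32, 32))
  expect_equal(dim(predict_logits(net2, xi)), c(2, 14))

  expect_error(wrn_config(17, 1, "1d"), "depth")
  expect_error(wrn_config(16, 0, "1d"), "width")
})

test_that("parameter accounting reproduces the published teacher/student table", {
  cases <- list(
    list(16, 1, "1d", 0.06), list(16, 3, "1d", 0.54),
    list(28, 1, "1d", 0.13), list(28, 3, "1d", 1.12),
    list(16, 1, "2d", 0.18), list(16, 3, "2d", 1.55),
    list(28, 1, "2d", 0.37))
  for (cs in cases) {
    cfg <- wrn_config(cs[[1]], cs[[2]], cs[[3]], 3, 14)
    expect_equal(count_params(cfg, millions = TRUE), cs[[4]],
                 info = sprintf("WRN%d-%d %s", cs[[1]], cs[[2]], cs[[3]]))
  }
})

test_that("two-teacher compression ratios come out of exact counts", {
  expect_equal(compression_ratio(1, 1, 3), 25)
  s <- count_params(wrn_config(16, 1, "1d", 3, 14))
  pairs <- list(c(16, 1, 25.93), c(16, 3, 2.94), c(28, 1, 12.36),
                c(28, 3, 1.39))
  for (p in pairs) {
    t1 <- count_params(wrn_config(p[1], p[2], "1d", 3, 14))
    t2 <- count_params(wrn_config(p[1], p[2], "2d", 3, 14))
    expect_equal(compression_ratio(s, t1, t2), p[3])
  }
  expect_error(compression_ratio(0, 1, 1), "positive")
})

test_that("parameter count is independent of the input size (global pooling)", {
  a <- count_params(wrn_config(16, 1, "1d", 3, 14, input_size = 100))
  b <- count_params(wrn_config(16, 1, "1d", 3, 14, input_size = 500))
  expect_identical(a, b)
})

test_that("flatten/load round trips exactly and zero weights silence the network", {
  cfg <- tiny_wrn()
  net <- build_wrn(cfg, seed = 3)
  x <- array(rnorm(4 * 2 * 64), c(4, 2, 64))
  l0 <- predict_logits(net, x)
  v <- flatten_params(net)
  load_params(net, v)
  expect_identical(predict_logits(net, x), l0)
  load_params(net, rep(0, length(v)))
  expect_true(all(predict_logits(net, x) == 0))
  expect_error(load_params(net, v[-1]), "length")
  net_b <- build_wrn(cfg, seed = 99)
  expect_length(flatten_params(net_b), length(v))
})

test_that("weight-vector interpolation has exact endpoints and extrapolation", {
  a <- c(1, 2, 3); b <- c(3, 0, -1)
  expect_identical(interpolate_params(a, b, 0), a)
  expect_identical(interpolate_params(a, b, 1), b)
  expect_identical(interpolate_params(a, a, 0.5), a)
  expect_identical(interpolate_params(a, b, 2), 2 * b - a)
  expect_error(interpolate_params(a, b[-1], 0.5), "length")
})

test_that("checkpoints restore into equal-architecture networks only, reproducing outputs", {
  cfg <- tiny_wrn()
  net <- build_wrn(cfg, seed = 5)
  x <- array(rnorm(3 * 2 * 64), c(3, 2, 64))
  l0 <- predict_logits(net, x)
  ck <- checkpoint(net)
  back <- restore_network(ck)
  expect_identical(predict_logits(back, x), l0)
  other <- build_wrn(wrn_config(16, 2, "1d", 2, 3, 64))
  expect_error(restore_network(ck, into = other), "match")

  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  expect_identical(predict_logits(load_checkpoint(path), x), l0)
  unlink(path)
})

test_that("evaluation-mode forward passes are deterministic", {
  net <- build_wrn(tiny_wrn(), seed = 2)
  x <- array(rnorm(5 * 2 * 64), c(5, 2, 64))
  expect_identical(predict_logits(net, x), predict_logits(net, x))
})
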