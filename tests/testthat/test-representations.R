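test_that("unit rescaling maps extremes to +/-1 and constants to zero", {
  expect_equal(rescale_unit(c(0, 5, 10)), c(-1, 0, 1))
  expect_equal(rescale_unit(c(7, 7, 7)), c(0, 0, 0))
  set.seed(1)
  x <- rescale_unit(rnorm(100))
  expect_identical(min(x), -1)
  expect_identical(max(x), 1)
})

test_that("angular fields match their closed forms on the 3-point example", {
  x <- c(1, 0, -1)
  gs <- gaf(x, "gasf")
  expect_equal(unclass(gs), matrix(c(1, 0, -1, 0, -1, 0, -1, 0, 1), 3, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  gd <- gaf(x, "gadf")
  expect_equal(unclass(gd),
               matrix(c(0, -1, 0, 1, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(gaf(c(0, 1.1)), "\\[-1, 1\\]")
})

test_that("summation field equals the Gramian inner product, with symmetry and diagonal identities", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rescale_unit(rnorm(40))
    m <- unclass(gaf(x, "gasf"))
    inner <- outer(x, x) - sqrt(1 - x^2) %o% sqrt(1 - x^2)
    expect_lt(max(abs(m - inner)), 1e-12)
    expect_identical(max(abs(m - t(m))), 0)              # exact symmetry
    expect_lt(max(abs(diag(m) - (2 * x^2 - 1))), 1e-12)  # diag = 2x^2-1
    d <- unclass(gaf(x, "gadf"))
    expect_lt(max(abs(d + t(d))), 1e-15)                 # anti-symmetry
    expect_identical(max(abs(diag(d))), 0)               # zero diagonal
  }
})

test_that("series resampling hits the target length and is exact on ramps", {
  expect_length(downsample_series(rnorm(500), 64), 64)
  x <- rnorm(50)
  expect_identical(downsample_series(x, 50), x)
  ramp <- seq(2, 9, length.out = 500)
  expect_equal(downsample_series(ramp, 64), seq(2, 9, length.out = 64),
               tolerance = 1e-12)
  expect_error(downsample_series(ramp, 1), "n_target")
})

test_that("delay embedding produces the defined point cloud and circles for sinusoids", {
  x <- seq_len(10)
  emb <- sliding_window_embed(x, m = 3, d = 2)
  expect_equal(dim(emb), c(6, 3))
  expect_equal(emb[1, ], c(1, 3, 5))
  expect_equal(unname(sliding_window_embed(x, m = 1, d = 1)),
               matrix(x, ncol = 1))
  expect_error(sliding_window_embed(x, m = 6, d = 2), "at least 11")

  # quarter-period delay turns a sinusoid into a circle of radius = amplitude
  a <- 1.7
  tt <- seq_len(400)
  x <- a * sin(2 * pi * tt / 40)
  cl <- sliding_window_embed(x, m = 2, d = 10)
  radii <- sqrt(rowSums(cl^2))
  expect_lt(max(abs(radii - a)), 1e-6)
})

test_that("persistence images match a brute-force Gaussian-sum oracle and its normalization contract", {
  cfg <- pi_config(grid_range = c(0, 4), sigma = 0.3, resolution = 16)
  pd <- structure(list(pairs = list(
    "0" = matrix(numeric(0), 0, 2),
    "1" = matrix(c(0.5, 1.6, 2.1, 0.5 + 1.0, 1.6 + 0.4, 2.1 + 1.5),
                 ncol = 2)), max_dim = 1L, n_points = 10L),
    class = "persistence_diagram")
  img <- pd_to_pi(pd, cfg)
  # dense oracle: direct double loop over grid cells and diagram points
  h <- 4 / 16
  centers <- 0 + (1:16 - 0.5) * h
  b <- pd$pairs[["1"]][, 1]
  pers <- pd$pairs[["1"]][, 2] - b
  w <- pers / max(pers)
  ref <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    for (p in seq_along(b)) {
      ref[i, j] <- ref[i, j] + w[p] *
        exp(-((centers[j] - b[p])^2 + (centers[i] - pers[p])^2) /
              (2 * 0.3^2)) / (2 * pi * 0.3^2)
    }
  }
  ref <- ref / max(ref)
  expect_lt(max(abs(img - ref)), 1e-9)
  expect_equal(max(img), 1)

  empty <- structure(list(pairs = list("1" = matrix(numeric(0), 0, 2)),
                          max_dim = 1L, n_points = 0L),
                     class = "persistence_diagram")
  expect_equal(pd_to_pi(empty, cfg), matrix(0, 16, 16))

  # duplicated point: normalization cancels the factor two
  one <- pd
  one$pairs[["1"]] <- pd$pairs[["1"]][c(1, 1), ]
  two <- pd
  two$pairs[["1"]] <- pd$pairs[["1"]][1, , drop = FALSE]
  expect_equal(pd_to_pi(one, cfg), pd_to_pi(two, cfg), tolerance = 1e-12)
})

test_that("persistence images are stable: pixel change shrinks with the perturbation", {
  cfg <- pi_config(grid_range = c(0, 4), sigma = 0.3, resolution = 16)
  base <- structure(list(pairs = list(
    "1" = matrix(c(0.6, 1.2, 2.0, 1.4, 2.4, 3.1), ncol = 2)),
    max_dim = 1L, n_points = 10L), class = "persistence_diagram")
  img0 <- pd_to_pi(base, cfg)
  set.seed(9)
  dir <- matrix(sample(c(-1, 1), 6, TRUE), ncol = 2)
  errs <- vapply(c(1e-1, 1e-2, 1e-3) * cfg$sigma, function(delta) {
    pert <- base
    pert$pairs[["1"]] <- base$pairs[["1"]] + delta * dir
    max(abs(pd_to_pi(pert, cfg) - img0))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 10)
})

test_that("window-to-image conversion yields normalized stacked channels of the right kind", {
  set.seed(11)
  w <- matrix(rnorm(3 * 500), nrow = 3)
  img <- window_to_image(w, kind = "gaf")
  expect_equal(dim(img$pixels), c(3, 64, 64))
  for (ch in 1:3) {
    m <- img$pixels[ch, , ]
    expect_identical(max(abs(m - t(m))), 0)  # GASF channels are symmetric
    expect_lte(max(abs(m)), 1)
  }
  # full-length field + bilinear resize stays close to the downsampled path
  img_r <- window_to_image(w, kind = "gaf", gaf_mode = "resize")
  expect_equal(dim(img_r$pixels), c(3, 64, 64))

  w1 <- matrix(rnorm(500), nrow = 1)
  pi_img <- window_to_image(w1, kind = "pi",
                            pi_cfg = pi_config(grid_range = c(0, 3),
                                               sigma = 0.25, resolution = 64),
                            max_points = 40)
  expect_equal(dim(pi_img$pixels), c(1, 64, 64))
  expect_equal(max(pi_img$pixels), 1)
  expect_true(all(pi_img$pixels >= 0))
})

test_that("batch conversion preserves order, labels and caching round trips", {
  ds <- tiny_dataset(windows_per_class = 3)
  imgs <- windows_to_images(ds, kind = "gaf", resolution = 16)
  expect_equal(dim(imgs$pixels)[1:2], c(dim(ds$windows)[1], 2))
  expect_identical(imgs$labels, ds$labels)
  i <- 5
  direct <- window_to_image(ds$windows[i, , ], kind = "gaf", resolution = 16)
  expect_equal(imgs$pixels[i, , , ], direct$pixels)

  cache <- file.path(tempdir(), "ir_cache_test")
  a <- windows_to_images(ds, kind = "gaf", resolution = 16, cache_dir = cache)
  b <- windows_to_images(ds, kind = "gaf", resolution = 16, cache_dir = cache)
  expect_identical(a$pixels, b$pixels)
  unlink(cache, recursive = TRUE)
})
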