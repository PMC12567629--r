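#' Rescale a series to [-1, 1]
#'
#' Affine map sending the minimum to -1 and the maximum to +1. A constant
#' series has no scale, so it maps to all zeros (the polar angle is then
#' pi/2 everywhere), which keeps the downstream angular transforms
#' deterministic.
#'
#' @param series numeric vector.
#' @return numeric vector in `[-1, 1]`.
#' @export
rescale_unit <- function(series) {
  if (length(series) < 1) stop("series must be non-empty", call. = FALSE)
  lo <- min(series); hi <- max(series)
  if (hi == lo) return(rep(0, length(series)))
  2 * (series - lo) / (hi - lo) - 1
}

#' Gramian angular field of a unit-scaled series
#'
#' Each value `x_t` in `[-1, 1]` is mapped to a polar angle
#' `phi_t = arccos(x_t)`. The summation variant (GASF) is
#' `cos(phi_i + phi_j)`: symmetric, with diagonal `cos(2 phi_i) = 2 x_i^2 - 1`,
#' so per-time-step magnitude survives on the main diagonal. The difference
#' variant (GADF) is `sin(phi_i - phi_j)`: anti-symmetric with a zero
#' diagonal. GASF also equals the Gramian inner product
#' `x_i x_j - sqrt(1 - x_i^2) sqrt(1 - x_j^2)`.
#'
#' @param series numeric vector with values in `[-1, 1]` (tolerance 1e-9,
#'   then clipped).
#' @param variant `"gasf"` (default) or `"gadf"`.
#' @return An `n x n` matrix of class `gaf_matrix` with attribute
#'   `variant`.
#' @export
gaf <- function(series, variant = c("gasf", "gadf")) {
  variant <- match.arg(variant)
  if (any(abs(series) > 1 + 1e-9))
    stop("series values must lie in [-1, 1] (tolerance 1e-9); rescale first",
         call. = FALSE)
  x <- pmin(pmax(series, -1), 1)
  phi <- acos(x)
  m <- if (variant == "gasf") cos(outer(phi, phi, "+"))
       else sin(outer(phi, phi, "-"))
  structure(m, variant = variant, class = c("gaf_matrix", class(m)))
}

#' Resample a series to a target length
#'
#' Linear interpolation onto `n_target` uniformly spaced points spanning
#' the original index range (used to bring a window down to the image
#' resolution before forming the angular field).
#'
#' @param series numeric vector.
#' @param n_target target length (>= 2).
#' @return numeric vector of length `n_target`.
#' @export
downsample_series <- function(series, n_target) {
  n <- length(series)
  if (n_target < 2) stop("n_target must be >= 2", call. = FALSE)
  if (n_target == n) return(series)
  approx(seq_len(n) - 1, series,
         xout = seq(0, n - 1, length.out = n_target))$y
}

#' Delay (sliding-window) embedding of a series
#'
#' Projects a scalar series into an `m`-dimensional point cloud: point `p`
#' is `(x_p, x_{p+d}, ..., x_{p+(m-1)d})`. This is the standard state-space
#' reconstruction that turns periodicity into loops, which persistent
#' homology can then measure.
#'
#' @param series numeric vector of length T.
#' @param m embedding dimension.
#' @param d delay in samples.
#' @return A `(T - (m-1) d) x m` matrix.
#' @export
sliding_window_embed <- function(series, m = 3, d = 2) {
  Tn <- length(series)
  need <- (m - 1) * d + 1
  if (Tn < need)
    stop(sprintf("series too short: need at least %d samples for m=%d, d=%d",
                 need, m, d), call. = FALSE)
  P <- Tn - (m - 1) * d
  idx <- outer(seq_len(P), (0:(m - 1)) * d, "+")
  matrix(series[idx], nrow = P, ncol = m)
}

#' Persistence diagram of a point cloud (Vietoris-Rips filtration)
#'
#' Computes birth-death pairs of the Rips filtration with the package's
#' built-in reduction backend (union-find for H0, Z/2 boundary-matrix
#' reduction for H1). Clouds larger than `max_points` are thinned to
#' evenly spaced points first, since the flag complex grows cubically.
#'
#' @param cloud numeric matrix, one point per row.
#' @param max_dim maximal homology dimension (0 or 1).
#' @param threshold maximal filtration value (default: the full complex).
#' @param max_points cloud size cap before the filtration is built.
#' @return Object of class `persistence_diagram`: a list with `pairs` (a
#'   list of two-column birth/death matrices indexed by dimension as
#'   character names `"0"`, `"1"`; infinite death marks essential
#'   classes), `max_dim` and `n_points`.
#' @export
compute_pd <- function(cloud, max_dim = 1, threshold = Inf, max_points = 100) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) < 1) stop("point cloud must be non-empty", call. = FALSE)
  if (max_dim > 1)
    stop("homology dimensions above 1 are not supported", call. = FALSE)
  if (nrow(cloud) > max_points) {
    keep <- unique(round(seq(1, nrow(cloud), length.out = max_points)))
    cloud <- cloud[keep, , drop = FALSE]
  }
  D <- as.matrix(stats::dist(cloud))
  res <- tryCatch(.rips_pairs(D, as.integer(max_dim), threshold),
                  error = function(e) {
    stop(sprintf("persistence backend failed on %d points (dim %d): %s",
                 nrow(cloud), max_dim, conditionMessage(e)), call. = FALSE)
  })
  pairs <- list("0" = res$h0)
  if (max_dim >= 1) pairs[["1"]] <- res$h1
  for (k in names(pairs)) colnames(pairs[[k]]) <- c("birth", "death")
  structure(list(pairs = pairs, max_dim = as.integer(max_dim),
                 n_points = nrow(cloud)),
            class = "persistence_diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> %d points, dims 0..%d\n",
              x$n_points, x$max_dim))
  for (k in names(x$pairs)) {
    p <- x$pairs[[k]]
    cat(sprintf("  H%s: %d pairs (%d essential)\n", k, nrow(p),
                sum(is.infinite(p[, 2]))))
  }
  invisible(x)
}

#' Persistence-image configuration
#'
#' @param grid_range length-2 numeric; the square grid spans this range on
#'   both the birth and the persistence axis.
#' @param sigma Gaussian bandwidth of the kernel placed at each diagram
#'   point.
#' @param resolution pixels per side (>= 2).
#' @param weight `"linear"` (weight proportional to persistence, the usual
#'   choice) or `"constant"`.
#' @param homology_dim which homology dimension feeds the image (default 1:
#'   loops, which carry the periodicity of quasi-periodic signals).
#' @return Object of class `pi_config`.
#' @export
pi_config <- function(grid_range = c(-10, 10), sigma = 0.25, resolution = 64,
                      weight = c("linear", "constant"), homology_dim = 1) {
  weight <- match.arg(weight)
  if (grid_range[1] >= grid_range[2]) stop("grid_range must increase", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (resolution < 2) stop("resolution must be >= 2", call. = FALSE)
  structure(list(grid_range = as.numeric(grid_range), sigma = sigma,
                 resolution = as.integer(resolution), weight = weight,
                 homology_dim = as.integer(homology_dim)),
            class = "pi_config")
}

#' Rasterize a persistence diagram into a persistence image
#'
#' Diagram points in the chosen dimension are mapped to (birth,
#' persistence) coordinates; essential (infinite-death) classes are
#' dropped, since they have no finite persistence coordinate. A weighted
#' isotropic Gaussian is placed at each point and the sum is evaluated at
#' the centers of a `resolution x resolution` grid over
#' `grid_range x grid_range`; the image is then normalized by its maximum
#' (an all-zero image stays zero).
#'
#' @param pd a [compute_pd()] result.
#' @param cfg a [pi_config()].
#' @return numeric `resolution x resolution` matrix; rows index the
#'   persistence axis (ascending), columns the birth axis.
#' @export
pd_to_pi <- function(pd, cfg = pi_config()) {
  stopifnot(inherits(pd, "persistence_diagram"), inherits(cfg, "pi_config"))
  res <- cfg$resolution
  img <- matrix(0, res, res)
  pts <- pd$pairs[[as.character(cfg$homology_dim)]]
  if (is.null(pts) || nrow(pts) == 0) return(img)
  fin <- is.finite(pts[, 2])
  pts <- pts[fin, , drop = FALSE]
  if (nrow(pts) == 0) return(img)
  b <- pts[, 1]
  pers <- pts[, 2] - pts[, 1]
  w <- if (cfg$weight == "linear") {
    mx <- max(pers)
    if (mx > 0) pers / mx else rep(0, length(pers))
  } else rep(1, length(pers))
  h <- diff(cfg$grid_range) / res
  centers <- cfg$grid_range[1] + (seq_len(res) - 0.5) * h
  for (i in seq_along(b)) {
    if (w[i] == 0) next
    img <- img + w[i] * (dnorm(centers, pers[i], cfg$sigma) %o%
                           dnorm(centers, b[i], cfg$sigma))
  }
  mx <- max(img)
  if (mx > 0) img <- img / mx
  img
}

#' Bilinear resize of a matrix
#' @param m numeric matrix.
#' @param nr,nc target rows/columns.
#' @return resized matrix.
#' @export
bilinear_resize <- function(m, nr, nc = nr) {
  sr <- seq(1, nrow(m), length.out = nr)
  sc <- seq(1, ncol(m), length.out = nc)
  r0 <- pmin(floor(sr), nrow(m) - 1); r1 <- r0 + 1; fr <- sr - r0
  c0 <- pmin(floor(sc), ncol(m) - 1); c1 <- c0 + 1; fc <- sc - c0
  if (nrow(m) == 1) { r0 <- r1 <- rep(1, nr); fr <- rep(0, nr) }
  if (ncol(m) == 1) { c0 <- c1 <- rep(1, nc); fc <- rep(0, nc) }
  a <- m[r0, c0, drop = FALSE] * ((1 - fr) %o% (1 - fc)) +
    m[r1, c0, drop = FALSE] * (fr %o% (1 - fc)) +
    m[r0, c1, drop = FALSE] * ((1 - fr) %o% fc) +
    m[r1, c1, drop = FALSE] * (fr %o% fc)
  a
}

#' Convert one multichannel window to an image representation
#'
#' For `kind = "gaf"` each channel is unit-rescaled, resampled to the
#' target resolution and turned into an angular field (set
#' `gaf_mode = "resize"` to instead form the full-length field and
#' bilinearly resize it). For `kind = "pi"` each channel is delay-embedded,
#' run through the Rips filtration and rasterized as a persistence image.
#' Channels are stacked, one image channel per input channel.
#'
#' @param window numeric `[channels x length]` matrix (or vector).
#' @param kind `"gaf"` or `"pi"`.
#' @param resolution image side in pixels (default 64).
#' @param variant GAF variant, `"gasf"` (default) or `"gadf"`.
#' @param gaf_mode `"downsample"` (series to resolution, then field) or
#'   `"resize"` (full field, then image resize).
#' @param pi_cfg a [pi_config()] for the persistence path.
#' @param embed_dim,embed_delay delay-embedding parameters.
#' @param max_points cloud size cap passed to [compute_pd()].
#' @return Object of class `ir_image`: list with `pixels`
#'   `[channels x resolution x resolution]`, `kind`, and `channel_map`.
#' @export
window_to_image <- function(window, kind = c("gaf", "pi"), resolution = 64,
                            variant = c("gasf", "gadf"),
                            gaf_mode = c("downsample", "resize"),
                            pi_cfg = pi_config(resolution = resolution),
                            embed_dim = 3, embed_delay = 2,
                            max_points = 100) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  gaf_mode <- match.arg(gaf_mode)
  if (is.vector(window)) window <- matrix(window, nrow = 1)
  C <- nrow(window)
  px <- array(0, dim = c(C, resolution, resolution))
  for (ch in seq_len(C)) {
    x <- window[ch, ]
    if (kind == "gaf") {
      u <- rescale_unit(x)
      m <- if (gaf_mode == "downsample") {
        unclass(gaf(downsample_series(u, resolution), variant))
      } else {
        bilinear_resize(unclass(gaf(u, variant)), resolution)
      }
      px[ch, , ] <- m
    } else {
      cloud <- sliding_window_embed(x, embed_dim, embed_delay)
      pd <- compute_pd(cloud, max_dim = pi_cfg$homology_dim,
                       max_points = max_points)
      px[ch, , ] <- pd_to_pi(pd, pi_cfg)
    }
  }
  structure(list(pixels = px, kind = kind, channel_map = seq_len(C)),
            class = "ir_image")
}

#' Batch-convert a window set to an image set
#'
#' Applies [window_to_image()] to every window, preserving order, labels
#' and subject ids. Persistence images are expensive (the filtration is
#' CPU-bound), so results can be cached: with a `cache_dir` the full
#' converted set is stored under a key derived from the input and options
#' and reused on identical calls.
#'
#' @param ws a [window_set()].
#' @param ... passed to [window_to_image()].
#' @param cache_dir optional directory for conversion caching.
#' @return Object of class `image_set`: list with `pixels`
#'   `[N x C x H x W]`, `labels`, `subject_ids`, `meta`.
#' @export
windows_to_images <- function(ws, ..., cache_dir = NULL) {
  stopifnot(inherits(ws, "window_set"))
  key <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    key <- file.path(cache_dir, paste0("ir_", content_hash(
      list(dim(ws$windows), sum(ws$windows), ws$labels, list(...))), ".rds"))
    if (file.exists(key)) return(readRDS(key))
  }
  n <- dim(ws$windows)[1]
  first <- window_to_image(ws$windows[1, , , drop = TRUE], ...)
  d <- dim(first$pixels)
  px <- array(0, dim = c(n, d))
  px[1, , , ] <- first$pixels
  if (n > 1) for (i in 2:n) {
    px[i, , , ] <- window_to_image(
      matrix(ws$windows[i, , ], nrow = d[1]), ...)$pixels
  }
  out <- structure(list(pixels = px, labels = ws$labels,
                        subject_ids = ws$subject_ids,
                        meta = c(ws$meta, list(kind = first$kind))),
                   class = "image_set")
  if (!is.null(key)) saveRDS(out, key)
  out
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_set> %d images, %d x %d x %d (%s)\n", d[1], d[2], d[3],
              d[4], x$meta$kind %||% "?"))
  invisible(x)
}

# stable content hash via the md5 of a serialized temp file
content_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, compress = FALSE)
  unname(tools::md5sum(f))
}
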