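#' Specification for a synthetic activity-recognition dataset
#'
#' Describes a class-structured, quasi-periodic multichannel signal
#' generator that emulates wrist-worn accelerometer recordings: each
#' activity class is a harmonic series at a class-specific fundamental
#' frequency, each subject perturbs frequency and amplitude
#' multiplicatively, each channel carries its own phase, and i.i.d.
#' Gaussian noise is added on top. The generator exists so that the whole
#' representation/distillation pipeline can be exercised end-to-end
#' without access to proprietary recordings.
#'
#' @param n_classes number of activity classes (>= 2).
#' @param n_subjects number of simulated subjects.
#' @param windows_per_class integer scalar or length-`n_classes` vector;
#'   a vector expresses class imbalance.
#' @param channels number of sensor channels (3 for a tri-axial device).
#' @param window_length samples per window (>= 8).
#' @param sample_rate sampling rate in Hz.
#' @param class_params optional list of per-class lists with fields
#'   `base_freq_hz`, `amplitude`, `harmonic_weights`, `noise_sd`; defaults
#'   to [default_class_params()].
#' @param subject_jitter multiplicative per-subject spread applied to
#'   frequency and amplitude (standard deviation of the factor around 1).
#' @param noise_sd default per-sample Gaussian noise SD used when
#'   `class_params` does not override it.
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @param subject_offset added to emitted subject ids, so that two specs
#'   can describe disjoint subject pools (e.g. train vs held-out subjects).
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_activity_dataset()]
#' @export
synthetic_spec <- function(n_classes = 5, n_subjects = 20,
                           windows_per_class = 200, channels = 3,
                           window_length = 500, sample_rate = 100,
                           class_params = NULL, subject_jitter = 0.1,
                           noise_sd = 0.3, seed = 1, subject_offset = 0) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (window_length < 8) stop("window_length must be >= 8", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  if (subject_jitter < 0) stop("subject_jitter must be >= 0", call. = FALSE)
  wpc <- as.integer(windows_per_class)
  if (length(wpc) == 1) wpc <- rep(wpc, n_classes)
  if (length(wpc) != n_classes)
    stop("windows_per_class must be scalar or one per class", call. = FALSE)
  if (any(wpc < 1)) stop("windows_per_class must be positive", call. = FALSE)
  cp <- class_params %||% default_class_params(n_classes, noise_sd)
  if (length(cp) != n_classes)
    stop("class_params must have one entry per class", call. = FALSE)
  for (i in seq_along(cp)) {
    p <- cp[[i]]
    need <- c("base_freq_hz", "amplitude", "harmonic_weights", "noise_sd")
    miss <- setdiff(need, names(p))
    if (length(miss) > 0)
      stop("class_params[[", i, "]] is missing field: ", miss[1], call. = FALSE)
    if (p$amplitude <= 0)
      stop("class_params[[", i, "]]: amplitude must be > 0", call. = FALSE)
    if (p$noise_sd < 0)
      stop("class_params[[", i, "]]: noise_sd must be >= 0", call. = FALSE)
  }
  structure(list(
    n_classes = as.integer(n_classes), n_subjects = as.integer(n_subjects),
    windows_per_class = wpc, channels = as.integer(channels),
    window_length = as.integer(window_length), sample_rate = sample_rate,
    class_params = cp, subject_jitter = subject_jitter,
    seed = as.integer(seed), subject_offset = as.integer(subject_offset)
  ), class = "synthetic_spec")
}

#' Default per-class signal parameters
#'
#' Fundamental frequencies follow a geometric ladder starting at 1 Hz with
#' ratio 1.3 (roughly the cadence range from slow walking to jogging, and
#' close enough between neighbours that per-subject frequency jitter makes
#' held-out subjects genuinely confusable). Harmonic content cycles through
#' three gait-like profiles so classes differ in timbre, not only in rate.
#'
#' @param n_classes number of classes.
#' @param noise_sd Gaussian noise SD shared by all classes.
#' @return List of per-class parameter lists.
#' @export
default_class_params <- function(n_classes, noise_sd = 0.3) {
  profiles <- list(c(1), c(1, 0.4), c(1, 0.25, 0.15))
  lapply(seq_len(n_classes), function(i) {
    list(base_freq_hz = 1.0 * 1.3^(i - 1), amplitude = 1.0,
         harmonic_weights = profiles[[(i - 1) %% 3 + 1]],
         noise_sd = noise_sd)
  })
}

#' Construct a labeled window set
#'
#' The universal dataset currency: an `N x channels x length` array of
#' windows with integer class labels (0-based), subject ids, and a
#' provenance record.
#'
#' @param windows numeric array `[N, channels, length]`.
#' @param labels integer vector of 0-based class codes, length N.
#' @param subject_ids integer vector, length N.
#' @param meta list of provenance fields.
#' @return Object of class `window_set`.
#' @export
window_set <- function(windows, labels, subject_ids = NULL, meta = list()) {
  stopifnot(length(dim(windows)) == 3)
  n <- dim(windows)[1]
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must match window count", call. = FALSE)
  subject_ids <- as.integer(subject_ids %||% rep(0L, n))
  if (length(subject_ids) != n)
    stop("subject_ids must match window count", call. = FALSE)
  structure(list(windows = windows, labels = labels,
                 subject_ids = subject_ids, meta = meta),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows, %d channels x %d samples, %d classes, %d subjects\n",
              d[1], d[2], d[3], length(unique(x$labels)),
              length(unique(x$subject_ids))))
  invisible(x)
}

#' Generate a synthetic activity dataset
#'
#' Draws every window as a sum of class-specific harmonics with a
#' subject-specific frequency/amplitude factor, per-channel random phase,
#' and additive Gaussian noise. Deterministic given the spec's seed; class
#' counts are produced exactly as requested, with subjects assigned
#' cyclically within each class.
#'
#' @param spec a [synthetic_spec()].
#' @return A [window_set()].
#' @export
generate_activity_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop("spec must be a synthetic_spec", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n_total <- sum(spec$windows_per_class)
  C <- spec$channels; L <- spec$window_length
  tt <- (seq_len(L) - 1) / spec$sample_rate
  freq_fac <- pmax(1 + spec$subject_jitter * rnorm(spec$n_subjects), 0.1)
  amp_fac <- pmax(1 + spec$subject_jitter * rnorm(spec$n_subjects), 0.1)

  windows <- array(0, dim = c(n_total, C, L))
  labels <- integer(n_total)
  subjects <- integer(n_total)
  row <- 1L
  for (ci in seq_len(spec$n_classes)) {
    p <- spec$class_params[[ci]]
    subj <- rep_len(seq_len(spec$n_subjects), spec$windows_per_class[ci])
    for (w in seq_len(spec$windows_per_class[ci])) {
      s <- subj[w]
      f <- p$base_freq_hz * freq_fac[s]
      a <- p$amplitude * amp_fac[s]
      for (ch in seq_len(C)) {
        phase <- runif(1, 0, 2 * pi)
        x <- numeric(L)
        for (k in seq_along(p$harmonic_weights))
          x <- x + p$harmonic_weights[k] * a * sin(2 * pi * k * f * tt + phase)
        if (p$noise_sd > 0) x <- x + rnorm(L, 0, p$noise_sd)
        windows[row, ch, ] <- x
      }
      labels[row] <- ci - 1L
      subjects[row] <- s + spec$subject_offset
      row <- row + 1L
    }
  }
  window_set(windows, labels, subjects,
             meta = list(source = "synthetic", spec = spec))
}

#' Segment a long series into sliding windows
#'
#' Windows start at multiples of `stride = window - overlap`; the trailing
#' remainder that does not fill a whole window is dropped. With
#' `overlap = 0` this is fully non-overlapped segmentation.
#'
#' @param series numeric matrix `[channels x T]` (a vector is treated as one
#'   channel).
#' @param window window length in samples.
#' @param overlap overlap in samples, `0 <= overlap < window`.
#' @param label,subject optional label/subject attached to every window.
#' @return A [window_set()]; zero windows (with a warning) when the series
#'   is shorter than `window`.
#' @export
segment_series <- function(series, window, overlap = 0,
                           label = NA_integer_, subject = 0L) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  Tn <- ncol(series)
  if (overlap < 0 || overlap >= window)
    stop("need 0 <= overlap < window", call. = FALSE)
  if (window > Tn) {
    warning("window longer than series; returning 0 windows")
    return(window_set(array(0, c(0, nrow(series), window)), integer(0)))
  }
  stride <- window - overlap
  n <- (Tn - window) %/% stride + 1
  starts <- (seq_len(n) - 1) * stride
  out <- array(0, dim = c(n, nrow(series), window))
  for (i in seq_len(n))
    out[i, , ] <- series[, (starts[i] + 1):(starts[i] + window), drop = FALSE]
  ws <- window_set(out, rep(as.integer(label), n), rep(as.integer(subject), n),
                   meta = list(starts = starts, stride = stride))
  ws
}

#' Resample a series to a lower rate by linear interpolation
#'
#' The output has `floor(T * to_hz / from_hz)` samples placed on a uniform
#' grid spanning the original index range, so endpoints are preserved.
#'
#' @param series numeric vector or `[channels x T]` matrix.
#' @param from_hz,to_hz source and target rates; `from_hz > to_hz > 0`.
#' @param method `"linear"` (interpolation, the default) or `"decimate"`
#'   (nearest-sample picking on the same grid).
#' @return Resampled vector/matrix.
#' @export
downsample_rate <- function(series, from_hz, to_hz,
                            method = c("linear", "decimate")) {
  method <- match.arg(method)
  if (!(from_hz > 0) || !(to_hz > 0))
    stop("rates must be positive", call. = FALSE)
  if (to_hz >= from_hz)
    stop("to_hz must be below from_hz", call. = FALSE)
  vec <- is.vector(series)
  if (vec) series <- matrix(series, nrow = 1)
  Tn <- ncol(series)
  n_new <- floor(Tn * to_hz / from_hz)
  if (n_new < 2) stop("target length below 2; series too short", call. = FALSE)
  xout <- seq(0, Tn - 1, length.out = n_new)
  out <- if (method == "linear") {
    t(apply(series, 1, function(y) approx(0:(Tn - 1), y, xout = xout)$y))
  } else {
    series[, round(xout) + 1, drop = FALSE]
  }
  if (vec) out[1, ] else out
}

#' Leave-one-subject-out splits
#'
#' One fold per distinct subject: the fold's test set is all of that
#' subject's windows and its training set is everything else, so the folds'
#' test sets partition the dataset exactly.
#'
#' @param ds a [window_set()] with at least two distinct subjects.
#' @return List of folds, each `list(subject, train, test)`.
#' @export
make_loso_splits <- function(ds) {
  subs <- sort(unique(ds$subject_ids))
  if (length(subs) < 2)
    stop("leave-one-subject-out needs >= 2 subjects", call. = FALSE)
  lapply(subs, function(s) {
    te <- ds$subject_ids == s
    list(subject = s,
         train = subset_window_set(ds, !te),
         test = subset_window_set(ds, te))
  })
}

#' Subset a window set by index or logical mask
#' @param ds a [window_set()].
#' @param i integer or logical index over windows.
#' @return A [window_set()].
#' @export
subset_window_set <- function(ds, i) {
  window_set(ds$windows[i, , , drop = FALSE], ds$labels[i],
             ds$subject_ids[i], ds$meta)
}

#' Write / read a window set as a directory
#'
#' Layout: `windows.bin` (little-endian float64, N x C x L in R array
#' order), `labels.tsv` (label, subject per window) and `meta.json`
#' (dimensions and provenance).
#'
#' @param ds a [window_set()].
#' @param dir target directory (created if needed).
#' @return `write_window_set` the directory, invisibly; `read_window_set`
#'   a [window_set()].
#' @export
write_window_set <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "windows.bin"), "wb")
  writeBin(as.vector(ds$windows), con, size = 8, endian = "little")
  close(con)
  tab <- data.frame(label = ds$labels, subject = ds$subject_ids)
  write.table(tab, file.path(dir, "labels.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  meta <- list(dim = dim(ds$windows),
               source = ds$meta$source %||% "unknown")
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  con <- file(file.path(dir, "windows.bin"), "rb")
  x <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
  close(con)
  tab <- read.table(file.path(dir, "labels.tsv"), header = TRUE, sep = "\t")
  window_set(array(x, dim = d), tab$label, tab$subject,
             meta = list(source = meta$source))
}

#' Ingest PAMAP2-style subject files (optional hook)
#'
#' Parses whitespace-delimited per-subject recordings (timestamp, activity
#' id, then sensor columns), selects the requested channel columns, drops
#' rows with missing values, resamples each contiguous activity bout from
#' `from_hz` to `to_hz`, and segments with the given window/overlap. Which
#' sensor columns to use is deliberately an argument: no canonical axis
#' subset is assumed.
#'
#' @param files character vector of subject file paths.
#' @param channels integer column indices of the sensor channels to keep.
#' @param activity_col column index of the activity label (default 2).
#' @param from_hz,to_hz resampling rates (default 100 -> 33).
#' @param window,overlap segmentation parameters (default 100 / 78).
#' @return A [window_set()] with subject ids taken from file order.
#' @export
read_pamap2 <- function(files, channels, activity_col = 2,
                        from_hz = 100, to_hz = 33,
                        window = 100, overlap = 78) {
  sets <- list()
  for (si in seq_along(files)) {
    raw <- read.table(files[si], header = FALSE)
    lab <- raw[[activity_col]]
    keep <- stats::complete.cases(raw[, channels, drop = FALSE])
    raw <- raw[keep, , drop = FALSE]; lab <- lab[keep]
    runs <- rle(lab)
    pos <- cumsum(c(0, runs$lengths))
    for (r in seq_along(runs$values)) {
      if (runs$values[r] == 0) next  # transient activity code
      seg <- t(as.matrix(raw[(pos[r] + 1):pos[r + 1], channels, drop = FALSE]))
      if (ncol(seg) * to_hz / from_hz < window + 2) next
      seg <- downsample_rate(seg, from_hz, to_hz)
      ws <- suppressWarnings(
        segment_series(seg, window, overlap, label = runs$values[r],
                       subject = si))
      if (dim(ws$windows)[1] > 0) sets[[length(sets) + 1]] <- ws
    }
  }
  if (length(sets) == 0) stop("no usable segments found", call. = FALSE)
  window_set(
    do.call(abind3, lapply(sets, function(s) s$windows)),
    unlist(lapply(sets, function(s) s$labels)),
    unlist(lapply(sets, function(s) s$subject_ids)),
    meta = list(source = "pamap2")
  )
}

# bind 3-d arrays along the first margin
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[-1]
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(n, d))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    if (k > 0) out[(at + 1):(at + k), , ] <- p
    at <- at + k
  }
  out
}
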