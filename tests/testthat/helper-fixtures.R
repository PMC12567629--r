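# Shared tiny fixtures; built in code, sized for fast unit tests.

tiny_spec <- function(seed = 7, noise_sd = 0.1, jitter = 0.05,
                      n_classes = 3, windows_per_class = 12, channels = 2,
                      window_length = 64, n_subjects = 4,
                      subject_offset = 0) {
  synthetic_spec(n_classes = n_classes, n_subjects = n_subjects,
                 windows_per_class = windows_per_class, channels = channels,
                 window_length = window_length, sample_rate = 32,
                 class_params = lapply(c(2, 4, 8)[seq_len(n_classes)],
                                       function(f) list(base_freq_hz = f,
                                                        amplitude = 1,
                                                        harmonic_weights = 1,
                                                        noise_sd = noise_sd)),
                 subject_jitter = jitter, seed = seed,
                 subject_offset = subject_offset)
}

tiny_dataset <- function(...) generate_activity_dataset(tiny_spec(...))

tiny_wrn <- function(dim = "1d", in_channels = 2, n_classes = 3,
                     input_size = if (dim == "1d") 64 else c(16, 16)) {
  wrn_config(16, 1, dim, in_channels, n_classes, input_size)
}

tiny_train_config <- function(epochs = 2, batch_size = 16) {
  train_config(epochs = epochs, batch_size = batch_size)
}

# dense reference for the softened-KL distillation term, written directly
# from the definition (kept independent of the package's implementation)
ref_kd <- function(lt, ls, tau) {
  soft <- function(m) {
    e <- exp(m / tau)
    e / rowSums(e)
  }
  t <- soft(lt); s <- soft(ls)
  tau^2 * mean(rowSums(t * (log(t) - log(s))))
}
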