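# Small shared fixtures, built in code at test time.

# a labeled 16px patch dataset used by several GAN/quality tests
tiny_patch_dataset <- function(counts = c(dense = 24, spread = 24),
                               size = 16, seed = 42) {
  make_patch_dataset(counts, seed = seed, size = size)
}

# an entropy_histogram from explicit probabilities (for closed-form cases)
manual_hist <- function(probs, edges = seq(0, length(probs))) {
  structure(list(bin_edges = edges, probabilities = probs,
                 n_samples = length(probs)),
            class = "entropy_histogram")
}

# brute-force confusion-matrix metrics, independent of evaluate_predictions()
brute_force_report <- function(pred, truth) {
  classes <- sort(unique(c(pred, truth)))
  tpr <- f1 <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp <- sum(pred == cl & truth == cl)
    fn <- sum(pred != cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    tpr[cl] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1[cl] <- if (tp + fn > 0) tp / (tp + 0.5 * (fp + fn)) else NA_real_
  }
  list(tpr = tpr, f1 = f1)
}
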