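# Image-entropy machinery: per-patch Shannon entropy over the 256-level
# gray histogram, entropy-distribution histograms on a fixed bin grid, the
# min-sum overlap fraction between real and generated entropy distributions,
# and the entropy-MSE term added to the discriminator's aggregate loss.

as_patch_list <- function(patches) {
  if (is.list(patches) && !is.null(patches$images)) patches <- patches$images
  if (is.matrix(patches)) return(list(patches))
  if (is.array(patches) && length(dim(patches)) == 3)
    return(lapply(seq_len(dim(patches)[3]), function(i) patches[, , i]))
  if (is.list(patches)) return(patches)
  stop("patches must be a matrix, a (h, w, n) array, a list, or a patch_dataset")
}

#' Shannon entropy of a gray patch
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} over the normalized 256-level gray
#' histogram of the patch (one bin per 8-bit level; empty bins contribute
#' zero). Ranges from 0 (constant patch) to 8 bits (all 256 levels equally
#' frequent).
#'
#' @param patch Matrix of gray values in 0-255 (fractional values are
#'   rounded to the nearest level).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(patch) {
  if (length(patch) == 0) stop("empty patch")
  v <- round(as.numeric(patch))
  if (any(v < 0 | v > 255)) stop("gray values outside 0-255")
  p <- tabulate(v + 1L, nbins = 256L)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p)) + 0 # + 0 normalizes IEEE -0 for the constant case
}

#' Default entropy-histogram bin edges
#'
#' @param n_bins Number of uniform bins over the attainable \[0, 8\] bit
#'   range (default 50).
#' @return Numeric vector of `n_bins + 1` edges.
#' @export
default_entropy_bins <- function(n_bins = 50) seq(0, 8, length.out = n_bins + 1)

#' Entropy-distribution histogram of a patch batch
#'
#' Computes each patch's Shannon entropy and bins the values on a fixed
#' grid (right-open bins, last bin closed). Entropies outside the edge
#' range are clipped into the end bins (with a message).
#'
#' @param patches Patches as a `(h, w, n)` array, list of matrices, or
#'   `patch_dataset`; alternatively a numeric vector of precomputed
#'   entropies.
#' @param bin_edges Strictly increasing edges (default
#'   [default_entropy_bins()]).
#' @return An `entropy_histogram`: `bin_edges`, `probabilities` (summing to
#'   1) and `n_samples`.
#' @export
entropy_histogram <- function(patches, bin_edges = default_entropy_bins()) {
  stopifnot(all(diff(bin_edges) > 0))
  h <- if (is.numeric(patches) && is.null(dim(patches)) && !is.list(patches))
    as.numeric(patches)
  else vapply(as_patch_list(patches), shannon_entropy, 0)
  if (length(h) < 1) stop("at least one patch required")
  lo <- bin_edges[1]; hi <- bin_edges[length(bin_edges)]
  n_out <- sum(h < lo | h > hi)
  if (n_out > 0) {
    message(n_out, " entropy value(s) outside the bin range; clipped")
    h <- pmin(pmax(h, lo), hi)
  }
  idx <- findInterval(h, bin_edges, rightmost.closed = TRUE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1)
  structure(list(bin_edges = bin_edges,
                 probabilities = counts / length(h),
                 n_samples = length(h)),
            class = "entropy_histogram")
}

check_same_edges <- function(h_real, h_fake) {
  stopifnot(inherits(h_real, "entropy_histogram"),
            inherits(h_fake, "entropy_histogram"))
  if (length(h_real$bin_edges) != length(h_fake$bin_edges) ||
      any(h_real$bin_edges != h_fake$bin_edges))
    stop("entropy histograms have mismatched bin edges")
}

#' Overlap fraction between two entropy histograms
#'
#' The sum over bins of the smaller of the two bin probabilities: 1 for
#' identical distributions, 0 for disjoint support.
#'
#' @param h_real,h_fake `entropy_histogram` objects on identical edges.
#' @return Overlap fraction in \[0, 1\].
#' @export
histogram_overlap <- function(h_real, h_fake) {
  check_same_edges(h_real, h_fake)
  sum(pmin(h_real$probabilities, h_fake$probabilities))
}

#' Entropy-histogram mean squared error
#'
#' Mean over bins of the squared difference between the two probability
#' vectors; the regularization term added to the discriminator's aggregate
#' loss in the entropy-regularized GAN.
#'
#' @param h_real,h_fake `entropy_histogram` objects on identical edges.
#' @return Non-negative loss; 0 iff the histograms are identical.
#' @export
entropy_mse <- function(h_real, h_fake) {
  check_same_edges(h_real, h_fake)
  mean((h_real$probabilities - h_fake$probabilities)^2)
}

#' Repeated real-vs-generated overlap trials
#'
#' Repeats the histogram construction and overlap computation over
#' `n_trials` independent draws of `n_patches` real and generated patches,
#' reporting the mean and standard deviation of the overlap (the per-class
#' five-trial protocol used to score trained generators).
#'
#' @param real_source Function `(n, seed)` returning `n` real patches.
#' @param patch_generator Function `(n, seed)` returning `n` generated
#'   patches.
#' @param n_patches Patches per side per trial (>= 2).
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer master seed.
#' @param bin_edges Histogram edges.
#' @return List with `mean`, `sd` (0 when `n_trials == 1`) and the
#'   per-trial `values`.
#' @export
overlap_trials <- function(real_source, patch_generator, n_patches = 1000,
                           n_trials = 5, seed = 1,
                           bin_edges = default_entropy_bins()) {
  stopifnot(n_patches >= 2, n_trials >= 1)
  vals <- vapply(seq_len(n_trials), function(t) {
    hr <- entropy_histogram(real_source(n_patches, derive_seed(seed, 2 * t)),
                            bin_edges)
    hf <- entropy_histogram(patch_generator(n_patches, derive_seed(seed, 2 * t + 1)),
                            bin_edges)
    histogram_overlap(hr, hf)
  }, 0)
  list(mean = mean(vals), sd = if (n_trials == 1) 0 else stats::sd(vals),
       values = vals)
}
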