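test_that("Shannon entropy closed forms hold", {
  expect_equal(shannon_entropy(matrix(7, 8, 8)), 0)
  expect_equal(shannon_entropy(matrix(0:255, 16, 16)), 8)
  expect_equal(shannon_entropy(matrix(c(10, 10, 20, 30), 2, 2)), 1.5)
  expect_error(shannon_entropy(matrix(numeric(0), 0, 0)), "empty")
  expect_error(shannon_entropy(matrix(300, 2, 2)), "0-255")
})

test_that("entropy is permutation-invariant in gray levels and bounded", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    h <- shannon_entropy(p)
    expect_gte(h, 0); expect_lte(h, 8)
    perm <- sample(0:255) # relabel gray levels bijectively
    expect_equal(shannon_entropy(matrix(perm[p + 1], 16, 16)), h)
  }
})

test_that("entropy histograms bin correctly and are order-invariant", {
  consts <- array(5L, c(4, 4, 10))
  h <- entropy_histogram(consts)
  expect_equal(h$probabilities[1], 1) # all mass in the bin containing 0
  expect_equal(sum(h$probabilities), 1)
  one <- entropy_histogram(array(make_class_texture("dense", 16, 1), c(16, 16, 1)))
  expect_equal(sort(one$probabilities, decreasing = TRUE)[1], 1) # one-hot
  ds <- make_patch_dataset(c(dense = 50, spread = 50), seed = 3, size = 16)
  ha <- entropy_histogram(ds$images)
  hb <- entropy_histogram(ds$images[, , rev(seq_len(100))])
  expect_equal(ha$probabilities, hb$probabilities)
  expect_message(entropy_histogram(c(1, 9.5), bin_edges = seq(0, 8, 1)),
                 "clipped")
})

test_that("overlap and entropy-MSE match their closed forms", {
  h1 <- manual_hist(c(0.5, 0.5))
  h2 <- manual_hist(c(0.25, 0.75))
  h3 <- manual_hist(c(0, 1))
  h4 <- manual_hist(c(1, 0))
  expect_equal(histogram_overlap(h1, h1), 1)
  expect_equal(histogram_overlap(h3, h4), 0)
  expect_equal(histogram_overlap(h1, h2), 0.75)
  expect_equal(entropy_mse(h1, h1), 0)
  expect_equal(entropy_mse(h1, h2), 0.0625)
  expect_equal(entropy_mse(h1, h2), entropy_mse(h2, h1))
  expect_error(histogram_overlap(h1, manual_hist(c(1, 0, 0))), "mismatched")
})

test_that("overlap equals the brute-force min-sum on random histogram pairs", {
  set.seed(11)
  for (i in 1:100) {
    k <- sample(2:30, 1)
    p <- stats::runif(k); p <- p / sum(p)
    q <- stats::runif(k); q <- q / sum(q)
    hp <- manual_hist(p, seq(0, k)); hq <- manual_hist(q, seq(0, k))
    brute <- 0
    for (j in seq_len(k)) brute <- brute + min(p[j], q[j])
    expect_equal(histogram_overlap(hp, hq), brute)
    expect_gte(histogram_overlap(hp, hq), 0)
    expect_lte(histogram_overlap(hp, hq), 1)
  }
})

test_that("self-overlap across trials is high; cross-class overlap is lower", {
  gen_dense <- fixture_patch_generator(16)
  src <- function(n, seed) gen_dense("dense", n, seed)
  self <- overlap_trials(src, src, n_patches = 1500, n_trials = 3, seed = 5)
  expect_gt(self$mean, 0.95)
  other <- function(n, seed) gen_dense("differentiated", n, seed)
  cross <- overlap_trials(src, other, n_patches = 1500, n_trials = 3, seed = 5)
  expect_lt(cross$mean, self$mean)
  single <- overlap_trials(src, src, n_patches = 100, n_trials = 1, seed = 1)
  expect_identical(single$sd, 0)
})
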