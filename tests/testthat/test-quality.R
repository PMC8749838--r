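test_that("inception score closed forms and invariances hold", {
  expect_equal(as.numeric(inception_score(matrix(0.25, 40, 4))), 1)
  onehot <- diag(4)[rep(1:4, 10), ]
  expect_equal(as.numeric(inception_score(onehot)), 4)
  expect_equal(as.numeric(inception_score(diag(7)[rep(1:7, 3), ])), 7)
  # row-order invariance and class-count bound
  set.seed(3)
  p <- matrix(stats::rgamma(50 * 4, 1), 50)
  p <- p / rowSums(p)
  s <- as.numeric(inception_score(p))
  expect_equal(as.numeric(inception_score(p[sample(50), ])), s)
  expect_lte(s, 4); expect_gte(s, 1)
  expect_error(inception_score(matrix(0.3, 5, 4)), "summing to 1")
})

test_that("inception score equals a direct evaluation of the KL definition", {
  set.seed(7)
  p <- matrix(stats::rgamma(30 * 4, 1), 30)
  p <- p / rowSums(p)
  q <- colMeans(p) # marginal over the generated distribution
  kl <- numeric(30)
  for (i in 1:30) {
    acc <- 0
    for (j in 1:4) if (p[i, j] > 0) acc <- acc + p[i, j] * log(p[i, j] / q[j])
    kl[i] <- acc
  }
  expect_equal(as.numeric(inception_score(p)), exp(mean(kl)))
})

test_that("FID closed forms, symmetry, and monotone interpolation hold", {
  set.seed(5)
  f <- matrix(stats::rnorm(400 * 6), 400)
  expect_lt(fid(f, f), 1e-6)
  shift <- sweep(f, 2, c(2, 0, 0, 0, 0, 0), "+") # same covariance, |dmu| = 2
  expect_equal(fid(f, shift), 4, tolerance = 1e-6)
  g <- matrix(stats::rnorm(400 * 6, 1, 2), 400)
  expect_equal(fid(f, g), fid(g, f), tolerance = 1e-8)
  expect_gte(fid(f, g), 0)
  # interpolating fake toward real drives FID monotonically to 0
  alphas <- c(1, 0.75, 0.5, 0.25, 0)
  path <- vapply(alphas, function(a) fid(f, (1 - a) * f + a * g), 0)
  expect_true(all(diff(path) < 0))
  expect_lt(path[5], 1e-6)
})

test_that("optimal-epoch selection takes the argmax with earliest-tie rule", {
  h <- data.frame(epoch = 1:3, inception_score = c(2.1, 2.6, 2.4))
  expect_equal(select_optimal_epoch(h), list(epoch = 2, score = 2.6))
  ties <- data.frame(epoch = 1:3, inception_score = c(2, 2, 2))
  expect_equal(select_optimal_epoch(ties)$epoch, 1)
  # record shape mirrors a (class, epoch, score) table row
  row <- data.frame(class = "debris", epoch = 116, inception_score = 2.60)
  expect_equal(select_optimal_epoch(row), list(epoch = 116, score = 2.60))
  expect_error(select_optimal_epoch(data.frame(epoch = integer(),
                                               inception_score = numeric())),
               "no inception scores")
})

test_that("the texture embedding separates fixture classes", {
  ds <- make_patch_dataset(c(dense = 40, spread = 40, debris = 40,
                             differentiated = 40), seed = 6, size = 32)
  emb <- fit_texture_embedding(ds)
  holdout <- make_patch_dataset(c(dense = 10, spread = 10, debris = 10,
                                  differentiated = 10), seed = 99, size = 32)
  pr <- predict_probs(emb, holdout)
  expect_equal(dim(pr), c(40, 4))
  expect_equal(unname(rowSums(pr)), rep(1, 40), tolerance = 1e-8)
  acc <- mean(colnames(pr)[apply(pr, 1, which.max)] ==
                as.character(holdout$labels))
  expect_gt(acc, 0.9)
  feats <- embed_features(emb, holdout)
  expect_equal(nrow(feats), 40)
  # IS of a class mix exceeds IS of a single class under the same embedding
  mix <- as.numeric(inception_score(pr))
  single <- as.numeric(inception_score(
    predict_probs(emb, make_patch_dataset(c(dense = 30), seed = 4, size = 32))))
  expect_gt(mix, single)
})
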