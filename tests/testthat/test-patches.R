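test_that("patch sampling stays inside the ROI and is seed-deterministic", {
  roi <- make_class_texture("dense", 64, seed = 1)
  ds <- sample_patches(roi, 5, size = 64, seed = 1)
  expect_equal(n_patches(ds), 5)
  for (i in 1:5) expect_identical(ds$images[, , i], unname(roi))
  roi2 <- make_class_texture("dense", 100, seed = 2)
  a <- sample_patches(roi2, 10, seed = 3)
  b <- sample_patches(roi2, 10, seed = 3)
  expect_identical(attr(a, "corners"), attr(b, "corners"))
  expect_identical(a$images, b$images)
  roi3 <- make_class_texture("spread", 200, seed = 4)
  big <- sample_patches(roi3, 1000, seed = 5)
  expect_true(all(attr(big, "corners") >= 0 & attr(big, "corners") <= 136))
  expect_error(sample_patches(matrix(0, 30, 30), 1, size = 64), "smaller")
})

test_that("stratified folds give the 80:20 split and partition the data", {
  ds <- make_patch_dataset(c(dense = 50, spread = 50), seed = 1, size = 16)
  ds <- make_folds(ds, k = 5, seed = 2)
  expect_equal(as.vector(table(ds$fold)), rep(20, 5))
  ds2 <- make_patch_dataset(c(dense = 50, debris = 10), seed = 1, size = 16)
  ds2 <- make_folds(ds2, k = 5, seed = 3)
  tab <- table(ds2$labels, ds2$fold)
  expect_true(all(tab["dense", ] == 10))
  expect_true(all(tab["debris", ] == 2))
  # union of test folds = whole dataset, no duplicates
  idx <- unlist(lapply(0:4, function(f) which(ds2$fold == f)))
  expect_identical(sort(idx), seq_len(n_patches(ds2)))
  # deterministic per seed
  expect_identical(make_folds(ds2, 5, seed = 3)$fold, ds2$fold)
  expect_error(make_folds(make_patch_dataset(c(dense = 3), size = 16), k = 5),
               "fewer than k")
})

test_that("stage balancing plans implement aggregate-minus-minority", {
  cts <- c(debris = 3587, dense = 3934, diff = 656, spread = 10506)
  p1 <- balancing_plan(cts, 1)
  expect_equal(p1$minority_class, "debris")
  expect_equal(p1$n_generated, 15096 - 3587) # 11509
  p2 <- balancing_plan(cts, 2)
  expect_equal(p2$minority_class, "differentiated")
  expect_equal(p2$n_generated, 14440 - 656) # 13784
  p3 <- balancing_plan(cts, 3)
  expect_equal(p3$minority_class, "dense")
  expect_equal(p3$n_generated, 10506 - 3934) # 6572
  eq <- balancing_plan(c(debris = 30, dense = 10, diff = 10, spread = 10), 1)
  expect_equal(eq$n_generated, 0)
  expect_error(balancing_plan(c(debris = -1, dense = 1, diff = 1, spread = 1), 1),
               "negative")
  expect_error(balancing_plan(c(debris = 1, dense = 1), 1), "missing counts")
})

test_that("generated patches never receive fold assignments", {
  real <- make_patch_dataset(c(dense = 10, spread = 10), seed = 1, size = 16)
  gen <- patch_dataset(fixture_patch_generator(16)("dense", 5, seed = 2),
                       labels = "dense", provenance = "generated")
  ds <- combine_patches(real, gen)
  ds <- make_folds(ds, k = 2, seed = 1)
  expect_true(all(is.na(ds$fold[ds$provenance == "generated"])))
  expect_true(all(!is.na(ds$fold[ds$provenance == "real"])))
})
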