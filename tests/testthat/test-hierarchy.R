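test_that("stage class sets encode the temporal ordering", {
  expect_equal(stage_class_sets(1),
               list(pos = "debris", neg = c("dense", "differentiated", "spread")))
  expect_equal(stage_class_sets(2),
               list(pos = "differentiated", neg = c("dense", "spread")))
  expect_equal(stage_class_sets(3), list(pos = "dense", neg = "spread"))
})

test_that("the learning-rate schedule halves halfway through training", {
  cc <- classifier_config(epochs = 200)
  expect_equal(lr_at_epoch(cc, 100), 0.005)
  expect_equal(lr_at_epoch(cc, 101), 0.0025)
  expect_equal(lr_at_epoch(cc, 200), 0.0025)
})

test_that("evaluate_predictions matches direct formula cases", {
  perfect <- evaluate_predictions(c("a", "b", "a"), c("a", "b", "a"))
  expect_true(all(perfect$tpr == 1) && all(perfect$f1 == 1))
  pred <- c(rep("pos", 90), rep("neg", 10))
  truth <- rep("pos", 100)
  r <- evaluate_predictions(pred, truth)
  expect_equal(unname(r$tpr["pos"]), 0.9)
  # TP=3, FP=1, FN=1 -> F1 = 3 / (3 + 0.5*2) = 0.75
  pred2 <- c("x", "x", "x", "x", "y")
  truth2 <- c("x", "x", "x", "y", "x")
  expect_equal(unname(evaluate_predictions(pred2, truth2)$f1["x"]), 0.75)
  # class absent from truth is reported as missing
  r3 <- evaluate_predictions(c("a", "b"), c("a", "a"))
  expect_true(is.na(r3$tpr["b"]))
})

test_that("evaluate_predictions agrees with a brute-force oracle", {
  set.seed(8)
  classes <- morphology_classes()
  pred <- sample(classes, 1000, replace = TRUE)
  truth <- sample(classes, 1000, replace = TRUE, prob = c(2, 3, 1, 6))
  r <- evaluate_predictions(pred, truth)
  bf <- brute_force_report(pred, truth)
  expect_equal(unname(r$tpr[names(bf$tpr)]), unname(bf$tpr))
  expect_equal(unname(r$f1[names(bf$f1)]), unname(bf$f1))
  expect_equal(unname(rowSums(r$confusion)),
               unname(as.vector(table(factor(truth, levels = rownames(r$confusion))))))
})

test_that("generator balancing equalizes stage classes and keeps real data", {
  ds <- make_patch_dataset(c(debris = 20, dense = 30, differentiated = 10,
                             spread = 40), seed = 3, size = 16)
  gen <- fixture_patch_generator(16)
  cc <- classifier_config(epochs = 1, input_size = 16, base_maps = 2, seed = 1)
  sm <- train_stage(stage_spec(1, "generator"), cc, ds, generator = gen)
  expect_equal(sm$train_counts[1], sm$train_counts[2]) # 80 vs 80
  pt <- sm$provenance_table
  expect_equal(unname(pt["real", ]), c(20, 80)) # all real patches intact
  expect_equal(unname(pt["generated", "1"]), 60)
  # counts (100 vs 300) -> training set 300 vs 300
  ds2 <- make_patch_dataset(c(dense = 100, spread = 300), seed = 4, size = 16)
  sm2 <- train_stage(stage_spec(3, "generator"), cc, ds2, generator = gen)
  expect_equal(unname(sm2$train_counts), c(300, 300))
  expect_error(train_stage(stage_spec(1, "generator"), cc, ds),
               "requires a generator")
  only_pos <- make_patch_dataset(c(debris = 5), seed = 1, size = 16)
  expect_error(train_stage(stage_spec(1), cc, only_pos), "lacks")
})

test_that("hierarchical routing assigns exactly one label per patch", {
  ds <- make_patch_dataset(c(debris = 30, dense = 30, differentiated = 30,
                             spread = 30), seed = 5, size = 32)
  cc <- classifier_config(epochs = 25, input_size = 32, base_maps = 4,
                          batch_size = 16, seed = 2)
  hm <- train_hierarchy(ds, cc, seed = 11)
  pred <- route_hierarchy(hm, ds)
  expect_equal(length(pred), n_patches(ds))
  expect_true(all(!is.na(pred)))
  expect_true(all(levels(pred) == morphology_classes()))
  # separable fixture classes: each trained stage is highly accurate
  rep <- evaluate_predictions(pred, as.character(ds$labels))
  expect_gt(rep$accuracy, 0.9)
})

test_that("saturation curve rows follow the increments and the zero row is a no-op", {
  ds <- make_patch_dataset(c(dense = 40, spread = 40), seed = 6, size = 16)
  ds <- make_folds(ds, k = 4, seed = 2)
  gen <- fixture_patch_generator(16)
  cc <- classifier_config(epochs = 4, input_size = 16, base_maps = 2, seed = 3)
  tab <- saturation_curve(ds, gen, c(0, 10, 30), cc, seed = 9)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_added, c(0, 10, 30))
  # increment 0 equals the plain stage-3 run under the same seed
  tab0 <- saturation_curve(ds, gen, 0, cc, seed = 9)
  expect_equal(tab[1, ], tab0[1, ])
  expect_error(saturation_curve(ds, gen, numeric(0), cc), "empty")
})
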