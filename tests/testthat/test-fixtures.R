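test_that("class textures are deterministic, 8-bit, and debris carries a halo", {
  a <- make_class_texture("dense", 64, seed = 1)
  b <- make_class_texture("dense", 64, seed = 1)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 255))
  expect_false(identical(a, make_class_texture("dense", 64, seed = 2)))
  for (s in c(3, 11, 99)) {
    d <- make_class_texture("debris", 64, seed = s)
    expect_gt(sum(d >= 240), 0)
  }
  expect_error(make_class_texture("mystery", 64), "unknown class")
})

test_that("the four texture families are separable by a trivial classifier", {
  # nearest-centroid on 32-bin gray histograms, 200 patches/class,
  # 50/50 train-holdout split; gates all texture-based downstream tests
  classes <- morphology_classes()
  histo <- function(p) tabulate(pmin(31L, p %/% 8L) + 1L, 32L) / length(p)
  feats <- lapply(classes, function(cl)
    vapply(1:200, function(i) histo(make_class_texture(cl, 64, seed = i)),
           numeric(32)))
  cent <- lapply(feats, function(f) rowMeans(f[, 1:100]))
  hold <- lapply(feats, function(f) f[, 101:200])
  hits <- unlist(lapply(seq_along(classes), function(k)
    apply(hold[[k]], 2, function(v)
      which.min(vapply(cent, function(ce) sum((ce - v)^2), 0)) == k)))
  expect_gt(mean(hits), 0.9)
})

test_that("colony scenes honour blob areas and are deterministic", {
  sp <- scene_spec(128, 128,
                   data.frame(class = "dense", area = 5000, cy = 64, cx = 64),
                   seed = 7)
  sc <- make_colony_scene(sp)
  expect_equal(nrow(sc$annotations), 1)
  expect_true(sc$annotations$area >= 4500 && sc$annotations$area <= 5500)
  expect_equal(sc$annotations$area, sum(sc$mask == 1))
  expect_identical(sc$image, make_colony_scene(sp)$image)
  # background stays near the requested level away from the blob
  bg <- sc$image[sc$mask == 0]
  expect_lt(abs(mean(bg) - sp$background_level), 3)
})

test_that("empty scenes and ill-fitting blobs are handled", {
  sc <- make_colony_scene(scene_spec(32, 32, seed = 1))
  expect_true(all(sc$mask == 0))
  expect_equal(nrow(sc$annotations), 0)
  expect_error(make_colony_scene(
    scene_spec(64, 64, data.frame(class = "dense", area = 4000, cy = 5, cx = 32))),
    "does not fit")
})

test_that("mask labels are consecutive and annotations match mask counts", {
  for (seed in 1:5) {
    sp <- scene_spec(160, 160,
                     data.frame(class = c("dense", "debris", "spread"),
                                area = c(2500, 2200, 3000),
                                cy = c(45, 115, 80), cx = c(45, 45, 120)),
                     seed = seed)
    sc <- make_colony_scene(sp)
    labs <- sort(unique(as.integer(sc$mask[sc$mask > 0])))
    expect_identical(labs, seq_along(labs))
    for (k in labs)
      expect_equal(sc$annotations$area[k], sum(sc$mask == k))
  }
})

test_that("patch datasets deliver the requested per-class counts", {
  ds <- make_patch_dataset(c(dense = 10, spread = 10), seed = 1)
  expect_equal(n_patches(ds), 20)
  expect_equal(as.vector(table(ds$labels)[c("dense", "spread")]), c(10, 10))
  expect_equal(dim(ds$images)[1:2], c(64, 64))
  # class proportions mirroring the study's data breakdown, scaled by 1/100
  cts <- round(c(debris = 3587, dense = 3934, diff = 656, spread = 10506) / 100)
  expect_equal(unname(cts), c(36, 39, 7, 105))
  ds2 <- make_patch_dataset(cts, seed = 2, size = 16)
  expect_equal(n_patches(ds2), 187)
  expect_equal(sum(ds2$labels == "differentiated"), 7)
  empty <- make_patch_dataset(c(dense = 0), seed = 1)
  expect_equal(n_patches(empty), 0)
})
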