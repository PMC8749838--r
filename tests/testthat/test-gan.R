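test_that("gan_spec validates its invariants", {
  expect_error(gan_spec(image_size = 30), "multiple of 4")
  expect_error(gan_spec("auxgan"), "n_classes")
  expect_s3_class(gan_spec("auxgan", n_classes = 4), "gan_spec")
})

test_that("generator and discriminator have the contracted shapes", {
  spec <- gan_spec("dcgan", latent_dim = 16, image_size = 16,
                   max_maps_g = 16, max_maps_d = 16)
  set.seed(1)
  models <- build_models(spec)
  eng <- asNamespace("colonyGAN")
  z <- matrix(stats::rnorm(16 * 3), 16)
  out <- eng$g_forward(models, z)$out
  expect_equal(dim(out), c(16, 16, 1, 3))
  expect_true(all(out >= -1 & out <= 1))
  sc <- eng$sigmoid(eng$d_forward(models, out)$adv_logits)
  expect_true(all(sc > 0 & sc < 1))
  # desk-scale 32px spec is shape-consistent end to end
  spec32 <- gan_spec("dcgan", latent_dim = 8, image_size = 32,
                     max_maps_g = 8, max_maps_d = 8)
  m32 <- build_models(spec32)
  o32 <- eng$g_forward(m32, matrix(stats::rnorm(8 * 2), 8))$out
  expect_equal(dim(o32), c(32, 32, 1, 2))
  expect_equal(length(eng$d_forward(m32, o32)$adv_logits), 2)
})

test_that("adversarial loss matches binary cross-entropy closed forms", {
  expect_lt(adversarial_loss(rep(1 - 1e-9, 5), "real"), 1e-6)
  expect_equal(adversarial_loss(0.5, "real"), -log(0.5))
  expect_equal(adversarial_loss(0.5, "fake"), -log(0.5))
  s <- c(0.3, 0.6, 0.9)
  expect_equal(adversarial_loss(s, "real"),
               mean(vapply(s, adversarial_loss, 0, target = "real")))
  expect_error(adversarial_loss(numeric(0)), "empty")
})

test_that("variant loss aggregates follow the stated sums and averages", {
  expect_equal(generator_loss("dcgan", list(adversarial = 0.7)), 0.7)
  expect_equal(generator_loss("auxgan", list(adversarial = 0.7, auxiliary = 0.3)), 1)
  expect_equal(generator_loss("wgan", list(scores = c(1, 3))), -2)
  expect_error(generator_loss("auxgan", list(adversarial = 0.7)), "missing part")
  expect_equal(discriminator_loss("dcgan", list(adversarial_real = 0.6,
                                                adversarial_fake = 0.8)), 0.7)
  expect_equal(discriminator_loss("dcgan_mse",
                                  list(adversarial = 0.7, entropy_mse = 0.0625)),
               0.7625)
  expect_equal(discriminator_loss("dcgan_mse",
                                  list(adversarial = 0.7, entropy_mse = 0)),
               discriminator_loss("dcgan", list(adversarial = 0.7)))
  expect_equal(discriminator_loss("wgan", list(scores_real = c(2, 4),
                                               scores_fake = c(1, 1))), -2)
  expect_error(discriminator_loss("dcgan_mse", list(adversarial = 0.7)),
               "missing part")
})

test_that("weight clipping clamps element-wise and is idempotent", {
  layers <- list(list(type = "dense", W = matrix(c(-0.5, 0.002, 0.5), 1),
                      b = 0))
  cl <- clip_weights(layers, 0.01)
  expect_equal(as.numeric(cl[[1]]$W), c(-0.01, 0.002, 0.01))
  expect_identical(clip_weights(cl, 0.01), cl)
  small <- list(list(type = "dense", W = matrix(c(-0.005, 0.005), 1), b = 0))
  expect_identical(clip_weights(small, 0.01)[[1]]$W, small[[1]]$W)
})

test_that("Metropolis-Hastings selection follows the discriminator odds", {
  expect_equal(mh_acceptance(0.9, 0.1), (0.1 / 0.9) / (0.9 / 0.1),
               tolerance = 1e-12)
  expect_equal(round(mh_acceptance(0.9, 0.1), 4), 0.0123)
  expect_equal(mh_acceptance(0.5, 0.5), 1)
  # equal odds: every proposal accepted, so the chain replays the proposals
  n <- 4
  sel <- mh_select(array(0, c(2, 2, n)), rep(0.5, n), chain_length = 7, seed = 3)
  replay <- colonyGAN:::with_seed(3, {
    cur <- sample.int(n, 1)
    for (t in 1:7) { cur <- sample.int(n, 1); stats::runif(1) }
    cur
  })
  expect_equal(sel$index, replay)
  expect_message(mh_select(array(0, c(2, 2, 2)), c(1, 0.5), 1, 1), "clamped")
  # stationary frequencies on a 2-candidate chain match the odds ratio
  d <- c(0.9, 0.1)
  set.seed(21)
  ends <- vapply(1:3000, function(i)
    mh_select(array(0, c(2, 2, 2)), d, chain_length = 15,
              seed = sample.int(2^31 - 2, 1))$index, 0L)
  odds <- (d / (1 - d)) / sum(d / (1 - d))
  chi <- stats::chisq.test(tabulate(ends, 2), p = odds)
  expect_gt(chi$p.value, 0.01)
})

test_that("short training runs are finite, seeded, and class-isolated", {
  spec <- gan_spec("dcgan", latent_dim = 8, image_size = 16,
                   max_maps_g = 8, max_maps_d = 8)
  cfg <- train_config(batch_size = 16, epochs = 3, seed = 5)
  ds <- tiny_patch_dataset(c(dense = 16))
  f1 <- train_gan(spec, cfg, ds$images)
  expect_equal(nrow(f1$history), 3)
  expect_true(all(is.finite(unlist(f1$history[c("d_loss", "g_loss")]))))
  f2 <- train_gan(spec, cfg, ds$images)
  expect_equal(f1$history, f2$history)
  # entropy-regularized variant with zero weight reproduces dcgan exactly
  spec0 <- gan_spec("dcgan_mse", latent_dim = 8, image_size = 16,
                    max_maps_g = 8, max_maps_d = 8, entropy_loss_weight = 0)
  f3 <- train_gan(spec0, cfg, ds$images)
  expect_equal(f3$history$d_loss, f1$history$d_loss)
  expect_equal(f3$history$g_loss, f1$history$g_loss)
  # one GAN per class: class-A training is unaffected by class-B patches
  dsA <- make_patch_dataset(c(dense = 16, spread = 16), seed = 7, size = 16)
  dsB <- make_patch_dataset(c(dense = 16, spread = 16), seed = 7, size = 16)
  dsB$images[, , dsB$labels == "spread"] <- 0L # corrupt the other class
  fitA <- train_class_gans(dsA, spec, cfg, classes = "dense")
  fitB <- train_class_gans(dsB, spec, cfg, classes = "dense")
  expect_equal(fitA$dense$history, fitB$dense$history)
})

test_that("wgan training keeps critic weights inside the clip bound", {
  spec <- gan_spec("wgan", latent_dim = 8, image_size = 16,
                   max_maps_g = 8, max_maps_d = 8, wgan_clip = 0.01)
  cfg <- train_config(batch_size = 16, epochs = 2, seed = 2)
  fit <- train_gan(spec, cfg, tiny_patch_dataset(c(dense = 16))$images)
  for (l in c(fit$models$trunk, fit$models$adv_head))
    if (colonyGAN:::has_params(l))
      expect_true(all(abs(l$W) <= 0.01 + 1e-12))
})

test_that("aux variants train with labels and condition generation on class", {
  spec <- gan_spec("auxgan", latent_dim = 8, image_size = 16,
                   max_maps_g = 8, max_maps_d = 8, n_classes = 2)
  cfg <- train_config(batch_size = 16, epochs = 2, seed = 4)
  ds <- tiny_patch_dataset(c(dense = 16, spread = 16))
  fit <- train_gan(spec, cfg, ds)
  expect_true(all(is.finite(fit$history$d_loss)))
  g <- generate(fit, 4, seed = 1, class_label = 1)
  expect_equal(dim(g), c(16, 16, 4))
  unlabeled <- ds; unlabeled$labels[] <- NA
  expect_error(train_gan(spec, cfg, unlabeled), "labeled")
})

test_that("generation is deterministic, bounded 8-bit, and sized correctly", {
  spec <- gan_spec("dcgan", latent_dim = 8, image_size = 16,
                   max_maps_g = 8, max_maps_d = 8)
  set.seed(9)
  models <- build_models(spec) # untrained generator
  g1 <- generate(models, 100, seed = 3)
  expect_equal(dim(g1), c(16, 16, 100))
  expect_true(all(g1 >= 0 & g1 <= 255) && !anyNA(g1))
  expect_identical(g1, generate(models, 100, seed = 3))
  expect_error(generate(models, 0), "positive")
  # mh variant routes through discriminator-guided selection
  mspec <- gan_spec("mhgan", latent_dim = 8, image_size = 16,
                    max_maps_g = 8, max_maps_d = 8)
  set.seed(9)
  mmodels <- build_models(mspec)
  gm <- generate(mmodels, 3, seed = 2, pool_size = 8, chain_length = 10)
  expect_equal(dim(gm), c(16, 16, 3))
})
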