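# Class-wise GAN variants built on the package's conv-net engine:
#   dcgan      deep convolutional GAN baseline
#   dcgan_mse  dcGAN with the entropy-histogram MSE term added to the
#              discriminator's aggregate loss
#   wgan       Wasserstein critic with weight clipping
#   auxgan     label-conditioned generator + auxiliary classification head
#   mhgan / aux_mhgan  dcgan/auxgan training with Metropolis-Hastings,
#              discriminator-guided selection at generation time
#
# The generator maps a Gaussian latent vector through a linear projection
# (to a quarter-resolution grid) and two nearest-neighbour upsample +
# convolution stages to a Tanh image in [-1, 1]; the discriminator stacks
# strided convolutions down to a 4x4 grid and a fully connected head.

GAN_VARIANTS <- c("dcgan", "dcgan_mse", "wgan", "auxgan", "mhgan", "aux_mhgan")

is_aux <- function(variant) variant %in% c("auxgan", "aux_mhgan")
is_mh <- function(variant) variant %in% c("mhgan", "aux_mhgan")

#' Specify a GAN architecture
#'
#' @param variant One of `r paste(GAN_VARIANTS, collapse = ", ")`.
#' @param latent_dim Length of the Gaussian latent vector (default 100).
#' @param image_size Output image side; must be a multiple of 4 (default 64).
#' @param max_maps_g,max_maps_d Maximum feature maps in generator /
#'   discriminator (default 512 each).
#' @param n_classes Number of classes (aux variants only, >= 2).
#' @param entropy_loss_weight Weight of the entropy-MSE term (`dcgan_mse`).
#' @param wgan_clip Weight-clipping bound c for the `wgan` critic.
#' @return A `gan_spec` object.
#' @export
gan_spec <- function(variant = "dcgan", latent_dim = 100, image_size = 64,
                     max_maps_g = 512, max_maps_d = 512, n_classes = NULL,
                     entropy_loss_weight = 1, wgan_clip = 0.01) {
  variant <- match.arg(variant, GAN_VARIANTS)
  if (image_size %% 4 != 0)
    stop("image_size must be a multiple of 4, got ", image_size)
  stopifnot(latent_dim >= 1, wgan_clip > 0)
  if (is_aux(variant) && (is.null(n_classes) || n_classes < 2))
    stop("aux variants require n_classes >= 2")
  structure(list(variant = variant, latent_dim = latent_dim,
                 image_size = image_size, max_maps_g = max_maps_g,
                 max_maps_d = max_maps_d, n_classes = n_classes,
                 entropy_loss_weight = entropy_loss_weight,
                 wgan_clip = wgan_clip),
            class = "gan_spec")
}

#' GAN training configuration
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 0.002, beta1 = 0.5, beta2 = 0.999.
#'
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decays (0 <= beta1 < beta2 < 1).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param d_steps Discriminator updates per generator update (the k of the
#'   alternating minimax procedure; default 2, each on a fresh fake batch).
#' @param seed Master seed; fans out to initialization, data order and
#'   noise streams.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 0.002, beta1 = 0.5, beta2 = 0.999,
                         batch_size = 64, epochs = 10, d_steps = 2, seed = 1) {
  stopifnot(lr > 0, beta1 >= 0, beta1 < beta2, beta2 < 1,
            batch_size >= 1, epochs >= 1, d_steps >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = batch_size, epochs = epochs, d_steps = d_steps,
                 seed = seed),
            class = "train_config")
}

#' Build generator and discriminator networks
#'
#' @param spec A [gan_spec()].
#' @return A `gan_models` object holding the generator, discriminator trunk
#'   and heads, and (for aux variants) the label embedding. Weights are
#'   drawn from the current RNG state.
#' @export
build_models <- function(spec) {
  stopifnot(inherits(spec, "gan_spec"))
  s2 <- spec$image_size
  s0 <- s2 %/% 4L
  s1 <- max(s0 + 1L, round(s2 * 36 / 64)) # intermediate grid, 36 at size 64
  f <- spec$max_maps_g
  f2 <- max(1L, f %/% 2L)
  emb_dim <- if (is_aux(spec$variant)) max(1L, spec$latent_dim %/% 4L) else 0L
  gen <- list(
    nn_dense(spec$latent_dim + emb_dim, s0 * s0 * f),
    nn_reshape(c(s0, s0, f)),
    nn_bnorm(f),
    nn_act("relu"),
    nn_upsample(s1),
    nn_conv(f, f),
    nn_bnorm(f),
    nn_act("relu"),
    nn_upsample(s2),
    nn_conv(f, f2),
    nn_bnorm(f2),
    nn_act("relu"),
    nn_conv(f2, 1),
    nn_act("tanh")
  )
  # near-zero output-layer init: the untrained generator emits flat mid-gray
  # patches, so entropy-based metrics start from a clean zero baseline
  gen[[length(gen) - 1]]$W[] <- 0
  nd <- max(1L, round(log2(s2 / 4)))
  chans <- spec$max_maps_d / 2^((nd - 1):0)
  chans <- pmax(1, round(chans))
  trunk <- list()
  s <- s2; c_in <- 1L
  for (i in seq_len(nd)) {
    trunk <- c(trunk, list(nn_conv(c_in, chans[i], k = 3, stride = 2, pad = 1)))
    if (i > 1) trunk <- c(trunk, list(nn_bnorm(chans[i]))) # dcGAN: no BN on conv 1
    trunk <- c(trunk, list(nn_act("lrelu")))
    c_in <- chans[i]
    s <- (s + 2L - 3L) %/% 2L + 1L
  }
  trunk <- c(trunk, list(nn_flatten()))
  feat_dim <- s * s * c_in
  adv_head <- list(nn_dense(feat_dim, 1))
  aux_head <- if (is_aux(spec$variant)) list(nn_dense(feat_dim, spec$n_classes)) else NULL
  emb <- if (emb_dim > 0) list(nn_dense(spec$n_classes, emb_dim)) else NULL
  structure(list(spec = spec, generator = gen, trunk = trunk,
                 adv_head = adv_head, aux_head = aux_head, embedding = emb),
            class = "gan_models")
}

onehot <- function(y, k) {
  m <- matrix(0, k, length(y))
  m[cbind(y, seq_along(y))] <- 1
  m
}

# forward the generator; labels (1..K) required for aux variants
g_forward <- function(models, z, labels = NULL) {
  if (!is.null(models$embedding)) {
    stopifnot(!is.null(labels))
    ef <- nn_forward(models$embedding, onehot(labels, models$spec$n_classes))
    z <- rbind(z, ef$out)
    fw <- nn_forward(models$generator, z)
    fw$emb_caches <- ef$caches
    fw
  } else nn_forward(models$generator, z)
}

# forward the discriminator; returns adversarial logits (and aux logits)
d_forward <- function(models, x) {
  tf <- nn_forward(models$trunk, x)
  af <- nn_forward(models$adv_head, tf$out)
  out <- list(adv_logits = af$out, trunk = tf, adv = af)
  if (!is.null(models$aux_head)) {
    xf <- nn_forward(models$aux_head, tf$out)
    out$aux_logits <- xf$out
    out$aux <- xf
  }
  out
}

#' Adversarial (binary cross-entropy) loss on realness scores
#'
#' @param scores Discriminator scores in (0, 1).
#' @param target `"real"` (label 1) or `"fake"` (label 0).
#' @return Mean binary cross-entropy over the batch.
#' @export
adversarial_loss <- function(scores, target = c("real", "fake")) {
  target <- match.arg(target)
  scores <- as.numeric(scores)
  if (length(scores) == 0) stop("empty batch of scores")
  stopifnot(all(scores > 0 & scores < 1))
  t <- if (target == "real") 1 else 0
  -mean(t * log(scores) + (1 - t) * log(1 - scores))
}

#' Aggregate generator loss for a GAN variant
#'
#' dcGAN-family variants use the adversarial term on the generated batch
#' (with the generator's target being "real"); aux variants add the
#' auxiliary classification term; the Wasserstein generator minimizes the
#' negated mean critic score.
#'
#' @param variant GAN variant name.
#' @param parts Named list: `adversarial` (and `auxiliary` for aux
#'   variants), or `scores` (raw critic outputs) for `wgan`.
#' @return Scalar loss.
#' @export
generator_loss <- function(variant, parts) {
  variant <- match.arg(variant, GAN_VARIANTS)
  need <- function(nm) {
    if (is.null(parts[[nm]])) stop("generator_loss(", variant,
                                   "): missing part '", nm, "'")
    parts[[nm]]
  }
  if (variant == "wgan") return(-mean(need("scores")))
  if (is_aux(variant)) return(need("adversarial") + need("auxiliary"))
  need("adversarial")
}

#' Aggregate discriminator loss for a GAN variant
#'
#' The dcGAN aggregate is the average of the real-batch and fake-batch
#' adversarial losses; `dcgan_mse` adds `lambda` times the entropy-MSE
#' between the real and generated mini-batch entropy histograms; aux
#' variants add the averaged auxiliary classification losses; the
#' Wasserstein critic uses `mean(fake) - mean(real)` raw scores.
#'
#' @param variant GAN variant name.
#' @param parts Named list. For dcGAN-family: `adversarial_real` and
#'   `adversarial_fake` (or a combined `adversarial`); for `dcgan_mse` also
#'   `entropy_mse` (and optional `lambda`, default 1); for aux variants also
#'   `auxiliary_real`/`auxiliary_fake`; for `wgan`: `scores_real`,
#'   `scores_fake`.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(variant, parts) {
  variant <- match.arg(variant, GAN_VARIANTS)
  need <- function(nm) {
    if (is.null(parts[[nm]])) stop("discriminator_loss(", variant,
                                   "): missing part '", nm, "'")
    parts[[nm]]
  }
  if (variant == "wgan")
    return(mean(need("scores_fake")) - mean(need("scores_real")))
  adv <- if (!is.null(parts$adversarial)) parts$adversarial
         else mean(c(need("adversarial_real"), need("adversarial_fake")))
  if (variant == "dcgan_mse") {
    lambda <- if (is.null(parts$lambda)) 1 else parts$lambda
    return(adv + lambda * need("entropy_mse"))
  }
  if (is_aux(variant))
    return(adv + mean(c(need("auxiliary_real"), need("auxiliary_fake"))))
  adv
}

#' Clip discriminator weights to \[-c, c\]
#'
#' Element-wise clamping of every discriminator parameter (the Wasserstein
#' weight-clipping step); idempotent.
#'
#' @param models A `gan_models` object (or a bare layer list).
#' @param c Positive clipping bound.
#' @return The object with clipped discriminator weights.
#' @export
clip_weights <- function(models, c = 0.01) {
  stopifnot(c > 0)
  clip_layers <- function(layers) lapply(layers, function(l) {
    if (has_params(l)) {
      l$W <- pmin(pmax(l$W, -c), c)
      l$b <- pmin(pmax(l$b, -c), c)
    }
    l
  })
  if (inherits(models, "gan_models")) {
    models$trunk <- clip_layers(models$trunk)
    models$adv_head <- clip_layers(models$adv_head)
    if (!is.null(models$aux_head)) models$aux_head <- clip_layers(models$aux_head)
    models
  } else clip_layers(models)
}

#' Metropolis-Hastings acceptance probability
#'
#' For the discriminator-guided chain with stationary odds
#' \eqn{D(x)/(1-D(x))}: \eqn{\alpha = \min(1, odds(x')/odds(x))}.
#'
#' @param d_current,d_proposal Discriminator scores in (0, 1).
#' @return Acceptance probability.
#' @export
mh_acceptance <- function(d_current, d_proposal) {
  odds <- function(d) d / (1 - d)
  min(1, odds(d_proposal) / odds(d_current))
}

#' Metropolis-Hastings selection over generated candidates
#'
#' Runs a Metropolis-Hastings chain with uniform independent proposals over
#' the candidate pool; the stationary distribution over candidates is
#' proportional to the discriminator odds D(x)/(1-D(x)). Scores exactly 0
#' or 1 are clamped into (eps, 1-eps) with a message.
#'
#' @param candidates Candidate images as a `(h, w, n)` array (or any list);
#'   only indexed, never modified.
#' @param d_scores Discriminator scores for the candidates.
#' @param chain_length Number of proposals (>= 1).
#' @param seed Integer seed; selection is deterministic per seed.
#' @return List with `index` (selected candidate) and `image` (if
#'   `candidates` is an array).
#' @export
mh_select <- function(candidates, d_scores, chain_length = 100, seed = 1) {
  n <- length(d_scores)
  stopifnot(n >= 1, chain_length >= 1)
  eps <- 1e-6
  if (any(d_scores <= 0 | d_scores >= 1)) {
    message("discriminator score(s) at 0/1 clamped into (eps, 1-eps)")
    d_scores <- pmin(pmax(d_scores, eps), 1 - eps)
  }
  with_seed(seed, {
    cur <- sample.int(n, 1)
    for (t in seq_len(chain_length)) {
      prop <- sample.int(n, 1)
      if (stats::runif(1) < mh_acceptance(d_scores[cur], d_scores[prop]))
        cur <- prop
    }
    out <- list(index = cur)
    if (is.array(candidates) && length(dim(candidates)) == 3)
      out$image <- candidates[, , cur]
    out
  })
}

denormalize_patches <- function(x) {
  # (h, w, 1, n) tanh output in [-1, 1] -> (h, w, n) 8-bit integers
  d <- dim(x)
  img <- round((x + 1) / 2 * 255)
  img[img < 0] <- 0; img[img > 255] <- 255
  array(as.integer(img), c(d[1], d[2], d[4]))
}

normalize_patches <- function(imgs) {
  # (h, w, n) 0..255 -> (h, w, 1, n) in [-1, 1]
  d <- dim(imgs)
  array(imgs / 255 * 2 - 1, c(d[1], d[2], 1L, d[3]))
}

#' Train a GAN on real patches
#'
#' Alternating discriminator/generator Adam updates with the variant's
#' aggregate losses. Per epoch the history records the mean discriminator
#' and generator losses, the entropy-MSE term, the entropy-histogram
#' overlap between a freshly generated sample and a fixed real sample, and
#' (if an embedding is supplied) the inception score and FID of the
#' generated sample. Fully deterministic given `config$seed`.
#'
#' @param spec A [gan_spec()].
#' @param config A [train_config()].
#' @param real_patches A `patch_dataset` or `(h, w, n)` array of 8-bit
#'   patches of side `spec$image_size`. For aux variants the dataset must
#'   carry class labels.
#' @param embedding Optional embedding/classifier from
#'   [fit_texture_embedding()] used to track inception score and FID.
#' @param target_class With `embedding`: the class this GAN models. The
#'   best-epoch generator is then selected by the mean posterior
#'   probability that generated images belong to that class (class
#'   fidelity), instead of inception score / overlap.
#' @param eval_n Generated sample size for the per-epoch metrics.
#' @param checkpoint_dir,checkpoint_every Optional: save the model state to
#'   `checkpoint_dir/epoch-<e>.rds` every `checkpoint_every` epochs.
#' @param verbose Print per-epoch progress.
#' @return A `gan_fit`: trained `models`, the `spec`/`config`, and a
#'   per-epoch `history` data frame.
#' @export
train_gan <- function(spec, config, real_patches, embedding = NULL,
                      target_class = NULL, eval_n = 128,
                      checkpoint_dir = NULL, checkpoint_every = 10,
                      verbose = FALSE) {
  stopifnot(inherits(spec, "gan_spec"), inherits(config, "train_config"))
  labels <- NULL
  if (inherits(real_patches, "patch_dataset")) {
    if (is_aux(spec$variant)) {
      labels <- as.integer(droplevels(real_patches$labels))
      if (anyNA(labels)) stop("aux variants require labeled patches")
    }
    real_patches <- real_patches$images
  }
  d <- dim(real_patches)
  stopifnot(length(d) == 3, d[1] == spec$image_size, d[2] == spec$image_size,
            d[3] >= 1)
  n <- d[3]
  bins <- default_entropy_bins()
  with_seed(config$seed, {
    models <- build_models(spec)
    ad_g <- adam_init(models$generator)
    ad_t <- adam_init(models$trunk)
    ad_a <- adam_init(models$adv_head)
    ad_x <- if (!is.null(models$aux_head)) adam_init(models$aux_head)
    ad_e <- if (!is.null(models$embedding)) adam_init(models$embedding)
    x_all <- normalize_patches(real_patches)
    eval_real_idx <- sample.int(n, min(n, eval_n))
    h_real_eval <- entropy_histogram(real_patches[, , eval_real_idx, drop = FALSE], bins)
    bsz <- min(config$batch_size, n)
    hist_rows <- vector("list", config$epochs)
    best_models <- NULL; best_epoch <- NA_integer_; best_metric <- -Inf
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      nb <- length(ord) %/% bsz
      dl <- gl <- el <- numeric(nb)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * bsz + 1):(bi * bsz)]
        xr <- x_all[, , , idx, drop = FALSE]
        yr <- if (!is.null(labels)) labels[idx]
        ## ---- discriminator update(s): separate real and fake passes, so
        ## batch-norm statistics never mix the two sources ----
        d_loss <- ent_term <- 0
        for (dsi in seq_len(config$d_steps)) {
          z <- matrix(stats::rnorm(spec$latent_dim * bsz), spec$latent_dim)
          yf <- if (!is.null(labels)) sample.int(spec$n_classes, bsz, replace = TRUE)
          xf <- g_forward(models, z, yf)$out
          dfw_r <- d_forward(models, xr)
          dfw_f <- d_forward(models, xf)
          if (spec$variant == "wgan") {
            d_loss_i <- mean(dfw_f$adv_logits) - mean(dfw_r$adv_logits)
            dadv_r <- matrix(rep(-1 / bsz, bsz), nrow = 1)
            dadv_f <- matrix(rep(1 / bsz, bsz), nrow = 1)
          } else {
            blr <- bce_logits(dfw_r$adv_logits, rep(1, bsz))
            blf <- bce_logits(dfw_f$adv_logits, rep(0, bsz))
            d_loss_i <- (blr$loss + blf$loss) / 2 # Eq-style source average
            dadv_r <- blr$dlogits / 2
            dadv_f <- blf$dlogits / 2
          }
          bwa_r <- nn_backward(models$adv_head, dfw_r$adv$caches, dadv_r)
          bwa_f <- nn_backward(models$adv_head, dfw_f$adv$caches, dadv_f)
          ga <- sum_grads(bwa_r$grads, bwa_f$grads)
          dfeat_r <- bwa_r$dx
          dfeat_f <- bwa_f$dx
          if (!is.null(models$aux_head)) {
            clr <- ce_loss_grad(dfw_r$aux_logits, yr)
            clf <- ce_loss_grad(dfw_f$aux_logits, yf)
            d_loss_i <- d_loss_i + (clr$loss + clf$loss) / 2
            bwx_r <- nn_backward(models$aux_head, dfw_r$aux$caches, clr$dlogits / 2)
            bwx_f <- nn_backward(models$aux_head, dfw_f$aux$caches, clf$dlogits / 2)
            dfeat_r <- dfeat_r + bwx_r$dx
            dfeat_f <- dfeat_f + bwx_f$dx
            st <- adam_step(models$aux_head, sum_grads(bwx_r$grads, bwx_f$grads),
                            ad_x, config$lr, config$beta1, config$beta2)
            models$aux_head <- st$layers; ad_x <- st$state
          }
          if (spec$variant == "dcgan_mse") {
            hr <- entropy_histogram(denormalize_patches(xr), bins)
            hf <- entropy_histogram(denormalize_patches(xf), bins)
            ent_i <- spec$entropy_loss_weight * entropy_mse(hr, hf)
            ent_term <- ent_term + ent_i / config$d_steps
            d_loss_i <- d_loss_i + ent_i # zero-gradient monitoring term
          }
          bwt_r <- nn_backward(models$trunk, dfw_r$trunk$caches, dfeat_r)
          bwt_f <- nn_backward(models$trunk, dfw_f$trunk$caches, dfeat_f)
          st <- adam_step(models$adv_head, ga, ad_a, config$lr,
                          config$beta1, config$beta2)
          models$adv_head <- st$layers; ad_a <- st$state
          st <- adam_step(models$trunk, sum_grads(bwt_r$grads, bwt_f$grads),
                          ad_t, config$lr, config$beta1, config$beta2)
          models$trunk <- st$layers; ad_t <- st$state
          if (spec$variant == "wgan") models <- clip_weights(models, spec$wgan_clip)
          d_loss <- d_loss + d_loss_i / config$d_steps
        }
        ## ---- generator update ----
        z <- matrix(stats::rnorm(spec$latent_dim * bsz), spec$latent_dim)
        yf <- if (!is.null(labels)) sample.int(spec$n_classes, bsz, replace = TRUE)
        gfw <- g_forward(models, z, yf)
        dfw <- d_forward(models, gfw$out)
        if (spec$variant == "wgan") {
          g_loss <- -mean(dfw$adv_logits)
          dadv <- matrix(rep(-1 / bsz, bsz), nrow = 1)
        } else {
          bl <- bce_logits(dfw$adv_logits, rep(1, bsz))
          g_loss <- bl$loss
          dadv <- bl$dlogits
        }
        bwa <- nn_backward(models$adv_head, dfw$adv$caches, dadv)
        dfeat <- bwa$dx
        if (!is.null(models$aux_head)) {
          cl <- ce_loss_grad(dfw$aux_logits, yf)
          g_loss <- g_loss + cl$loss
          bwx <- nn_backward(models$aux_head, dfw$aux$caches, cl$dlogits)
          dfeat <- dfeat + bwx$dx
        }
        bwt <- nn_backward(models$trunk, dfw$trunk$caches, dfeat)
        bwg <- nn_backward(models$generator, gfw$caches, bwt$dx)
        st <- adam_step(models$generator, bwg$grads, ad_g, config$lr,
                        config$beta1, config$beta2)
        models$generator <- st$layers; ad_g <- st$state
        if (!is.null(models$embedding)) {
          demb <- bwg$dx[spec$latent_dim + seq_len(nrow(models$embedding[[1]]$W)), ,
                         drop = FALSE]
          bwe <- nn_backward(models$embedding, gfw$emb_caches, demb)
          st <- adam_step(models$embedding, bwe$grads, ad_e, config$lr,
                          config$beta1, config$beta2)
          models$embedding <- st$layers; ad_e <- st$state
        }
        if (!is.finite(d_loss) || !is.finite(g_loss))
          stop("non-finite loss at epoch ", ep, " batch ", bi,
               " (d=", d_loss, ", g=", g_loss, ")")
        dl[bi] <- d_loss; gl[bi] <- g_loss; el[bi] <- ent_term
      }
      ## ---- per-epoch evaluation ----
      zev <- matrix(stats::rnorm(spec$latent_dim * eval_n), spec$latent_dim)
      yev <- if (!is.null(labels)) sample.int(spec$n_classes, eval_n, replace = TRUE)
      fake_ev <- denormalize_patches(g_forward(models, zev, yev)$out)
      ov <- histogram_overlap(h_real_eval, entropy_histogram(fake_ev, bins))
      is_val <- fid_val <- cls_val <- NA_real_
      if (!is.null(embedding)) suppressMessages({
        pr <- predict_probs(embedding, fake_ev)
        is_val <- inception_score(pr)
        fr <- embed_features(embedding, real_patches[, , eval_real_idx, drop = FALSE])
        ff <- embed_features(embedding, fake_ev)
        fid_val <- fid(fr, ff)
        if (!is.null(target_class))
          cls_val <- mean(pr[, normalize_class(target_class)])
      })
      hist_rows[[ep]] <- data.frame(
        epoch = ep, d_loss = mean(dl), g_loss = mean(gl),
        entropy_loss = mean(el), overlap = ov,
        inception_score = is_val, fid = fid_val, class_fidelity = cls_val)
      # optimal-epoch tracking: class fidelity when the target class is
      # known, else inception score with an embedding, else the
      # entropy-histogram overlap
      sel <- if (!is.null(embedding) && !is.null(target_class)) cls_val
             else if (!is.null(embedding)) is_val else ov
      if (is.finite(sel) && sel > best_metric) {
        best_metric <- sel; best_epoch <- ep; best_models <- models
      }
      if (verbose)
        message(sprintf("epoch %3d  d %.4f  g %.4f  overlap %.3f",
                        ep, mean(dl), mean(gl), ov))
      if (!is.null(checkpoint_dir) && ep %% checkpoint_every == 0) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(list(models = models, epoch = ep,
                     history = do.call(rbind, hist_rows[seq_len(ep)])),
                file.path(checkpoint_dir, sprintf("epoch-%04d.rds", ep)))
      }
    }
    structure(list(models = models, spec = spec, config = config,
                   history = do.call(rbind, hist_rows),
                   best_models = best_models, best_epoch = best_epoch),
              class = "gan_fit")
  })
}

#' Generate patches from a trained generator
#'
#' Feeds Gaussian noise through the generator and de-normalizes the Tanh
#' output to 8-bit gray. For Metropolis-Hastings variants each returned
#' patch is selected by a discriminator-guided chain over a candidate pool.
#'
#' @param fit A `gan_fit` (or `gan_models`).
#' @param n Number of patches (> 0).
#' @param seed Integer seed.
#' @param class_label Class index 1..K (aux variants only).
#' @param pool_size,chain_length Metropolis-Hastings candidate pool and
#'   chain length (mh variants).
#' @param use `"best"` (default) generates from the optimal-epoch
#'   generator tracked during training, `"final"` from the last epoch.
#' @param mh Force Metropolis-Hastings selection even for non-mh variants
#'   (default: only mh variants select); the trained discriminator then
#'   filters each output from a candidate pool.
#' @return `(h, w, n)` integer array of 8-bit patches.
#' @export
generate <- function(fit, n, seed = 1, class_label = NULL,
                     pool_size = 32, chain_length = 100,
                     use = c("best", "final"), mh = NULL) {
  if (n <= 0) stop("n must be positive")
  use <- match.arg(use)
  models <- if (inherits(fit, "gan_fit")) {
    if (use == "best" && !is.null(fit$best_models)) fit$best_models
    else fit$models
  } else fit
  spec <- models$spec
  if (is.null(mh)) mh <- is_mh(spec$variant)
  with_seed(seed, {
    make_batch <- function(m) {
      z <- matrix(stats::rnorm(spec$latent_dim * m), spec$latent_dim)
      y <- if (is_aux(spec$variant)) {
        if (is.null(class_label)) sample.int(spec$n_classes, m, replace = TRUE)
        else rep(as.integer(class_label), m)
      }
      denormalize_patches(g_forward(models, z, y)$out)
    }
    if (!mh) return(make_batch(n))
    out <- array(0L, c(spec$image_size, spec$image_size, n))
    for (i in seq_len(n)) {
      pool <- make_batch(pool_size)
      sc <- sigmoid(as.numeric(d_forward(models, normalize_patches(pool))$adv_logits))
      sel <- mh_select(pool, sc, chain_length = chain_length,
                      seed = sample.int(.Machine$integer.max, 1))
      out[, , i] <- sel$image
    }
    out
  })
}

#' Train one GAN per morphological class
#'
#' Each class's GAN sees only that class's patches (the class-wise
#' modeling scheme); classes absent from the dataset are skipped.
#'
#' @param ds A labeled `patch_dataset`.
#' @param spec A [gan_spec()] shared across classes (non-aux variant).
#' @param config A [train_config()]; per-class seeds are derived from
#'   `config$seed`.
#' @param classes Classes to train (default: all present).
#' @param target_updates If set, each class's epoch count is chosen so that
#'   its generator receives about this many optimizer updates — smaller
#'   classes train for more epochs, mirroring the observation that the
#'   optimal epoch grows as class size shrinks. `NULL` uses
#'   `config$epochs` for every class.
#' @param ... Passed to [train_gan()].
#' @return Named list of `gan_fit` objects.
#' @export
train_class_gans <- function(ds, spec, config, classes = NULL,
                             target_updates = NULL, ...) {
  present <- levels(droplevels(ds$labels))
  if (is.null(classes)) classes <- present
  fits <- list()
  for (cl in classes) {
    idx <- which(as.character(ds$labels) == cl & ds$provenance == "real")
    cfg <- config
    cfg$seed <- derive_seed(config$seed, match(cl, morphology_classes()))
    imgs <- subset_patches(ds, idx)$images
    if (dim(imgs)[1] != spec$image_size)
      imgs <- resize_nearest(imgs, spec$image_size)
    if (!is.null(target_updates)) {
      per_epoch <- max(1L, dim(imgs)[3] %/% min(cfg$batch_size, dim(imgs)[3]))
      cfg$epochs <- max(1L, round(target_updates / per_epoch))
    }
    fits[[cl]] <- train_gan(spec, cfg, imgs, target_class = cl, ...)
  }
  fits
}

#' Patch generator backed by trained class GANs
#'
#' Wraps a named list of per-class `gan_fit` objects into the
#' `(class_label, n, seed)` generator interface used for stage balancing;
#' patches are nearest-neighbour resized to `size_out` when the GAN's
#' native size differs.
#'
#' @param fits Named list of `gan_fit` objects (names are class labels).
#' @param size_out Output patch side (default 64).
#' @param mh Apply discriminator-guided Metropolis-Hastings selection to
#'   every drawn patch (default `FALSE`).
#' @param pool_size,chain_length MH parameters when `mh = TRUE`.
#' @return A generator function returning `(size_out, size_out, n)` arrays.
#' @export
gan_patch_generator <- function(fits, size_out = 64, mh = FALSE,
                                pool_size = 12, chain_length = 30) {
  force(fits); force(size_out); force(mh)
  force(pool_size); force(chain_length)
  function(class_label, n, seed = 1) {
    cl <- normalize_class(class_label)
    if (is.null(fits[[cl]])) stop("no trained GAN for class ", cl)
    imgs <- generate(fits[[cl]], n, seed = seed, mh = if (mh) TRUE,
                     pool_size = pool_size, chain_length = chain_length)
    if (dim(imgs)[1] != size_out) imgs <- resize_nearest(imgs, size_out)
    storage.mode(imgs) <- "integer"
    imgs
  }
}
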