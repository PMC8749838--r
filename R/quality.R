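# Generated-image quality control: inception score (exponentiated mean KL
# between per-image class posteriors and their marginal), Frechet inception
# distance between Gaussian fits to embedding features, and optimal-epoch
# selection from a training history. The embedding/classifier is a softmax
# model on hand-crafted texture features trained on the fixture classes; a
# pretrained natural-image network is neither available offline nor
# meaningful on synthetic textures.

#' Inception score from class posteriors
#'
#' \eqn{\exp(\mathrm{mean}_i D_{KL}(p(y|x_i) \,\|\, p(y)))}, averaged over
#' `n_splits` equal splits. Ranges from 1 (all posteriors equal to the
#' marginal) to the number of classes (confident and evenly spread).
#'
#' @param class_probabilities Matrix, one row per image, rows summing to 1.
#' @param n_splits Number of splits (default 1; 10 is customary for large
#'   samples).
#' @return The score (mean over splits), with the per-split values as the
#'   `"splits"` attribute.
#' @export
inception_score <- function(class_probabilities, n_splits = 1) {
  p <- as.matrix(class_probabilities)
  if (any(abs(rowSums(p) - 1) > 1e-6) || any(p < 0))
    stop("rows of class_probabilities must be probability vectors summing to 1")
  n <- nrow(p)
  stopifnot(n >= 1, n_splits >= 1, n_splits <= n)
  split_id <- rep_len(seq_len(n_splits), n)
  scores <- vapply(seq_len(n_splits), function(s) {
    ps <- p[split_id == s, , drop = FALSE]
    py <- colMeans(ps)
    kl <- apply(ps, 1, function(r) {
      nz <- r > 0
      sum(r[nz] * (log(r[nz]) - log(py[nz])))
    })
    exp(mean(kl))
  }, 0)
  structure(mean(scores), splits = scores)
}

sqrtm_sym <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- e$values
  if (any(v < -1e-8 * max(abs(v), 1)))
    message("negative covariance eigenvalue(s) truncated in matrix sqrt")
  v <- pmax(v, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two feature distributions
#'
#' Fits a Gaussian to each feature set and returns
#' \eqn{\|\mu_1-\mu_2\|^2 + \mathrm{Tr}(\Sigma_1+\Sigma_2 -
#' 2(\Sigma_1\Sigma_2)^{1/2})}. Near-singular covariances are stabilized by
#' a small diagonal regularization (logged).
#'
#' @param features_real,features_fake Matrices (samples x features) with
#'   equal feature dimension and >= 2 samples each.
#' @return Non-negative distance; 0 for identical distributions.
#' @export
fid <- function(features_real, features_fake) {
  fr <- as.matrix(features_real); ff <- as.matrix(features_fake)
  stopifnot(nrow(fr) >= 2, nrow(ff) >= 2, ncol(fr) == ncol(ff))
  mu1 <- colMeans(fr); mu2 <- colMeans(ff)
  s1 <- stats::cov(fr); s2 <- stats::cov(ff)
  jitter <- function(S) {
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(abs(ev), 1)) {
      message("near-singular covariance regularized with a small diagonal")
      S <- S + diag(1e-8, nrow(S))
    }
    S
  }
  s1 <- jitter(s1); s2 <- jitter(s2)
  sq1 <- sqrtm_sym(s1)
  covmean <- sqrtm_sym(sq1 %*% s2 %*% sq1)
  val <- sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) -
    2 * sum(diag(covmean))
  max(0, val)
}

#' Select the optimal generator epoch
#'
#' The epoch with the maximal inception score (ties broken by the earliest
#' epoch) — the criterion used to pick which checkpoint generates the
#' augmentation images.
#'
#' @param history A `gan_fit` history data frame (or a `gan_fit`) with
#'   `epoch` and `inception_score` columns.
#' @return List with `epoch` and `score`.
#' @export
select_optimal_epoch <- function(history) {
  if (inherits(history, "gan_fit")) history <- history$history
  stopifnot(is.data.frame(history))
  h <- history[is.finite(history$inception_score), , drop = FALSE]
  if (nrow(h) == 0) stop("history has no inception scores")
  i <- which.max(h$inception_score) # which.max returns the first maximum
  list(epoch = h$epoch[i], score = h$inception_score[i])
}

#' Hand-crafted texture features for a patch batch
#'
#' Per patch: the 32-bin normalized gray histogram, mean and standard
#' deviation of gray (scaled to \[0,1\]), Shannon entropy (scaled by 8),
#' and the mean and standard deviation of horizontal/vertical gradient
#' magnitudes.
#'
#' @param patches `(h, w, n)` array, list of matrices, or `patch_dataset`.
#' @return Numeric matrix (n x 37).
#' @export
texture_features <- function(patches) {
  pl <- as_patch_list(patches)
  t(vapply(pl, function(m) {
    v <- as.numeric(m)
    hst <- tabulate(pmin(31L, floor(v / 8)) + 1L, nbins = 32L) / length(v)
    gx <- diff(t(m)); gy <- diff(m)
    g <- c(abs(gx), abs(gy)) / 255
    c(hst, mean(v) / 255, stats::sd(v) / 255, shannon_entropy(m) / 8,
      mean(g), stats::sd(g))
  }, numeric(37)))
}

#' Fit the texture embedding / classifier
#'
#' Multinomial logistic regression (via \pkg{nnet}) on
#' [texture_features()], trained on labeled patches. Supplies the class
#' posteriors for the inception score and the (standardized) feature
#' vectors for FID.
#'
#' @param ds A labeled `patch_dataset` (or a `(h, w, n)` array, with
#'   `labels` given).
#' @param labels Class labels when `ds` is a plain array.
#' @return A `texture_embedding` object.
#' @export
fit_texture_embedding <- function(ds, labels = NULL) {
  if (inherits(ds, "patch_dataset")) {
    labels <- droplevels(ds$labels)
    ds <- ds$images
  }
  stopifnot(!is.null(labels))
  x <- texture_features(ds)
  mu <- colMeans(x); sdev <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- scale(x, mu, sdev)
  df <- data.frame(y = factor(labels), xs)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, MaxNWts = 5000)
  structure(list(fit = fit, mu = mu, sd = sdev,
                 classes = levels(factor(labels))),
            class = "texture_embedding")
}

#' Class posteriors from the texture embedding
#' @param embedding A `texture_embedding`.
#' @param patches Patches (array, list, or `patch_dataset`).
#' @return Matrix (n x K) of class probabilities.
#' @export
predict_probs <- function(embedding, patches) {
  xs <- scale(texture_features(patches), embedding$mu, embedding$sd)
  pr <- stats::predict(embedding$fit, newdata = data.frame(xs), type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr) # two-class case
  pr <- as.matrix(pr)
  colnames(pr) <- embedding$classes
  pr
}

#' Standardized feature vectors from the texture embedding
#' @param embedding A `texture_embedding`.
#' @param patches Patches (array, list, or `patch_dataset`).
#' @return Matrix (n x 37) of standardized features.
#' @export
embed_features <- function(embedding, patches) {
  unname(scale(texture_features(patches), embedding$mu, embedding$sd))
}
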