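# Minimal convolutional network engine used by the GAN variants and the
# stage classifiers. Layers operate on arrays of shape (H, W, C, N) in
# [-1, 1] (images) or matrices (features x N). All randomness goes through
# R's RNG so runs are reproducible from a single seed.

# init: "dcgan" = N(0, 0.02) as in the dcGAN recipe (Adam training);
#        "he"    = N(0, sqrt(2/fan_in)), suited to plain SGD classifiers
nn_dense <- function(n_in, n_out, init = "dcgan") {
  sd <- if (init == "he") sqrt(2 / n_in) else 0.02
  list(type = "dense",
       W = matrix(stats::rnorm(n_out * n_in, 0, sd), n_out, n_in),
       b = numeric(n_out))
}

nn_conv <- function(c_in, c_out, k = 3L, stride = 1L, pad = 1L, init = "dcgan") {
  fan_in <- k * k * c_in
  sd <- if (init == "he") sqrt(2 / fan_in) else 0.02
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), c_in = c_in, c_out = c_out,
       W = matrix(stats::rnorm(c_out * fan_in, 0, sd), c_out, fan_in),
       b = numeric(c_out))
}

nn_upsample <- function(out_hw) list(type = "upsample", out_hw = as.integer(out_hw))

# feature matrix (prod(dims) x N) -> array (dims, N)
nn_reshape <- function(dims) list(type = "reshape", dims = as.integer(dims))

nn_flatten <- function() list(type = "flatten")

nn_act <- function(fun = c("relu", "lrelu", "tanh")) {
  list(type = "act", fun = match.arg(fun))
}

# per-channel batch normalization (batch statistics; learned gamma/beta are
# stored as W/b so the optimizers treat them like any other parameters)
nn_bnorm <- function(c) {
  list(type = "bnorm", c = c, W = rep(1, c), b = numeric(c), eps = 1e-5)
}

nn_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(x = x)
      x <- l$W %*% x + l$b
    } else if (l$type == "conv") {
      d <- dim(x)
      cols <- im2col_cpp(x, l$k, l$stride, l$pad)
      out <- l$W %*% cols + l$b
      oh <- (d[1] + 2L * l$pad - l$k) %/% l$stride + 1L
      ow <- (d[2] + 2L * l$pad - l$k) %/% l$stride + 1L
      caches[[i]] <- list(cols = cols, dims = d, oh = oh, ow = ow)
      x <- aperm(array(out, c(l$c_out, oh, ow, d[4])), c(2, 3, 1, 4))
    } else if (l$type == "upsample") {
      d <- dim(x)
      s <- l$out_hw
      iy <- floor((0:(s - 1)) * d[1] / s) + 1L
      ix <- floor((0:(s - 1)) * d[2] / s) + 1L
      caches[[i]] <- list(dims = d, iy = iy, ix = ix)
      x <- x[iy, ix, , , drop = FALSE]
    } else if (l$type == "reshape") {
      caches[[i]] <- list(n = ncol(x))
      x <- array(x, c(l$dims, ncol(x)))
    } else if (l$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(dims = d)
      x <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
    } else if (l$type == "bnorm") {
      d <- dim(x)
      xm <- aperm(x, c(1, 2, 4, 3))          # (H, W, N, C)
      dim(xm) <- c(d[1] * d[2] * d[4], d[3]) # rows = spatial x batch
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      istd <- 1 / sqrt(colMeans(xc^2) + l$eps)
      xhat <- sweep(xc, 2, istd, "*")
      y <- sweep(sweep(xhat, 2, l$W, "*"), 2, l$b, "+")
      caches[[i]] <- list(dims = d, xhat = xhat, istd = istd)
      dim(y) <- c(d[1], d[2], d[4], d[3])
      x <- aperm(y, c(1, 2, 4, 3))
    } else if (l$type == "act") {
      if (l$fun == "relu") {
        y <- x; y[y < 0] <- 0
      } else if (l$fun == "lrelu") {
        y <- x; neg <- x < 0; y[neg] <- 0.2 * x[neg]
      } else {
        y <- tanh(x)
      }
      caches[[i]] <- list(x = x, y = y)
      x <- y
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, caches = caches)
}

# Returns list(dx = gradient w.r.t. input, grads = per-layer list(W, b) or NULL)
nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; cc <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = dout %*% t(cc$x), b = rowSums(dout))
      dout <- crossprod(l$W, dout)
    } else if (l$type == "conv") {
      d <- cc$dims
      dmat <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = l$c_out)
      grads[[i]] <- list(W = dmat %*% t(cc$cols), b = rowSums(dmat))
      dcols <- crossprod(l$W, dmat)
      dout <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    } else if (l$type == "upsample") {
      d <- cc$dims; s <- l$out_hw
      g <- rep(cc$iy, times = s) + d[1] * (rep(cc$ix, each = s) - 1L)
      m <- matrix(dout, nrow = s * s)
      rs <- rowsum(m, group = g)
      dx <- matrix(0, d[1] * d[2], d[3] * d[4])
      dx[as.integer(rownames(rs)), ] <- rs
      dout <- array(dx, d)
    } else if (l$type == "reshape") {
      dout <- matrix(dout, ncol = cc$n)
    } else if (l$type == "flatten") {
      dout <- array(dout, cc$dims)
    } else if (l$type == "bnorm") {
      d <- cc$dims
      m <- d[1] * d[2] * d[4]
      dm <- aperm(dout, c(1, 2, 4, 3))
      dim(dm) <- c(m, d[3])
      grads[[i]] <- list(W = colSums(dm * cc$xhat), b = colSums(dm))
      dxhat <- sweep(dm, 2, l$W, "*")
      t1 <- colMeans(dxhat)
      t2 <- colMeans(dxhat * cc$xhat)
      dx <- sweep(dxhat, 2, t1) - sweep(cc$xhat, 2, t2, "*")
      dx <- sweep(dx, 2, cc$istd, "*")
      dim(dx) <- c(d[1], d[2], d[4], d[3])
      dout <- aperm(dx, c(1, 2, 4, 3))
    } else if (l$type == "act") {
      if (l$fun == "relu") {
        dout <- dout * (cc$x > 0)
      } else if (l$fun == "lrelu") {
        m <- array(1, dim(cc$x)); m[cc$x < 0] <- 0.2
        dout <- dout * m
      } else {
        dout <- dout * (1 - cc$y^2)
      }
    }
  }
  list(dx = dout, grads = grads)
}

has_params <- function(l) l$type %in% c("dense", "conv", "bnorm")

# element-wise sum of two per-layer gradient lists
sum_grads <- function(a, b) {
  lapply(seq_along(a), function(i) {
    if (is.null(a[[i]])) return(NULL)
    list(W = a[[i]]$W + b[[i]]$W, b = a[[i]]$b + b[[i]]$b)
  })
}

# ---- optimizers ------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (!has_params(l)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0, t = 0L)
  })
}

adam_step <- function(layers, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (!has_params(layers[[i]])) next
    s <- state[[i]]; g <- grads[[i]]
    s$t <- s$t + 1L
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^s$t; c2 <- 1 - beta2^s$t
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

sgd_init <- function(layers) {
  lapply(layers, function(l) {
    if (!has_params(l)) return(NULL)
    list(vW = l$W * 0, vb = l$b * 0)
  })
}

sgd_step <- function(layers, grads, state, lr, momentum = 0.8,
                     weight_decay = 1e-4) {
  for (i in seq_along(layers)) {
    if (!has_params(layers[[i]])) next
    s <- state[[i]]; g <- grads[[i]]
    gW <- g$W + weight_decay * layers[[i]]$W
    s$vW <- momentum * s$vW + gW
    s$vb <- momentum * s$vb + g$b
    layers[[i]]$W <- layers[[i]]$W - lr * s$vW
    layers[[i]]$b <- layers[[i]]$b - lr * s$vb
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# ---- losses ----------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable binary cross-entropy on logits; target is 0 or 1
bce_logits <- function(logits, target) {
  z <- as.numeric(logits)
  loss <- mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
  dl <- (sigmoid(z) - target) / length(z)
  list(loss = loss, dlogits = matrix(dl, nrow = 1))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# logits: K x N, y: integer labels 1..K, w: optional per-class weights
ce_loss_grad <- function(logits, y, w = NULL) {
  p <- softmax_cols(logits)
  n <- length(y)
  idx <- cbind(y, seq_len(n))
  if (is.null(w)) w <- rep(1, nrow(logits))
  wy <- w[y]
  loss <- sum(-log(pmax(p[idx], 1e-12)) * wy) / sum(wy)
  d <- sweep(p, 2, wy, "*")
  d[idx] <- d[idx] - wy
  list(loss = loss, dlogits = d / sum(wy))
}

# nearest-neighbour resize of a stack of gray images (H, W, N) -> (s, s, N)
resize_nearest <- function(imgs, s) {
  d <- dim(imgs)
  if (length(d) == 2) { imgs <- array(imgs, c(d, 1)); d <- dim(imgs) }
  iy <- floor((0:(s - 1)) * d[1] / s) + 1L
  ix <- floor((0:(s - 1)) * d[2] / s) + 1L
  imgs[iy, ix, , drop = FALSE]
}
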