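# Deterministic synthetic fixtures emulating the four colony morphologies.
# The textures are parametric stand-ins, not photorealistic colonies: what
# matters downstream is that they are 8-bit, deterministic per seed, that
# debris carries a bright halo rim, and that the four families are
# statistically separable by simple gray-level features.

gsmooth <- function(m, sigma) {
  # mirror-pad so the Gaussian brush fits even for small patches
  p <- ceiling(3 * sigma) + 1L
  ri <- c(pmin(nrow(m), p:1), seq_len(nrow(m)), nrow(m) - pmin(nrow(m), 1:p) + 1L)
  ci <- c(pmin(ncol(m), p:1), seq_len(ncol(m)), ncol(m) - pmin(ncol(m), 1:p) + 1L)
  big <- EBImage::imageData(EBImage::gblur(EBImage::Image(m[ri, ci]), sigma = sigma))
  big[p + seq_len(nrow(m)), p + seq_len(ncol(m))]
}

clip255 <- function(m) {
  m <- round(m)
  m[m < 0] <- 0; m[m > 255] <- 255
  storage.mode(m) <- "integer"
  m
}

#' Generate one synthetic class texture patch
#'
#' Four distinct parametric texture families: `dense` is a mid-gray
#' fine-grained speckle (narrow histogram), `spread` a brighter large-scale
#' mottle (wide histogram), `differentiated` a dark field with sparse bright
#' puncta and dark processes (bimodal), and `debris` a mid-gray field with
#' circular bright "halo" rims around dark cores. The debris halo always
#' contains pixels at gray >= 240.
#'
#' @param class_label One of [morphology_classes()] (the `diff` shorthand is
#'   accepted).
#' @param size Patch side in pixels (>= 8).
#' @param seed Integer seed; the patch is a pure function of
#'   `(class_label, size, seed, contrast)`.
#' @param contrast Multiplier on texture deviation from the class base gray
#'   (1 = default).
#' @return `size` x `size` integer matrix of 8-bit gray values.
#' @export
make_class_texture <- function(class_label, size, seed = 1, contrast = 1) {
  cl <- normalize_class(class_label)
  stopifnot(length(cl) == 1, size >= 8)
  with_seed(derive_seed(seed, match(cl, morphology_classes())), {
    noise <- matrix(stats::rnorm(size * size), size, size)
    if (cl == "dense") {
      tex <- 120 + contrast * 28 * gsmooth(noise, 0.7)
    } else if (cl == "spread") {
      tex <- 165 + contrast * 60 * gsmooth(noise, 2.5)
      # discernible cell boundaries: dark lines where the mottle crosses zero
      b <- gsmooth(matrix(stats::rnorm(size * size), size, size), 2)
      tex[abs(b) < 0.05] <- tex[abs(b) < 0.05] - contrast * 60
    } else if (cl == "differentiated") {
      tex <- 62 + contrast * 18 * gsmooth(noise, 1.2)
      k <- max(3L, round(size * size / 80))
      spots <- sample.int(size * size, k)
      tex[spots] <- 225 + stats::runif(k, 0, 30) # bright cell-body boundaries
      dark <- sample.int(size * size, k)
      tex[dark] <- 15 + stats::runif(k, 0, 15)   # dark axon-like pixels
    } else { # debris: circular bright halos around dark cores
      tex <- 115 + contrast * 14 * gsmooth(noise, 1)
      n_blob <- max(1L, round(size / 22))
      for (i in seq_len(n_blob)) {
        r <- stats::runif(1, size / 9, size / 5)
        cy <- stats::runif(1, r + 1, size - r)
        cx <- stats::runif(1, r + 1, size - r)
        dd <- sqrt(outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+"))
        tex[dd <= r - 1.2] <- 75 + contrast * 10 * noise[dd <= r - 1.2]
        tex[abs(dd - r) <= 1.2] <- 248 # high-intensity white halo
      }
    }
    clip255(tex)
  })
}

#' Specify a synthetic colony scene
#'
#' @param height,width Scene size in pixels.
#' @param blobs Data frame with columns `class`, `area` (target pixels) and
#'   `cy`, `cx` (blob centers); may have zero rows.
#' @param background_level Flat background gray value.
#' @param noise_sd Standard deviation of additive Gaussian background noise
#'   (clipped to 0-255).
#' @param contrast Texture contrast passed to [make_class_texture()].
#' @param seed Integer seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(height, width, blobs = NULL, background_level = 40,
                       noise_sd = 2, contrast = 1, seed = 1) {
  if (is.null(blobs))
    blobs <- data.frame(class = character(), area = numeric(),
                        cy = numeric(), cx = numeric())
  stopifnot(all(blobs$area > 0),
            all(blobs$cy >= 1 & blobs$cy <= height),
            all(blobs$cx >= 1 & blobs$cx <= width))
  normalize_class(blobs$class)
  structure(list(height = height, width = width, blobs = blobs,
                 background_level = background_level, noise_sd = noise_sd,
                 contrast = contrast, seed = seed),
            class = "scene_spec")
}

# random smooth closed contour: disk radius modulated by low-order harmonics
blob_mask <- function(height, width, cy, cx, area) {
  r0 <- sqrt(area / pi)
  amp <- stats::runif(3, 0.01, 0.05)
  phi <- stats::runif(3, 0, 2 * pi)
  radius_at <- function(theta, r0)
    r0 * (1 + amp[1] * cos(2 * theta + phi[1]) +
              amp[2] * cos(3 * theta + phi[2]) +
              amp[3] * cos(4 * theta + phi[3]))
  make <- function(r0) {
    rmax <- r0 * 1.2
    ys <- max(1, floor(cy - rmax)):min(height, ceiling(cy + rmax))
    xs <- max(1, floor(cx - rmax)):min(width, ceiling(cx + rmax))
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    theta <- atan2(dy, dx)
    inside <- sqrt(dy^2 + dx^2) <= radius_at(theta, r0)
    list(ys = ys, xs = xs, inside = inside)
  }
  m <- make(r0)
  got <- sum(m$inside)
  if (abs(got - area) / area > 0.02 && got > 0)
    m <- make(r0 * sqrt(area / got)) # one corrective rescale
  if (sum(m$inside) == 0) stop("blob with target area ", area, " cannot fit")
  m
}

#' Render a synthetic colony scene
#'
#' A flat noisy background with textured colony blobs whose outlines are
#' low-order Fourier perturbations of a disk. Annotated areas are recounted
#' from the final label mask, so they stay consistent even when blobs touch.
#'
#' @param spec A [scene_spec()].
#' @return A `colony_scene`: `image` (8-bit integer matrix), `mask` (integer
#'   label matrix, 0 = background), and `annotations` (data frame with
#'   label, class, area and 0-based half-open bbox).
#' @export
make_colony_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    img <- matrix(spec$background_level +
                    stats::rnorm(spec$height * spec$width, 0, spec$noise_sd),
                  spec$height, spec$width)
    mask <- matrix(0L, spec$height, spec$width)
    nb <- nrow(spec$blobs)
    for (i in seq_len(nb)) {
      b <- spec$blobs[i, ]
      rmax <- sqrt(b$area / pi) * 1.15
      if (b$cy - rmax < 1 || b$cy + rmax > spec$height ||
          b$cx - rmax < 1 || b$cx + rmax > spec$width)
        stop("blob ", i, " (area ", b$area, ") does not fit in the image")
      m <- blob_mask(spec$height, spec$width, b$cy, b$cx, b$area)
      side <- max(length(m$ys), length(m$xs))
      tex <- make_class_texture(b$class, max(8L, side),
                                seed = derive_seed(spec$seed, 100 + i),
                                contrast = spec$contrast)
      sub_img <- img[m$ys, m$xs, drop = FALSE]
      sub_mask <- mask[m$ys, m$xs, drop = FALSE]
      sub_img[m$inside] <- tex[seq_along(m$ys), seq_along(m$xs)][m$inside]
      sub_mask[m$inside] <- i
      img[m$ys, m$xs] <- sub_img
      mask[m$ys, m$xs] <- sub_mask
    }
    # recount from the final mask; relabel consecutively in blob order
    kept <- sort(unique(mask[mask > 0]))
    ann <- data.frame(label = integer(), class = character(), area = integer(),
                      row_min = integer(), col_min = integer(),
                      row_max = integer(), col_max = integer())
    relab <- matrix(0L, spec$height, spec$width)
    for (j in seq_along(kept)) {
      sel <- mask == kept[j]
      relab[sel] <- j
      rows <- which(rowSums(sel) > 0); cols <- which(colSums(sel) > 0)
      ann[j, ] <- list(j, normalize_class(spec$blobs$class[kept[j]]),
                       sum(sel), min(rows) - 1L, min(cols) - 1L,
                       max(rows), max(cols))
    }
    structure(list(image = clip255(img), mask = relab, annotations = ann),
              class = "colony_scene")
  })
}

#' Build a labeled synthetic patch dataset
#'
#' Generates `counts[cl]` independent texture patches per class; a
#' deterministic stand-in for a real patch dataset.
#'
#' @param counts Named per-class patch counts (>= 0; `diff` shorthand ok).
#' @param seed Integer seed.
#' @param size Patch side (default 64).
#' @param contrast Texture contrast.
#' @return A `patch_dataset` with `sum(counts)` real patches.
#' @export
make_patch_dataset <- function(counts, seed = 1, size = 64, contrast = 1) {
  stopifnot(all(counts >= 0))
  nm <- normalize_class(names(counts))
  total <- sum(counts)
  imgs <- array(0L, c(size, size, total))
  labels <- character(total)
  at <- 0L
  for (i in seq_along(counts)) {
    for (j in seq_len(counts[[i]])) {
      at <- at + 1L
      imgs[, , at] <- make_class_texture(nm[i], size,
                                         seed = derive_seed(seed, at),
                                         contrast = contrast)
      labels[at] <- nm[i]
    }
  }
  if (total == 0)
    return(patch_dataset(array(0L, c(size, size, 0)), labels = character()))
  patch_dataset(imgs, labels = labels,
                source = sprintf("fixture-%06d", seq_len(total)))
}

#' Fixture patch generator
#'
#' Returns a generator function `(class_label, n, seed)` drawing fresh
#' fixture texture patches — the same interface as [gan_patch_generator()],
#' useful for tests and as an oracle.
#'
#' @param size Patch side.
#' @param contrast Texture contrast.
#' @return A function producing a 3-D array of `n` patches.
#' @export
fixture_patch_generator <- function(size = 64, contrast = 1) {
  force(size); force(contrast)
  function(class_label, n, seed = 1) {
    imgs <- array(0L, c(size, size, n))
    for (i in seq_len(n))
      imgs[, , i] <- make_class_texture(class_label, size,
                                        seed = derive_seed(seed, i),
                                        contrast = contrast)
    imgs
  }
}
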