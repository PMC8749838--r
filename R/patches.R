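# Labeled 64x64 patch datasets: container, random patch sampling from colony
# ROIs, stratified cross-validation folds, and the stage-wise balancing
# arithmetic that decides how many generated images to add.

#' Canonical morphological class names
#'
#' The four colony morphologies, in their temporal/developmental order of
#' treatment by the hierarchy: debris (removed first), then differentiated,
#' then dense vs. spread.
#'
#' @return Character vector of the four class names.
#' @export
morphology_classes <- function() c("debris", "dense", "differentiated", "spread")

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  seed <- as.integer(seed) # force now: a lazily passed seed may itself draw
                           # from the caller's RNG, which we are about to save
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# derive a bounded child seed from a master seed and a stream index
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629 + 1
}

normalize_class <- function(x) {
  x <- as.character(x)
  x[x %in% c("diff", "diff.", "Diff", "Diff.")] <- "differentiated"
  x <- tolower(x)
  bad <- setdiff(unique(x), morphology_classes())
  if (length(bad) > 0)
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  x
}

#' Construct a patch dataset
#'
#' @param images 3-D integer array (height, width, n) of 8-bit gray values.
#' @param labels Class labels (one of [morphology_classes()]), or `NA`.
#' @param provenance `"real"` or `"generated"`, recycled.
#' @param source Free-form source identifiers, recycled.
#' @param fold Integer fold assignment (0-based) or `NA`.
#' @return An object of class `patch_dataset`.
#' @export
patch_dataset <- function(images, labels = NA, provenance = "real",
                          source = NA_character_, fold = NA_integer_) {
  if (length(dim(images)) == 2) images <- array(images, c(dim(images), 1))
  stopifnot(length(dim(images)) == 3)
  n <- dim(images)[3]
  labels <- if (all(is.na(labels))) factor(rep(NA_character_, n), levels = morphology_classes())
            else factor(normalize_class(rep_len(labels, n)), levels = morphology_classes())
  structure(list(
    images = images,
    labels = labels,
    provenance = rep_len(provenance, n),
    source = rep_len(source, n),
    fold = rep_len(as.integer(fold), n)
  ), class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<patch_dataset> %d patches of %dx%d\n", d[3], d[1], d[2]))
  if (!all(is.na(x$labels))) print(table(x$labels))
  invisible(x)
}

#' Number of patches in a dataset
#' @param ds A `patch_dataset`.
#' @return Integer count.
#' @export
n_patches <- function(ds) dim(ds$images)[3]

#' Combine patch datasets
#' @param ... `patch_dataset` objects with equal patch size.
#' @return A single `patch_dataset`.
#' @export
combine_patches <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]]$images)
  imgs <- array(0L, c(d[1], d[2], sum(vapply(parts, n_patches, 0L))))
  at <- 0L
  for (p in parts) {
    k <- n_patches(p)
    imgs[, , at + seq_len(k)] <- p$images
    at <- at + k
  }
  structure(list(
    images = imgs,
    labels = factor(unlist(lapply(parts, function(p) as.character(p$labels))),
                    levels = morphology_classes()),
    provenance = unlist(lapply(parts, `[[`, "provenance")),
    source = unlist(lapply(parts, `[[`, "source")),
    fold = unlist(lapply(parts, `[[`, "fold"))
  ), class = "patch_dataset")
}

#' Subset a patch dataset
#' @param ds A `patch_dataset`.
#' @param idx Integer or logical index over patches.
#' @return A `patch_dataset`.
#' @export
subset_patches <- function(ds, idx) {
  structure(list(
    images = ds$images[, , idx, drop = FALSE],
    labels = ds$labels[idx],
    provenance = ds$provenance[idx],
    source = ds$source[idx],
    fold = ds$fold[idx]
  ), class = "patch_dataset")
}

#' Sample random patches from a colony ROI
#'
#' Top-left corners are drawn uniformly (with replacement) over all
#' placements that keep the patch fully inside the ROI.
#'
#' @param roi A `colony_roi` (see [crop_rois()]) or a gray-value matrix.
#' @param n Number of patches.
#' @param size Patch side in pixels (default 64).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param label Optional class label attached to every patch.
#' @return A `patch_dataset` with `n` patches.
#' @export
sample_patches <- function(roi, n, size = 64, seed = 1, label = NA) {
  img <- if (inherits(roi, "colony_roi")) roi$image else roi
  src <- if (inherits(roi, "colony_roi")) roi$id else NA_character_
  h <- nrow(img); w <- ncol(img)
  if (h < size || w < size)
    stop("ROI (", h, "x", w, ") is smaller than the patch size ", size)
  with_seed(seed, {
    ys <- sample.int(h - size + 1L, n, replace = TRUE)
    xs <- sample.int(w - size + 1L, n, replace = TRUE)
    imgs <- array(0L, c(size, size, n))
    for (i in seq_len(n))
      imgs[, , i] <- img[ys[i]:(ys[i] + size - 1L), xs[i]:(xs[i] + size - 1L)]
    ds <- patch_dataset(imgs, labels = label, source = src)
    attr(ds, "corners") <- cbind(row = ys - 1L, col = xs - 1L)
    ds
  })
}

#' Assign stratified cross-validation folds
#'
#' Patches are partitioned into `k` folds stratified by class, so each
#' fold's test share is about `1/k` per class (the 80:20 split at the
#' default `k = 5`). Only patches with `provenance == "real"` may be
#' assigned; generated patches keep `fold = NA` and never enter test sets.
#'
#' @param ds A labeled `patch_dataset`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return The dataset with its `fold` field populated (0-based).
#' @export
make_folds <- function(ds, k = 5, seed = 1) {
  stopifnot(k >= 2)
  labs <- as.character(ds$labels)
  real <- ds$provenance == "real"
  cnt <- table(labs[real])
  if (any(cnt < k))
    stop("class(es) with fewer than k patches: ",
         paste(names(cnt)[cnt < k], collapse = ", "))
  fold <- rep(NA_integer_, length(labs))
  with_seed(seed, {
    for (cl in names(cnt)) {
      idx <- which(real & labs == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(0:(k - 1), length(idx))
    }
  })
  ds$fold <- fold
  ds
}

#' Stage balancing plan
#'
#' Computes how many generated minority-class images are needed to balance
#' each stage of the temporal hierarchy: at every stage the smaller single
#' class is topped up with generated images until it matches the larger
#' (aggregate) class.
#'
#' @param class_counts Named counts for the four classes (names may use the
#'   `diff` shorthand for `differentiated`).
#' @param stage Hierarchy stage: 1 (debris vs. rest), 2 (differentiated vs.
#'   dense+spread), 3 (dense vs. spread).
#' @return A `balancing_plan`: stage, minority class, majority/minority
#'   totals, and `n_generated = max(0, majority - minority)`.
#' @export
balancing_plan <- function(class_counts, stage) {
  stopifnot(stage %in% 1:3)
  nm <- normalize_class(names(class_counts))
  counts <- as.numeric(class_counts)
  if (any(counts < 0)) stop("negative class counts")
  names(counts) <- nm
  missing <- setdiff(morphology_classes(), nm)
  if (length(missing) > 0)
    stop("missing counts for class(es): ", paste(missing, collapse = ", "))
  if (stage == 1) {
    minority <- "debris"
    majority_total <- sum(counts[c("dense", "differentiated", "spread")])
  } else if (stage == 2) {
    minority <- "differentiated"
    majority_total <- sum(counts[c("dense", "spread")])
  } else {
    minority <- if (counts["dense"] <= counts["spread"]) "dense" else "spread"
    majority_total <- max(counts["dense"], counts["spread"])
  }
  minority_total <- unname(counts[minority])
  structure(list(
    stage = stage,
    minority_class = minority,
    minority_total = minority_total,
    majority_total = unname(majority_total),
    n_generated = max(0, unname(majority_total) - minority_total)
  ), class = "balancing_plan")
}

#' @export
print.balancing_plan <- function(x, ...) {
  cat(sprintf("<balancing_plan> stage %d: add %d generated '%s' (%d vs %d)\n",
              x$stage, x$n_generated, x$minority_class,
              x$minority_total, x$majority_total))
  invisible(x)
}

#' Binary class sets for each hierarchy stage
#' @param stage Stage id (1, 2 or 3).
#' @return List with `pos` and `neg` class-name vectors.
#' @export
stage_class_sets <- function(stage) {
  stopifnot(stage %in% 1:3)
  switch(stage,
    list(pos = "debris", neg = c("dense", "differentiated", "spread")),
    list(pos = "differentiated", neg = c("dense", "spread")),
    list(pos = "dense", neg = "spread"))
}
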