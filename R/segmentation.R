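# Morphological colony detection: 3x3 Gaussian blur -> local-entropy disk
# filter (radius 3) -> grayscale opening (radius-3 disk) -> Otsu threshold
# -> hole filling -> removal of components under 2000 pixels. The entropy
# step is what separates textured colony area from flat background.

#' Segment colonies in a grayscale dish image
#'
#' Applies the sequential morphological pipeline and returns the binary
#' foreground mask together with connected-component labels (8-connectivity).
#' Every surviving component has at least `min_area` pixels and its holes
#' filled. A constant image (Otsu undefined) yields an empty mask with a
#' warning.
#'
#' @param image Gray-value matrix (0-255), or a `colony_scene`.
#' @param min_area Minimum component size in pixels (default 2000).
#' @param entropy_radius Disk radius of the local-entropy filter (default 3).
#' @param opening_radius Disk radius of the grayscale opening (default 3).
#' @param blur_sigma Sigma of the 3x3 Gaussian blur (default 0.8, the
#'   kernel-standard value for a 3-pixel window).
#' @return A `colony_segmentation`: `mask` (logical matrix) and `labels`
#'   (integer matrix, 0 = background, consecutive labels).
#' @export
segment_colonies <- function(image, min_area = 2000, entropy_radius = 3,
                             opening_radius = 3, blur_sigma = 0.8) {
  if (inherits(image, "colony_scene")) image <- image$image
  stopifnot(is.matrix(image), nrow(image) >= 8, ncol(image) >= 8)
  empty <- function() structure(
    list(mask = matrix(FALSE, nrow(image), ncol(image)),
         labels = matrix(0L, nrow(image), ncol(image))),
    class = "colony_segmentation")
  if (diff(range(image)) == 0) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    return(empty())
  }
  g <- stats::dnorm(-1:1, 0, blur_sigma)
  kern <- outer(g, g); kern <- kern / sum(kern)
  blurred <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(image / 255), kern, boundary = "replicate"))
  q <- round(blurred * 255); q[q < 0] <- 0; q[q > 255] <- 255
  storage.mode(q) <- "integer"
  ent <- disk_entropy_cpp(q, as.integer(entropy_radius))
  rng <- range(ent)
  if (diff(rng) == 0) {
    warning("entropy image is constant, returning empty mask")
    return(empty())
  }
  ent8 <- round((ent - rng[1]) / diff(rng) * 255) / 255 # 8-bit rescale, on [0,1]
  brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
  opened <- EBImage::imageData(EBImage::opening(EBImage::Image(ent8), brush))
  th <- EBImage::otsu(EBImage::Image(opened), range = c(0, 1))
  bin <- opened > th
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bin))) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(filled)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  relab <- matrix(0L, nrow(image), ncol(image))
  for (j in seq_along(keep)) relab[lab == keep[j]] <- j
  structure(list(mask = relab > 0, labels = relab),
            class = "colony_segmentation")
}

#' Crop detected colonies to ROIs
#'
#' One ROI per label, ordered by label id; each ROI image is the source
#' sub-array at the component's bounding box (0-based half-open coordinates).
#'
#' @param image The gray-value matrix passed to [segment_colonies()].
#' @param segmentation A `colony_segmentation` (or an integer label matrix)
#'   computed on the same image.
#' @return List of `colony_roi` objects: `image`, `bbox`
#'   `(row_min, col_min, row_max, col_max)`, `area` (foreground pixels),
#'   `id`.
#' @export
crop_rois <- function(image, segmentation) {
  if (inherits(image, "colony_scene")) image <- image$image
  labels <- if (inherits(segmentation, "colony_segmentation"))
    segmentation$labels else segmentation
  if (!all(dim(labels) == dim(image)))
    stop("label matrix shape ", paste(dim(labels), collapse = "x"),
         " does not match image shape ", paste(dim(image), collapse = "x"))
  ids <- sort(unique(labels[labels > 0]))
  lapply(ids, function(k) {
    sel <- labels == k
    rows <- which(rowSums(sel) > 0); cols <- which(colSums(sel) > 0)
    structure(list(
      image = image[min(rows):max(rows), min(cols):max(cols), drop = FALSE],
      bbox = c(row_min = min(rows) - 1L, col_min = min(cols) - 1L,
               row_max = max(rows), col_max = max(cols)),
      area = sum(sel),
      id = sprintf("roi-%03d", k)
    ), class = "colony_roi")
  })
}

#' Jaccard index between two binary masks
#' @param a,b Logical matrices of equal shape.
#' @return Intersection over union (1 if both masks are empty).
#' @export
jaccard_index <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
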