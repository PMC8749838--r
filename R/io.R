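# Image and manifest I/O: 8-bit gray PNG/TIFF in, class-per-directory patch
# datasets with a CSV manifest out. CSV artifacts carry a comment header
# with the config hash and seed for provenance.

#' Read an 8-bit grayscale image
#' @param path PNG or TIFF file.
#' @return Integer matrix of gray values 0-255.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  clip255(img * 255)
}

#' Write an 8-bit grayscale PNG
#' @param image Integer matrix of gray values 0-255.
#' @param path Output file.
#' @export
write_gray_png <- function(image, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a CSV artifact with a provenance header
#'
#' The first line is a `#` comment carrying the config hash and seed; read
#' back with [read_csv_artifact()].
#'
#' @param df Data frame.
#' @param path Output file.
#' @param config_hash,seed Provenance stamps.
#' @export
write_csv_artifact <- function(df, path, config_hash = "none", seed = NA) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# colonyGAN config=%s seed=%s", config_hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV artifact written by [write_csv_artifact()]
#' @param path File path.
#' @return Data frame.
#' @export
read_csv_artifact <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a patch dataset to disk
#'
#' Layout: `<root>/<class>/<id>.png` plus `<root>/manifest.csv` with
#' columns id, class, provenance, fold.
#'
#' @param ds A labeled `patch_dataset`.
#' @param root Output directory.
#' @param config_hash,seed Provenance stamps for the manifest.
#' @return `root`, invisibly.
#' @export
write_patch_dataset <- function(ds, root, config_hash = "none", seed = NA) {
  n <- n_patches(ds)
  cls <- as.character(ds$labels)
  cls[is.na(cls)] <- "unlabeled"
  id <- sprintf("patch-%06d", seq_len(n))
  for (i in seq_len(n))
    write_gray_png(ds$images[, , i], file.path(root, cls[i],
                                               paste0(id[i], ".png")))
  write_csv_artifact(
    data.frame(id = id, class = cls, provenance = ds$provenance,
               fold = ds$fold),
    file.path(root, "manifest.csv"), config_hash, seed)
  invisible(root)
}

#' Read a patch dataset written by [write_patch_dataset()]
#' @param root Dataset directory with a `manifest.csv`.
#' @return A `patch_dataset`.
#' @export
read_patch_dataset <- function(root) {
  mf <- file.path(root, "manifest.csv")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  man <- read_csv_artifact(mf)
  imgs <- NULL
  for (i in seq_len(nrow(man))) {
    m <- read_gray_image(file.path(root, man$class[i],
                                   paste0(man$id[i], ".png")))
    if (is.null(imgs)) imgs <- array(0L, c(dim(m), nrow(man)))
    imgs[, , i] <- m
  }
  labs <- man$class
  labs[labs == "unlabeled"] <- NA
  patch_dataset(imgs, labels = labs, provenance = man$provenance,
                source = man$id, fold = man$fold)
}
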