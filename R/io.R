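# Raster and dataset I/O. Images travel as multiband float TIFF (one sample
# per band, values in [0, 1]); labels as single-band 8-bit TIFF with 255 as
# the ignore value. Patch origins (for georeferenced stitching) live in the
# manifest CSV next to the patch files.

read_tiff_array <- function(path) {
  x <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

#' Write a scene to an image/labels TIFF pair
#'
#' @param scn A `cropseg_scene`.
#' @param image_path Output path for the multiband float image.
#' @param labels_path Output path for the 8-bit label raster.
#' @param mask_csv Optional path: writes the rectangles recorded by
#'   [generate_scene()] (attribute `"mask_rects"`) as a
#'   `row0,col0,row1,col1` CSV.
#' @return Invisibly, the scene.
#' @export
write_scene <- function(scn, image_path, labels_path, mask_csv = NULL) {
  stopifnot(inherits(scn, "cropseg_scene"))
  tiff::writeTIFF(scn$image, image_path, bits.per.sample = 32L)
  tiff::writeTIFF(scn$labels / 255, labels_path, bits.per.sample = 8L)
  if (!is.null(mask_csv)) {
    rects <- attr(scn, "mask_rects")
    if (is.null(rects)) {
      rects <- matrix(integer(0), 0, 4,
                      dimnames = list(NULL, c("row0", "col0", "row1", "col1")))
    }
    write.csv(as.data.frame(rects), mask_csv, row.names = FALSE)
  }
  invisible(scn)
}

#' Read a scene from an image/labels raster pair
#'
#' @param image_path Multiband image TIFF.
#' @param labels_path Single-band 8-bit label TIFF (255 = ignore).
#' @return A `cropseg_scene`.
#' @export
read_scene <- function(image_path, labels_path) {
  img <- read_tiff_array(image_path)
  lab <- read_tiff_array(labels_path)
  lab <- matrix(as.integer(round(lab[, , 1] * 255)), dim(lab)[1], dim(lab)[2])
  if (!all(dim(lab) == dim(img)[1:2])) {
    stop(sprintf("misaligned rasters: image %s vs labels %s",
                 paste(dim(img)[1:2], collapse = "x"),
                 paste(dim(lab), collapse = "x")))
  }
  scene(img, lab)
}

#' Read mask rectangles from CSV
#'
#' Accepts a plain `row0,col0,row1,col1` file with or without a header row.
#'
#' @param path CSV path.
#' @return Integer matrix with one rectangle per row.
#' @export
read_mask_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[0-9]", first)
  m <- as.matrix(read.csv(path, header = has_header))
  if (nrow(m) > 0 && ncol(m) != 4L) stop("mask CSV must have 4 columns")
  storage.mode(m) <- "integer"
  colnames(m) <- c("row0", "col0", "row1", "col1")
  m
}

#' Write a patch dataset to disk
#'
#' One directory per split, each patch stored as a paired multiband image
#' TIFF and label TIFF, plus a `manifest.csv` (patch id, origin, masked
#' fraction, split) at the top level.
#'
#' @param patches List of patches from [tile()].
#' @param splits Result of [split_patches()].
#' @param outdir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_patch_dataset <- function(patches, splits, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (sp in names(splits)) {
    spdir <- file.path(outdir, sp)
    dir.create(spdir, showWarnings = FALSE)
    for (i in splits[[sp]]) {
      p <- patches[[i]]
      id <- sprintf("patch_%04d", i)
      img_rel <- file.path(sp, paste0(id, "_img.tif"))
      lab_rel <- file.path(sp, paste0(id, "_lab.tif"))
      tiff::writeTIFF(p$image, file.path(outdir, img_rel),
                      bits.per.sample = 32L)
      tiff::writeTIFF(p$labels / 255, file.path(outdir, lab_rel),
                      bits.per.sample = 8L)
      rows[[length(rows) + 1L]] <- data.frame(
        patch_id = id, origin_row = p$origin[["row"]],
        origin_col = p$origin[["col"]],
        masked_fraction = p$masked_fraction, split = sp,
        image = img_rel, labels = lab_rel)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a patch dataset written by [write_patch_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @param split Optional split name to restrict to.
#' @return List with `patches` and the `manifest` data frame (rows aligned).
#' @export
read_patch_dataset <- function(dir, split = NULL) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mf)
  if (!is.null(split)) manifest <- manifest[manifest$split == split, ]
  if (nrow(manifest) == 0L) stop("no patches found in ", dir)
  patches <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_tiff_array(file.path(dir, manifest$image[i]))
    lab <- read_tiff_array(file.path(dir, manifest$labels[i]))
    lab <- matrix(as.integer(round(lab[, , 1] * 255)),
                  dim(lab)[1], dim(lab)[2])
    list(image = img, labels = lab,
         origin = c(row = manifest$origin_row[i],
                    col = manifest$origin_col[i]),
         masked_fraction = mean(lab == IGNORE_VALUE))
  })
  list(patches = patches, manifest = manifest)
}

#' Save / load a model
#'
#' Checkpoints embed the full network configuration alongside the weights.
#'
#' @param model A `cropseg_model`.
#' @param path File path (`.rds`).
#' @return `save_model` the path; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "cropseg_model")) stop("not a cropseg model checkpoint")
  m
}
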