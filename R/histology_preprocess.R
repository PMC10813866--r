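#' @import EBImage
NULL

# ITU-R 601 luminance in 0-255 units from an HxWx3 array (0-255).
.luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

.as_rgb_array <- function(img) {
  if (is.list(img) && !is.null(img$image)) img <- img$image
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("expected an HxWx3 RGB array with 0-255 values")
  img
}

#' Compute a tissue mask for a slide image
#'
#' Implements the standard slide-preparation sequence, in this exact
#' order: ITU-R 601 luminance grayscale, Otsu threshold with tissue taken
#' as the darker-than-threshold side (H&E tissue is darker than glass),
#' binary dilation with a disk brush, filling of enclosed holes smaller
#' than `min_hole_area`, and removal of connected components smaller than
#' `min_object_area`.
#'
#' This masking presumes slide-scale imagery where the dominant intensity
#' contrast is tissue versus bright glass background. On a single
#' high-magnification patch that is entirely tissue, the Otsu split falls
#' between nuclei and cytoplasm instead; use the nucleus-score filter for
#' patch-level content decisions (see [nucleus_score()]).
#'
#' @param img RGB array (HxWx3, 0-255).
#' @param dilate_radius disk radius in pixels for the dilation (default 2).
#' @param min_hole_area holes (enclosed background components) smaller than
#'   this many pixels are filled (default 256).
#' @param min_object_area tissue components smaller than this many pixels
#'   are removed (default 1024).
#' @return An object of class `tissue_mask`: list with `mask` (logical
#'   matrix, same height/width as the image) and `tissue_fraction`.
#'   A fully uniform image (Otsu undefined) yields an empty mask with a
#'   warning.
#' @export
compute_tissue_mask <- function(img, dilate_radius = 2L,
                                min_hole_area = 256L,
                                min_object_area = 1024L) {
  img <- .as_rgb_array(img)
  gray <- .luminance(img) / 255
  if (max(gray) - min(gray) < 1e-9) {
    warning("uniform image: Otsu threshold undefined, returning empty mask")
    mask <- matrix(FALSE, nrow(gray), ncol(gray))
    return(structure(list(mask = mask, tissue_fraction = 0),
                     class = "tissue_mask"))
  }
  th <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  mask <- gray < th
  if (dilate_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_radius) + 1L, "disc")
    mask <- EBImage::dilate(EBImage::Image(mask), brush) > 0.5
  }
  # fill enclosed background components smaller than min_hole_area
  bg <- EBImage::bwlabel(EBImage::Image(!mask))
  bg <- matrix(as.integer(bg), nrow(mask), ncol(mask))
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  tab <- tabulate(bg)
  fill <- which(tab < min_hole_area)
  fill <- setdiff(fill, border_labels)
  if (length(fill)) mask[bg %in% fill] <- TRUE
  # remove small tissue objects
  cc <- EBImage::bwlabel(EBImage::Image(mask))
  cc <- matrix(as.integer(cc), nrow(mask), ncol(mask))
  tab <- tabulate(cc)
  drop <- which(tab < min_object_area)
  if (length(drop)) mask[cc %in% drop] <- FALSE
  structure(list(mask = mask, tissue_fraction = mean(mask)),
            class = "tissue_mask")
}

#' Extract grid patches meeting a tissue-content threshold
#'
#' Tiles the image with a non-overlapping grid anchored at the top-left
#' (0-based, half-open extents); partial edge tiles are discarded. A patch
#' is returned iff the mean of the tissue mask within it is at least
#' `tissue_threshold`. Patches are returned in row-major order.
#'
#' @param img RGB array (HxWx3, 0-255).
#' @param mask a `tissue_mask` (or logical matrix). NULL treats every
#'   pixel as tissue.
#' @param patch_size patch side in pixels (default 512).
#' @param tissue_threshold minimum within-patch tissue fraction, in
#'   \[0,1\] (default 0.8).
#' @param patient_id identifier carried on each patch.
#' @return list of `tile_patch` objects (fields: `patient_id`, `row0`,
#'   `col0`, `size`, `image`, `tissue_fraction`, `nucleus_score` — the
#'   score is NA until [nucleus_score()] is applied). An image smaller
#'   than `patch_size` yields an empty list with a warning.
#' @export
extract_patches <- function(img, mask = NULL, patch_size = 512L,
                            tissue_threshold = 0.8, patient_id = NA_character_) {
  stopifnot(tissue_threshold >= 0, tissue_threshold <= 1)
  img <- .as_rgb_array(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < patch_size || w < patch_size) {
    warning("image smaller than patch_size: no patches extracted")
    return(list())
  }
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  stopifnot(nrow(mask) == h, ncol(mask) == w)
  out <- list()
  for (r0 in seq(0L, h - patch_size, by = patch_size)) {
    for (c0 in seq(0L, w - patch_size, by = patch_size)) {
      rows <- (r0 + 1L):(r0 + patch_size)
      cols <- (c0 + 1L):(c0 + patch_size)
      tf <- mean(mask[rows, cols])
      if (tf >= tissue_threshold) {
        out[[length(out) + 1L]] <- structure(
          list(patient_id = patient_id, row0 = r0, col0 = c0,
               size = as.integer(patch_size),
               image = img[rows, cols, , drop = FALSE],
               tissue_fraction = tf, nucleus_score = NA_real_),
          class = "tile_patch")
      }
    }
  }
  out
}

#' Wrap a standalone tile image as a patch
#'
#' Convenience for pre-tiled inputs (e.g. the synthetic generator, or
#' tiles exported by another tool), which are already extracted patches:
#' tissue fraction is taken as 1 by construction.
#'
#' @param img RGB array (HxWx3, 0-255) of exactly the patch size.
#' @param patient_id,tile_id identifiers carried on the patch.
#' @return a `tile_patch`.
#' @export
as_tile_patch <- function(img, patient_id = NA_character_, tile_id = 1L) {
  img <- .as_rgb_array(img)
  stopifnot(dim(img)[1] == dim(img)[2])
  structure(list(patient_id = patient_id, row0 = 0L, col0 = 0L,
                 size = dim(img)[1], image = img, tile_id = tile_id,
                 tissue_fraction = 1, nucleus_score = NA_real_),
            class = "tile_patch")
}

#' Classify nucleus pixels in an H&E patch
#'
#' The shared nucleus-pixel classifier used both for patch scoring and as
#' the watershed foreground source: a hematoxylin-like channel is formed
#' as the mean red/green optical darkness, `0.5*(255-R) + 0.5*(255-G)`
#' (hematoxylin-stained chromatin absorbs red and green strongly while
#' eosin-pink cytoplasm does not), thresholded at a fixed absolute level,
#' then cleaned by a morphological opening.
#'
#' @param img RGB array or `tile_patch`.
#' @param threshold hematoxylin-channel cutoff in 0-255 units (default 100).
#' @param opening_radius disk radius of the opening (default 2); 0 skips it.
#' @return logical matrix, TRUE at nucleus pixels.
#' @export
nucleus_pixel_mask <- function(img, threshold = 100, opening_radius = 2L) {
  if (inherits(img, "tile_patch")) img <- img$image
  img <- .as_rgb_array(img)
  hema <- 0.5 * (255 - img[, , 1]) + 0.5 * (255 - img[, , 2])
  m <- hema > threshold
  if (opening_radius > 0 && any(m)) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    m <- EBImage::opening(EBImage::Image(m), brush) > 0.5
  }
  m
}

#' Nucleus score of a patch
#'
#' Fraction of patch pixels classified as nucleus by
#' [nucleus_pixel_mask()]. Patches with score below 0.15 are conventionally
#' discarded (see [filter_patches()]).
#'
#' @param patch a `tile_patch` (or RGB array).
#' @param ... passed to [nucleus_pixel_mask()].
#' @return the patch with `nucleus_score` set (if given a `tile_patch`),
#'   otherwise the numeric score.
#' @export
nucleus_score <- function(patch, ...) {
  score <- mean(nucleus_pixel_mask(patch, ...))
  if (inherits(patch, "tile_patch")) {
    patch$nucleus_score <- score
    patch
  } else {
    score
  }
}

#' Filter patches by nucleus score
#'
#' Retains patches whose `nucleus_score` is at least `min_score`
#' (boundary inclusive), preserving order. Patches with an unset score
#' are scored first.
#'
#' @param patches list of `tile_patch` objects.
#' @param min_score minimum score in \[0,1\] (default 0.15).
#' @return the retained patches; a warning is emitted when none survive
#'   (the slide is then excluded downstream).
#' @export
filter_patches <- function(patches, min_score = 0.15) {
  stopifnot(min_score >= 0, min_score <= 1)
  patches <- lapply(patches, function(p) {
    if (is.na(p$nucleus_score)) nucleus_score(p) else p
  })
  keep <- vapply(patches, function(p) p$nucleus_score >= min_score, logical(1))
  if (!any(keep) && length(patches))
    warning("no patches meet the nucleus-score threshold; slide will be excluded")
  patches[keep]
}

#' Patch manifest as a data frame
#'
#' @param patches list of `tile_patch` objects.
#' @param kept optional logical vector marking retained patches.
#' @return data.frame with patient_id, row, col, tissue_fraction,
#'   nucleus_score and the kept flag.
#' @export
patch_manifest <- function(patches, kept = rep(TRUE, length(patches))) {
  data.frame(
    patient_id = vapply(patches, `[[`, character(1), "patient_id"),
    row = vapply(patches, `[[`, integer(1), "row0"),
    col = vapply(patches, `[[`, integer(1), "col0"),
    tissue_fraction = vapply(patches, `[[`, numeric(1), "tissue_fraction"),
    nucleus_score = vapply(patches, `[[`, numeric(1), "nucleus_score"),
    kept = kept,
    stringsAsFactors = FALSE
  )
}
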