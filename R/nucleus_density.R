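#' Watershed segmentation of nuclei in a patch
#'
#' Marker-controlled watershed in the classic order: nucleus-pixel
#' classification (hematoxylin-channel threshold, [nucleus_pixel_mask()]),
#' morphological opening (small white noise), hole filling, Euclidean
#' distance transform, sure-foreground markers where the distance exceeds
#' `fg_frac` times its maximum, sure-background as the complement of the
#' dilated mask, and watershed growth of the connected-component markers
#' over the distance map restricted to the nucleus mask. Touching nuclei
#' are separated into distinct labels wherever each retains its own
#' distance peak above the marker threshold.
#'
#' With disks of radius r whose centers are d apart, the distance saddle
#' between them has height sqrt(r^2 - (d/2)^2); the pair is split exactly
#' when that saddle falls below `fg_frac * r`. At the default
#' `fg_frac = 0.4` this resolves overlaps shallower than about 0.17 r.
#'
#' @param patch a `tile_patch` or RGB array.
#' @param fg_frac sure-foreground threshold as a fraction of the maximum
#'   distance-transform value (default 0.4).
#' @param threshold,opening_radius passed to [nucleus_pixel_mask()].
#' @return An object of class `nucleus_segmentation`: list with `labels`
#'   (integer matrix, 0 = background, labels contiguous 1..nucleus_count),
#'   `nucleus_count`, and `attributes` (data.frame: label, area px^2,
#'   eccentricity). No nucleus pixels gives count 0 and empty attributes.
#' @export
segment_nuclei <- function(patch, fg_frac = 0.4, threshold = 100,
                           opening_radius = 2L) {
  m <- nucleus_pixel_mask(patch, threshold = threshold,
                          opening_radius = opening_radius)
  if (!any(m)) {
    return(structure(list(labels = matrix(0L, nrow(m), ncol(m)),
                          nucleus_count = 0L,
                          attributes = data.frame(label = integer(0),
                                                  area = numeric(0),
                                                  eccentricity = numeric(0))),
                     class = "nucleus_segmentation"))
  }
  m <- EBImage::fillHull(EBImage::Image(m)) > 0.5
  dist <- EBImage::distmap(EBImage::Image(m))
  fg <- dist > fg_frac * max(dist)
  markers <- EBImage::bwlabel(fg)
  labels <- EBImage::propagate(dist, seeds = markers, mask = m, lambda = 100)
  labels <- matrix(as.integer(labels), nrow(m), ncol(m))
  # contiguous relabeling 1..n
  present <- sort(unique(labels[labels > 0L]))
  if (length(present)) {
    remap <- integer(max(present))
    remap[present] <- seq_along(present)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  n <- length(present)
  attrs <- data.frame(label = integer(0), area = numeric(0),
                      eccentricity = numeric(0))
  if (n > 0L) {
    mom <- EBImage::computeFeatures.moment(labels)
    shp <- EBImage::computeFeatures.shape(labels)
    attrs <- data.frame(label = seq_len(n),
                        area = as.numeric(shp[, "s.area"]),
                        eccentricity = as.numeric(mom[, "m.eccentricity"]))
  }
  structure(list(labels = labels, nucleus_count = n, attributes = attrs),
            class = "nucleus_segmentation")
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat(sprintf("nucleus_segmentation: %d nuclei over %d x %d px\n",
              x$nucleus_count, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Categorize segmented nuclei by size and shape
#'
#' Assigns each nucleus a size category (small/medium/large, by area
#' cutoffs) and a shape category (round/elongated, by an eccentricity
#' threshold; eccentricity is the ellipse-fit value sqrt(1-(b/a)^2), so a
#' circle scores 0 and a 3:1 ellipse about 0.94). Categories are carried
#' as metadata only; the texture features downstream do not use them.
#'
#' @param seg a `nucleus_segmentation`.
#' @param size_cutoffs length-2 increasing area cutoffs in px^2 separating
#'   small/medium and medium/large (default c(150, 300)).
#' @param ecc_cutoff eccentricity above which a nucleus is "elongated"
#'   (default 0.8).
#' @return the attribute table with `size_category` and `shape_category`
#'   columns added (empty for an empty segmentation).
#' @export
categorize_nuclei <- function(seg, size_cutoffs = c(150, 300),
                              ecc_cutoff = 0.8) {
  stopifnot(inherits(seg, "nucleus_segmentation"),
            length(size_cutoffs) == 2L, diff(size_cutoffs) > 0)
  at <- seg$attributes
  at$size_category <- cut(at$area, c(-Inf, size_cutoffs, Inf),
                          labels = c("small", "medium", "large"))
  at$shape_category <- factor(ifelse(at$eccentricity > ecc_cutoff,
                                     "elongated", "round"),
                              levels = c("round", "elongated"))
  at
}

# Block mean of a numeric matrix over non-overlapping s x s bins.
.block_mean <- function(m, s) {
  nr <- nrow(m) %/% s
  nc <- ncol(m) %/% s
  dim(m) <- c(s, nr, s, nc)
  out <- apply(m, c(2, 4), mean)
  matrix(out, nr, nc)
}

#' Quantized cell-density map of a segmented patch
#'
#' Divides the patch into non-overlapping `scale` x `scale` pixel bins and
#' computes, per bin, the raw density as the fraction of bin pixels
#' labeled nucleus. The raw density is quantized to `Ng` gray levels with
#' fixed absolute bins over \[0,1\]: `level = floor(raw * Ng)`, clipped to
#' `Ng - 1`, so maps are directly comparable across patches and patients.
#' A per-patch relative mode (rescaling by the patch maximum before
#' quantization) is available behind `mode = "relative"`.
#'
#' @param seg a `nucleus_segmentation` (or logical/integer nucleus mask).
#' @param scale bin side in pixels; must divide the patch size. The
#'   conventional scales are 16, 32 and 64 px.
#' @param Ng number of gray levels (>= 2, default 8).
#' @param mode "absolute" (default) or "relative" quantization.
#' @return An object of class `density_map`: list with `levels` (integer
#'   matrix of shape (patch/scale)^2 with values 0..Ng-1), `raw` (per-bin
#'   nucleus-pixel fractions), `scale`, `Ng`, `mode`.
#' @export
density_map <- function(seg, scale, Ng = 8L, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  if (Ng < 2L) stop("Ng must be >= 2")
  labels <- if (inherits(seg, "nucleus_segmentation")) seg$labels else seg
  if (nrow(labels) %% scale != 0L || ncol(labels) %% scale != 0L)
    stop(sprintf("scale %d does not divide the patch size %d x %d",
                 scale, nrow(labels), ncol(labels)))
  raw <- .block_mean((labels > 0L) * 1, as.integer(scale))
  q <- raw
  if (mode == "relative" && max(raw) > 0) q <- raw / max(raw)
  lev <- pmin(floor(q * Ng), Ng - 1L)
  storage.mode(lev) <- "integer"
  structure(list(levels = lev, raw = raw, scale = as.integer(scale),
                 Ng = as.integer(Ng), mode = mode),
            class = "density_map")
}
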