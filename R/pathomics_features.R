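#' @keywords internal
.haralick_names <- c("energy", "contrast", "correlation", "variance",
                     "inverse_difference_moment", "sum_average",
                     "sum_variance", "sum_entropy", "entropy",
                     "difference_variance", "difference_entropy",
                     "IMC1", "IMC2")

.directions <- c("D1", "D2", "D3", "D4")
# (row, col) lattice offsets: D1 horizontal 0deg, D2 vertical 90deg,
# D3 minor diagonal 45deg, D4 main diagonal 135deg.
.direction_offsets <- list(D1 = c(0L, 1L), D2 = c(1L, 0L),
                           D3 = c(-1L, 1L), D4 = c(1L, 1L))

.scale_tags <- c(S1 = 16L, S2 = 32L, S3 = 64L)
.agg_stats <- c("mean", "median", "var", "kurtosis", "skewness")

#' Directional gray-level co-occurrence matrix of a density map
#'
#' Counts all ordered pairs of quantized gray levels at lattice offset
#' distance 1 in the requested direction, symmetrized (both orders of each
#' pair counted) and normalized to total mass 1. Directions follow the
#' usual texture convention: D1 horizontal (0 deg), D2 vertical (90 deg),
#' D3 minor diagonal (45 deg), D4 main diagonal (135 deg).
#'
#' @param dm a `density_map`, or an integer matrix of levels in 0..Ng-1
#'   (then `Ng` must be supplied).
#' @param direction one of "D1", "D2", "D3", "D4".
#' @param Ng number of gray levels when `dm` is a plain matrix.
#' @return An object of class `glcm`: list with `P` (Ng x Ng symmetric
#'   matrix summing to 1, rows/cols indexed by levels 0..Ng-1),
#'   `direction`, `Ng`, `distance` (fixed at 1 bin).
#' @export
cooccurrence <- function(dm, direction = c("D1", "D2", "D3", "D4"), Ng = NULL) {
  direction <- match.arg(direction)
  if (inherits(dm, "density_map")) {
    lev <- dm$levels
    Ng <- dm$Ng
  } else {
    lev <- dm
    if (is.null(Ng)) stop("Ng is required for a plain level matrix")
  }
  off <- .direction_offsets[[direction]]
  nr <- nrow(lev); nc <- ncol(lev)
  if (nr < abs(off[1]) + 1L || nc < abs(off[2]) + 1L ||
      (off[1] == 0L && nc < 2L) || (off[2] == 0L && nr < 2L))
    stop(sprintf("density map too small for direction %s", direction))
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + off[1], c1 + off[2], drop = FALSE]
  idx <- as.vector(a) * Ng + as.vector(b) + 1L
  counts <- matrix(tabulate(idx, nbins = Ng * Ng), Ng, Ng, byrow = TRUE)
  P <- counts + t(counts)
  P <- P / sum(P)
  structure(list(P = P, direction = direction, Ng = as.integer(Ng),
                 distance = 1L), class = "glcm")
}

#' The 13 classic Haralick texture statistics of a GLCM
#'
#' Computes, from a normalized symmetric co-occurrence matrix, the
#' canonical 13 statistics: energy (angular second moment), contrast,
#' correlation, variance (sum of squares), inverse difference moment,
#' sum average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, and the two information measures of correlation
#' (IMC1, IMC2). The 14th statistic (maximal correlation coefficient) is
#' excluded, as is conventional. Gray levels are indexed by their values
#' 0..Ng-1. Logarithms are base 2 and zero-probability terms are skipped
#' (0 log 0 := 0). Sum variance is centred on the sum average.
#' Degenerate cases are guarded: a constant map has zero marginal SD and
#' zero marginal entropy, for which correlation and IMC1 are defined as 0;
#' the IMC2 radicand is clipped at 0.
#'
#' @param glcm a `glcm`, or a normalized symmetric numeric matrix.
#' @return named numeric vector of length 13.
#' @export
haralick <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$P else glcm
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  Ng <- nrow(P)
  lev <- 0:(Ng - 1)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))

  I <- matrix(lev, Ng, Ng)
  J <- t(I)
  # p_{x+y}(k), k = 0..2(Ng-1); p_{x-y}(k), k = 0..Ng-1
  sums <- as.vector(I + J)
  diffs <- as.vector(abs(I - J))
  p_sum <- vapply(0:(2 * Ng - 2), function(k) sum(P[sums == k]), numeric(1))
  p_diff <- vapply(0:(Ng - 1), function(k) sum(P[diffs == k]), numeric(1))
  ks <- 0:(2 * Ng - 2)
  kd <- 0:(Ng - 1)

  log2z <- function(p) ifelse(p > 0, log2(p), 0)
  ent <- function(p) -sum(p * log2z(p))

  energy <- sum(P^2)
  contrast <- sum(kd^2 * p_diff)
  correlation <- if (sd_x > 0 && sd_y > 0)
    (sum(I * J * P) - mu_x * mu_y) / (sd_x * sd_y) else 0
  variance <- sum((I - mu_x)^2 * P)
  idm <- sum(P / (1 + (I - J)^2))
  sum_average <- sum(ks * p_sum)
  sum_variance <- sum((ks - sum_average)^2 * p_sum)
  sum_entropy <- ent(p_sum)
  entropy <- ent(P)
  mu_d <- sum(kd * p_diff)
  difference_variance <- sum((kd - mu_d)^2 * p_diff)
  difference_entropy <- ent(p_diff)

  hx <- ent(px)
  hy <- ent(py)
  PXY <- outer(px, py)
  hxy1 <- -sum(P * log2z(PXY))
  hxy2 <- -sum(PXY * log2z(PXY))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))

  stats::setNames(
    c(energy, contrast, correlation, variance, idm, sum_average,
      sum_variance, sum_entropy, entropy, difference_variance,
      difference_entropy, imc1, imc2),
    .haralick_names)
}

#' Patch-level pathomics feature vector
#'
#' For each of the three density-map scales (S1 = 16x16 px, S2 = 32x32 px,
#' S3 = 64x64 px) and each of the four co-occurrence directions, computes
#' the 13 Haralick statistics: 13 x 4 x 3 = 156 named values per patch.
#'
#' @param dmaps named list of `density_map`s with names "S1", "S2", "S3"
#'   (all three must be present).
#' @return named numeric vector of length 156; names are
#'   `{feature}_{direction}_{scale}` (e.g. `sum_average_D1_S3`).
#' @export
patch_features <- function(dmaps) {
  missing_scales <- setdiff(names(.scale_tags), names(dmaps))
  if (length(missing_scales))
    stop("missing density map scale(s): ", paste(missing_scales, collapse = ", "))
  out <- numeric(0)
  for (sc in names(.scale_tags)) {
    for (d in .directions) {
      h <- haralick(cooccurrence(dmaps[[sc]], d))
      names(h) <- paste(names(h), d, sc, sep = "_")
      out <- c(out, h)
    }
  }
  out
}

#' Canonical slide-level pathomics schema
#'
#' Enumerates, in deterministic order, the slide-level feature names:
#' per scale, 5 aggregation statistics x 13 Haralick statistics x 4
#' directions = 260 attributes. The display name `{stat}_{feature}_{dir}`
#' (e.g. `var_sum_average_D1`, `kurtosis_IMC1_D3`) matches the field's
#' reporting convention, with the scale carried separately; `column`
#' appends the scale tag to keep names unique when scales are combined in
#' one table.
#'
#' @param scales character subset of c("S1", "S2", "S3").
#' @return data.frame with columns `column`, `name`, `stat`, `feature`,
#'   `direction`, `scale`, `scale_px`.
#' @export
enumerate_pathomics_schema <- function(scales = c("S1", "S2", "S3")) {
  unknown <- setdiff(scales, names(.scale_tags))
  if (length(unknown)) stop("unknown scale tag(s): ", paste(unknown, collapse = ", "))
  grid <- expand.grid(direction = .directions, feature = .haralick_names,
                      stat = .agg_stats, scale = scales,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("scale", "stat", "feature", "direction")]
  grid$name <- paste(grid$stat, grid$feature, grid$direction, sep = "_")
  grid$column <- paste(grid$name, grid$scale, sep = "_")
  grid$scale_px <- .scale_tags[grid$scale]
  grid[, c("column", "name", "stat", "feature", "direction", "scale", "scale_px")]
}

#' Aggregate patch features to one slide-level row
#'
#' Aggregates each patch-level feature over all retained patches of a
#' slide with five statistics: mean, median, variance (sample, n-1),
#' excess kurtosis and skewness (both in the bias-adjusted sample form).
#' This yields 5 x 13 x 4 = 260 attributes per scale. With fewer than 4
#' patches, kurtosis and skewness are undefined in the adjusted form and
#' returned as NA with a warning; with no patches the slide is excluded
#' (error).
#'
#' @param patch_matrix numeric matrix (patches x 156) as rows of
#'   [patch_features()] output, or a list of such vectors.
#' @return named numeric vector of length 260 per scale present, named by
#'   the schema `column` ( `{stat}_{feature}_{direction}_{scale}` ).
#' @export
aggregate_slide <- function(patch_matrix) {
  if (is.list(patch_matrix) && !is.matrix(patch_matrix))
    patch_matrix <- do.call(rbind, patch_matrix)
  if (is.vector(patch_matrix))
    patch_matrix <- matrix(patch_matrix, nrow = 1,
                           dimnames = list(NULL, names(patch_matrix)))
  n <- nrow(patch_matrix)
  if (is.null(n) || n == 0L) stop("no retained patches: slide excluded")
  if (n < 4L)
    warning("fewer than 4 patches: kurtosis and skewness are undefined (NA)")
  scales <- intersect(names(.scale_tags),
                      unique(sub(".*_(S[123])$", "\\1", colnames(patch_matrix))))
  schema <- enumerate_pathomics_schema(scales)
  out <- stats::setNames(numeric(nrow(schema)), schema$column)
  for (r in seq_len(nrow(schema))) {
    src <- paste(schema$feature[r], schema$direction[r], schema$scale[r],
                 sep = "_")
    x <- patch_matrix[, src]
    out[r] <- switch(schema$stat[r],
      mean = mean(x),
      median = stats::median(x),
      var = if (n >= 2L) stats::var(x) else NA_real_,
      kurtosis = if (n >= 4L) e1071::kurtosis(x, type = 2) else NA_real_,
      skewness = if (n >= 3L) e1071::skewness(x, type = 2) else NA_real_)
  }
  out
}

#' Slide-level pathomics feature table for a set of patches
#'
#' Convenience wrapper running the full patch -> density map -> GLCM ->
#' Haralick -> aggregation chain for a list of retained patches grouped by
#' patient. Patches are segmented with [segment_nuclei()], density maps
#' computed at the three conventional scales, and aggregated per patient.
#'
#' @param patches list of `tile_patch` objects (each carrying `patient_id`).
#' @param Ng gray levels for the density maps (default 8).
#' @param fg_frac watershed sure-foreground fraction (default 0.4).
#' @param mode density quantization mode (default "absolute").
#' @return list with `table` (data.frame: patient_id + 780 feature
#'   columns), `schema` (the pathomics schema), and `patch_features`
#'   (matrix of per-patch 156-vectors with patient ids as row names).
#' @export
compute_pathomics <- function(patches, Ng = 8L, fg_frac = 0.4,
                              mode = "absolute") {
  stopifnot(length(patches) > 0)
  ids <- vapply(patches, `[[`, character(1), "patient_id")
  feats <- t(vapply(patches, function(p) {
    seg <- segment_nuclei(p, fg_frac = fg_frac)
    dmaps <- lapply(.scale_tags, function(s) density_map(seg, s, Ng, mode))
    names(dmaps) <- names(.scale_tags)
    patch_features(dmaps)
  }, numeric(length(.haralick_names) * 4L * 3L)))
  rownames(feats) <- ids
  schema <- enumerate_pathomics_schema()
  rows <- lapply(split(seq_along(ids), ids), function(ix) {
    suppressWarnings(aggregate_slide(feats[ix, , drop = FALSE]))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(data.frame(patient_id = names(rows), stringsAsFactors = FALSE),
               tab)
  rownames(tab) <- NULL
  list(table = tab, schema = schema, patch_features = feats)
}
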