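#' Specify a synthetic radiopathomics cohort
#'
#' Defines the generating model for a seeded synthetic cohort in which a
#' per-patient latent factor \eqn{z_i \sim N(0, \sigma_z^2)} drives
#' (i) the nucleus density of that patient's H&E-like tiles,
#' (ii) the patient's CT radiomics feature values, and
#' (iii) clinical endpoints (overall survival, progression-free survival,
#' CD8-positive fraction). Because all three views load on the same latent
#' factor, downstream cross-modal and endpoint associations have known
#' planted values and can be tested by parameter recovery.
#'
#' The generating model, per patient \eqn{i} and radiomics feature \eqn{j}:
#' \itemize{
#'   \item tile nucleus rate \eqn{\lambda_i = \lambda_0 \exp(\beta z_i)};
#'     each tile draws Poisson(\eqn{\lambda_i}) nuclei,
#'   \item radiomics \eqn{x_{ij} = a_j z_i + \epsilon_{ij}},
#'     \eqn{\epsilon_{ij} \sim N(0, \mathrm{noise\_sd}^2)}, with loadings
#'     \eqn{a_j} drawn uniformly from \code{radiomics_loading_range},
#'   \item \eqn{OS_i = \mathrm{os\_scale} \cdot \exp(0.5 z_i + \epsilon)},
#'     \eqn{PFS_i} analogous with \code{pfs_scale}, each
#'     \eqn{\epsilon \sim N(0, 0.25)} independently,
#'   \item \eqn{CD8_i = 100 \cdot \mathrm{logistic}(\mathrm{cd8\_slope}
#'     \cdot z_i + \mathrm{cd8\_intercept} + \epsilon)},
#'     \eqn{\epsilon \sim N(0, 0.25)}.
#' }
#'
#' @param n_patients number of patients (>= 2). Default 36, a typical
#'   single-institution immunotherapy cohort size.
#' @param latent_sd standard deviation of the latent factor z.
#' @param nuclei_rate_base expected nuclei per tile at z = 0. The default
#'   of 260 yields tiles whose nucleus-pixel fraction sits comfortably
#'   above the 15% patch-retention cutoff at the default tile size.
#' @param nuclei_rate_slope log-linear effect of z on the nucleus rate.
#' @param n_tiles_per_patient tiles generated per patient (>= 1).
#' @param tile_size tile side in pixels; must be divisible by 64 so the
#'   16/32/64 px density-map bins tile evenly.
#' @param nucleus_radius_range length-2 vector, min/max nucleus semi-axis
#'   in pixels; eccentricity is capped at 2:1.
#' @param n_radiomics_features number of synthetic radiomics columns.
#' @param radiomics_loading_range length-2 interval from which per-feature
#'   loadings on z are drawn uniformly.
#' @param noise_sd SD of radiomics feature noise (>= 0).
#' @param os_scale,pfs_scale log-normal survival scales, in months.
#' @param cd8_slope effect of z on the CD8 logit.
#' @param cd8_intercept CD8 logit intercept; the default -2.5 centres CD8
#'   near 8%, a realistic immune-infiltration level.
#' @param censor_horizon optional administrative censoring horizon in
#'   months; if finite, OS/PFS are truncated at the horizon and event
#'   flags are recorded. Default `Inf` (no censoring).
#' @param seed integer seed controlling every random draw.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [generate_tile()]
#' @export
synthetic_cohort_spec <- function(n_patients = 36,
                                  latent_sd = 1,
                                  nuclei_rate_base = 260,
                                  nuclei_rate_slope = 0.25,
                                  n_tiles_per_patient = 4,
                                  tile_size = 512,
                                  nucleus_radius_range = c(6, 10),
                                  n_radiomics_features = 100,
                                  radiomics_loading_range = c(0.3, 0.9),
                                  noise_sd = 0.6,
                                  os_scale = 20,
                                  pfs_scale = 10,
                                  cd8_slope = 1,
                                  cd8_intercept = -2.5,
                                  censor_horizon = Inf,
                                  seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients),
    latent_sd = latent_sd,
    nuclei_rate_base = nuclei_rate_base,
    nuclei_rate_slope = nuclei_rate_slope,
    n_tiles_per_patient = as.integer(n_tiles_per_patient),
    tile_size = as.integer(tile_size),
    nucleus_radius_range = nucleus_radius_range,
    n_radiomics_features = as.integer(n_radiomics_features),
    radiomics_loading_range = radiomics_loading_range,
    noise_sd = noise_sd,
    os_scale = os_scale,
    pfs_scale = pfs_scale,
    cd8_slope = cd8_slope,
    cd8_intercept = cd8_intercept,
    censor_horizon = censor_horizon,
    seed = as.integer(seed)
  )
  if (spec$n_patients < 2L) stop("n_patients must be >= 2")
  if (spec$n_tiles_per_patient < 1L) stop("n_tiles_per_patient must be >= 1")
  if (spec$tile_size %% 64L != 0L) stop("tile_size must be divisible by 64")
  if (spec$nuclei_rate_base <= 0) stop("nuclei_rate_base must be > 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(spec$nucleus_radius_range) != 2L ||
      spec$nucleus_radius_range[1] <= 0 ||
      diff(spec$nucleus_radius_range) < 0)
    stop("nucleus_radius_range must be an increasing positive pair")
  if (length(spec$radiomics_loading_range) != 2L ||
      diff(spec$radiomics_loading_range) < 0)
    stop("radiomics_loading_range must be a non-decreasing pair")
  structure(spec, class = "cohort_spec")
}

# Fixed H&E-like palette: keeps grayscale and nucleus-channel behaviour
# stable across runs (see the methods vignette).
.he_palette <- list(background = c(240, 220, 225), nucleus = c(90, 60, 120))

#' Generate one synthetic H&E-like tile
#'
#' Draws a Poisson number of non-overlapping dark-purple filled ellipses
#' (nuclei) on a pale pink background with mild additive Gaussian noise.
#' Nuclei are placed by rejection sampling (at most 1000 attempts per
#' nucleus, then the nucleus is skipped) and are kept fully inside the
#' tile. The ground-truth mask labels each placed nucleus with a distinct
#' positive integer; the count of positive labels is the authoritative
#' nucleus count for recovery tests.
#'
#' Randomness comes from R's global RNG: seed with [set.seed()] for
#' reproducible tiles. Nuclei are deliberately simple ellipses: the
#' downstream density computation only requires countable dark blobs.
#'
#' @param rate expected nucleus count (Poisson mean, >= 0).
#' @param tile_size tile side in pixels (>= 64).
#' @param nucleus_radius_range min/max semi-axis length in pixels.
#' @param noise_sd SD of the additive pixel noise, in 0-255 units.
#' @return list with `image` (tile_size x tile_size x 3 integer array,
#'   0-255), `mask` (integer label matrix), and `n_nuclei`.
#' @export
generate_tile <- function(rate, tile_size = 512L,
                          nucleus_radius_range = c(6, 10),
                          noise_sd = 3) {
  if (tile_size < 64L) stop("tile_size must be >= 64")
  if (rate < 0) stop("rate must be >= 0")
  sz <- as.integer(tile_size)
  mask <- matrix(0L, sz, sz)
  n_target <- stats::rpois(1L, rate)
  rmin <- nucleus_radius_range[1]
  rmax <- nucleus_radius_range[2]
  placed <- 0L
  for (k in seq_len(n_target)) {
    for (attempt in seq_len(1000L)) {
      a <- stats::runif(1L, rmin, rmax)              # semi-major
      b <- stats::runif(1L, max(rmin, a / 2), a)      # semi-minor, ecc <= 2:1
      theta <- stats::runif(1L, 0, pi)
      m <- ceiling(a) + 2L
      if (2L * m >= sz) next
      cy <- stats::runif(1L, m + 1L, sz - m)
      cx <- stats::runif(1L, m + 1L, sz - m)
      rows <- max(1L, floor(cy - m)):min(sz, ceiling(cy + m))
      cols <- max(1L, floor(cx - m)):min(sz, ceiling(cx + m))
      dy <- rows - cy
      dx <- cols - cx
      u <- outer(dy, dx, function(y, x)  x * cos(theta) + y * sin(theta))
      v <- outer(dy, dx, function(y, x) -x * sin(theta) + y * cos(theta))
      inside <- (u / a)^2 + (v / b)^2 <= 1
      # reject when a neighbour lies within a 2 px margin: keeps nuclei
      # disconnected at pixel adjacency, so "non-overlapping" holds for
      # connected-component analysis as well
      near <- (u / (a + 2))^2 + (v / (b + 2))^2 <= 1
      sub <- mask[rows, cols, drop = FALSE]
      if (any(sub[near] > 0L)) next
      sub[inside] <- placed + 1L
      mask[rows, cols] <- sub
      placed <- placed + 1L
      break
    }
  }
  img <- array(0, dim = c(sz, sz, 3L))
  nuc <- mask > 0L
  for (ch in 1:3) {
    plane <- matrix(.he_palette$background[ch], sz, sz)
    plane[nuc] <- .he_palette$nucleus[ch]
    plane <- plane + stats::rnorm(sz * sz, 0, noise_sd)
    img[, , ch] <- pmin(pmax(round(plane), 0), 255)
  }
  storage.mode(img) <- "integer"
  list(image = img, mask = mask, n_nuclei = placed)
}

#' Generate a full synthetic cohort
#'
#' Realizes a [synthetic_cohort_spec()]: per-patient latent factors, tile
#' images with ground-truth nucleus masks, a radiomics feature table with
#' planted loadings, and a clinical endpoints table. All ground truth
#' (latent factors, loadings, per-tile nucleus counts) is retained so that
#' downstream stages can be validated by parameter recovery.
#'
#' @param spec a `cohort_spec`.
#' @param make_images generate tile images and masks (default TRUE). With
#'   FALSE only the tabular views are produced, which is convenient for
#'   statistical experiments at large n where the imaging path is not
#'   under study.
#' @return An object of class `synthetic_cohort`: list with `spec`, `z`,
#'   `loadings`, `tiles` (list of per-tile records or NULL), `radiomics`
#'   (data.frame with `patient_id` + feature columns), `clinical`
#'   (data.frame with `patient_id`, `os_months`, `pfs_months`,
#'   `progression`, `cd8_pct`, and event flags when censoring is enabled).
#' @export
generate_cohort <- function(spec, make_images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  z <- stats::rnorm(n, 0, spec$latent_sd)
  loadings <- stats::runif(spec$n_radiomics_features,
                           spec$radiomics_loading_range[1],
                           spec$radiomics_loading_range[2])

  radio <- sapply(seq_len(spec$n_radiomics_features), function(j) {
    loadings[j] * z + stats::rnorm(n, 0, spec$noise_sd)
  })
  radio <- as.data.frame(radio)
  names(radio) <- sprintf("f%03d", seq_len(spec$n_radiomics_features))
  radio <- cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE), radio)

  os <- spec$os_scale * exp(0.5 * z + stats::rnorm(n, 0, 0.5))
  pfs <- spec$pfs_scale * exp(0.5 * z + stats::rnorm(n, 0, 0.5))
  progression <- stats::rbinom(n, 1L, stats::plogis(-0.8 * z))
  cd8 <- 100 * stats::plogis(spec$cd8_slope * z + spec$cd8_intercept +
                             stats::rnorm(n, 0, 0.5))
  clinical <- data.frame(patient_id = ids,
                         os_months = os, pfs_months = pfs,
                         progression = progression, cd8_pct = cd8,
                         stringsAsFactors = FALSE)
  if (is.finite(spec$censor_horizon)) {
    clinical$os_event <- as.integer(os <= spec$censor_horizon)
    clinical$pfs_event <- as.integer(pfs <= spec$censor_horizon)
    clinical$os_months <- pmin(os, spec$censor_horizon)
    clinical$pfs_months <- pmin(pfs, spec$censor_horizon)
  }

  tiles <- NULL
  if (make_images) {
    rate <- spec$nuclei_rate_base * exp(spec$nuclei_rate_slope * z)
    tiles <- vector("list", n * spec$n_tiles_per_patient)
    k <- 0L
    for (i in seq_len(n)) {
      for (t in seq_len(spec$n_tiles_per_patient)) {
        tl <- generate_tile(rate[i], spec$tile_size,
                            spec$nucleus_radius_range)
        k <- k + 1L
        tiles[[k]] <- list(patient_id = ids[i], tile_id = t,
                           image = tl$image, mask = tl$mask,
                           n_nuclei = tl$n_nuclei)
      }
    }
  }
  structure(list(spec = spec, patient_ids = ids, z = z, loadings = loadings,
                 tiles = tiles, radiomics = radio, clinical = clinical),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients, %d tiles, %d radiomics features\n",
              x$spec$n_patients,
              if (is.null(x$tiles)) 0L else length(x$tiles),
              x$spec$n_radiomics_features))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Tiles are written as PNG, ground-truth label masks as 16-bit TIFF, the
#' radiomics and clinical tables as CSV keyed by `patient_id`, and a JSON
#' manifest recording the spec, latent factors, loadings and per-tile
#' nucleus counts.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tile_records <- list()
  if (!is.null(cohort$tiles)) {
    dir.create(file.path(dir, "tiles"), showWarnings = FALSE)
    for (tl in cohort$tiles) {
      stem <- sprintf("%s_tile%02d", tl$patient_id, tl$tile_id)
      png::writePNG(aperm(array(tl$image / 255, dim = dim(tl$image)),
                          c(1, 2, 3)),
                    file.path(dir, "tiles", paste0(stem, ".png")))
      tiff::writeTIFF(tl$mask / 65535,
                      file.path(dir, "tiles", paste0(stem, "_mask.tif")),
                      bits.per.sample = 16L)
      tile_records[[stem]] <- list(patient_id = tl$patient_id,
                                   tile_id = tl$tile_id,
                                   n_nuclei = tl$n_nuclei)
    }
  }
  utils::write.csv(cohort$radiomics, file.path(dir, "radiomics.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  manifest <- list(spec = unclass(cohort$spec), patient_ids = cohort$patient_ids,
                   z = cohort$z, loadings = cohort$loadings,
                   tiles = tile_records)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a latent-driven feature table
#'
#' Low-level helper behind the radiomics arm of [generate_cohort()]:
#' given latent factors and per-feature loadings, returns a table whose
#' column j equals `loadings[j] * z + N(0, noise_sd^2)`. Useful for
#' planting two feature "modalities" with controlled, possibly different,
#' couplings to the same endpoints.
#'
#' @param z numeric latent factors (one per row).
#' @param loadings numeric per-feature loadings.
#' @param noise_sd noise SD (>= 0).
#' @param prefix column-name prefix.
#' @return data.frame of length(z) rows and length(loadings) columns.
#' @export
generate_feature_table <- function(z, loadings, noise_sd, prefix = "f") {
  stopifnot(noise_sd >= 0)
  tab <- sapply(seq_along(loadings), function(j) {
    loadings[j] * z + stats::rnorm(length(z), 0, noise_sd)
  })
  tab <- as.data.frame(tab)
  names(tab) <- sprintf("%s%03d", prefix, seq_along(loadings))
  tab
}
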