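#' Configure an end-to-end radiopathomics run
#'
#' Collects every stage parameter with the conventional defaults: 512 px
#' patches, 80% minimum tissue content, 15% minimum nucleus score,
#' density-map scales 16/32/64 px with 8 gray levels, |r| = 0.9 redundancy
#' threshold, FDR level 0.05, Ward/Euclidean two-cluster stratification,
#' and a single seed from which all randomness flows.
#'
#' @param cohort_spec a [synthetic_cohort_spec()] for synthetic input, or
#'   NULL when data paths are supplied.
#' @param tiles_dir directory of pre-extracted PNG tiles named
#'   `<patient>_tile<k>.png` (alternative to a synthetic spec).
#' @param radiomics_csv path to a patients x features radiomics CSV with a
#'   `patient_id` column; NULL skips the association stages.
#' @param clinical_csv path to a clinical endpoints CSV (`patient_id`,
#'   `os_months`, `pfs_months`, `progression`, `cd8_pct`).
#' @param patch_size patch side in pixels (default 512).
#' @param tissue_threshold minimum within-patch tissue fraction when
#'   patching a slide image (default 0.8).
#' @param min_nucleus_score minimum patch nucleus score (default 0.15).
#' @param Ng density-map gray levels (default 8).
#' @param fg_frac watershed sure-foreground fraction (default 0.4).
#' @param density_mode density quantization mode (default "absolute").
#' @param filter_threshold redundancy filter |r| threshold (default 0.9).
#' @param report_threshold |rho| cutoff for the strongest-pair table
#'   (default 0.5).
#' @param fdr_level FDR level recorded with endpoint correlations
#'   (default 0.05).
#' @param linkage,metric clustering linkage and metric (Ward/Euclidean).
#' @param k number of patient clusters (default 2).
#' @param months_cutoff survival dichotomization for cluster summaries.
#' @param seed run seed.
#' @param output_dir directory for the report bundle; NULL keeps results
#'   in memory only.
#' @return an object of class `run_config` (a validated list).
#' @export
run_config <- function(cohort_spec = NULL, tiles_dir = NULL,
                       radiomics_csv = NULL, clinical_csv = NULL,
                       patch_size = 512L, tissue_threshold = 0.8,
                       min_nucleus_score = 0.15, Ng = 8L, fg_frac = 0.4,
                       density_mode = "absolute",
                       filter_threshold = 0.9, report_threshold = 0.5,
                       fdr_level = 0.05, linkage = "ward.D2",
                       metric = "euclidean", k = 2L, months_cutoff = 12,
                       seed = 1L, output_dir = NULL) {
  cfg <- list(cohort_spec = cohort_spec, tiles_dir = tiles_dir,
              radiomics_csv = radiomics_csv, clinical_csv = clinical_csv,
              patch_size = as.integer(patch_size),
              tissue_threshold = tissue_threshold,
              min_nucleus_score = min_nucleus_score, Ng = as.integer(Ng),
              fg_frac = fg_frac, density_mode = density_mode,
              filter_threshold = filter_threshold,
              report_threshold = report_threshold, fdr_level = fdr_level,
              linkage = linkage, metric = metric, k = as.integer(k),
              months_cutoff = months_cutoff, seed = as.integer(seed),
              output_dir = output_dir,
              scales_px = c(16L, 32L, 64L))
  if (is.null(cfg$cohort_spec) && is.null(cfg$tiles_dir))
    stop("either a cohort_spec or a tiles_dir must be given")
  if (!is.null(cfg$cohort_spec))
    stopifnot(inherits(cfg$cohort_spec, "cohort_spec"))
  stopifnot(cfg$tissue_threshold >= 0, cfg$tissue_threshold <= 1,
            cfg$min_nucleus_score >= 0, cfg$min_nucleus_score <= 1,
            cfg$filter_threshold > 0, cfg$filter_threshold <= 1)
  structure(cfg, class = "run_config")
}

.read_tiles_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "_tile\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no '<patient>_tile<k>.png' tiles found in ", dir)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    img <- round(img[, , 1:3, drop = FALSE] * 255)
    storage.mode(img) <- "integer"
    stem <- sub("\\.png$", "", basename(f))
    pid <- sub("_tile\\d+$", "", stem)
    tid <- as.integer(sub(".*_tile(\\d+)$", "\\1", stem))
    list(patient_id = pid, tile_id = tid, image = img)
  })
}

#' Run the full radiopathomics pipeline
#'
#' Executes the complete flow: obtain tiles (synthetic generation or
#' reading from disk), score and filter patches by nucleus content,
#' segment nuclei, build multi-scale density maps, compute patch and
#' slide-level Haralick pathomics features, join the radiomics table,
#' z-score both modalities, apply the Spearman redundancy filter (per
#' scale on pathomics), compute cross-modal correlations, per-endpoint
#' correlations with FDR and Kolmogorov-Smirnov comparisons of the two
#' modalities' correlation distributions, and stratify patients by
#' two-cluster hierarchical clustering per modality. When tiles come
#' pre-extracted (synthetic tiles or a tiles directory) they are treated
#' as already-qualified patches and slide-level tissue masking is not
#' re-applied; supply whole-slide imagery through [compute_tissue_mask()]
#' and [extract_patches()] to use the tissue filter.
#'
#' The run is deterministic for a fixed seed, and when `output_dir` is set
#' every table is written as CSV/JSON along with a manifest (config, seed,
#' package version, config hash).
#'
#' @param config a [run_config()].
#' @return a `run_result` list: `pathomics` (slide-level table), `schema`,
#'   `patch_manifest`, `radiomics`, `clinical`, `filtered` (retained
#'   column names per modality), `cross` (`cross_correlation`),
#'   `endpoints` (per endpoint and modality), `ks` (per endpoint),
#'   `clusters`, `cluster_summaries`, `switches`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- NULL
  if (!is.null(config$cohort_spec)) {
    cohort <- stage("input", generate_cohort(config$cohort_spec))
    tiles <- cohort$tiles
  } else {
    tiles <- stage("input", .read_tiles_dir(config$tiles_dir))
  }

  patches <- stage("patching", {
    ps <- lapply(tiles, function(tl)
      as_tile_patch(tl$image, tl$patient_id, tl$tile_id))
    ps <- lapply(ps, nucleus_score)
    kept <- filter_patches(ps, config$min_nucleus_score)
    if (!length(kept)) stop("no patches retained")
    attr(kept, "manifest") <- patch_manifest(
      ps, vapply(ps, function(p) p$nucleus_score >= config$min_nucleus_score,
                 logical(1)))
    kept
  })

  patho <- stage("pathomics", {
    compute_pathomics(patches, Ng = config$Ng, fg_frac = config$fg_frac,
                      mode = config$density_mode)
  })

  radiomics <- stage("radiomics", {
    if (!is.null(cohort)) cohort$radiomics
    else if (!is.null(config$radiomics_csv))
      read_radiomics_table(config$radiomics_csv)$table
    else NULL
  })
  clinical <- stage("clinical", {
    if (!is.null(cohort)) cohort$clinical
    else if (!is.null(config$clinical_csv))
      utils::read.csv(config$clinical_csv, stringsAsFactors = FALSE)
    else NULL
  })

  patho_z <- stage("normalize", suppressWarnings(zscore(patho$table)))
  filtered <- stage("redundancy_filter", {
    schema <- patho$schema
    by_scale <- split(schema$column, schema$scale_px)
    patho_kept <- unlist(lapply(by_scale, function(cols) {
      cols <- intersect(cols, names(patho_z))
      if (length(cols) < 2L) return(cols)
      correlation_filter(patho_z[, cols, drop = FALSE],
                         config$filter_threshold)
    }), use.names = FALSE)
    radio_kept <- NULL
    if (!is.null(radiomics)) {
      radio_z <- suppressWarnings(zscore(radiomics))
      radio_kept <- correlation_filter(radio_z, config$filter_threshold)
    }
    list(pathomics = patho_kept, radiomics = radio_kept)
  })

  cross <- NULL; endpoints <- NULL; ks <- NULL
  clusters <- list(); summaries <- list(); switches <- NULL
  if (is.null(radiomics)) {
    message("no radiomics table supplied: association stages skipped")
  } else {
    radio_z <- suppressWarnings(zscore(radiomics))
    pz <- cbind(patho_z["patient_id"],
                patho_z[, filtered$pathomics, drop = FALSE])
    rz <- cbind(radio_z["patient_id"],
                radio_z[, filtered$radiomics, drop = FALSE])
    cross <- stage("cross_correlation",
                   cross_correlation(pz, rz, schema = patho$schema,
                                     report_threshold = config$report_threshold))
    if (!is.null(clinical)) {
      eps <- c(os = "os_months", pfs = "pfs_months", cd8 = "cd8_pct")
      endpoints <- stage("endpoint_correlation", {
        lapply(eps, function(col) {
          ev <- stats::setNames(clinical[[col]], clinical$patient_id)
          list(pathomics = endpoint_correlation(pz, ev),
               radiomics = endpoint_correlation(rz, ev))
        })
      })
      ks <- stage("ks_comparison", {
        lapply(endpoints, function(e)
          ks_compare(e$radiomics$rho, e$pathomics$rho))
      })
    }
    clust <- stage("clustering", {
      cp <- hac_cluster(pz, k = config$k, linkage = config$linkage,
                        metric = config$metric, modality = "pathomics")
      cr <- hac_cluster(rz[match(pz$patient_id, rz$patient_id), ],
                        k = config$k, linkage = config$linkage,
                        metric = config$metric, modality = "radiomics")
      sums <- list()
      if (!is.null(clinical)) {
        sums$pathomics <- cluster_summary(cp, clinical, config$months_cutoff)
        sums$radiomics <- cluster_summary(cr, clinical, config$months_cutoff)
      }
      list(clusters = list(pathomics = cp, radiomics = cr),
           summaries = sums, switches = compare_assignments(cp, cr))
    })
    clusters <- clust$clusters
    summaries <- clust$summaries
    switches <- clust$switches
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("radiopathomics")),
    parameters = list(patch_size = config$patch_size,
                      tissue_threshold = config$tissue_threshold,
                      min_nucleus_score = config$min_nucleus_score,
                      scales_px = config$scales_px, Ng = config$Ng,
                      fg_frac = config$fg_frac,
                      density_mode = config$density_mode,
                      filter_threshold = config$filter_threshold,
                      report_threshold = config$report_threshold,
                      fdr_level = config$fdr_level,
                      linkage = config$linkage, metric = config$metric,
                      k = config$k, months_cutoff = config$months_cutoff))
  cfg_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  result <- structure(
    list(pathomics = patho$table, schema = patho$schema,
         patch_manifest = attr(patches, "manifest"),
         radiomics = radiomics, clinical = clinical, filtered = filtered,
         cross = cross, endpoints = endpoints, ks = ks,
         clusters = clusters, cluster_summaries = summaries,
         switches = switches, manifest = manifest),
    class = "run_result")
  if (!is.null(config$output_dir)) write_run_bundle(result, config)
  result
}

#' Write a pipeline report bundle
#'
#' @param result a `run_result`.
#' @param config the `run_config` used (for the output directory and
#'   manifest echo).
#' @return invisibly, the output directory.
#' @export
write_run_bundle <- function(result, config) {
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$pathomics, file.path(dir, "pathomics_features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$patch_manifest, file.path(dir, "patch_manifest.csv"),
                   row.names = FALSE)
  if (!is.null(result$cross)) {
    utils::write.csv(as.data.frame(result$cross$rho),
                     file.path(dir, "cross_correlation_matrix.csv"))
    utils::write.csv(result$cross$sign_counts,
                     file.path(dir, "cross_correlation_signs.csv"),
                     row.names = FALSE)
    utils::write.csv(result$cross$top_pairs,
                     file.path(dir, "top_pairs.csv"), row.names = FALSE)
  }
  if (!is.null(result$endpoints)) {
    for (ep in names(result$endpoints)) {
      for (mod in c("pathomics", "radiomics")) {
        utils::write.csv(result$endpoints[[ep]][[mod]],
                         file.path(dir, sprintf("endpoint_%s_%s.csv", ep, mod)),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(
      lapply(result$ks, function(x) x[c("D", "p", "n1", "n2")]),
      file.path(dir, "ks_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  if (length(result$clusters)) {
    assign_df <- data.frame(
      patient_id = names(result$clusters$pathomics$labels),
      pathomics_cluster = unname(result$clusters$pathomics$labels),
      radiomics_cluster = unname(
        result$clusters$radiomics$labels[
          names(result$clusters$pathomics$labels)]))
    utils::write.csv(assign_df, file.path(dir, "cluster_assignments.csv"),
                     row.names = FALSE)
    for (mod in names(result$cluster_summaries))
      utils::write.csv(result$cluster_summaries[[mod]],
                       file.path(dir, sprintf("cluster_summary_%s.csv", mod)),
                       row.names = FALSE)
    jsonlite::write_json(
      lapply(result$clusters, function(cl)
        list(merge_heights = cl$merge_heights, merge = cl$hclust$merge,
             labels = as.list(cl$labels))),
      file.path(dir, "dendrograms.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
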