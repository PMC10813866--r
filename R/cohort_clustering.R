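#' Two-cluster hierarchical stratification of patients
#'
#' Agglomerative clustering of patients on a (z-scored) feature table —
#' Ward linkage on Euclidean distances by default — with the dendrogram
#' cut to exactly k clusters. Labels are canonicalized so the output does
#' not depend on input row order: cluster 0 is the larger cluster, and on
#' a size tie cluster 0 is the one containing the lexicographically
#' smallest patient id.
#'
#' @param features data.frame with `patient_id` + numeric columns, or a
#'   numeric matrix with patient ids as row names.
#' @param k number of clusters (default 2; n >= k required).
#' @param linkage hclust agglomeration method (default "ward.D2", Ward on
#'   Euclidean distances).
#' @param metric dist metric (default "euclidean").
#' @param modality tag carried on the result ("pathomics" or "radiomics",
#'   free-form).
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (integer 0/1.. named by patient_id), `modality`, `linkage`, `metric`,
#'   `merge_heights` (the hclust merge heights), and `hclust`.
#' @export
hac_cluster <- function(features, k = 2L, linkage = "ward.D2",
                        metric = "euclidean", modality = NA_character_) {
  if (is.data.frame(features)) {
    ids <- if ("patient_id" %in% names(features)) features$patient_id
           else rownames(features)
    m <- as.matrix(features[, setdiff(names(features), "patient_id"),
                            drop = FALSE])
  } else {
    m <- as.matrix(features)
    ids <- rownames(m)
  }
  if (is.null(ids)) ids <- sprintf("row%03d", seq_len(nrow(m)))
  n <- nrow(m)
  if (n < k) stop("need at least k patients to form k clusters")
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  raw <- stats::cutree(hc, k = k)
  names(raw) <- ids
  # canonicalize: relabel clusters by decreasing size, ties by the
  # lexicographically smallest member id
  sizes <- table(raw)
  min_id <- vapply(names(sizes), function(cl) min(ids[raw == cl]),
                   character(1))
  ord <- order(-as.integer(sizes), min_id)
  remap <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  labels <- remap[as.character(raw)]
  names(labels) <- ids
  structure(list(labels = labels, modality = modality, k = as.integer(k),
                 linkage = linkage, metric = metric,
                 merge_heights = hc$height, hclust = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s, %s/%s): sizes %s\n",
              ifelse(is.na(x$modality), "unlabelled", x$modality),
              x$linkage, x$metric,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Clinical characterization of patient clusters
#'
#' Summarizes each cluster the way stratified immunotherapy cohorts are
#' reported: cluster size, number and percentage of patients with PFS
#' above `months_cutoff`, with OS above `months_cutoff`, and with CD8
#' strictly above the cohort median (computed over all patients with
#' non-missing CD8). Observed times are used regardless of censoring.
#' Patients missing an endpoint are excluded from that endpoint's
#' denominator.
#'
#' @param assignment a `cluster_assignment`.
#' @param clinical data.frame with `patient_id`, `os_months`, `pfs_months`,
#'   `cd8_pct`.
#' @param months_cutoff survival dichotomization point in months
#'   (default 12).
#' @return data.frame with one row per cluster: `cluster`, `size`,
#'   `pfs_gt_cutoff`, `pfs_pct`, `os_gt_cutoff`, `os_pct`,
#'   `cd8_gt_median`, `cd8_pct_gt_median` (percentages exact, not
#'   rounded).
#' @export
cluster_summary <- function(assignment, clinical, months_cutoff = 12) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ids <- names(assignment$labels)
  if (!all(ids %in% clinical$patient_id))
    stop("clinical table does not cover all clustered patients")
  cl <- clinical[match(ids, clinical$patient_id), ]
  cd8_median <- stats::median(clinical$cd8_pct, na.rm = TRUE)
  out <- lapply(sort(unique(assignment$labels)), function(g) {
    sel <- assignment$labels == g
    pfs <- cl$pfs_months[sel]; os <- cl$os_months[sel]; cd8 <- cl$cd8_pct[sel]
    data.frame(
      cluster = g,
      size = sum(sel),
      pfs_gt_cutoff = sum(pfs > months_cutoff, na.rm = TRUE),
      pfs_pct = 100 * mean(pfs > months_cutoff, na.rm = TRUE),
      os_gt_cutoff = sum(os > months_cutoff, na.rm = TRUE),
      os_pct = 100 * mean(os > months_cutoff, na.rm = TRUE),
      cd8_gt_median = sum(cd8 > cd8_median, na.rm = TRUE),
      cd8_pct_gt_median = 100 * mean(cd8 > cd8_median, na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "cd8_median") <- cd8_median
  attr(out, "months_cutoff") <- months_cutoff
  out
}

#' Count patients switching clusters between two assignments
#'
#' Aligns the labels of two assignments over the same patient set by the
#' best of the two possible label permutations (maximum agreement) and
#' reports how many patients carry different aligned labels, along with
#' the raw (unaligned) switch count.
#'
#' @param a,b `cluster_assignment` objects over the same patients.
#' @return list with `switched` (aligned count), `raw_switched`,
#'   `permutation_applied` (logical: were b's labels flipped).
#' @export
compare_assignments <- function(a, b) {
  stopifnot(inherits(a, "cluster_assignment"),
            inherits(b, "cluster_assignment"))
  if (!setequal(names(a$labels), names(b$labels)))
    stop("assignments cover different patient sets")
  if (a$k != 2L || b$k != 2L)
    stop("label alignment is defined for two-cluster assignments")
  lb <- b$labels[names(a$labels)]
  raw <- sum(a$labels != lb)
  flipped <- sum(a$labels != (1L - lb))
  list(switched = min(raw, flipped), raw_switched = raw,
       permutation_applied = flipped < raw)
}
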