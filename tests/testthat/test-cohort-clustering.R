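make_blobs <- function(n_per = 20, sep = 10, p = 5, seed = 171) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, sep), n_per, p))
  rownames(m) <- sprintf("P%03d", seq_len(2 * n_per))
  list(m = m, truth = rep(0:1, each = n_per))
}

test_that("two well-separated blobs are recovered exactly", {
  bl <- make_blobs()
  asg <- hac_cluster(bl$m, k = 2)
  agree <- max(mean(asg$labels == bl$truth),
               mean(asg$labels == 1 - bl$truth))
  expect_equal(agree, 1)
  expect_length(unique(asg$labels), 2L)
  expect_equal(sort(unique(asg$labels)), c(0L, 1L))
})

test_that("duplicated patients share a label and n=2 gives singletons", {
  bl <- make_blobs(n_per = 5)
  m <- rbind(bl$m, dup = bl$m[1, , drop = FALSE])
  rownames(m)[nrow(m)] <- "Pdup"
  asg <- hac_cluster(m, k = 2)
  expect_equal(unname(asg$labels["Pdup"]), unname(asg$labels["P001"]))

  two <- matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), NULL))
  asg2 <- hac_cluster(two, k = 2)
  expect_equal(sort(unname(asg2$labels)), c(0L, 1L))
  # size tie: cluster 0 holds the lexicographically smallest id
  expect_equal(unname(asg2$labels["A"]), 0L)
  expect_error(hac_cluster(two, k = 3), "at least k")
})

test_that("labels are canonical and invariant to row order", {
  bl <- make_blobs(n_per = 12, seed = 181)
  asg1 <- hac_cluster(bl$m, k = 2)
  set.seed(191)
  perm <- sample(nrow(bl$m))
  asg2 <- hac_cluster(bl$m[perm, ], k = 2)
  expect_equal(asg1$labels[sort(names(asg1$labels))],
               asg2$labels[sort(names(asg2$labels))])
  # larger cluster is cluster 0
  bl3 <- make_blobs(n_per = 15, seed = 201)
  m <- bl3$m[1:25, ]  # 15 in blob A, 10 in blob B
  asg3 <- hac_cluster(m, k = 2)
  expect_gte(sum(asg3$labels == 0L), sum(asg3$labels == 1L))
})

test_that("the two-cluster cut equals the last-merge partition", {
  bl <- make_blobs(n_per = 8, seed = 211)
  asg <- hac_cluster(bl$m, k = 2)
  hc <- asg$hclust
  # cutting just below the final merge height reproduces the labels
  cut_h <- cutree(hc, h = max(hc$height) - 1e-9)
  names(cut_h) <- rownames(bl$m)
  agree <- max(mean((cut_h - 1) == asg$labels),
               mean((2 - cut_h) == asg$labels))
  expect_equal(agree, 1)
})

test_that("cluster summaries match brute-force counting", {
  set.seed(221)
  n <- 30
  clinical <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    os_months = runif(n, 1, 60), pfs_months = runif(n, 0.5, 40),
    progression = rbinom(n, 1, 0.5), cd8_pct = runif(n, 0, 30))
  labels <- rep(c(0L, 1L), c(18, 12))
  asg <- structure(list(labels = setNames(labels, clinical$patient_id),
                        modality = "test", k = 2L, linkage = "ward.D2",
                        metric = "euclidean"),
                   class = "cluster_assignment")
  sm <- cluster_summary(asg, clinical, months_cutoff = 12)
  expect_equal(sum(sm$size), n)
  med <- median(clinical$cd8_pct)
  for (g in 0:1) {
    sel <- labels == g
    expect_equal(sm$pfs_gt_cutoff[sm$cluster == g],
                 sum(clinical$pfs_months[sel] > 12))
    expect_equal(sm$os_gt_cutoff[sm$cluster == g],
                 sum(clinical$os_months[sel] > 12))
    expect_equal(sm$cd8_gt_median[sm$cluster == g],
                 sum(clinical$cd8_pct[sel] > med))
    expect_equal(sm$pfs_pct[sm$cluster == g],
                 100 * mean(clinical$pfs_months[sel] > 12))
  }

  # all OS at 24 months: 100% above 12 in both clusters
  cl2 <- clinical; cl2$os_months <- 24
  sm2 <- cluster_summary(asg, cl2)
  expect_true(all(sm2$os_pct == 100))
  # equal CD8 everywhere: strict inequality leaves zero above the median
  cl3 <- clinical; cl3$cd8_pct <- 5
  sm3 <- cluster_summary(asg, cl3)
  expect_true(all(sm3$cd8_gt_median == 0))

  expect_error(cluster_summary(asg, clinical[-1, ]), "cover")
})

test_that("planted-signal cohorts put high-CD8 patients in one cluster", {
  spec <- synthetic_cohort_spec(n_patients = 60, latent_sd = 1.5,
                                radiomics_loading_range = c(0.7, 0.9),
                                noise_sd = 0.3, cd8_slope = 2, seed = 31)
  co <- generate_cohort(spec, make_images = FALSE)
  z <- suppressWarnings(zscore(co$radiomics))
  asg <- hac_cluster(z, k = 2, modality = "radiomics")
  sm <- cluster_summary(asg, co$clinical)
  mean_z <- tapply(co$z, asg$labels[co$patient_ids], mean)
  hi <- names(which.max(mean_z))
  lo <- names(which.min(mean_z))
  expect_gt(sm$cd8_pct_gt_median[sm$cluster == as.integer(hi)],
            sm$cd8_pct_gt_median[sm$cluster == as.integer(lo)])
})

test_that("assignment comparison aligns labels before counting switches", {
  ids <- sprintf("P%02d", 1:10)
  mk <- function(lab) structure(list(labels = setNames(lab, ids), k = 2L),
                                class = "cluster_assignment")
  a <- mk(rep(c(0L, 1L), each = 5))
  expect_equal(compare_assignments(a, a)$switched, 0L)
  comp <- compare_assignments(a, mk(rep(c(1L, 0L), each = 5)))
  expect_equal(comp$switched, 0L)
  expect_equal(comp$raw_switched, 10L)

  set.seed(241)
  for (i in 1:10) {
    lb <- sample(0:1, 10, replace = TRUE)
    got <- compare_assignments(a, mk(lb))$switched
    brute <- min(sum(a$labels != lb), sum(a$labels != 1L - lb))
    expect_equal(got, brute)
  }
  b <- structure(list(labels = setNames(rep(0L, 3), c("X", "Y", "Z")), k = 2L),
                 class = "cluster_assignment")
  expect_error(compare_assignments(a, b), "different patient sets")
})
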