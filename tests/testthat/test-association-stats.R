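test_that("z-score normalization centers, scales, drops constants, and is idempotent", {
  x <- data.frame(a = c(1, 2, 3), b = c(5, -1, 7), const = c(2, 2, 2))
  expect_warning(z <- zscore(x), "const")
  expect_equal(names(z), c("a", "b"))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(as.matrix(zscore(z)), as.matrix(z), tolerance = 1e-12)
  expect_error(zscore(data.frame(a = 1)), "at least 2")
  # patient_id passes through
  y <- zscore(data.frame(patient_id = c("A", "B", "C"), v = c(1, 2, 4)))
  expect_equal(y$patient_id, c("A", "B", "C"))
})

test_that("spearman equals the rank-based hand computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(3, 1, 4, 1, 5)
  # hand ranks: y -> (3, 1.5, 4, 1.5, 5); Pearson of ranks
  rx <- 1:5
  ry <- c(3, 1.5, 4, 1.5, 5)
  hand <- sum((rx - 3) * (ry - mean(ry))) /
    sqrt(sum((rx - 3)^2) * sum((ry - mean(ry))^2))
  s <- spearman(x, y)
  expect_equal(s$rho, hand, tolerance = 1e-12)
  tval <- hand * sqrt(3 / (1 - hand^2))
  expect_equal(s$p, 2 * pt(-abs(tval), 3), tolerance = 1e-12)

  expect_equal(spearman(x, x^3)$rho, 1)      # monotone transform
  expect_equal(spearman(x, -x)$rho, -1)
  expect_equal(spearman(x, x^3)$p, 0)
  expect_warning(s0 <- spearman(x, rep(1, 5)), "constant")
  expect_true(is.na(s0$rho))
  expect_error(spearman(1:2, 2:1), "at least 3")

  # invariance under strictly monotone transforms of either argument
  set.seed(111)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman(a, b)$rho, spearman(exp(a), b)$rho)
  expect_equal(spearman(a, b)$rho, spearman(a, qlogis(plogis(b)))$rho,
               tolerance = 1e-12)
})

test_that("the redundancy filter reproduces the hand-derived eliminations", {
  # A=B exactly, C independent: exactly one of A/B removed
  set.seed(121)
  A <- rnorm(40); C <- rnorm(40)
  tab <- data.frame(A = A, B = A, C = C)
  kept <- correlation_filter(tab, 0.9)
  expect_length(intersect(kept, c("A", "B")), 1L)
  expect_true("C" %in% kept)
  # ties eliminate the lexicographically later name: B goes, A stays
  expect_equal(kept, c("A", "C"))

  # |r(A,B)|=0.95, |r(A,C)|=0.92, |r(B,C)|=0.1: A has the highest mean
  # absolute correlation and is removed first; then B,C survive
  R <- matrix(c(1, 0.95, 0.92,
                0.95, 1, 0.10,
                0.92, 0.10, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(correlation_filter_matrix(R, 0.9), c("B", "C"))

  # threshold 1 with no perfect pair: everything retained
  expect_equal(correlation_filter_matrix(R, 1), c("A", "B", "C"))
})

test_that("no retained pair exceeds the threshold on random tables", {
  set.seed(131)
  for (i in 1:20) {
    n <- 30
    k <- 50
    base <- matrix(rnorm(n * 5), n, 5)
    m <- base[, sample(5, k, replace = TRUE)] + matrix(rnorm(n * k, 0, 0.3), n, k)
    colnames(m) <- sprintf("v%02d", 1:k)
    kept <- correlation_filter(m, 0.9)
    expect_gt(length(kept), 0L)
    if (length(kept) >= 2) {
      R <- abs(cor(m[, kept], method = "spearman"))
      diag(R) <- 0
      expect_lte(max(R), 0.9)
    }
    # determinism
    expect_identical(kept, correlation_filter(m, 0.9))
  }
})

test_that("cross-modal correlation is exact on identical columns and calibrated on noise", {
  set.seed(141)
  n <- 200
  shared <- sprintf("P%03d", 1:n)
  pth <- data.frame(patient_id = shared, p1 = rnorm(n), p2 = rnorm(n))
  rad <- data.frame(patient_id = shared, r1 = pth$p1, r2 = rnorm(n),
                    r3 = rnorm(n))
  cc <- cross_correlation(pth, rad)
  expect_equal(cc$rho["p1", "r1"], 1)
  expect_equal(sum(cc$sign_counts$positive + cc$sign_counts$negative +
                   cc$sign_counts$zero), length(cc$rho))
  expect_true(all(abs(cc$rho) <= 1))
  expect_equal(cc$top_pairs$pathomics_feature[1], "p1")

  # independent noise: about 5% of |rho| beyond the 5% critical value
  p2 <- as.data.frame(matrix(rnorm(n * 30), n, 30))
  names(p2) <- sprintf("a%02d", 1:30)
  p2 <- cbind(data.frame(patient_id = shared), p2)
  r2 <- as.data.frame(matrix(rnorm(n * 30), n, 30))
  names(r2) <- sprintf("b%02d", 1:30)
  r2 <- cbind(data.frame(patient_id = shared), r2)
  cc2 <- cross_correlation(p2, r2)
  crit <- qnorm(0.975) / sqrt(n - 1)
  frac <- mean(abs(cc2$rho) > crit)
  expect_lt(abs(frac - 0.05), 0.03)

  expect_error(cross_correlation(pth[1:2, ], rad[1:2, ]), "3 shared")
})

test_that("endpoint correlation ranks a self-feature first and BH follows the step-up formula", {
  set.seed(151)
  n <- 40
  tab <- data.frame(patient_id = sprintf("P%02d", 1:n),
                    f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  ep <- tab$f2 + 0.001 * rnorm(n)
  res <- endpoint_correlation(tab, ep)
  expect_equal(res$feature[which.max(abs(res$rho))], "f2")
  expect_equal(res$feature[which.min(res$q)], "f2")
  expect_true(all(res$q >= res$p))

  # hand-computed BH on p = (.01,.02,.03,.5):
  # raw p*n/i = (.04,.04,.04,.5); monotone step-up leaves (.04,.04,.04,.5)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))

  # null cohort: essentially nothing significant after FDR
  null_tab <- cbind(data.frame(patient_id = sprintf("P%02d", 1:n)),
                    as.data.frame(matrix(rnorm(n * 50), n, 50)))
  res0 <- endpoint_correlation(null_tab, rnorm(n))
  expect_lte(mean(res0$q < 0.05), 0.02)
  expect_error(endpoint_correlation(tab, rep(NA_real_, n)), "missing")
})

test_that("KS comparison matches the ECDF sweep and its invariances", {
  r <- ks_compare(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))
  expect_equal(r$D, 1 / 3, tolerance = 1e-12)

  same <- ks_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  disjoint <- ks_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disjoint$D, 1)

  set.seed(161)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  x <- ks_compare(a, b); y <- ks_compare(b, a)
  expect_equal(x$D, y$D)
  expect_equal(x$p, y$p)
  # invariant under a common strictly monotone transform
  z <- ks_compare(exp(a), exp(b))
  expect_equal(x$D, z$D)
  # asymptotic p agrees with the standard implementation
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(x$D, unname(ref$statistic), tolerance = 1e-12)
  # both are asymptotic Kolmogorov evaluations; numerical schemes differ
  # slightly in the far decimals
  expect_equal(x$p, ref$p.value, tolerance = 1e-4)
  expect_error(ks_compare(1, c(1, 2)), "at least 2")
})
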