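test_that("co-occurrence matrices match brute-force pair enumeration", {
  offsets <- list(D1 = c(0L, 1L), D2 = c(1L, 0L),
                  D3 = c(-1L, 1L), D4 = c(1L, 1L))
  # the documented 2x2 example: [[0,1],[0,1]] horizontally
  lev <- matrix(c(0L, 0L, 1L, 1L), 2, 2)  # column-major: rows are (0,1),(0,1)
  g <- cooccurrence(lev, "D1", Ng = 2)
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  set.seed(51)
  for (i in 1:5) {
    lev <- matrix(sample(0:7, 12 * 12, replace = TRUE), 12, 12)
    for (d in names(offsets)) {
      got <- cooccurrence(lev, d, Ng = 8)$P
      want <- cooccurrence_bruteforce(lev, offsets[[d]], 8)
      expect_equal(got, want, tolerance = 1e-12)
      expect_equal(got, t(got))                    # symmetry
      expect_equal(sum(got), 1, tolerance = 1e-12) # total mass
      expect_true(all(got >= 0))
    }
  }

  # constant map: all mass on the diagonal cell
  gc <- cooccurrence(matrix(3L, 4, 4), "D2", Ng = 8)
  expect_equal(gc$P[4, 4], 1)
  expect_error(cooccurrence(matrix(0L, 1, 5), "D2", Ng = 2), "D2")
})

test_that("haralick matches the brute-force formulas on random GLCMs", {
  set.seed(61)
  worst <- 0
  for (i in 1:40) {
    P <- random_glcm(sample(4:10, 1))
    got <- haralick(P)
    want <- haralick_bruteforce(P)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-8)
})

test_that("haralick degenerate and textbook cases", {
  # constant map
  g <- cooccurrence(matrix(2L, 6, 6), "D1", Ng = 8)
  h <- haralick(g)
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["energy"]), 1)
  expect_equal(unname(h["entropy"]), 0)
  expect_equal(unname(h["correlation"]), 0)  # zero marginal SD guard

  # checkerboard: every horizontal pair differs by exactly 1
  cb <- (matrix(rep(0:7, each = 8), 8, 8) + matrix(rep(0:7, 8), 8, 8)) %% 2
  storage.mode(cb) <- "integer"
  hc <- haralick(cooccurrence(cb, "D1", Ng = 2))
  expect_equal(unname(hc["contrast"]), 1)

  expect_error(haralick(matrix(1, 4, 4)), "normalized")

  set.seed(71)
  for (i in 1:10) {
    h <- haralick(random_glcm(8))
    expect_true(h["energy"] > 0 && h["energy"] <= 1)
    expect_gte(h["entropy"], 0)
    expect_true(h["IMC2"] >= 0 && h["IMC2"] < 1)
  }
})

test_that("haralick and co-occurrence agree with scikit-image on shared statistics", {
  set.seed(81)
  lev <- matrix(sample(0:7, 24 * 24, replace = TRUE), 24, 24)
  ours <- list(
    D1 = haralick(cooccurrence(lev, "D1", Ng = 8)),
    D2 = haralick(cooccurrence(lev, "D2", Ng = 8))
  )
  csv <- tempfile(fileext = ".csv")
  write.table(lev, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from skimage.feature import graycomatrix, graycoprops",
    "lev = np.loadtxt(sys.argv[1], delimiter=',').astype(np.uint8)",
    "# angle 0 is horizontal, pi/2 vertical; symmetric+normed as in our GLCM",
    "g = graycomatrix(lev, [1], [0, np.pi/2], levels=8, symmetric=True, normed=True)",
    "for k in range(2):",
    "    P = g[:, :, 0, k]",
    "    print(graycoprops(g, 'contrast')[0, k],",
    "          graycoprops(g, 'ASM')[0, k],",
    "          graycoprops(g, 'correlation')[0, k],",
    "          graycoprops(g, 'homogeneity')[0, k])"
  ), py)
  out <- system2("python", c(py, csv), stdout = TRUE)
  ref <- do.call(rbind, lapply(strsplit(out, " +"), as.numeric))
  for (k in 1:2) {
    h <- ours[[k]]
    expect_equal(unname(h["contrast"]), ref[k, 1], tolerance = 1e-10)
    expect_equal(unname(h["energy"]), ref[k, 2], tolerance = 1e-10)
    expect_equal(unname(h["correlation"]), ref[k, 3], tolerance = 1e-10)
    expect_equal(unname(h["inverse_difference_moment"]), ref[k, 4],
                 tolerance = 1e-10)
  }
})

test_that("patch features count 156 with 52 per scale and transposition swaps D1/D2", {
  set.seed(91)
  tl <- generate_tile(60, 256)
  seg <- segment_nuclei(tl$image)
  dmaps <- lapply(c(S1 = 16, S2 = 32, S3 = 64),
                  function(s) density_map(seg, s))
  pf <- patch_features(dmaps)
  expect_length(pf, 156L)
  expect_false(any(duplicated(names(pf))))
  expect_equal(sum(grepl("_S1$", names(pf))), 52L)
  expect_equal(sum(grepl("_S2$", names(pf))), 52L)
  expect_equal(sum(grepl("_S3$", names(pf))), 52L)
  expect_error(patch_features(dmaps[c("S1", "S2")]), "S3")

  # transposing the density map swaps horizontal and vertical features
  lev <- dmaps$S1$levels
  h1 <- haralick(cooccurrence(lev, "D1", Ng = 8))
  h2 <- haralick(cooccurrence(t(lev), "D2", Ng = 8))
  expect_equal(h1, h2, tolerance = 1e-12)
  # and the diagonals map onto each other under transposition
  h3 <- haralick(cooccurrence(lev, "D3", Ng = 8))
  h4 <- haralick(cooccurrence(t(lev), "D3", Ng = 8))
  expect_equal(h3, h4, tolerance = 1e-12)

  # all-zero density maps give zero contrast everywhere
  zm <- matrix(0L, 32, 32)
  z <- haralick(cooccurrence(zm, "D1", Ng = 8))
  expect_equal(unname(z["contrast"]), 0)
})

test_that("slide aggregation yields 260 named attributes per scale", {
  schema <- enumerate_pathomics_schema()
  expect_equal(nrow(schema), 780L)
  expect_equal(sum(schema$scale == "S1"), 260L)
  expect_false(any(duplicated(schema$column)))
  expect_true("kurtosis_IMC1_D3" %in% schema$name)
  expect_true("var_sum_average_D1" %in% schema$name)
  expect_equal(nrow(enumerate_pathomics_schema("S2")), 260L)
  expect_error(enumerate_pathomics_schema("S9"), "unknown scale")

  set.seed(101)
  pf <- lapply(1:5, function(i) {
    tl <- generate_tile(40, 128)
    seg <- segment_nuclei(tl$image)
    patch_features(lapply(c(S1 = 16, S2 = 32, S3 = 64),
                          function(s) density_map(seg, s)))
  })
  agg <- aggregate_slide(do.call(rbind, pf))
  expect_length(agg, 780L)
  expect_identical(names(agg), schema$column)

  # identical patches: var 0, mean = median = the common value
  same <- aggregate_slide(rbind(pf[[1]], pf[[1]], pf[[1]], pf[[1]]))
  expect_true(all(abs(same[schema$column[schema$stat == "var"]]) < 1e-20))
  expect_equal(unname(same[paste0("mean_", schema$name[1], "_S1")]),
               unname(same[sub("mean_", "median_", paste0("mean_", schema$name[1], "_S1"))]))

  # single patch: mean = the value, higher moments undefined
  expect_warning(one <- aggregate_slide(pf[[1]]), "fewer than 4")
  expect_equal(unname(one["mean_energy_D1_S1"]), unname(pf[[1]]["energy_D1_S1"]))
  expect_true(all(is.na(one[schema$column[schema$stat == "kurtosis"]])))
  expect_error(aggregate_slide(matrix(numeric(0), 0, 156)), "excluded")
})

test_that("aggregation statistics follow the bias-adjusted sample conventions", {
  x <- c(1, 2, 4, 8, 16)
  m <- matrix(rep(x, 156), 5, 156)
  colnames(m) <- names(patch_features(lapply(c(S1 = 16, S2 = 32, S3 = 64),
    function(s) density_map(matrix(0L, 128, 128), s))))
  agg <- aggregate_slide(m)
  expect_equal(unname(agg["mean_energy_D1_S1"]), mean(x))
  expect_equal(unname(agg["var_energy_D1_S1"]), var(x))
  n <- 5
  g1 <- (sum((x - mean(x))^3) / n) / (sum((x - mean(x))^2) / n)^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  expect_equal(unname(agg["skewness_energy_D1_S1"]), G1)
  g2 <- (sum((x - mean(x))^4) / n) / (sum((x - mean(x))^2) / n)^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  expect_equal(unname(agg["kurtosis_energy_D1_S1"]), G2)
})
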