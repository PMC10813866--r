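# Independent brute-force oracles, written straight from the defining
# formulas with explicit loops; deliberately kept separate from the
# package's vectorized implementations.

# The 13 classic Haralick statistics from a normalized symmetric GLCM,
# levels indexed 0..Ng-1, log base 2, 0*log(0) = 0.
haralick_bruteforce <- function(P) {
  Ng <- nrow(P)
  lg <- function(p) if (p > 0) log2(p) else 0
  px <- numeric(Ng); py <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mu_x <- 0; mu_y <- 0
  for (i in 1:Ng) { mu_x <- mu_x + (i - 1) * px[i]; mu_y <- mu_y + (i - 1) * py[i] }
  sd_x <- 0; sd_y <- 0
  for (i in 1:Ng) {
    sd_x <- sd_x + (i - 1 - mu_x)^2 * px[i]
    sd_y <- sd_y + (i - 1 - mu_y)^2 * py[i]
  }
  sd_x <- sqrt(sd_x); sd_y <- sqrt(sd_y)
  p_sum <- numeric(2 * Ng - 1)   # k = 0 .. 2(Ng-1)
  p_diff <- numeric(Ng)          # k = 0 .. Ng-1
  for (i in 1:Ng) for (j in 1:Ng) {
    p_sum[(i - 1) + (j - 1) + 1] <- p_sum[(i - 1) + (j - 1) + 1] + P[i, j]
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + P[i, j]
  }
  energy <- 0; entropy <- 0; variance <- 0; idm <- 0; corr_num <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    energy <- energy + P[i, j]^2
    entropy <- entropy - P[i, j] * lg(P[i, j])
    variance <- variance + (i - 1 - mu_x)^2 * P[i, j]
    idm <- idm + P[i, j] / (1 + ((i - 1) - (j - 1))^2)
    corr_num <- corr_num + (i - 1) * (j - 1) * P[i, j]
  }
  correlation <- if (sd_x > 0 && sd_y > 0)
    (corr_num - mu_x * mu_y) / (sd_x * sd_y) else 0
  contrast <- 0; mu_d <- 0; diff_ent <- 0
  for (k in 0:(Ng - 1)) {
    contrast <- contrast + k^2 * p_diff[k + 1]
    mu_d <- mu_d + k * p_diff[k + 1]
    diff_ent <- diff_ent - p_diff[k + 1] * lg(p_diff[k + 1])
  }
  diff_var <- 0
  for (k in 0:(Ng - 1)) diff_var <- diff_var + (k - mu_d)^2 * p_diff[k + 1]
  sum_avg <- 0; sum_ent <- 0
  for (k in 0:(2 * Ng - 2)) {
    sum_avg <- sum_avg + k * p_sum[k + 1]
    sum_ent <- sum_ent - p_sum[k + 1] * lg(p_sum[k + 1])
  }
  sum_var <- 0
  for (k in 0:(2 * Ng - 2)) sum_var <- sum_var + (k - sum_avg)^2 * p_sum[k + 1]
  hx <- 0; hy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) hx <- hx - px[i] * lg(px[i])
  for (j in 1:Ng) hy <- hy - py[j] * lg(py[j])
  for (i in 1:Ng) for (j in 1:Ng) {
    hxy1 <- hxy1 - P[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(energy = energy, contrast = contrast, correlation = correlation,
    variance = variance, inverse_difference_moment = idm,
    sum_average = sum_avg, sum_variance = sum_var, sum_entropy = sum_ent,
    entropy = entropy, difference_variance = diff_var,
    difference_entropy = diff_ent, IMC1 = imc1, IMC2 = imc2)
}

# Random normalized symmetric GLCM.
random_glcm <- function(Ng = 8) {
  m <- matrix(stats::rexp(Ng * Ng), Ng, Ng)
  m <- m + t(m)
  m / sum(m)
}

# Brute-force co-occurrence by pair enumeration.
cooccurrence_bruteforce <- function(lev, offset, Ng) {
  counts <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(lev))) for (cc in seq_len(ncol(lev))) {
    r2 <- r + offset[1]; c2 <- cc + offset[2]
    if (r2 >= 1 && r2 <= nrow(lev) && c2 >= 1 && c2 <= ncol(lev)) {
      counts[lev[r, cc] + 1, lev[r2, c2] + 1] <-
        counts[lev[r, cc] + 1, lev[r2, c2] + 1] + 1
      counts[lev[r2, c2] + 1, lev[r, cc] + 1] <-
        counts[lev[r2, c2] + 1, lev[r, cc] + 1] + 1
    }
  }
  counts / sum(counts)
}

# RGB image of dark disks/ellipses on a pale background (no noise):
# centers is a matrix with columns row, col, a, b (semi-axes, axis-aligned).
draw_nuclei_image <- function(size, centers,
                              bg = c(240, 220, 225), fg = c(90, 60, 120)) {
  img <- array(0L, dim = c(size, size, 3))
  mask <- matrix(FALSE, size, size)
  for (k in seq_len(nrow(centers))) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    a <- centers[k, 3]; b <- centers[k, 4]
    for (r in max(1, floor(cy - b)):min(size, ceiling(cy + b)))
      for (cc in max(1, floor(cx - a)):min(size, ceiling(cx + a)))
        if (((cc - cx) / a)^2 + ((r - cy) / b)^2 <= 1) mask[r, cc] <- TRUE
  }
  for (ch in 1:3) {
    plane <- matrix(bg[ch], size, size)
    plane[mask] <- fg[ch]
    img[, , ch] <- plane
  }
  storage.mode(img) <- "integer"
  list(image = img, mask = mask)
}

# Small seeded cohort spec kept cheap for unit tests.
tiny_cohort_spec <- function(seed = 11, ...) {
  synthetic_cohort_spec(n_patients = 4, n_tiles_per_patient = 2,
                        tile_size = 128, nuclei_rate_base = 24,
                        nucleus_radius_range = c(5, 8),
                        n_radiomics_features = 12, seed = seed, ...)
}
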