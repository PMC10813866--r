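#' Z-score normalize a feature table
#'
#' Centers each numeric column to mean 0 and scales to sample SD 1
#' (n-1 denominator). Zero-variance columns cannot be scaled and are
#' dropped with a warning. A `patient_id` column, if present, is carried
#' through untouched.
#'
#' @param table data.frame or numeric matrix.
#' @return table of the same type with normalized columns.
#' @export
zscore <- function(table) {
  is_df <- is.data.frame(table)
  id <- NULL
  if (is_df && "patient_id" %in% names(table)) {
    id <- table$patient_id
    table <- table[, setdiff(names(table), "patient_id"), drop = FALSE]
  }
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("z-score normalization needs at least 2 rows")
  sds <- apply(m, 2, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(m)[zero], collapse = ", "))
    m <- m[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  m <- scale(m, center = TRUE, scale = sds)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  if (is_df) {
    out <- as.data.frame(m)
    if (!is.null(id)) out <- cbind(data.frame(patient_id = id,
                                              stringsAsFactors = FALSE), out)
    out
  } else m
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of average (midrank) ranks; the two-sided p-value
#' uses the usual t approximation with n-2 degrees of freedom. Missing
#' values are removed pairwise. A constant vector has undefined rank
#' correlation and yields NA with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return list with `rho`, `p`, `n` (complete pairs used).
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Iterative Spearman redundancy filter
#'
#' Removes mutually redundant features: while any pair of retained columns
#' has absolute Spearman correlation above the threshold, the currently
#' strongest such pair is examined and the member with the higher mean
#' absolute correlation against all currently retained columns is
#' eliminated; mean correlations are recomputed over the survivors after
#' each elimination. The iteration order is fixed for determinism: the
#' largest |r| pair is processed first, ties broken by lexicographic
#' column-name order, and an elimination tie drops the lexicographically
#' later name.
#'
#' @param table data.frame or matrix of features (a `patient_id` column is
#'   ignored); alternatively supply a precomputed correlation matrix via
#'   [correlation_filter_matrix()].
#' @param threshold absolute correlation threshold in (0, 1\] (default 0.9).
#' @return character vector of retained column names, in original order.
#' @export
correlation_filter <- function(table, threshold = 0.9) {
  if (is.data.frame(table))
    table <- table[, setdiff(names(table), "patient_id"), drop = FALSE]
  m <- as.matrix(table)
  if (ncol(m) < 2L) return(colnames(m))
  R <- stats::cor(m, method = "spearman")
  correlation_filter_matrix(R, threshold)
}

#' Redundancy filter on a precomputed correlation matrix
#'
#' @param R square correlation matrix with dimnames.
#' @param threshold absolute correlation threshold in (0, 1\].
#' @return retained column names, in the matrix's column order.
#' @rdname correlation_filter
#' @export
correlation_filter_matrix <- function(R, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1, nrow(R) == ncol(R))
  nm <- colnames(R)
  stopifnot(!is.null(nm))
  A <- abs(R)
  diag(A) <- 0
  keep <- rep(TRUE, ncol(A))
  repeat {
    S <- A[keep, keep, drop = FALSE]
    if (all(S <= threshold | is.na(S))) break
    # strongest offending pair; lexicographic tie-break on the name pair
    mx <- max(S, na.rm = TRUE)
    hits <- which(S == mx, arr.ind = TRUE)
    pairs <- t(apply(hits, 1, function(ij) sort(rownames(S)[ij])))
    pairs <- unique(pairs)
    ord <- order(pairs[, 1], pairs[, 2])
    pair <- pairs[ord[1], ]
    means <- rowMeans(S, na.rm = TRUE)
    m1 <- means[pair[1]]; m2 <- means[pair[2]]
    drop_name <- if (m1 > m2) pair[1]
                 else if (m2 > m1) pair[2]
                 else max(pair)  # tie: lexicographically later name
    keep[match(drop_name, nm)] <- FALSE
  }
  nm[keep]
}

#' Cross-modal correlation of pathomics and radiomics features
#'
#' Spearman correlation for every (pathomics, radiomics) feature pair over
#' the patients shared by both tables (inner join on `patient_id`;
#' mismatches are reported in the result). Sign counts and percentages are
#' reported per pathomics scale when a schema maps pathomics columns to
#' scales, and the strongest pairs (|rho| above `report_threshold`) are
#' tabulated with names, rho and scale.
#'
#' @param pathomics,radiomics data.frames with `patient_id` + numeric
#'   feature columns.
#' @param schema optional pathomics schema (as from
#'   [enumerate_pathomics_schema()]) mapping `column` to `scale_px`;
#'   columns not covered are grouped as scale NA.
#' @param report_threshold |rho| cutoff for the top-pair table (default 0.5).
#' @return An object of class `cross_correlation`: list with `rho`
#'   (pathomics x radiomics matrix), `p` (matching p-values),
#'   `sign_counts` (per scale: positive/negative/zero counts and
#'   percentages and the rho range), `top_pairs` (data.frame), and
#'   `patients` (ids used).
#' @export
cross_correlation <- function(pathomics, radiomics, schema = NULL,
                              report_threshold = 0.5) {
  shared <- intersect(pathomics$patient_id, radiomics$patient_id)
  if (length(shared) < 3L) stop("fewer than 3 shared patients")
  P <- as.matrix(pathomics[match(shared, pathomics$patient_id),
                           setdiff(names(pathomics), "patient_id"),
                           drop = FALSE])
  R <- as.matrix(radiomics[match(shared, radiomics$patient_id),
                           setdiff(names(radiomics), "patient_id"),
                           drop = FALSE])
  n <- length(shared)
  rho <- stats::cor(P, R, method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  pmat <- 2 * stats::pt(-abs(tstat), n - 2)
  pmat[abs(rho) >= 1] <- 0

  scale_of <- rep(NA_integer_, nrow(rho))
  if (!is.null(schema))
    scale_of <- schema$scale_px[match(rownames(rho), schema$column)]
  grp <- ifelse(is.na(scale_of), "all", as.character(scale_of))
  groups <- split(seq_len(nrow(rho)), grp)
  sign_counts <- do.call(rbind, lapply(names(groups), function(g) {
    r <- rho[groups[[g]], , drop = FALSE]
    r <- r[!is.na(r)]
    if (!length(r))
      return(data.frame(scale_px = g, n_pairs = 0L, positive = 0L,
                        negative = 0L, zero = 0L, pct_positive = NA_real_,
                        pct_negative = NA_real_, rho_min = NA_real_,
                        rho_max = NA_real_, stringsAsFactors = FALSE))
    data.frame(scale_px = g, n_pairs = length(r),
               positive = sum(r > 0), negative = sum(r < 0),
               zero = sum(r == 0),
               pct_positive = 100 * mean(r > 0),
               pct_negative = 100 * mean(r < 0),
               rho_min = min(r), rho_max = max(r),
               stringsAsFactors = FALSE)
  }))
  hits <- which(abs(rho) > report_threshold, arr.ind = TRUE)
  top <- data.frame(
    radiomics_feature = colnames(rho)[hits[, 2]],
    pathomics_feature = rownames(rho)[hits[, 1]],
    rho = rho[hits],
    scale_px = scale_of[hits[, 1]],
    stringsAsFactors = FALSE)
  top <- top[order(-abs(top$rho)), ]
  rownames(top) <- NULL
  structure(list(rho = rho, p = pmat, sign_counts = sign_counts,
                 top_pairs = top, patients = shared),
            class = "cross_correlation")
}

#' Correlate features with a clinical endpoint
#'
#' Per-feature Spearman correlation against one endpoint (e.g. OS months,
#' PFS months, or CD8 %), with Benjamini-Hochberg q-values and sign
#' counts. Missing endpoint values are handled pairwise-complete with the
#' per-feature n recorded.
#'
#' @param features data.frame with `patient_id` + numeric feature columns.
#' @param endpoint numeric vector aligned to `features` rows, or a named
#'   vector keyed by patient id.
#' @return An object of class `endpoint_correlation`: data.frame with
#'   `feature`, `rho`, `p`, `q`, `n`, plus attributes `n_positive` and
#'   `n_negative`.
#' @export
endpoint_correlation <- function(features, endpoint) {
  cols <- setdiff(names(features), "patient_id")
  if (!is.null(names(endpoint)) && "patient_id" %in% names(features))
    endpoint <- endpoint[features$patient_id]
  if (all(is.na(endpoint))) stop("endpoint is entirely missing")
  res <- lapply(cols, function(cn) {
    s <- suppressWarnings(spearman(features[[cn]], endpoint))
    data.frame(feature = cn, rho = s$rho, p = s$p, n = s$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[, c("feature", "rho", "p", "q", "n")]
  structure(res, class = c("endpoint_correlation", "data.frame"),
            n_positive = sum(res$rho > 0, na.rm = TRUE),
            n_negative = sum(res$rho < 0, na.rm = TRUE))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum gap between the two empirical CDFs; the two-sided
#' p-value uses the asymptotic Kolmogorov distribution evaluated at
#' sqrt(n1 n2 / (n1 + n2)) * D, the standard two-sample effective size.
#'
#' @param a,b numeric samples (each of size >= 2; NAs dropped).
#' @return An object of class `ks_result`: list with `D`, `p`, `n1`, `n2`.
#' @export
ks_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples must have at least 2 non-missing values")
  n1 <- length(a); n2 <- length(b)
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(grid, function(t) mean(b <= t), numeric(1))
  D <- max(abs(Fa - Fb))
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * D
  # Kolmogorov CDF: theta-series for small arguments, alternating series
  # otherwise (the two agree to ~1e-7 at the switch point)
  cdf <- if (lambda <= 0) 0
         else if (lambda < 1) {
    v <- (2 * (1:20) - 1)^2 * pi^2 / (8 * lambda^2)
    sqrt(2 * pi) / lambda * sum(exp(-v))
  } else {
    k <- 1:100
    1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  p <- min(1, max(0, 1 - cdf))
  structure(list(D = D, p = p, n1 = n1, n2 = n2), class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4g, p = %.4g (n = %d, %d)\n",
              x$D, x$p, x$n1, x$n2))
  invisible(x)
}
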