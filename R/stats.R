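# The statistical battery: D'Agostino-Pearson normality screen,
# Mann-Whitney group comparisons at ROI-level n, PCA fingerprints with
# per-PC Welch tests, cross-stain Pearson correlation heatmaps with
# significance counting, and simple linear regression for lesion volume.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness and kurtosis Z transforms (D'Agostino 1970;
#' Anscombe & Glynn 1983) into the K-squared statistic, chi-squared with 2
#' degrees of freedom under normality. Used to annotate parameters; group
#' comparisons default to the rank-based Mann-Whitney test regardless.
#'
#' @param x numeric vector, n >= 8.
#' @return tibble with `statistic` (K squared) and `p`.
#' @export
normality_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("insufficient n for omnibus test (need n >= 8)",
                  call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 <= 0) stop("zero variance", call. = FALSE)
  b1 <- m3 / m2^1.5
  # skewness transform (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  tibble::tibble(statistic = k2, p = stats::pchisq(k2, 2, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' `U` counts, over all cross-group pairs, the wins for group `a` (+1/2 per
#' tie). The two-sided p-value is computed by exact enumeration of all
#' `choose(n1 + n2, n1)` group labelings when that count is at most
#' `exact_limit` (ties handled exactly); otherwise by normal approximation
#' with tie-corrected variance and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_limit maximum number of labelings to enumerate
#'   (default 20000).
#' @return tibble with `U`, `p`, `method` ("exact" or "normal"), `n1`, `n2`.
#' @export
mann_whitney <- function(a, b, exact_limit = 20000) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("empty group", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n_lab <- choose(n1 + n2, n1)
  if (n_lab <= exact_limit) {
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    v <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    z <- (abs(u_obs - mu) - 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal"
  }
  tibble::tibble(U = u_obs, p = p, method = method, n1 = n1, n2 = n2)
}

#' Welch's unpaired two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided.
#' Degenerate inputs (zero variance in both groups) use the documented
#' convention: equal means give p = 1; unequal means give p = 0 with a
#' warning.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return tibble with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = NA_real_, p = 1))
    }
    warning("zero variance in both groups with unequal means")
    return(tibble::tibble(t = sign(mean(a) - mean(b)) * Inf,
                          df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Mann-Whitney comparison battery over stains, regions and parameters
#'
#' Runs [mann_whitney()] on the pooled ROI-level vectors of every requested
#' stain x region x parameter stratum, reporting group medians alongside.
#'
#' @param records ROI records from [assign_regions()].
#' @param stains,regions strata to compare (defaults: all stains present;
#'   hemispheric + perilesional).
#' @param parameters parameters to compare (default all 19).
#' @param alpha significance level for the `significant` flag (default
#'   0.05, uncorrected as in per-parameter reporting; see `adjust`).
#' @param adjust optional p-adjustment method passed to [stats::p.adjust()]
#'   (e.g. `"BH"`); `"none"` (default) reports raw p-values.
#' @return tibble with one row per comparison: `stain`, `region`,
#'   `parameter`, `n_NS`, `n_S`, `median_NS`, `median_S`, `U`, `p`,
#'   `method`, `significant`.
#' @export
compare_groups <- function(records, stains = NULL,
                           regions = c("hemispheric", "perilesional"),
                           parameters = morph_parameters(),
                           alpha = 0.05, adjust = "none") {
  if (is.null(stains)) stains <- unique(records$stain)
  combos <- expand.grid(stain = stains, region = regions,
                        parameter = parameters, stringsAsFactors = FALSE)
  rows <- purrr::pmap(combos, function(stain, region, parameter) {
    va <- pool_parameter(records, stain, region, parameter, "NS")
    vb <- pool_parameter(records, stain, region, parameter, "S")
    if (length(va) == 0L || length(vb) == 0L) return(NULL)
    mw <- mann_whitney(va, vb)
    tibble::tibble(stain = stain, region = region, parameter = parameter,
                   n_NS = length(va), n_S = length(vb),
                   median_NS = stats::median(va), median_S = stats::median(vb),
                   U = mw$U, p = mw$p, method = mw$method)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p_adj < alpha
  out
}

#' PCA morphological fingerprint with per-PC Welch tests
#'
#' Standardizes each parameter to zero mean and unit variance pooled over
#' both groups (mixed pixel and unitless scales make unscaled PCA
#' degenerate), drops ROIs with missing descriptor means and zero-variance
#' columns (with a warning), and fits principal components by SVD. Loading
#' signs follow the convention that each loading's largest-magnitude
#' component is positive. Group differences on the first `n_pc` score
#' vectors are tested with [welch_t()].
#'
#' @param x tibble or matrix of ROI-by-parameter values.
#' @param groups factor/character vector of group labels (two levels).
#' @param n_pc number of leading PCs to test (default 3).
#' @return object of class `morph_pca`: standardization (`center`,
#'   `scale`), `loadings`, `ev` (per-component variances, summing to the
#'   number of retained standardized columns), `ev_frac`
#'   (explained-variance fractions),
#'   `scores` tibble with group, `welch` tibble for PC1..n_pc, and the
#'   numbers of dropped rows/columns.
#' @export
pca_fit <- function(x, groups, n_pc = 3) {
  xm <- as.matrix(as.data.frame(x))
  storage.mode(xm) <- "double"
  stopifnot(nrow(xm) == length(groups))
  complete <- stats::complete.cases(xm)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " ROIs with missing descriptor means dropped")
  }
  xm <- xm[complete, , drop = FALSE]
  groups <- groups[complete]
  if (nrow(xm) < 2) stop("need at least 2 complete rows", call. = FALSE)
  sds <- apply(xm, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(xm)[sds == 0], collapse = ", "))
    xm <- xm[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(xm, center = TRUE, scale. = TRUE)
  # sign convention: largest-magnitude loading component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  n_pc <- min(n_pc, ncol(pc$x))
  glev <- unique(as.character(groups))
  welch <- dplyr::bind_rows(lapply(seq_len(n_pc), function(j) {
    w <- welch_t(pc$x[groups == glev[1], j], pc$x[groups == glev[2], j])
    dplyr::bind_cols(tibble::tibble(component = paste0("PC", j)), w)
  }))
  scores <- tibble::as_tibble(pc$x)
  scores$group <- as.character(groups)
  structure(list(center = pc$center, scale = pc$scale,
                 loadings = pc$rotation, ev = ev, ev_frac = ev / sum(ev),
                 scores = scores, welch = welch, n_pc = n_pc,
                 n_dropped_rows = n_dropped,
                 dropped_cols = names(sds)[sds == 0]),
            class = "morph_pca")
}

#' @export
print.morph_pca <- function(x, ...) {
  cat("<morph_pca> ", nrow(x$scores), " ROIs x ", nrow(x$loadings),
      " parameters\n", sep = "")
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$ev_frac[seq_len(x$n_pc)]),
             collapse = ", "), "\n")
  print(x$welch)
  invisible(x)
}

#' Cross-stain correlation heatmap for one region
#'
#' Pearson correlation (two-sided p from the t distribution with n - 2
#' degrees of freedom) between every parameter of stain A and every
#' parameter of stain B across per-animal means, using pairwise-complete
#' animals per cell. Cells with fewer than 3 complete animals are flagged
#' not computable and excluded from the significant-cell count and its
#' denominator. Spearman rank correlation is available behind `method`.
#'
#' @param mat_a,mat_b per-animal matrices from [per_animal_matrix()]
#'   (same animals, one stain each).
#' @param stains length-2 character vector naming the pair.
#' @param region region label carried through to the output.
#' @param alpha significance level (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return object of class `morph_cormat` with 19 x 19 matrices `r`, `p`,
#'   `n`, the `sig_count` and `n_computable`.
#' @export
correlation_heatmaps <- function(mat_a, mat_b, stains = c("A", "B"),
                                 region = "hemispheric", alpha = 0.05,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pars <- morph_parameters()
  joined <- dplyr::inner_join(mat_a, mat_b, by = "animal",
                              suffix = c("_a", "_b"))
  if (nrow(joined) < 3) stop("need at least 3 animals", call. = FALSE)
  k <- length(pars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(pars, pars))
  nmat <- matrix(0L, k, k, dimnames = list(pars, pars))
  for (i in seq_len(k)) {
    xa <- joined[[paste0(pars[i], "_a")]]
    for (j in seq_len(k)) {
      yb <- joined[[paste0(pars[j], "_b")]]
      ok <- !is.na(xa) & !is.na(yb)
      nmat[i, j] <- sum(ok)
      if (sum(ok) >= 3 && stats::sd(xa[ok]) > 0 && stats::sd(yb[ok]) > 0) {
        ct <- stats::cor.test(xa[ok], yb[ok], method = method, exact = FALSE)
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  computable <- !is.na(p)
  structure(list(stains = stains, region = region, method = method,
                 alpha = alpha, r = r, p = p, n = nmat,
                 sig_count = sum(p < alpha, na.rm = TRUE),
                 n_computable = sum(computable)),
            class = "morph_cormat")
}

#' @export
print.morph_cormat <- function(x, ...) {
  cat("<morph_cormat> ", x$stains[1], " vs ", x$stains[2], " (", x$region,
      ", ", x$method, ")\n", sep = "")
  cat(x$sig_count, "of", x$n_computable, "cells significant at alpha =",
      x$alpha, "\n")
  invisible(x)
}

#' Count significant correlation cells across heatmaps
#'
#' @param cormats list of `morph_cormat` objects.
#' @param alpha significance level (default: each matrix's own).
#' @return tibble with one row per matrix (stain pair, region, count,
#'   denominator) plus a `total` attribute-free summary row.
#' @export
count_significant <- function(cormats, alpha = NULL) {
  rows <- dplyr::bind_rows(lapply(cormats, function(cm) {
    a <- if (is.null(alpha)) cm$alpha else alpha
    tibble::tibble(stain_a = cm$stains[1], stain_b = cm$stains[2],
                   region = cm$region,
                   n_significant = sum(cm$p < a, na.rm = TRUE),
                   n_computable = cm$n_computable)
  }))
  dplyr::bind_rows(rows, tibble::tibble(
    stain_a = "all", stain_b = "all", region = "all",
    n_significant = sum(rows$n_significant),
    n_computable = sum(rows$n_computable)))
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()]; the p-value is
#' the F test on the slope. Used for lesion volume against per-animal
#' whole-section area occupied per stain.
#'
#' @param x,y numeric vectors, n >= 3, `x` with nonzero variance.
#' @return tibble with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
simple_linreg <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # perfect fits handled below
  p <- if (nrow(sm$coefficients) < 2 || sm$sigma == 0) {
    if (sm$r.squared >= 1 - 1e-12) 0 else NA_real_
  } else {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  }
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared, p = p, n = length(x))
}
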