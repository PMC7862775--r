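# The statistical battery.

test_that("the omnibus normality test matches an external reference", {
  # fixtures with reference K2/p frozen from an independent implementation
  set.seed(101); x1 <- round(rnorm(50), 6)
  r1 <- normality_test(x1)
  expect_equal(r1$statistic, 3.53339619, tolerance = 1e-8)
  expect_equal(r1$p, 0.1708963417, tolerance = 1e-8)
  set.seed(202); x2 <- round(rexp(40), 6)
  r2 <- normality_test(x2)
  expect_equal(r2$statistic, 8.668432744, tolerance = 1e-8)
  expect_equal(r2$p, 0.01311214509, tolerance = 1e-8)
  r3 <- normality_test(c(1, 2, 3, 4, 5, 6, 7, 8.5))
  expect_equal(r3$statistic, 0.3935729275, tolerance = 1e-8)
  expect_error(normality_test(1:5), "insufficient n")
})

test_that("the normality screen separates normal from skewed data", {
  set.seed(11)
  expect_gt(normality_test(rnorm(5000))$p, 0.01)
  expect_lt(normality_test(rexp(5000))$p, 0.001)
})

test_that("Mann-Whitney exact p comes from full enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$method, "exact")
  # identical multisets are maximally non-significant
  expect_equal(mann_whitney(c(5, 5, 7), c(5, 7, 5))$p, 1)
  # spot agreement with the direct pairwise-win enumeration oracle
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:30, sample(3:6, 1)); b <- sample(1:30, sample(3:6, 1))
    o <- oracle_mw_exact(a, b)
    r <- mann_whitney(a, b)
    expect_equal(r$U, o$U)
    expect_equal(r$p, o$p, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty group")
})

test_that("ties are handled exactly in enumeration and corrected in the approximation", {
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  o <- oracle_mw_exact(a, b)
  r <- mann_whitney(a, b)
  expect_equal(r$U, o$U)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  # large-sample path agrees with the reference implementation
  set.seed(13)
  a2 <- rnorm(20); b2 <- rnorm(20) + 0.5
  r2 <- mann_whitney(a2, b2)
  expect_equal(r2$method, "normal")
  ref <- stats::wilcox.test(a2, b2, correct = TRUE, exact = FALSE)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-10)
})

test_that("Welch's t matches the closed form and degenerate conventions", {
  r <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -sqrt(1.5), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(-sqrt(1.5), 4), tolerance = 1e-12)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_warning(z <- welch_t(c(2, 2), c(3, 3)), "zero variance")
  expect_equal(z$p, 0)
})

test_that("PCA recovers a known covariance direction and conserves variance", {
  set.seed(14)
  n <- 10000
  z1 <- rnorm(n); z2 <- rnorm(n)
  # covariance [[2,1],[1,2]] has leading eigenvector (1,1)/sqrt(2)
  x <- cbind(a = sqrt(1.5) * z1 + sqrt(0.5) * z2,
             b = sqrt(1.5) * z1 - sqrt(0.5) * z2)
  fit <- pca_fit(tibble::as_tibble(x), rep(c("NS", "S"), each = n / 2),
                 n_pc = 2)
  ang <- acos(min(1, abs(sum(fit$loadings[, 1] * c(1, 1) / sqrt(2))))) * 180 / pi
  expect_lt(ang, 2)
  expect_equal(sum(fit$ev_frac), 1, tolerance = 1e-8)
  expect_equal(crossprod(fit$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA standardized reconstruction is exact and signs are canonical", {
  set.seed(15)
  x <- matrix(rnorm(40 * 6), 40)
  colnames(x) <- paste0("p", 1:6)
  fit <- pca_fit(x, rep(c("NS", "S"), 20), n_pc = 3)
  xs <- scale(x, center = fit$center, scale = fit$scale)
  scores <- as.matrix(fit$scores[, colnames(fit$loadings)])
  rec <- scores %*% t(fit$loadings)
  expect_lt(max(abs(rec - xs)), 1e-8)
  for (j in seq_len(ncol(fit$loadings))) {
    i <- which.max(abs(fit$loadings[, j]))
    expect_gt(fit$loadings[i, j], 0)
  }
  # non-increasing explained variance
  expect_true(all(diff(fit$ev_frac) <= 1e-12))
})

test_that("PCA drops incomplete rows and zero-variance columns with notice", {
  set.seed(16)
  x <- matrix(rnorm(30 * 4), 30)
  colnames(x) <- paste0("p", 1:4)
  x[3, 2] <- NA
  x[, 4] <- 5
  expect_warning(
    expect_message(fit <- pca_fit(x, rep(c("NS", "S"), 15)), "dropped"),
    "zero-variance")
  expect_equal(fit$n_dropped_rows, 1L)
  expect_equal(fit$dropped_cols, "p4")
})

test_that("a planted group shift separates PC scores", {
  set.seed(17)
  x <- matrix(rnorm(400 * 5), 400)
  colnames(x) <- paste0("p", 1:5)
  grp <- rep(c("NS", "S"), each = 200)
  x[grp == "S", 1] <- x[grp == "S", 1] + 3
  fit <- pca_fit(x, grp)
  expect_lt(min(fit$welch$p), 1e-6)
})

test_that("correlation heatmaps match a hand-computed Pearson oracle", {
  # fixed 5-animal toy: r and p from the closed-form t transform
  pars <- morph_parameters()
  set.seed(18)
  base <- tibble::tibble(animal = paste0("A", 1:5), group = "S")
  ma <- mb <- base
  for (p in pars) { ma[[p]] <- rnorm(5); mb[[p]] <- rnorm(5) }
  cm <- correlation_heatmaps(ma, mb, stains = c("X", "Y"))
  for (i in c(1, 7, 19)) for (j in c(2, 11)) {
    x <- ma[[pars[i]]]; y <- mb[[pars[j]]]
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
    p_hand <- 2 * stats::pt(-abs(t_hand), 3)
    expect_equal(cm$r[i, j], r_hand, tolerance = 1e-9)
    expect_equal(cm$p[i, j], p_hand, tolerance = 1e-9)
  }
  expect_equal(cm$n_computable, 361L)
  # perfect linear relation
  mb2 <- mb; mb2[[pars[1]]] <- 2 * ma[[pars[1]]]
  cm2 <- correlation_heatmaps(ma, mb2, stains = c("X", "Y"))
  expect_equal(cm2$r[1, 1], 1, tolerance = 1e-9)
  expect_lt(cm2$p[1, 1], 1e-12)
  expect_error(correlation_heatmaps(ma[1:2, ], mb[1:2, ]), "at least 3")
})

test_that("cells with insufficient pairwise-complete animals are excluded", {
  pars <- morph_parameters()
  set.seed(19)
  ma <- mb <- tibble::tibble(animal = paste0("A", 1:4), group = "S")
  for (p in pars) { ma[[p]] <- rnorm(4); mb[[p]] <- rnorm(4) }
  ma[[pars[1]]][1:2] <- NA                      # only 2 complete animals
  cm <- correlation_heatmaps(ma, mb)
  expect_true(all(is.na(cm$p[1, ])))
  expect_equal(cm$n_computable, 361L - 19L)
  cs <- count_significant(list(cm))
  expect_equal(cs$n_computable[1], 342L)
})

test_that("count_significant sums counts and denominators", {
  pars <- morph_parameters()
  set.seed(20)
  mk <- function() {
    m <- tibble::tibble(animal = paste0("A", 1:5), group = "S")
    for (p in pars) m[[p]] <- rnorm(5)
    m
  }
  cms <- list(correlation_heatmaps(mk(), mk(), stains = c("A", "B")),
              correlation_heatmaps(mk(), mk(), stains = c("A", "C"),
                                   region = "perilesional"))
  cs <- count_significant(cms)
  expect_equal(nrow(cs), 3)
  expect_equal(cs$n_computable[3], 722L)
  expect_equal(cs$n_significant[3], sum(cs$n_significant[1:2]))
  # all p = 1 gives zero significant
  cm0 <- cms[[1]]; cm0$p[] <- 1
  expect_equal(count_significant(list(cm0))$n_significant[1], 0L)
})

test_that("simple linear regression matches the normal equations", {
  r <- simple_linreg(1:5, 3 * (1:5) - 1)
  expect_equal(r$slope, 3, tolerance = 1e-12)
  expect_equal(r$intercept, -1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  set.seed(21)
  x <- c(1.2, 2.5, 3.1, 4.8, 5.5, 7.2); y <- rnorm(6, 2 * x + 1)
  r2 <- simple_linreg(x, y)
  # normal-equation oracle
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  expect_equal(r2$slope, sl, tolerance = 1e-9)
  expect_equal(r2$intercept, ic, tolerance = 1e-9)
  ss_res <- sum((y - ic - sl * x)^2); ss_tot <- sum((y - mean(y))^2)
  expect_equal(r2$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-9)
  f <- (ss_tot - ss_res) / (ss_res / 4)
  expect_equal(r2$p, stats::pf(f, 1, 4, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_error(simple_linreg(rep(2, 5), rnorm(5)), "zero variance")
  expect_error(simple_linreg(1:2, 1:2), "n >= 3")
})

test_that("tidy and glance methods return well-formed tibbles", {
  set.seed(22)
  x <- matrix(rnorm(60 * 5), 60); colnames(x) <- paste0("p", 1:5)
  fit <- pca_fit(x, rep(c("NS", "S"), 30))
  td <- tidy(fit)
  expect_equal(nrow(td), 25)
  expect_named(td, c("parameter", "component", "loading"))
  gl <- glance(fit)
  expect_equal(gl$n_roi, 60)
  pars <- morph_parameters()
  ma <- mb <- tibble::tibble(animal = paste0("A", 1:5), group = "S")
  for (p in pars) { ma[[p]] <- rnorm(5); mb[[p]] <- rnorm(5) }
  cm <- correlation_heatmaps(ma, mb)
  tdc <- tidy(cm)
  expect_equal(nrow(tdc), 361)
  expect_equal(glance(cm)$n_computable, 361L)
})
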