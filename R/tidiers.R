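# broom-style tidiers for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA fingerprint: loadings in long form
#'
#' @param x a `morph_pca` object.
#' @param ... unused.
#' @return tibble with `parameter`, `component`, `loading`.
#' @method tidy morph_pca
#' @export
tidy.morph_pca <- function(x, ...) {
  l <- x$loadings
  tibble::tibble(
    parameter = rep(rownames(l), times = ncol(l)),
    component = rep(colnames(l), each = nrow(l)),
    loading = as.vector(l))
}

#' One-row PCA summary: explained variance and per-PC Welch p-values
#'
#' @param x a `morph_pca` object.
#' @param ... unused.
#' @return one-row tibble with `n_roi`, `n_parameters`, explained-variance
#'   fractions and Welch p-values for the tested components.
#' @method glance morph_pca
#' @export
glance.morph_pca <- function(x, ...) {
  out <- tibble::tibble(n_roi = nrow(x$scores),
                        n_parameters = nrow(x$loadings))
  for (j in seq_len(x$n_pc)) {
    out[[paste0("ev_frac_pc", j)]] <- x$ev_frac[j]
    out[[paste0("p_pc", j)]] <- x$welch$p[j]
  }
  out
}

#' Tidy a correlation heatmap: one row per parameter-pair cell
#'
#' @param x a `morph_cormat` object.
#' @param ... unused.
#' @return tibble with `parameter_a`, `parameter_b`, `r`, `p`, `n`,
#'   `significant`.
#' @method tidy morph_cormat
#' @export
tidy.morph_cormat <- function(x, ...) {
  pars <- rownames(x$r)
  tibble::tibble(
    parameter_a = rep(pars, times = ncol(x$r)),
    parameter_b = rep(colnames(x$r), each = nrow(x$r)),
    r = as.vector(x$r),
    p = as.vector(x$p),
    n = as.vector(x$n),
    significant = as.vector(x$p < x$alpha))
}

#' One-row correlation-heatmap summary
#'
#' @param x a `morph_cormat` object.
#' @param ... unused.
#' @return one-row tibble with the stain pair, region, significant-cell
#'   count and computable denominator.
#' @method glance morph_cormat
#' @export
glance.morph_cormat <- function(x, ...) {
  tibble::tibble(stain_a = x$stains[1], stain_b = x$stains[2],
                 region = x$region, method = x$method,
                 n_significant = x$sig_count,
                 n_computable = x$n_computable)
}
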