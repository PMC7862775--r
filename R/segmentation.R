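# DAB-positive area segmentation of RGB brightfield tiles:
# optical density -> colour deconvolution -> Otsu threshold -> 8-connected
# labelling -> minimum-size filter. No hole filling and no smoothing, so the
# Euler number of each object is preserved.

#' Default hematoxylin / DAB / residual stain vectors
#'
#' The classical brightfield hematoxylin and DAB optical-density directions,
#' completed by their normalized cross product as residual channel. Rows are
#' stains (hematoxylin, dab, residual), columns RGB; every row has unit
#' Euclidean norm and the matrix is invertible.
#'
#' @return 3 x 3 numeric matrix with rownames `hematoxylin`, `dab`,
#'   `residual`.
#' @export
default_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  v <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(v) <- c("R", "G", "B")
  v
}

#' Convert an 8-bit RGB tile to optical density
#'
#' `OD_c = -log10(max(I_c, 1) / 255)` per channel; intensities of 0 are
#' clamped to 1 so the OD is finite (maximum `log10(255)`, about 2.407).
#'
#' @param tile numeric array `h x w x 3` with values in `[0, 255]`.
#' @return array of the same shape with non-negative optical densities.
#' @export
rgb_to_od <- function(tile) {
  if (length(dim(tile)) != 3L || dim(tile)[3] != 3L) {
    stop("tile must be an h x w x 3 RGB array", call. = FALSE)
  }
  if (min(tile) < 0 || max(tile) > 255) {
    stop("tile values must be in [0, 255]", call. = FALSE)
  }
  -log10(pmax(tile, 1) / 255)
}

#' Colour deconvolution of an optical-density tile
#'
#' Solves the per-pixel 3 x 3 linear system `od = conc %*% vectors` for the
#' stain concentrations (Ruifrok-Johnston colour deconvolution). Negative
#' concentrations are clipped to 0 unless `clip = FALSE`.
#'
#' @param od optical-density array `h x w x 3` from [rgb_to_od()].
#' @param vectors 3 x 3 stain matrix, rows = stains (see
#'   [default_stain_vectors()]).
#' @param clip clip negative concentrations to zero (default `TRUE`).
#' @return array `h x w x 3` of per-stain concentrations, stain order as in
#'   `vectors` rows.
#' @export
deconvolve <- function(od, vectors = default_stain_vectors(), clip = TRUE) {
  stopifnot(length(dim(od)) == 3L, dim(od)[3] == 3L,
            is.matrix(vectors), all(dim(vectors) == c(3L, 3L)))
  if (abs(det(vectors)) < 1e-8) {
    stop("singular stain vector matrix", call. = FALSE)
  }
  d <- dim(od)
  odm <- matrix(od, ncol = 3L)
  conc <- odm %*% solve(vectors)
  if (clip) conc[conc < 0] <- 0
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(vectors))
  out
}

#' Otsu threshold of a concentration grid
#'
#' Builds a 256-bin histogram over the observed value range and returns the
#' bin boundary maximizing the between-class variance. Ties — typically a
#' run of empty bins between two well-separated modes — are broken by
#' taking the middle of the tied range, so the threshold sits centrally in
#' the gap. Deterministic; a constant grid has no separable classes and
#' raises an error (callers treat such a tile as all background).
#'
#' @param x numeric matrix (or vector) of channel values.
#' @param n_bins number of histogram bins (default 256).
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) stop("degenerate histogram", call. = FALSE)
  br <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L),
                     n_bins), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[n_bins]; mtot <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- mu[-n_bins] / w0
  m1 <- (mtot - mu[-n_bins]) / w1
  sb <- ifelse(valid, w0 * w1 * (m0 - m1)^2, -Inf)
  mx <- max(sb)
  ties <- which(sb >= mx - abs(mx) * 1e-12)
  k <- ties[(length(ties) + 1L) %/% 2L]  # middle of the tied range
  br[k + 1L]
}

#' Segment a tile into labelled DAB-positive objects
#'
#' Pipeline: [rgb_to_od()] -> [deconvolve()] -> threshold the DAB channel
#' (Otsu by default, or a manual override) -> 8-connected labelling ->
#' remove objects smaller than `min_area`. Labels are contiguous `1..N`; no
#' hole filling or smoothing is applied. A tile whose DAB channel has a
#' degenerate (constant) histogram is returned as all background.
#'
#' @param tile 8-bit RGB array `h x w x 3` with values in `[0, 255]`.
#' @param vectors stain vector matrix (see [default_stain_vectors()]).
#' @param min_area minimum object area in pixels (default 4).
#' @param threshold `"auto"` for Otsu or a numeric DAB-concentration value.
#' @return integer label matrix with attribute `"areas"` (per-label pixel
#'   counts) and `"threshold"` (the threshold used, `NA` for a blank tile).
#' @export
segment_tile <- function(tile, vectors = default_stain_vectors(),
                         min_area = 4L, threshold = "auto") {
  od <- rgb_to_od(tile)
  conc <- deconvolve(od, vectors)
  dab <- conc[, , "dab"]
  thr <- if (identical(threshold, "auto")) {
    tryCatch(otsu_threshold(dab), error = function(e) NA_real_)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  if (is.na(thr)) {
    lab <- matrix(0L, nrow(dab), ncol(dab))
    attr(lab, "areas") <- integer(0)
    attr(lab, "threshold") <- NA_real_
    return(lab)
  }
  mask <- dab > thr
  lab <- label_components(mask, connectivity = 8)
  areas <- attr(lab, "areas")
  keep <- which(areas >= min_area)
  if (length(keep) < length(areas)) {
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep)
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
    attr(lab, "areas") <- areas[keep]
  }
  attr(lab, "threshold") <- thr
  lab
}
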