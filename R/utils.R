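# Internal helpers shared across modules.

#' Convert a mask or coordinate matrix to an n x 2 integer matrix of (row, col)
#' pixel centers.
#' @noRd
as_pixel_matrix <- function(px) {
  if (!is.matrix(px)) {
    stop("pixel set must be a mask matrix or an n x 2 (row, col) matrix",
         call. = FALSE)
  }
  # a matrix is a mask when logical, not 2 columns wide, or containing only
  # 0/1 values (valid coordinates are positive integers, so an all-0/1 two-
  # column matrix can only be a 2-pixel-wide mask)
  is_mask <- is.logical(px) || ncol(px) != 2L || all(px %in% c(0, 1))
  if (is_mask) {
    px <- which(px != 0, arr.ind = TRUE)
  }
  colnames(px) <- c("row", "col")
  px
}

pixels_to_mask <- function(px, nrow = NULL, ncol = NULL) {
  px <- as_pixel_matrix(px)
  if (is.null(nrow)) nrow <- max(px[, 1])
  if (is.null(ncol)) ncol <- max(px[, 2])
  m <- matrix(FALSE, nrow, ncol)
  m[px] <- TRUE
  m
}

#' Label connected components of a binary mask
#'
#' Foreground components are labelled with 8-connectivity by default;
#' background topology (holes, Euler number) uses the dual 4-connectivity.
#' Labels are contiguous integers 1..N assigned in column-major order of each
#' component's first pixel.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 is background. The per-label
#'   pixel counts are attached as attribute `"areas"`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) {
    attr(lab, "areas") <- integer(0)
    return(lab)
  }
  # map full linear index -> vertex id
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))          # S, E
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))  # SE, NE
  edges <- list()
  for (s in shifts) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- m[nb]
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        cbind(vid[idx[ok]][hit], vid[nb[hit]])
    }
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(idx)
  }
  # relabel so labels follow column-major order of first occurrence
  first <- match(unique(comp), comp)
  relab <- integer(max(comp))
  relab[comp[sort(first)]] <- seq_along(first)
  lab[idx] <- relab[comp]
  attr(lab, "areas") <- tabulate(lab[idx])
  lab
}

#' Dilate a mask by a (2k+1) square structuring element via shifts.
#' @noRd
dilate_box <- function(mask, k) {
  m <- mask != 0
  if (k <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (dr in -k:k) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    sl <- m[rt, , drop = FALSE]
    for (dc in -k:k) {
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      ct <- max(1, 1 - dc):min(nc, nc - dc)
      out[rs, cs] <- out[rs, cs] | sl[, ct, drop = FALSE]
    }
  }
  out
}

#' Round half away from zero to integers (8-bit quantization rule).
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Derive a reproducible child seed below 2^31 from a master seed.
#' @noRd
child_seed <- function(master, i) {
  (as.numeric(master) * 48271 + 7919 * as.numeric(i)) %% 2147483647
}
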