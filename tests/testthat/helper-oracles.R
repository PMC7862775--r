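# Independent brute-force oracles for the shape descriptors. These are
# deliberately slow, direct transcriptions of each definition, sharing no
# code with the package implementation.

# random 8-connected blob grown by neighbour accretion on a bounded canvas
random_blob <- function(n_px, canvas = 40L) {
  px <- matrix(c(canvas %/% 2L, canvas %/% 2L), ncol = 2)
  while (nrow(px) < n_px) {
    base <- px[sample.int(nrow(px), 1L), ]
    cand <- base + sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
    if (all(cand >= 1L & cand <= canvas) &&
        !any(px[, 1] == cand[1] & px[, 2] == cand[2])) {
      px <- rbind(px, cand)
    }
  }
  colnames(px) <- c("row", "col")
  px
}

blob_to_mask <- function(px, pad = 1L) {
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  m <- matrix(FALSE, max(px[, 1]) - r0 + 1L + 2L * pad,
              max(px[, 2]) - c0 + 1L + 2L * pad)
  m[cbind(px[, 1] - r0 + 1L + pad, px[, 2] - c0 + 1L + pad)] <- TRUE
  m
}

oracle_extent <- function(px) {
  nrow(px) / ((diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1))
}

# Euler number by flood fill: 1 minus the number of 4-connected background
# components not reaching the padded border (independent of the quad-count
# formula used in the package)
oracle_euler <- function(px) {
  m <- blob_to_mask(px)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- matrix(c(i, j), ncol = 2)
      lab[i, j] <- nxt
      while (nrow(queue)) {
        q <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          a <- q[1] + d[1]; b <- q[2] + d[2]
          if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
              !m[a, b] && lab[a, b] == 0L) {
            lab[a, b] <- nxt
            queue <- rbind(queue, c(a, b))
          }
        }
      }
    }
  }
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  1L - length(setdiff(unique(lab[lab > 0L]), border))
}

# exhaustive pairwise maximum Feret over all pixel centers
oracle_max_feret <- function(px) {
  if (nrow(px) == 1L) return(0)
  max(stats::dist(px))
}

# minimum caliper width: the minimum over candidate directions of the
# projection extent of all pixel centers. Candidate directions are the
# normals of every hull-vertex pair (the minimum width of a convex set is
# attained flush with a hull edge), so the scan is exact.
oracle_min_feret <- function(px) {
  if (nrow(px) == 1L) return(0)
  pts <- cbind(px[, 2], px[, 1])
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) < 2L) return(0)
  best <- Inf
  for (i in seq_len(nrow(hp) - 1L)) for (j in (i + 1L):nrow(hp)) {
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nvec <- c(-e[2], e[1]) / len
    proj <- pts %*% nvec
    best <- min(best, max(proj) - min(proj))
  }
  if (!is.finite(best)) 0 else best
}

# rasterized convex area by ray-casting point-in-polygon with an explicit
# on-boundary test (different algorithm from the half-plane test inside the
# package)
oracle_convex_area <- function(px) {
  if (nrow(px) == 1L) return(1L)
  pts <- cbind(px[, 2], px[, 1])
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  xs <- min(pts[, 1]):max(pts[, 1]); ys <- min(pts[, 2]):max(pts[, 2])
  k <- nrow(hp)
  on_segment <- function(p, a, b) {
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cr) > 1e-9) return(FALSE)
    p[1] >= min(a[1], b[1]) - 1e-9 && p[1] <= max(a[1], b[1]) + 1e-9 &&
      p[2] >= min(a[2], b[2]) - 1e-9 && p[2] <= max(a[2], b[2]) + 1e-9
  }
  count <- 0L
  for (x in xs) for (y in ys) {
    p <- c(x, y)
    on <- FALSE
    for (i in seq_len(k)) {
      if (on_segment(p, hp[i, ], hp[(i %% k) + 1L, ])) { on <- TRUE; break }
    }
    if (on) { count <- count + 1L; next }
    # ray casting with an irrational slope to dodge vertex degeneracies
    crossings <- 0L
    for (i in seq_len(k)) {
      a <- hp[i, ]; b <- hp[(i %% k) + 1L, ]
      # ray from p in direction (1, sqrt(2)/1e3)
      dr <- c(1, sqrt(2) / 1000)
      d1 <- b - a
      den <- d1[1] * dr[2] - d1[2] * dr[1]
      if (abs(den) < 1e-14) next
      t <- ((p[1] - a[1]) * dr[2] - (p[2] - a[2]) * dr[1]) / den
      s <- ((p[1] - a[1]) * d1[2] - (p[2] - a[2]) * d1[1]) / den
      if (t > 0 && t < 1 && s > 0) crossings <- crossings + 1L
    }
    if (crossings %% 2L == 1L) count <- count + 1L
  }
  count
}

# per-pixel Euclidean distance to the nearest background pixel center.
# The nearest background pixel is always 8-adjacent to some object pixel,
# so the candidate set is the background boundary of the padded mask.
oracle_radii <- function(px) {
  m <- blob_to_mask(px)
  fg <- which(m, arr.ind = TRUE)
  bg <- which(!m, arr.ind = TRUE)
  touch <- vapply(seq_len(nrow(bg)), function(i) {
    any(abs(fg[, 1] - bg[i, 1]) <= 1 & abs(fg[, 2] - bg[i, 2]) <= 1)
  }, logical(1))
  cand <- bg[touch, , drop = FALSE]
  d <- vapply(seq_len(nrow(fg)), function(i) {
    sqrt(min((cand[, 1] - fg[i, 1])^2 + (cand[, 2] - fg[i, 2])^2))
  }, numeric(1))
  n <- length(d); ds <- sort(d)
  list(max_radius = max(d), mean_radius = mean(d),
       median_radius = if (n %% 2L == 0L) ds[n %/% 2L] else ds[(n + 1L) %/% 2L])
}

oracle_moments <- function(px) {
  x <- px[, 2]; y <- px[, 1]
  mu20 <- mean((x - mean(x))^2); mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2))$values
  l1 <- max(ev); l2 <- min(ev)
  th <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (th <= -90) th <- th + 180
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(max(0, l2)),
       ecc = if (l1 <= 0) 0 else sqrt(1 - l2 / l1), orientation = th)
}

oracle_compactness <- function(px) {
  cy <- mean(px[, 1]); cx <- mean(px[, 2])
  2 * pi * mean((px[, 1] - cy)^2 + (px[, 2] - cx)^2) / nrow(px)
}

# between-class variance scan over every candidate histogram boundary,
# with the documented middle-of-tied-range tie-break
oracle_otsu <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  br <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  sb <- rep(-Inf, n_bins - 1L)
  for (k in seq_len(n_bins - 1L)) {
    lo <- bin <= k
    n0 <- sum(lo); n1 <- sum(!lo)
    if (n0 == 0L || n1 == 0L) next
    m0 <- mean(mids[bin[lo]]); m1 <- mean(mids[bin[!lo]])
    sb[k] <- n0 * n1 * (m0 - m1)^2
  }
  ties <- which(sb >= max(sb) - abs(max(sb)) * 1e-12)
  br[ties[(length(ties) + 1L) %/% 2L] + 1L]
}

# exact Mann-Whitney two-sided p by direct enumeration of group labelings,
# with U computed by pairwise win counting (not ranks)
oracle_mw_exact <- function(a, b) {
  u_of <- function(x, y) {
    sum(outer(x, y, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  u_obs <- u_of(a, b)
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  cols <- utils::combn(length(pooled), n1)
  us <- apply(cols, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# chain-code perimeter by an independently written counterclockwise
# Moore-neighbour trace (the closed outer boundary has the same length in
# either direction); single pixel = 4 by convention
oracle_perimeter <- function(px) {
  if (nrow(px) == 1L) return(4)
  m <- blob_to_mask(px)
  # counterclockwise neighbour order starting West
  dd <- rbind(c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L),
              c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  fg <- which(m, arr.ind = TRUE)
  o <- order(fg[, 1], fg[, 2])
  start <- c(fg[o[1], 1], fg[o[1], 2])
  cur <- start; back <- 1L
  visited <- character(0)
  pts <- list(start)
  repeat {
    state <- paste(cur[1], cur[2], back)
    if (state %in% visited) break
    visited <- c(visited, state)
    moved <- FALSE
    for (k in 0:7) {
      j <- ((back - 1L + k) %% 8L) + 1L
      nb <- cur + dd[j, ]
      if (m[nb[1], nb[2]]) {
        pj <- ((j - 2L) %% 8L) + 1L
        pb <- cur + dd[pj, ]
        cur <- nb
        rel <- pb - nb
        back <- which(dd[, 1] == rel[1] & dd[, 2] == rel[2])
        moved <- TRUE
        break
      }
    }
    if (!moved) break
    pts[[length(pts) + 1L]] <- cur
  }
  # drop the lead-in before the cycle: find first repeat of the final state
  first <- match(paste(cur[1], cur[2], back), visited)
  seg <- do.call(rbind, pts)[first:length(pts), , drop = FALSE]
  d <- diff(seg)
  sum(ifelse(abs(d[, 1]) + abs(d[, 2]) == 1L, 1, sqrt(2)))
}
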