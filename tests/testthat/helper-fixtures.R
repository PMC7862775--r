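# Shared fixtures built in code.

# a ramified star: small body with six thin arms (low solidity)
make_star_fixture <- function() {
  n <- 41L; c0 <- 21
  ii <- matrix(1:n, n, n); jj <- t(ii)
  m <- (ii - c0)^2 + (jj - c0)^2 <= 3^2
  for (th in seq(0, 2 * pi, length.out = 7)[-7]) {
    dx <- cos(th); dy <- sin(th)
    t <- pmin(pmax((jj - c0) * dx + (ii - c0) * dy, 0), 15)
    m <- m | ((jj - c0 - t * dx)^2 + (ii - c0 - t * dy)^2 <= 1^2)
  }
  m
}

# descriptors of a blob translated by (dr, dc)
measure_pixels_shifted <- function(px, dr, dc) {
  histomorph:::measure_pixels(cbind(px[, 1] + dr, px[, 2] + dc))
}

# rasterized disk of radius R on a minimal canvas
make_disk <- function(R) {
  n <- 2L * ceiling(R) + 3L
  c0 <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2 <= R^2)
}

# small noiseless synthetic tile with planted disks; returns tile + truth
make_disk_tile <- function(n_disks = 5, tile = c(72L, 72L), seed = 3) {
  set.seed(seed)
  shapes <- replicate(n_disks,
                      make_shape(shape_family_spec("disk", radius = c(5, 1),
                                                   density = n_disks)),
                      simplify = FALSE)
  placed <- place_objects(shapes, tile)
  gt <- matrix(0L, tile[1], tile[2])
  for (k in seq_along(placed$masks)) gt[placed$masks[[k]]] <- k
  list(tile = render_tile(placed$masks, tile_shape = tile, noise_sd = 0),
       gt = gt, placed = placed)
}
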