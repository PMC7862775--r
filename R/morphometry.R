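# Per-object shape descriptors and tile (ROI) level aggregation.
#
# All coordinates are pixel centers on the integer grid: x = column, y = row,
# with the row index increasing downward. Units are pixels throughout.

#' Names of the 19 morphological parameters
#'
#' Three tile-level occupancy measures (`area_occupied`, `count`,
#' `total_perimeter`) followed by the 16 per-object shape descriptors, whose
#' tile-level values are unweighted means over the objects of the tile.
#'
#' @return character vector of length 19 in the fixed analysis order.
#' @export
morph_parameters <- function() {
  c("area_occupied", "count", "total_perimeter",
    morph_object_descriptors())
}

#' Names of the 16 per-object shape descriptors
#' @return character vector of length 16.
#' @export
morph_object_descriptors <- function() {
  c("area", "perimeter", "compactness", "eccentricity", "euler_number",
    "extent", "form_factor", "major_axis_length", "max_feret", "max_radius",
    "mean_radius", "median_radius", "min_feret", "minor_axis_length",
    "orientation", "solidity")
}

#' Object area
#'
#' Exact count of pixels belonging to the object.
#'
#' @param px binary mask matrix or an n x 2 (row, col) matrix of pixel
#'   coordinates.
#' @return area in px^2.
#' @export
object_area <- function(px) {
  px <- as_pixel_matrix(px)
  if (nrow(px) == 0L) stop("empty pixel set", call. = FALSE)
  nrow(px)
}

#' Object perimeter by Moore boundary tracing
#'
#' Length of the closed outer-boundary polygon obtained by Moore-neighbour
#' tracing through boundary pixel centers: axial steps contribute 1, diagonal
#' steps sqrt(2). Inner (hole) boundaries are excluded; a single pixel has
#' perimeter 4 by convention. A 1-pixel-wide arm is traced out and back, so
#' both sides are counted.
#'
#' @inheritParams object_area
#' @return perimeter in px.
#' @export
object_perimeter <- function(px) {
  px <- as_pixel_matrix(px)
  n <- nrow(px)
  if (n == 0L) stop("empty pixel set", call. = FALSE)
  if (n == 1L) return(4)
  r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
  m <- pixels_to_mask(cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L))
  m <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)    # 1-pixel background pad
  path <- moore_trace(m)
  d <- diff(path)
  sum(ifelse(abs(d[, 1]) + abs(d[, 2]) == 1L, 1, sqrt(2)))
}

# Moore-neighbour boundary trace of the single foreground object in a padded
# mask. Returns the closed path of boundary pixel (row, col) coordinates
# (first == last). The trace is a deterministic walk over states
# (pixel, backtrack direction); it stops when the initial state recurs
# (Jacob's stopping criterion).
#' @noRd
moore_trace <- function(m) {
  # clockwise Moore neighbourhood starting West, for (x right, y down) grid
  dirs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  # direction index lookup by (dr, dc) offset
  dir_idx <- matrix(0L, 3, 3)
  for (j in 1:8) dir_idx[dirs[j, 1] + 2L, dirs[j, 2] + 2L] <- j
  fg <- which(m, arr.ind = TRUE)
  ord <- order(fg[, 1], fg[, 2])      # raster scan: top row first, then left
  sr <- fg[ord[1L], 1L]; sc <- fg[ord[1L], 2L]
  # virtual entry into the start pixel from its West background neighbour
  cr <- sr; cc <- sc
  back_dir <- 1L                      # index into dirs pointing at backtrack
  nr <- nrow(m)
  n_states <- nr * ncol(m) * 8L
  seen <- integer(n_states)           # path row at which a state was seen
  seen[((sc - 1L) * nr + (sr - 1L)) * 8L + back_dir] <- 1L
  max_iter <- 8L * nrow(fg) + 16L
  path <- matrix(0L, max_iter + 1L, 2L)
  path[1L, ] <- c(sr, sc)
  np <- 1L
  for (iter in seq_len(max_iter)) {
    found <- FALSE
    for (k in 0:7) {
      j <- ((back_dir - 1L + k) %% 8L) + 1L
      nbr <- cr + dirs[j, 1L]; nbc <- cc + dirs[j, 2L]
      if (m[nbr, nbc]) {
        # backtrack for the next step: the neighbour checked just before j,
        # expressed relative to the new current pixel
        prev_j <- ((j - 2L) %% 8L) + 1L
        pr <- cr + dirs[prev_j, 1L]; pc <- cc + dirs[prev_j, 2L]
        cr <- nbr; cc <- nbc
        back_dir <- dir_idx[pr - cr + 2L, pc - cc + 2L]
        found <- TRUE
        break
      }
    }
    if (!found) break                 # isolated pixel (caller special-cases)
    np <- np + 1L
    path[np, ] <- c(cr, cc)
    key <- ((cc - 1L) * nr + (cr - 1L)) * 8L + back_dir
    i0 <- seen[key]
    if (i0 > 0L) {
      # closed boundary cycle: rows i0..np revisit the same state
      return(path[i0:np, , drop = FALSE])
    }
    seen[key] <- np
  }
  path[seq_len(np), , drop = FALSE]
}

#' Second-moment ellipse of an object
#'
#' Central second moments of the pixel centers, normalized by area, give the
#' 2 x 2 covariance; its eigenvalues lambda1 >= lambda2 define
#' `major_axis_length = 4*sqrt(lambda1)`, `minor_axis_length = 4*sqrt(lambda2)`,
#' `eccentricity = sqrt(1 - lambda2/lambda1)` (0 when lambda1 = 0), and
#' `orientation = 0.5 * atan2(2*mu11, mu20 - mu02)` in degrees, measured from
#' the horizontal image axis (row index increasing downward), mapped to
#' (-90, 90].
#'
#' @inheritParams object_area
#' @return named list with `major_axis_length`, `minor_axis_length`,
#'   `eccentricity`, `orientation`.
#' @export
moment_ellipse <- function(px) {
  px <- as_pixel_matrix(px)
  if (nrow(px) == 0L) stop("empty pixel set", call. = FALSE)
  x <- px[, 2]; y <- px[, 1]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  list(major_axis_length = 4 * sqrt(l1), minor_axis_length = 4 * sqrt(max(0, l2)),
       eccentricity = ecc, orientation = theta)
}

#' Object extent
#'
#' Area divided by the bounding-box area (whole-pixel box).
#' @inheritParams object_area
#' @export
object_extent <- function(px) {
  px <- as_pixel_matrix(px)
  if (nrow(px) == 0L) stop("empty pixel set", call. = FALSE)
  h <- diff(range(px[, 1])) + 1
  w <- diff(range(px[, 2])) + 1
  nrow(px) / (h * w)
}

#' Euler number of an object
#'
#' 1 minus the number of fully enclosed background holes. The object is
#' 8-connected; holes are 4-connected background components, the standard dual
#' avoiding topological paradoxes.
#'
#' @inheritParams object_area
#' @export
object_euler <- function(px) {
  px <- as_pixel_matrix(px)
  if (nrow(px) == 0L) stop("empty pixel set", call. = FALSE)
  r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
  m <- pixels_to_mask(cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L))
  m <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  # Gray's quad-count formula for the 8-connected Euler number: scan all
  # 2 x 2 windows; count those with exactly one (Q1) or three (Q3) foreground
  # pixels and the two-pixel diagonal configurations (QD)
  a <- m[-nrow(m), -ncol(m)]; b <- m[-nrow(m), -1]
  d <- m[-1, -ncol(m)];      e <- m[-1, -1]
  s <- a + b + d + e
  q1 <- sum(s == 1L)
  q3 <- sum(s == 3L)
  qd <- sum(s == 2L & ((a & e & !b & !d) | (b & d & !a & !e)))
  as.integer((q1 - q3 - 2L * qd) / 4L)
}

#' Maximum and minimum Feret (caliper) diameters
#'
#' Over pixel centers: `max_feret` is the largest pairwise Euclidean distance
#' (computed on convex-hull vertices); `min_feret` is the smallest width of
#' the convex hull over all directions (rotating calipers: for each hull edge,
#' the farthest hull vertex from that edge's line). Collinear pixel sets have
#' `min_feret` 0; a single pixel has both 0.
#'
#' @inheritParams object_area
#' @return named list with `max_feret`, `min_feret`.
#' @export
feret_diameters <- function(px) {
  px <- as_pixel_matrix(px)
  n <- nrow(px)
  if (n == 0L) stop("empty pixel set", call. = FALSE)
  if (n == 1L) return(list(max_feret = 0, min_feret = 0))
  pts <- cbind(x = px[, 2], y = px[, 1])
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  dmax <- max(stats::dist(hp))
  # collinearity: all hull points on one line
  if (nrow(hp) < 3L || all(abs(
    (hp[, 1] - hp[1, 1]) * (hp[2, 2] - hp[1, 2]) -
      (hp[, 2] - hp[1, 2]) * (hp[2, 1] - hp[1, 1])) < 1e-9)) {
    return(list(max_feret = dmax, min_feret = 0))
  }
  k <- nrow(hp)
  widths <- vapply(seq_len(k), function(i) {
    a <- hp[i, ]; b <- hp[(i %% k) + 1L, ]
    e <- b - a; len <- sqrt(sum(e^2))
    if (len < 1e-12) return(Inf)
    max(abs((hp[, 1] - a[1]) * e[2] - (hp[, 2] - a[2]) * e[1]) / len)
  }, numeric(1))
  list(max_feret = dmax, min_feret = min(widths))
}

#' Radius statistics from the Euclidean distance transform
#'
#' Each object pixel's radius is its Euclidean distance to the nearest
#' non-object pixel center (the tile padded by background). `max_radius`,
#' `mean_radius` and `median_radius` summarize these; the median is the lower
#' median for even counts.
#'
#' @inheritParams object_area
#' @return named list with `max_radius`, `mean_radius`, `median_radius`.
#' @export
radius_stats <- function(px) {
  px <- as_pixel_matrix(px)
  if (nrow(px) == 0L) stop("empty pixel set", call. = FALSE)
  r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
  m <- pixels_to_mask(cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L))
  m <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  d <- EBImage::distmap(m * 1, metric = "euclidean")
  v <- d[m]
  n <- length(v)
  vs <- sort(v)
  med <- if (n %% 2L == 0L) vs[n %/% 2L] else vs[(n + 1L) %/% 2L]
  list(max_radius = max(v), mean_radius = mean(v), median_radius = med)
}

#' Solidity against the rasterized convex hull
#'
#' `solidity = area / convex_area`, where the convex area is the number of
#' grid pixels whose centers lie inside or on the convex-hull polygon of the
#' object's pixel centers. Rasterizing the hull (rather than using its
#' polygon area) makes every convex digital shape score exactly 1.
#'
#' @inheritParams object_area
#' @export
convex_solidity <- function(px) {
  px <- as_pixel_matrix(px)
  n <- nrow(px)
  if (n == 0L) stop("empty pixel set", call. = FALSE)
  n / convex_pixel_area(px)
}

# takes an already-converted n x 2 (row, col) coordinate matrix
#' @noRd
convex_pixel_area <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(1L)
  pts <- cbind(x = px[, 2], y = px[, 1])
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  grid <- expand.grid(x = min(pts[, 1]):max(pts[, 1]),
                      y = min(pts[, 2]):max(pts[, 2]))
  if (nrow(hp) < 3L) {
    # degenerate (collinear): pixels whose centers lie on the segment
    a <- hp[1, ]; b <- hp[nrow(hp), ]
    e <- b - a; len2 <- sum(e^2)
    if (len2 < 1e-12) return(1L)
    t <- ((grid$x - a[1]) * e[1] + (grid$y - a[2]) * e[2]) / len2
    perp <- abs((grid$x - a[1]) * e[2] - (grid$y - a[2]) * e[1]) / sqrt(len2)
    return(sum(perp < 1e-9 & t >= -1e-9 & t <= 1 + 1e-9))
  }
  # inside-or-on test against every hull edge's half-plane; the interior
  # cross-product sign is fixed by the hull's vertex order (shoelace)
  k <- nrow(hp)
  s <- sign_of_interior(hp)
  inside <- rep(TRUE, nrow(grid))
  for (i in seq_len(k)) {
    a <- hp[i, ]; b <- hp[(i %% k) + 1L, ]
    cr <- (b[1] - a[1]) * (grid$y - a[2]) - (b[2] - a[2]) * (grid$x - a[1])
    inside <- inside & (s * cr >= -1e-9)
  }
  sum(inside)
}

#' @noRd
sign_of_interior <- function(hp) {
  # signed area of the hull polygon (shoelace); positive means counter-
  # clockwise in the (x, y) frame used, so interior cross products are >= 0
  x <- hp[, 1]; y <- hp[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (s >= 0) 1 else -1
}

#' Compactness
#'
#' `2 * pi * E[d^2] / area`, where `E[d^2]` is the mean squared Euclidean
#' distance of object pixel centers from the centroid. A filled disk tends to
#' 1 in the continuum limit; elongated or ramified shapes score above 1. A
#' single pixel scores 0 by convention.
#'
#' @inheritParams object_area
#' @export
compactness <- function(px) {
  px <- as_pixel_matrix(px)
  n <- nrow(px)
  if (n == 0L) stop("empty pixel set", call. = FALSE)
  d2 <- (px[, 1] - mean(px[, 1]))^2 + (px[, 2] - mean(px[, 2]))^2
  2 * pi * mean(d2) / n
}

#' Form factor
#'
#' `4 * pi * area / perimeter^2`; 1 for an ideal circle. Under the chain-code
#' perimeter this can exceed 1 for very small objects (documented estimator
#' bias).
#'
#' @param area object area in px^2.
#' @param perimeter object perimeter in px (> 0).
#' @export
form_factor <- function(area, perimeter) {
  stopifnot(all(perimeter > 0))
  4 * pi * area / perimeter^2
}

#' Measure all 16 shape descriptors of one labelled object
#'
#' @param label_map integer label matrix (0 = background).
#' @param id object label present in `label_map`.
#' @return one-row tibble with the 16 descriptors plus `centroid_row`,
#'   `centroid_col`.
#' @export
measure_object <- function(label_map, id) {
  px <- which(label_map == id, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("unknown label: ", id, call. = FALSE)
  measure_pixels(px, id)
}

#' @noRd
measure_pixels <- function(px, id = NA_integer_) {
  tibble::as_tibble(measure_pixels_list(as_pixel_matrix(px), id))
}

# plain named list of the 16 descriptors + ids/centroid (fast path)
#' @noRd
measure_pixels_list <- function(px, id = NA_integer_) {
  a <- nrow(px)
  p <- object_perimeter(px)
  me <- moment_ellipse(px)
  fer <- feret_diameters(px)
  rad <- radius_stats(px)
  list(
    object_id = as.integer(id),
    area = as.numeric(a),
    perimeter = p,
    compactness = compactness(px),
    eccentricity = me$eccentricity,
    euler_number = object_euler(px),
    extent = object_extent(px),
    form_factor = form_factor(a, p),
    major_axis_length = me$major_axis_length,
    max_feret = fer$max_feret,
    max_radius = rad$max_radius,
    mean_radius = rad$mean_radius,
    median_radius = rad$median_radius,
    min_feret = fer$min_feret,
    minor_axis_length = me$minor_axis_length,
    orientation = me$orientation,
    solidity = convex_solidity(px),
    centroid_row = mean(px[, 1]),
    centroid_col = mean(px[, 2])
  )
}

#' Measure every object of a label map
#'
#' @param label_map integer label matrix as returned by [segment_tile()].
#' @return tibble with one row per object (possibly zero rows).
#' @export
measure_tile <- function(label_map) {
  ids <- setdiff(sort(unique(as.vector(label_map))), 0L)
  if (length(ids) == 0L) {
    return(measure_pixels(cbind(1L, 1L))[0, ])
  }
  all_px <- which(label_map > 0L, arr.ind = TRUE)
  labs <- label_map[all_px]
  rows <- lapply(ids, function(i) {
    measure_pixels_list(all_px[labs == i, , drop = FALSE], i)
  })
  fields <- names(rows[[1]])
  out <- lapply(fields, function(f) vapply(rows, `[[`, numeric(1), f))
  names(out) <- fields
  out$object_id <- as.integer(out$object_id)
  tibble::as_tibble(out)
}

#' Aggregate a tile's objects into the 19 ROI-level parameters
#'
#' The three occupancy measures are totals over the tile: `area_occupied`
#' (positive pixels), `count` (objects) and `total_perimeter` (sum of object
#' perimeters). The 16 shape descriptors are unweighted arithmetic means over
#' objects — including `orientation`, an arithmetic mean of angles (a
#' documented caveat: angles near the +/-90 wrap can average misleadingly).
#' An empty tile yields count 0, occupancy 0, and missing (NA) means.
#'
#' @param x label matrix or a per-object tibble from [measure_tile()].
#' @return one-row tibble with the 19 parameters of [morph_parameters()].
#' @export
measure_roi <- function(x) {
  obj <- if (is.matrix(x)) measure_tile(x) else x
  desc <- morph_object_descriptors()
  if (nrow(obj) == 0L) {
    out <- tibble::tibble(area_occupied = 0, count = 0L, total_perimeter = 0)
    out[desc] <- NA_real_
    return(out)
  }
  out <- tibble::tibble(
    area_occupied = sum(obj$area),
    count = nrow(obj),
    total_perimeter = sum(obj$perimeter)
  )
  out[desc] <- lapply(obj[desc], mean)
  out
}
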