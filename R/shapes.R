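# Synthetic shape families emulating the stain-specific morphologies seen in
# brightfield IHC of stroked brain tissue: disks and ellipses for nuclear
# stains, ramified stars for resting microglia/astrocytes, tubes for vessels,
# annuli for testing hole topology.

#' Specify a synthetic shape family
#'
#' Size parameters are `(mean, sd)` pairs sampled per object from a normal
#' distribution and truncated to at least 1 px. `density` is the expected
#' number of objects per tile (Poisson).
#'
#' @param family one of `"disk"`, `"ellipse"`, `"ramified"`, `"tube"`,
#'   `"annulus"`.
#' @param ... family size parameters, each a numeric `c(mean, sd)` (a single
#'   number means sd 0): disk takes `radius`; ellipse `axis_a`, `axis_b`;
#'   ramified `body_radius`, `n_processes`, `process_length`,
#'   `process_width`; tube `length`, `width`; annulus `radius`,
#'   `hole_radius`.
#' @param density expected objects per tile (>= 0).
#' @return object of class `shape_family_spec`.
#' @export
shape_family_spec <- function(family = c("disk", "ellipse", "ramified",
                                         "tube", "annulus"),
                              ..., density = 8) {
  family <- match.arg(family)
  pars <- list(...)
  required <- switch(family,
    disk = "radius",
    ellipse = c("axis_a", "axis_b"),
    ramified = c("body_radius", "n_processes", "process_length",
                 "process_width"),
    tube = c("length", "width"),
    annulus = c("radius", "hole_radius"))
  missing <- setdiff(required, names(pars))
  if (length(missing)) {
    stop("missing size parameters for ", family, " family: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pars <- lapply(pars[required], function(p) {
    p <- as.numeric(p)
    if (length(p) == 1L) p <- c(p, 0)
    if (p[1] <= 0) stop("size means must be > 0", call. = FALSE)
    if (p[2] < 0) stop("size sds must be >= 0", call. = FALSE)
    stats::setNames(p, c("mean", "sd"))
  })
  if (density < 0) stop("density must be >= 0", call. = FALSE)
  structure(list(family = family, params = pars, density = density),
            class = "shape_family_spec")
}

#' @export
print.shape_family_spec <- function(x, ...) {
  cat("<shape_family_spec>", x$family, "(density", x$density, "objects/tile)\n")
  for (nm in names(x$params)) {
    cat("  ", nm, ": mean ", x$params[[nm]]["mean"],
        ", sd ", x$params[[nm]]["sd"], "\n", sep = "")
  }
  invisible(x)
}

#' @noRd
sample_size <- function(p, rng_min = 1) {
  max(rng_min, stats::rnorm(1, p["mean"], p["sd"]))
}

#' Draw one shape from a family specification
#'
#' Samples the family's size parameters (truncated to >= 1 px), rasterizes
#' the shape on a minimal canvas of pixel centers, and returns both the
#' binary mask and the true sampled parameters for later recovery tests.
#' The mask is always one 8-connected object.
#'
#' @param spec a [shape_family_spec()].
#' @param canvas optional `c(rows, cols)` canvas limit; an error names the
#'   offending parameter if the sampled shape cannot fit.
#' @return list with `mask` (logical matrix) and `params` (named list of the
#'   sampled true values, including `family`).
#' @export
make_shape <- function(spec, canvas = NULL) {
  stopifnot(inherits(spec, "shape_family_spec"))
  p <- spec$params
  res <- switch(spec$family,
    disk = {
      r <- sample_size(p$radius)
      list(mask = raster_disk(r), params = list(radius = r))
    },
    ellipse = {
      a <- sample_size(p$axis_a); b <- sample_size(p$axis_b)
      if (b > a) { tmp <- a; a <- b; b <- tmp }
      th <- stats::runif(1, 0, pi)
      list(mask = raster_ellipse(a, b, th),
           params = list(axis_a = a, axis_b = b, angle = th))
    },
    ramified = {
      nb <- max(1L, round(stats::rnorm(1, p$n_processes["mean"],
                                       p$n_processes["sd"])))
      r0 <- sample_size(p$body_radius)
      len <- vapply(seq_len(nb), function(i) sample_size(p$process_length),
                    numeric(1))
      wid <- sample_size(p$process_width)
      base <- stats::runif(1, 0, 2 * pi)
      ang <- base + 2 * pi * (seq_len(nb) - 1) / nb +
        stats::rnorm(nb, 0, 0.2)
      list(mask = raster_ramified(r0, ang, len, wid),
           params = list(body_radius = r0, n_processes = nb,
                         process_length = mean(len), process_width = wid))
    },
    tube = {
      len <- sample_size(p$length); wid <- sample_size(p$width)
      th <- stats::runif(1, 0, pi)
      list(mask = raster_tube(len, wid, th),
           params = list(length = len, width = wid, angle = th))
    },
    annulus = {
      r <- sample_size(p$radius)
      hr <- min(sample_size(p$hole_radius), r - 1.5)
      hr <- max(hr, 0.6)
      list(mask = raster_annulus(r, hr),
           params = list(radius = r, hole_radius = hr))
    })
  if (!is.null(canvas)) {
    if (nrow(res$mask) > canvas[1] || ncol(res$mask) > canvas[2]) {
      big <- names(which.max(vapply(res$params[vapply(res$params, is.numeric,
        logical(1))], max, numeric(1))))
      stop("sampled shape exceeds canvas; offending parameter: ", big,
           call. = FALSE)
    }
  }
  res$params$family <- spec$family
  res
}

#' @noRd
raster_disk <- function(r) {
  n <- 2L * ceiling(r) + 3L
  c0 <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

#' @noRd
raster_ellipse <- function(a, b, theta) {
  n <- 2L * ceiling(a) + 3L
  c0 <- (n + 1) / 2
  ct <- cos(theta); st <- sin(theta)
  outer(1:n, 1:n, function(i, j) {
    u <- (j - c0) * ct + (i - c0) * st
    v <- -(j - c0) * st + (i - c0) * ct
    (u / a)^2 + (v / b)^2 <= 1
  })
}

#' @noRd
raster_annulus <- function(r, hole_r) {
  n <- 2L * ceiling(r) + 3L
  c0 <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) {
    d2 <- (i - c0)^2 + (j - c0)^2
    d2 <= r^2 & d2 > hole_r^2
  })
}

# union of a central disk and thick radial segments; always 8-connected
# because every process starts at the body center
#' @noRd
raster_ramified <- function(body_r, angles, lengths, width) {
  reach <- ceiling(body_r + max(lengths) + width)
  n <- 2L * reach + 3L
  c0 <- (n + 1) / 2
  ii <- matrix(1:n, n, n); jj <- t(ii)
  m <- (ii - c0)^2 + (jj - c0)^2 <= body_r^2
  for (k in seq_along(angles)) {
    m <- m | thick_segment(ii - c0, jj - c0, angles[k], lengths[k] + body_r,
                           width / 2)
  }
  m
}

#' @noRd
raster_tube <- function(len, width, theta) {
  reach <- ceiling(len / 2 + width)
  n <- 2L * reach + 3L
  c0 <- (n + 1) / 2
  ii <- matrix(1:n, n, n); jj <- t(ii)
  thick_segment(ii - c0, jj - c0, theta, len / 2, width / 2,
                t_min = -len / 2)
}

# pixels within half_w (Euclidean) of the segment running along direction
# theta from t_min to t_max; di/dj are offsets from the segment origin
# (y = row down, x = col right)
#' @noRd
thick_segment <- function(di, dj, theta, t_max, half_w, t_min = 0) {
  dx <- cos(theta); dy <- sin(theta)
  t <- pmin(pmax(dj * dx + di * dy, t_min), t_max)
  (dj - t * dx)^2 + (di - t * dy)^2 <= half_w^2
}

#' Place object masks on a tile without overlap
#'
#' Rejection sampling: each object is dropped at a uniform position and
#' accepted only if, after dilating the already-placed occupancy by 2 px, it
#' touches nothing (guaranteeing a >= 2 px gap so segmentation ground truth
#' is unambiguous). Objects that cannot be placed after `max_tries`
#' attempts are skipped.
#'
#' @param shapes list of shape lists from [make_shape()].
#' @param tile_shape `c(rows, cols)` of the tile.
#' @param max_tries placement attempts per object (default 40).
#' @return list with `masks` (full-tile logical matrices, pairwise disjoint)
#'   and `params` (true parameters of the placed objects, with `row`/`col`
#'   offsets).
#' @export
place_objects <- function(shapes, tile_shape, max_tries = 40L) {
  nr <- tile_shape[1]; nc <- tile_shape[2]
  occupied <- matrix(FALSE, nr, nc)
  masks <- list(); params <- list()
  for (sh in shapes) {
    sm <- sh$mask
    dsm <- dilate_box(sm, 2L)          # accept only with >= 2 px gap
    hr <- nrow(sm); wc <- ncol(sm)
    if (hr > nr || wc > nc) next
    for (try in seq_len(max_tries)) {
      r0 <- sample.int(nr - hr + 1L, 1L) - 1L
      c0 <- sample.int(nc - wc + 1L, 1L) - 1L
      block <- occupied[(r0 + 1L):(r0 + hr), (c0 + 1L):(c0 + wc)]
      if (!any(block & dsm)) {
        full <- matrix(FALSE, nr, nc)
        full[(r0 + 1L):(r0 + hr), (c0 + 1L):(c0 + wc)] <- sm
        masks[[length(masks) + 1L]] <- full
        p <- sh$params
        p$row <- r0; p$col <- c0
        params[[length(params) + 1L]] <- p
        occupied <- occupied | full
        break
      }
    }
  }
  list(masks = masks, params = params)
}
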