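# Synthetic study generator: renders DAB-brown objects over a hematoxylin
# background with Beer-Lambert mixing, writes a directory layout the
# pipeline consumes unchanged, and returns the ground truth.

#' Render an RGB brightfield tile from object masks
#'
#' Beer-Lambert transmission per channel:
#' `I_c = I0 * 10^(-(C_hema * V_hema,c + C_dab * V_dab,c))`, where the
#' hematoxylin concentration is uniform background and the DAB concentration
#' is `dab_od` on object pixels. Gaussian noise (sd in 8-bit intensity
#' units) is added, values are clipped to `[0, 255]` and quantized by
#' rounding half up (so a pixel with total OD 1 at `I0 = 255` renders as
#' `round(25.5) = 26`). Zero noise makes the tile deterministic.
#'
#' @param masks list of full-tile logical matrices (pairwise disjoint).
#' @param tile_shape `c(rows, cols)`; required when `masks` is empty.
#' @param vectors stain vector matrix, rows hematoxylin/dab/residual.
#' @param hema_bg background hematoxylin optical density (default 0.25).
#' @param dab_od DAB optical density on object pixels (default 1.0).
#' @param intensity incident light intensity I0 (default 255).
#' @param noise_sd additive Gaussian noise sd in intensity units (default 0).
#' @return numeric array `rows x cols x 3` of quantized 8-bit values.
#' @export
render_tile <- function(masks, tile_shape = NULL,
                        vectors = default_stain_vectors(),
                        hema_bg = 0.25, dab_od = 1.0, intensity = 255,
                        noise_sd = 0) {
  if (length(masks)) {
    tile_shape <- dim(masks[[1]])
    tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    if (max(tot) > 1L) stop("overlapping object masks", call. = FALSE)
    dab <- tot * dab_od
  } else {
    if (is.null(tile_shape)) stop("tile_shape required for empty mask list",
                                  call. = FALSE)
    dab <- matrix(0, tile_shape[1], tile_shape[2])
  }
  nr <- tile_shape[1]; nc <- tile_shape[2]
  tile <- array(0, c(nr, nc, 3L))
  for (ch in 1:3) {
    od <- hema_bg * vectors["hematoxylin", ch] + dab * vectors["dab", ch]
    I <- intensity * 10^(-od)
    if (noise_sd > 0) I <- I + stats::rnorm(length(I), 0, noise_sd)
    tile[, , ch] <- round_half_up(pmin(pmax(I, 0), 255))
  }
  tile
}

#' Configure a synthetic two-group study
#'
#' The defaults emulate the study design the pipeline targets: two groups
#' (non-stroke NS, stroke S), five stains with stain-specific shape families,
#' a grid of tiles per animal with a fixed perilesional coordinate block
#' (identical coordinates in both groups, i.e. matched neuroanatomical
#' locations) and an SVZ block for the neuroblast stain, plus per-animal
#' lesion volumetry. Group-specific shape parameters plant the reported
#' directional shifts: ameboid microglia (solidity up, eccentricity down,
#' occupancy up), sprawling astrocytes (major axis up, solidity down),
#' neuronal loss (occupancy down), denser but smaller vessels (occupancy up,
#' size down), and smaller rounder neuroblasts.
#'
#' @param n_per_group named integer vector `c(NS = , S = )`.
#' @param stains character vector of stain names to simulate.
#' @param grid `c(rows, cols)` tile grid per animal.
#' @param tile_px `c(rows, cols)` pixel size of one tile.
#' @param perilesional 2-column matrix of (grid_row, grid_col) flagged
#'   perilesional; must fall inside `grid`.
#' @param svz 2-column matrix of SVZ coordinates (used for the DCX stain).
#' @param families named list: `families[[stain]][[group]]` is a
#'   [shape_family_spec()].
#' @param hema_bg,dab_od,intensity,noise_sd rendering model, see
#'   [render_tile()].
#' @param vectors stain vector matrix.
#' @param seed master seed; a fixed seed makes the generated dataset
#'   byte-identical across runs.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_per_group = c(NS = 5L, S = 5L),
                         stains = c("IBA1", "GFAP", "NeuN", "FactorVIII",
                                    "DCX"),
                         grid = c(10L, 10L),
                         tile_px = c(72L, 72L),
                         perilesional = as.matrix(expand.grid(4:7, 4:8)),
                         svz = cbind(9:10, 1L),
                         families = default_shape_families(),
                         hema_bg = 0.25, dab_od = 1.0, intensity = 255,
                         noise_sd = 2, vectors = default_stain_vectors(),
                         seed = 1L) {
  stopifnot(all(c("NS", "S") %in% names(n_per_group)),
            all(n_per_group >= 1))
  perilesional <- as.matrix(perilesional)
  svz <- as.matrix(svz)
  if (any(perilesional[, 1] > grid[1]) || any(perilesional[, 2] > grid[2]) ||
      any(svz[, 1] > grid[1]) || any(svz[, 2] > grid[2]) ||
      any(perilesional < 1) || any(svz < 1)) {
    stop("perilesional/SVZ coordinates must lie inside the grid",
         call. = FALSE)
  }
  missing <- setdiff(stains, names(families))
  if (length(missing)) {
    stop("no shape families for stains: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_per_group = n_per_group, stains = stains, grid = as.integer(grid),
    tile_px = as.integer(tile_px), perilesional = perilesional, svz = svz,
    families = families, hema_bg = hema_bg, dab_od = dab_od,
    intensity = intensity, noise_sd = noise_sd, vectors = vectors,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Default per-stain, per-group shape families
#'
#' One family per stain, with group S parameters shifted in the directions
#' the analysis is expected to recover (see [study_config()]).
#'
#' @return named list `families[[stain]][[group]]` of
#'   [shape_family_spec()] objects.
#' @export
default_shape_families <- function() {
  list(
    IBA1 = list(  # ramified -> ameboid: S rounder, more solid, more area
      NS = shape_family_spec("ramified", body_radius = c(2.5, 0.4),
                             n_processes = c(6, 1), process_length = c(10, 2),
                             process_width = c(1.6, 0.2), density = 8),
      S = shape_family_spec("ramified", body_radius = c(5.5, 0.6),
                            n_processes = c(3, 1),
                            process_length = c(2.5, 0.8),
                            process_width = c(2, 0.2), density = 12)),
    GFAP = list(  # S sprawled: longer processes, lower solidity
      NS = shape_family_spec("ramified", body_radius = c(2, 0.3),
                             n_processes = c(5, 1), process_length = c(6, 1.5),
                             process_width = c(1.6, 0.2), density = 9),
      S = shape_family_spec("ramified", body_radius = c(2, 0.3),
                            n_processes = c(6, 1), process_length = c(11, 2),
                            process_width = c(1.6, 0.2), density = 9)),
    NeuN = list(  # S: neuronal loss, occupancy down
      NS = shape_family_spec("disk", radius = c(4, 0.8), density = 12),
      S = shape_family_spec("disk", radius = c(3.6, 0.8), density = 7)),
    FactorVIII = list(  # S: more but smaller vessels
      NS = shape_family_spec("tube", length = c(18, 4), width = c(3, 0.4),
                             density = 5),
      S = shape_family_spec("tube", length = c(11, 3), width = c(3, 0.4),
                            density = 11)),
    DCX = list(  # S: smaller, rounder neuroblasts, more of them
      NS = shape_family_spec("ellipse", axis_a = c(4, 0.7),
                             axis_b = c(2, 0.3), density = 8),
      S = shape_family_spec("ellipse", axis_a = c(2.7, 0.5),
                            axis_b = c(1.9, 0.3), density = 12))
  )
}

#' Generate a synthetic study to disk
#'
#' Writes `tiles/{animal}_{stain}_r{row}_c{col}.png`, `annotations.csv`
#' (animal, group, stain, grid_row, grid_col, region), `volumetry.csv`
#' (animal, group, HVc_cm3, HVi_cm3, LVu_cm3), per-tile ground-truth
#' 8-bit label masks under `ground_truth/` (unless `write_masks = FALSE`) and
#' `ground_truth.json` with the true sampled shape parameters. The same
#' config and seed reproduce the dataset byte for byte.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created; must be writable).
#' @param write_masks also write 16-bit label-mask PNGs (default TRUE).
#' @return invisibly, a list with `annotations`, `volumetry` and `truth`
#'   tibbles (truth has one row per planted object) and the output paths.
#' @export
generate_study <- function(config, out_dir, write_masks = TRUE) {
  stopifnot(inherits(config, "study_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  tiles_dir <- file.path(out_dir, "tiles")
  dir.create(tiles_dir, showWarnings = FALSE)
  if (write_masks) {
    dir.create(file.path(out_dir, "ground_truth"), showWarnings = FALSE)
  }
  set.seed(config$seed)
  animals <- c(sprintf("NS%02d", seq_len(config$n_per_group[["NS"]])),
               sprintf("S%02d", seq_len(config$n_per_group[["S"]])))
  groups <- rep(c("NS", "S"), config$n_per_group[c("NS", "S")])
  grid_coords <- expand.grid(grid_row = seq_len(config$grid[1]),
                             grid_col = seq_len(config$grid[2]))
  peri_key <- paste(config$perilesional[, 1], config$perilesional[, 2])
  svz_key <- paste(config$svz[, 1], config$svz[, 2])
  region <- rep("hemispheric", nrow(grid_coords))
  key <- paste(grid_coords$grid_row, grid_coords$grid_col)
  region[key %in% peri_key] <- "perilesional"
  region[key %in% svz_key] <- "SVZ"

  ann <- list(); truth <- list()
  for (ai in seq_along(animals)) {
    for (stain in config$stains) {
      fam <- config$families[[stain]][[groups[ai]]]
      for (ti in seq_len(nrow(grid_coords))) {
        gr <- grid_coords$grid_row[ti]; gc <- grid_coords$grid_col[ti]
        n_obj <- stats::rpois(1, fam$density)
        shapes <- lapply(seq_len(n_obj), function(i)
          make_shape(fam, canvas = config$tile_px))
        placed <- place_objects(shapes, config$tile_px)
        tile <- render_tile(placed$masks, tile_shape = config$tile_px,
                            vectors = config$vectors,
                            hema_bg = config$hema_bg, dab_od = config$dab_od,
                            intensity = config$intensity,
                            noise_sd = config$noise_sd)
        stem <- sprintf("%s_%s_r%02d_c%02d", animals[ai], stain, gr, gc)
        png::writePNG(tile / 255, file.path(tiles_dir, paste0(stem, ".png")))
        if (write_masks) {
          lab <- matrix(0L, config$tile_px[1], config$tile_px[2])
          for (k in seq_along(placed$masks)) lab[placed$masks[[k]]] <- k
          # 8-bit label PNG; object counts per tile are far below 255
          png::writePNG(lab / 255,
                        file.path(out_dir, "ground_truth",
                                  paste0(stem, "_mask.png")))
        }
        ann[[length(ann) + 1L]] <- data.frame(
          animal = animals[ai], group = groups[ai], stain = stain,
          grid_row = gr, grid_col = gc, region = region[ti],
          stringsAsFactors = FALSE)
        if (length(placed$params)) {
          truth[[length(truth) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(animal = animals[ai], group = groups[ai],
                           stain = stain, grid_row = gr, grid_col = gc,
                           object = seq_along(placed$params)),
            dplyr::bind_rows(lapply(placed$params, function(p)
              tibble::as_tibble(p[!vapply(p, is.character, logical(1)) |
                                    names(p) == "family"]))))
        }
      }
    }
  }
  annotations <- tibble::as_tibble(dplyr::bind_rows(ann))
  truth <- dplyr::bind_rows(truth)
  volumetry <- sample_volumetry(animals, groups)
  utils::write.csv(annotations, file.path(out_dir, "annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(volumetry, file.path(out_dir, "volumetry.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       digits = NA)
  invisible(list(annotations = annotations, volumetry = volumetry,
                 truth = truth, out_dir = out_dir, tiles_dir = tiles_dir))
}

# plausible porcine hemisphere volumes (cm^3) with stroke-group edema
# swelling and lesion volumes around the reported cohort scale
#' @noRd
sample_volumetry <- function(animals, groups) {
  n <- length(animals)
  hvc <- stats::rnorm(n, 30, 1.5)
  swell <- ifelse(groups == "S", stats::runif(n, 1.04, 1.14), 1)
  hvi <- hvc * swell
  lvu <- ifelse(groups == "S",
                pmin(pmax(stats::rnorm(n, 5.36, 3.68), 0.5), 12), 0)
  tibble::tibble(animal = animals, group = groups,
                 HVc_cm3 = round(hvc, 3), HVi_cm3 = round(hvi, 3),
                 LVu_cm3 = round(lvu, 3))
}
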