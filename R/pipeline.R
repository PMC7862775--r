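# End-to-end orchestration: simulate -> segment -> measure -> analyze, with
# cached stage outputs, a run manifest, and a plain-text report.

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; keys mirror the arguments of
#'   [run_pipeline()].
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# read a PNG or TIFF tile as an 8-bit-scale RGB array
#' @noRd
read_tile <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]          # drop alpha
  }
  img * 255
}

#' Segment and measure every tile of a study directory
#'
#' Reads each annotated tile image, runs [segment_tile()] and
#' [measure_roi()], and returns the ROI-level 19-parameter table.
#'
#' @param tiles_dir directory of `{animal}_{stain}_r{row}_c{col}` tiles
#'   (PNG or TIFF).
#' @param annotations annotation tibble (or path to `annotations.csv`).
#' @param vectors,min_area,threshold segmentation settings, see
#'   [segment_tile()].
#' @param per_object also return the per-object descriptor table (default
#'   FALSE).
#' @return tibble of per-tile measures keyed by animal/stain/grid
#'   coordinates; with `per_object = TRUE`, a list of `roi` and `objects`
#'   tibbles.
#' @export
measure_study <- function(tiles_dir, annotations,
                          vectors = default_stain_vectors(), min_area = 4L,
                          threshold = "auto", per_object = FALSE) {
  if (is.character(annotations)) {
    annotations <- tibble::as_tibble(
      utils::read.csv(annotations, stringsAsFactors = FALSE))
  }
  roi <- vector("list", nrow(annotations))
  objs <- if (per_object) vector("list", nrow(annotations)) else NULL
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    stem <- sprintf("%s_%s_r%02d_c%02d", a$animal, a$stain,
                    a$grid_row, a$grid_col)
    path <- NULL
    for (ext in c(".png", ".tif", ".tiff")) {
      cand <- file.path(tiles_dir, paste0(stem, ext))
      if (file.exists(cand)) { path <- cand; break }
    }
    if (is.null(path)) {
      stop("missing tile image: ",
           file.path(tiles_dir, paste0(stem, ".png")), call. = FALSE)
    }
    tile <- read_tile(path)
    lab <- segment_tile(tile, vectors = vectors, min_area = min_area,
                        threshold = threshold)
    obj <- measure_tile(lab)
    roi[[i]] <- dplyr::bind_cols(
      tibble::tibble(animal = a$animal, stain = a$stain,
                     grid_row = a$grid_row, grid_col = a$grid_col),
      measure_roi(obj))
    if (per_object && nrow(obj)) {
      objs[[i]] <- dplyr::bind_cols(
        tibble::tibble(animal = a$animal, stain = a$stain,
                       grid_row = a$grid_row, grid_col = a$grid_col), obj)
    }
  }
  roi <- dplyr::bind_rows(roi)
  if (per_object) list(roi = roi, objects = dplyr::bind_rows(objs)) else roi
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a synthetic study unless an input directory with
#' tiles and annotations is given; (2) segment and measure all tiles;
#' (3) attach regions; (4) group comparisons, PCA, cross-stain correlation
#' heatmaps and volumetrics as toggled. Stage outputs are written as CSV
#' under `out_dir` and reused on rerun (`resume = TRUE`); a
#' `manifest.json` records the configuration hash and per-stage counts. The
#' run is deterministic for a fixed config and seed.
#'
#' @param config list (or path to YAML/JSON) with optional keys:
#'   `input_dir`, `out_dir` (required), `seed`, `study` (arguments for
#'   [study_config()]), `min_area`, `threshold`, `alpha`, `n_pc`,
#'   `parameters` (subset of the 19), `analyses` (character subset of
#'   `c("comparisons", "pca", "correlations", "volumetrics")`),
#'   `correlation_pairs` (list of stain pairs), `resume`.
#' @return invisible list of result tables (`roi`, `records`,
#'   `comparisons`, `pca`, `correlations`, `volumetry`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir is required",
                             call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  min_area <- config$min_area %||% 4L
  threshold <- config$threshold %||% "auto"
  n_pc <- config$n_pc %||% 3L
  analyses <- config$analyses %||% c("comparisons", "pca", "correlations",
                                     "volumetrics")
  parameters <- config$parameters %||% morph_parameters()
  if (!all(parameters %in% morph_parameters())) {
    stop("config error: unknown parameters: ",
         paste(setdiff(parameters, morph_parameters()), collapse = ", "),
         call. = FALSE)
  }
  resume <- isTRUE(config$resume)
  manifest <- list(config_hash = rlang::hash(config),
                   package_version = as.character(
                     utils::packageVersion("histomorph")),
                   seed = seed, counts = list())

  # stage 1: input data (simulate if no input_dir given)
  if (is.null(config$input_dir)) {
    sc_args <- config$study %||% list()
    sc_args$seed <- sc_args$seed %||% seed
    sc <- do.call(study_config, sc_args)
    input_dir <- file.path(out_dir, "synthetic")
    if (!resume || !file.exists(file.path(input_dir, "annotations.csv"))) {
      generate_study(sc, input_dir, write_masks = FALSE)
    }
  } else {
    input_dir <- config$input_dir
  }
  ann_path <- file.path(input_dir, "annotations.csv")
  if (!file.exists(ann_path)) {
    stop("data error: no annotations.csv in ", input_dir, call. = FALSE)
  }
  annotations <- tibble::as_tibble(
    utils::read.csv(ann_path, stringsAsFactors = FALSE))
  manifest$counts$tiles <- nrow(annotations)

  # stage 2: segment + measure (cached)
  roi_path <- file.path(out_dir, "roi_measures.csv")
  if (resume && file.exists(roi_path)) {
    roi <- tibble::as_tibble(utils::read.csv(roi_path,
                                             stringsAsFactors = FALSE))
  } else {
    roi <- measure_study(file.path(input_dir, "tiles"), annotations,
                         min_area = min_area, threshold = threshold)
    utils::write.csv(roi, roi_path, row.names = FALSE)
  }
  manifest$counts$objects_per_stain <- as.list(
    tapply(roi$count, roi$stain, sum))

  # stage 3: regions
  records <- assign_regions(roi, annotations)
  manifest$counts$rois_per_region <- as.list(table(records$region))
  utils::write.csv(records, file.path(out_dir, "roi_records.csv"),
                   row.names = FALSE)

  results <- list(roi = roi, records = records)

  if ("comparisons" %in% analyses) {
    comp <- compare_groups(records, parameters = parameters, alpha = alpha)
    utils::write.csv(comp, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    results$comparisons <- comp
  }
  if ("pca" %in% analyses) {
    pca_res <- list()
    for (stain in unique(records$stain)) {
      for (region in c("hemispheric", "perilesional")) {
        rec <- filter_region(records[records$stain == stain, ], region)
        xm <- rec[, intersect(parameters, names(rec)), drop = FALSE]
        fit <- tryCatch(
          suppressMessages(pca_fit(xm, rec$group, n_pc = n_pc)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          pca_res[[paste(stain, region, sep = "_")]] <- fit
        }
      }
    }
    pca_tests <- dplyr::bind_rows(lapply(names(pca_res), function(nm) {
      dplyr::bind_cols(tibble::tibble(stratum = nm), pca_res[[nm]]$welch)
    }))
    utils::write.csv(pca_tests, file.path(out_dir, "pca_tests.csv"),
                     row.names = FALSE)
    results$pca <- pca_res
    results$pca_tests <- pca_tests
  }
  if ("correlations" %in% analyses) {
    pairs <- config$correlation_pairs %||%
      list(c("IBA1", "GFAP"), c("IBA1", "NeuN"), c("GFAP", "NeuN"))
    pairs <- Filter(function(p) all(p %in% unique(records$stain)), pairs)
    cors <- list()
    for (grp in c("NS", "S")) {
      grec <- records[records$group == grp, ]
      for (pr in pairs) {
        for (region in c("hemispheric", "perilesional")) {
          ma <- per_animal_matrix(grec, pr[1], region)
          mb <- per_animal_matrix(grec, pr[2], region)
          cm <- tryCatch(
            correlation_heatmaps(ma, mb, stains = pr, region = region,
                                 alpha = alpha),
            error = function(e) NULL)
          if (!is.null(cm)) {
            cors[[paste(grp, pr[1], pr[2], region, sep = "_")]] <- cm
          }
        }
      }
    }
    if (length(cors)) {
      sig <- count_significant(cors)
      sig$stratum <- c(names(cors), "total")
      utils::write.csv(sig, file.path(out_dir, "significance_summary.csv"),
                       row.names = FALSE)
      results$correlations <- cors
      results$significance <- sig
    }
  }
  if ("volumetrics" %in% analyses) {
    vol_path <- file.path(input_dir, "volumetry.csv")
    if (file.exists(vol_path)) {
      vol <- correct_volumetry(tibble::as_tibble(
        utils::read.csv(vol_path, stringsAsFactors = FALSE)))
      utils::write.csv(vol, file.path(out_dir, "volumetry_corrected.csv"),
                       row.names = FALSE)
      results$volumetry <- vol
      # lesion volume vs whole-section area occupied per stain
      area_tbl <- records |>
        dplyr::group_by(.data$animal, .data$stain) |>
        dplyr::summarise(area_occupied = mean(.data$area_occupied),
                         .groups = "drop")
      lv <- dplyr::bind_rows(lapply(unique(area_tbl$stain), function(st) {
        d <- dplyr::inner_join(area_tbl[area_tbl$stain == st, ], vol,
                               by = "animal")
        d <- d[d$group == "S", ]
        if (nrow(d) >= 3 && stats::var(d$LVc_cm3) > 0) {
          dplyr::bind_cols(tibble::tibble(stain = st),
                           simple_linreg(d$LVc_cm3, d$area_occupied))
        }
      }))
      if (nrow(lv)) {
        utils::write.csv(lv, file.path(out_dir, "lesion_regression.csv"),
                         row.names = FALSE)
        results$lesion_regression <- lv
      }
    }
  }
  manifest$analyses <- analyses
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Write a plain-text analysis report
#'
#' Summarizes the comparison battery (medians, U, p with significance stars
#' at 0.05 / 0.001 / 0.0001), the per-PC Welch tests, and the
#' significant-correlation counts with their denominators.
#'
#' @param results list from [run_pipeline()].
#' @param path output text file; `NULL` returns the lines invisibly.
#' @return invisibly, the report lines.
#' @export
write_report <- function(results, path = NULL) {
  stars <- function(p) {
    dplyr::case_when(p < 0.0001 ~ "****", p < 0.001 ~ "***",
                     p < 0.05 ~ "*", TRUE ~ "")
  }
  lines <- c("histomorph analysis report",
             strrep("=", 26), "")
  if (!is.null(results$comparisons) && nrow(results$comparisons)) {
    cmp <- results$comparisons
    lines <- c(lines, "Group comparisons (Mann-Whitney, ROI level):")
    for (i in seq_len(nrow(cmp))) {
      lines <- c(lines, sprintf(
        "  %-10s %-12s %-18s NS=%.4g S=%.4g U=%.1f p=%.3g %s",
        cmp$stain[i], cmp$region[i], cmp$parameter[i], cmp$median_NS[i],
        cmp$median_S[i], cmp$U[i], cmp$p[i], stars(cmp$p[i])))
    }
  } else {
    lines <- c(lines, "No comparisons run.")
  }
  if (!is.null(results$pca_tests) && nrow(results$pca_tests)) {
    lines <- c(lines, "", "PCA per-component Welch tests:")
    pt <- results$pca_tests
    for (i in seq_len(nrow(pt))) {
      lines <- c(lines, sprintf("  %-24s %s t=%.3f p=%.3g %s",
                                pt$stratum[i], pt$component[i], pt$t[i],
                                pt$p[i], stars(pt$p[i])))
    }
  }
  if (!is.null(results$significance) && nrow(results$significance)) {
    sig <- results$significance
    lines <- c(lines, "", "Significant correlation cells:")
    for (i in seq_len(nrow(sig))) {
      lines <- c(lines, sprintf("  %-30s %d of %d", sig$stratum[i],
                                sig$n_significant[i], sig$n_computable[i]))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
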