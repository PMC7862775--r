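# Region-stratified assembly of ROI records and per-animal feature matrices.
#
# Every tile (ROI) belongs to the hemispheric analysis set; perilesional and
# SVZ tiles are flagged subsets, so pooled perilesional vectors are always
# sub-vectors of the hemispheric ones.

#' Attach region labels and grouping to measured ROIs
#'
#' Joins the per-tile 19-parameter table with the region annotation table by
#' (animal, stain, grid_row, grid_col). Every measured tile must have an
#' annotation row.
#'
#' @param measures tibble with columns `animal`, `stain`, `grid_row`,
#'   `grid_col` and the 19 parameters of [morph_parameters()].
#' @param annotations tibble with columns `animal`, `group`, `stain`,
#'   `grid_row`, `grid_col`, `region`.
#' @return tibble of ROI records (one row per tile) with `group` and
#'   `region` attached.
#' @export
assign_regions <- function(measures, annotations) {
  keys <- c("animal", "stain", "grid_row", "grid_col")
  stopifnot(all(keys %in% names(measures)),
            all(c(keys, "group", "region") %in% names(annotations)))
  out <- dplyr::left_join(
    measures,
    dplyr::select(annotations, dplyr::all_of(c(keys, "group", "region"))),
    by = keys)
  if (anyNA(out$region)) {
    bad <- dplyr::distinct(out[is.na(out$region), keys])
    stop("tiles without annotation: ",
         paste(utils::capture.output(print(as.data.frame(bad))),
               collapse = "\n"), call. = FALSE)
  }
  dplyr::relocate(out, dplyr::all_of(c("animal", "group", "stain",
                                       "grid_row", "grid_col", "region")))
}

# region membership: the hemispheric set is every tile of the section;
# perilesional and SVZ are flagged subsets
#' @noRd
filter_region <- function(records, region) {
  region <- match.arg(region, c("hemispheric", "perilesional", "SVZ"))
  if (region == "hemispheric") records
  else records[records$region == region, , drop = FALSE]
}

#' Pool one parameter's ROI-level values for a group
#'
#' Returns one value per ROI (the statistical unit of the group
#' comparisons). For the 16 per-object descriptor means, ROIs with zero
#' objects carry no value and are excluded (the number excluded is attached
#' as attribute `"n_excluded"`); the occupancy measures `area_occupied`,
#' `count` and `total_perimeter` are real zeros and always included.
#'
#' @param records ROI records from [assign_regions()].
#' @param stain,region,group the stratum to pool.
#' @param parameter one of [morph_parameters()].
#' @return numeric vector with attribute `n_excluded`.
#' @export
pool_parameter <- function(records, stain, region, parameter, group) {
  if (!parameter %in% morph_parameters()) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  rec <- filter_region(records, region)
  rec <- rec[rec$stain == stain & rec$group == group, , drop = FALSE]
  v <- rec[[parameter]]
  n_excl <- 0L
  if (parameter %in% morph_object_descriptors()) {
    n_excl <- sum(is.na(v))
    v <- v[!is.na(v)]
  }
  attr(v, "n_excluded") <- n_excl
  v
}

#' Per-animal feature matrix for one stain and region
#'
#' Unweighted means of each of the 19 parameters over the animal's ROIs in
#' the region (ROIs with no objects are skipped for the per-object
#' descriptor means). Animals with zero qualifying ROIs get an all-NA row,
#' which downstream correlation uses pairwise-complete.
#'
#' @param records ROI records from [assign_regions()].
#' @param stain,region the stratum.
#' @return tibble: `animal`, `group`, then the 19 parameter columns.
#' @export
per_animal_matrix <- function(records, stain, region) {
  rec <- filter_region(records, region)
  rec <- rec[rec$stain == stain, , drop = FALSE]
  pars <- morph_parameters()
  all_animals <- dplyr::distinct(records, .data$animal, .data$group)
  out <- rec |>
    dplyr::group_by(.data$animal, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(pars),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  out <- dplyr::left_join(all_animals, out, by = c("animal", "group"))
  out[pars] <- lapply(out[pars], function(x) ifelse(is.nan(x), NA_real_, x))
  dplyr::arrange(out, .data$animal)
}
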