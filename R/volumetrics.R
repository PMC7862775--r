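# Edema-corrected lesion volume from hemisphere volumes.

#' Edema-corrected lesion volume
#'
#' `LVc = HVc + HVi - (HVc + HVi - LVu) * (HVc + HVi) / (2 * HVc)`.
#'
#' The correction rescales the intact tissue volume of the swollen
#' ipsilateral hemisphere to the contralateral reference: with no swelling
#' (`HVi = HVc`) the factor is 1 and `LVc = LVu` exactly (the no-edema
#' identity that fixes the grouping of the final factor; an alternative
#' reading can be supplied via `factor_fun`). For extreme edema the
#' corrected volume can be negative; it is returned with a warning rather
#' than clipped.
#'
#' @param HVc contralateral hemisphere volume (cm^3, > 0).
#' @param HVi ipsilateral hemisphere volume (cm^3, > 0).
#' @param LVu uncorrected lesion volume (cm^3, in `[0, HVi]`).
#' @param factor_fun optional function `(HVc, HVi) -> factor` replacing the
#'   default `(HVc + HVi) / (2 * HVc)` reading.
#' @return corrected lesion volume(s) LVc in cm^3 (vectorized).
#' @export
corrected_lesion_volume <- function(HVc, HVi, LVu, factor_fun = NULL) {
  if (any(HVc <= 0)) stop("HVc must be > 0", call. = FALSE)
  if (any(HVi <= 0)) stop("HVi must be > 0", call. = FALSE)
  if (any(LVu < 0)) stop("LVu must be >= 0", call. = FALSE)
  if (any(LVu > HVi)) stop("LVu must not exceed HVi", call. = FALSE)
  f <- if (is.null(factor_fun)) (HVc + HVi) / (2 * HVc)
       else factor_fun(HVc, HVi)
  # algebraically identical to HVc + HVi - (HVc + HVi - LVu) * f, arranged
  # so the no-edema case (f exactly 1) returns LVu bit-for-bit
  lvc <- (HVc + HVi) * (1 - f) + LVu * f
  if (any(lvc < 0)) {
    warning("negative corrected lesion volume (extreme edema); not clipped")
  }
  lvc
}

#' Add corrected lesion volumes to a volumetry table
#'
#' @param volumetry tibble with columns `HVc_cm3`, `HVi_cm3`, `LVu_cm3`
#'   (as written by [generate_study()]).
#' @return the table with an `LVc_cm3` column appended.
#' @export
correct_volumetry <- function(volumetry) {
  stopifnot(all(c("HVc_cm3", "HVi_cm3", "LVu_cm3") %in% names(volumetry)))
  dplyr::mutate(volumetry,
                LVc_cm3 = corrected_lesion_volume(.data$HVc_cm3,
                                                  .data$HVi_cm3,
                                                  .data$LVu_cm3))
}
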