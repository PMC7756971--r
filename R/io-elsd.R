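#' Read an ELSD peak table
#'
#' Reads integrated evaporative light scattering detection (ELSD) peak areas
#' for each herb extract. Columns: `herb`, `rt`, `area`, optional `label` and
#' `qms_mz` (nominal m/z observed on the in-line single quadrupole, used as
#' optional corroboration when assigning ELSD peaks to HRMS features).
#'
#' @param path CSV file path.
#' @param manifest Sample manifest; every `herb` value must be a declared
#'   herb code.
#' @return A tibble `herb_code`, `rt`, `area`, `label`, `qms_mz`.
#' @export
read_elsd_table <- function(path, manifest) {
  stopifnot(file.exists(path))
  manifest <- validate_manifest(manifest)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0) {
    return(tibble(herb_code = character(), rt = numeric(), area = numeric(),
                  label = character(), qms_mz = numeric()))
  }
  names(raw) <- tolower(names(raw))
  needed <- c("herb", "rt", "area")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("ELSD table is missing column(s): ", paste(missing, collapse = ", ")),
          class = "formulanet_format_error")
  }
  out <- tibble(
    herb_code = as.character(raw$herb),
    rt = as.numeric(raw$rt),
    area = as.numeric(raw$area),
    label = if ("label" %in% names(raw)) as.character(raw$label) else NA_character_,
    qms_mz = if ("qms_mz" %in% names(raw)) as.numeric(raw$qms_mz) else NA_real_
  )
  unknown <- setdiff(out$herb_code, manifest_herbs(manifest))
  if (length(unknown) > 0) {
    abort(paste0("ELSD table names herb(s) absent from manifest: ",
                 paste(unknown, collapse = ", ")),
          class = "formulanet_validation_error")
  }
  if (any(out$area < 0)) {
    abort("ELSD areas must be >= 0", class = "formulanet_validation_error")
  }
  out
}
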