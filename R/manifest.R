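#' Read and validate a sample manifest
#'
#' The manifest declares every sample of one ionization mode: its role
#' (`formula`, `herb` or `blank`), the herb code for herb extracts, a display
#' color, and the herb's weight/weight proportion in the crude mixture before
#' decoction.
#'
#' @param path Path to a CSV or YAML manifest. CSV columns: `sample_id`,
#'   `role`, `herb_code`, `herb_color`, `ww_proportion`. A YAML manifest holds
#'   a list of records with the same fields.
#' @return A validated tibble with columns `sample_id`, `role`, `herb_code`,
#'   `herb_color`, `ww_proportion`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "sample_id,role,herb_code,herb_color,ww_proportion",
#'   "F,formula,,,",
#'   "H_A,herb,A,#1b9e77,0.5",
#'   "H_B,herb,B,#d95f02,0.5",
#'   "BLK,blank,,,"
#' ), path)
#' read_manifest(path)
read_manifest <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    man <- purrr::map_dfr(recs, function(r) {
      tibble(
        sample_id = as.character(r$sample_id),
        role = as.character(r$role),
        herb_code = as.character(r$herb_code %||% NA_character_),
        herb_color = as.character(r$herb_color %||% NA_character_),
        ww_proportion = as.numeric(r$ww_proportion %||% NA_real_)
      )
    })
  } else {
    man <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    names(man) <- tolower(names(man))
    man <- man |>
      mutate(
        herb_code = if ("herb_code" %in% names(man)) .data$herb_code else NA_character_,
        herb_color = if ("herb_color" %in% names(man)) .data$herb_color else NA_character_,
        ww_proportion = suppressWarnings(as.numeric(
          if ("ww_proportion" %in% names(man)) .data$ww_proportion else NA_real_
        ))
      ) |>
      select("sample_id", "role", "herb_code", "herb_color", "ww_proportion")
  }
  man$herb_code[!is.na(man$herb_code) & man$herb_code == ""] <- NA_character_
  validate_manifest(man)
}

#' Validate a sample manifest
#'
#' Checks the manifest invariants: unique sample ids, exactly one formula
#' sample, unique herb codes, and herb w/w proportions summing to 1 when all
#' are provided.
#'
#' @param manifest A manifest tibble (see [read_manifest()]).
#' @return The manifest, invisibly coerced to a tibble, if valid.
#' @export
validate_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  needed <- c("sample_id", "role", "herb_code", "ww_proportion")
  missing <- setdiff(needed, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ", paste(missing, collapse = ", ")),
          class = "formulanet_format_error")
  }
  if (!"herb_color" %in% names(manifest)) manifest$herb_color <- NA_character_
  if (anyDuplicated(manifest$sample_id)) {
    abort("manifest sample_ids must be unique", class = "formulanet_validation_error")
  }
  if (!all(manifest$role %in% c("formula", "herb", "blank"))) {
    abort("manifest roles must be one of formula/herb/blank",
          class = "formulanet_validation_error")
  }
  if (sum(manifest$role == "formula") != 1) {
    abort("manifest must declare exactly one formula sample",
          class = "formulanet_validation_error")
  }
  herbs <- manifest[manifest$role == "herb", ]
  if (nrow(herbs) == 0) {
    abort("manifest must declare at least one herb sample",
          class = "formulanet_validation_error")
  }
  if (any(is.na(herbs$herb_code))) {
    abort("every herb sample needs a herb_code", class = "formulanet_validation_error")
  }
  if (anyDuplicated(herbs$herb_code)) {
    abort("herb_codes must be unique", class = "formulanet_validation_error")
  }
  ww <- herbs$ww_proportion
  if (all(!is.na(ww)) && abs(sum(ww) - 1) > 1e-6) {
    abort(sprintf("herb ww_proportions must sum to 1 (got %.8f)", sum(ww)),
          class = "formulanet_validation_error")
  }
  manifest
}

# convenience accessors -------------------------------------------------------

manifest_herbs <- function(manifest) {
  manifest$herb_code[manifest$role == "herb"]
}

manifest_herb_samples <- function(manifest) {
  manifest$sample_id[manifest$role == "herb"]
}

manifest_formula_sample <- function(manifest) {
  id <- manifest$sample_id[manifest$role == "formula"]
  if (length(id) != 1) {
    abort("manifest must declare exactly one formula sample",
          class = "formulanet_config_error")
  }
  id
}

manifest_blank_samples <- function(manifest) {
  manifest$sample_id[manifest$role == "blank"]
}

# sample_id -> herb_code for herb samples
manifest_herb_map <- function(manifest) {
  herbs <- manifest[manifest$role == "herb", ]
  setNames(herbs$herb_code, herbs$sample_id)
}
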