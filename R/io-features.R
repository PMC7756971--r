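#' Read an aligned feature quantification table
#'
#' Parses an aligned LC-MS feature table in either the GNPS/MZmine dialect
#' (`row ID`, `row m/z`, `row retention time`, `<sample> Peak height`) or a
#' plain `id,mz,rt,<sample>...` header, auto-detected by header sniffing.
#' Missing height cells are read as 0 ("not detected" after alignment).
#'
#' @param path CSV file path.
#' @param manifest Sample manifest (see [read_manifest()]); one height column
#'   per manifest sample is required. Height columns for samples absent from
#'   the manifest are dropped with a warning.
#' @param mode Ionization mode tag, `"PI"` or `"NI"`.
#' @return A feature table: a tibble with columns `feature_id`, `mz`, `rt`
#'   and one numeric height column per manifest sample, with attribute
#'   `mode`.
#' @export
read_feature_table <- function(path, manifest, mode = c("PI", "NI")) {
  mode <- match.arg(mode)
  stopifnot(file.exists(path))
  manifest <- validate_manifest(manifest)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  nm <- names(raw)
  # GNPS dialect sniffing
  gnps_id <- grepl("^row ID$", nm, ignore.case = TRUE)
  if (any(gnps_id)) {
    id_col <- nm[gnps_id][1]
    mz_col <- nm[grepl("^row m/?z$", nm, ignore.case = TRUE)][1]
    rt_col <- nm[grepl("^row retention time$", nm, ignore.case = TRUE)][1]
    height_cols <- nm[grepl(" Peak height$", nm)]
    sample_of <- sub(" Peak height$", "", height_cols)
    sample_of <- sub("\\.mzX?ML$", "", sample_of, ignore.case = TRUE)
  } else {
    id_col <- nm[tolower(nm) %in% c("id", "feature_id")][1]
    mz_col <- nm[tolower(nm) %in% c("mz", "m/z")][1]
    rt_col <- nm[tolower(nm) %in% c("rt", "retention_time")][1]
    height_cols <- setdiff(nm, c(id_col, mz_col, rt_col))
    sample_of <- height_cols
  }
  if (is.na(id_col)) abort("feature table is missing the feature id column",
                           class = "formulanet_format_error")
  if (is.na(mz_col)) abort("feature table is missing the m/z column",
                           class = "formulanet_format_error")
  if (is.na(rt_col)) abort("feature table is missing the rt column",
                           class = "formulanet_format_error")

  unknown <- setdiff(sample_of, manifest$sample_id)
  if (length(unknown) > 0) {
    warn(paste0("ignoring height column(s) for unknown sample(s): ",
                paste(unknown, collapse = ", ")))
  }
  absent <- setdiff(manifest$sample_id, sample_of)
  if (length(absent) > 0) {
    abort(paste0("feature table is missing height column(s) for sample(s): ",
                 paste(absent, collapse = ", ")),
          class = "formulanet_format_error")
  }

  keep_idx <- sample_of %in% manifest$sample_id
  heights <- raw[height_cols[keep_idx]]
  names(heights) <- sample_of[keep_idx]
  heights <- heights[manifest$sample_id]
  heights[] <- lapply(heights, function(x) {
    x <- suppressWarnings(as.numeric(x))
    x[is.na(x)] <- 0
    x
  })

  ft <- tibble(
    feature_id = as.integer(raw[[id_col]]),
    mz = as.numeric(raw[[mz_col]]),
    rt = as.numeric(raw[[rt_col]])
  )
  ft <- bind_cols(ft, as_tibble(heights))
  validate_feature_table(ft, manifest, mode)
}

#' Validate a feature table
#'
#' @param ft Feature table tibble (`feature_id`, `mz`, `rt`, heights).
#' @param manifest Sample manifest.
#' @param mode Ionization mode tag.
#' @return The table, sorted by feature id, with attribute `mode` set.
#' @export
validate_feature_table <- function(ft, manifest, mode = c("PI", "NI")) {
  mode <- match.arg(mode)
  if (anyDuplicated(ft$feature_id)) {
    abort("duplicate feature ids in feature table",
          class = "formulanet_validation_error")
  }
  if (any(ft$mz <= 0) || any(ft$rt < 0)) {
    abort("feature m/z must be > 0 and rt >= 0",
          class = "formulanet_validation_error")
  }
  hcols <- intersect(manifest$sample_id, names(ft))
  if (any(vapply(ft[hcols], function(x) any(x < 0), logical(1)))) {
    abort("feature heights must be >= 0", class = "formulanet_validation_error")
  }
  ft <- arrange(ft, .data$feature_id)
  attr(ft, "mode") <- mode
  ft
}

#' Write a feature table as CSV (plain dialect)
#'
#' @param ft Feature table tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  out <- ft
  names(out)[1:3] <- c("id", "mz", "rt")
  readr::write_csv(out, path)
  invisible(path)
}

# heights of one feature table in long form: feature_id, sample_id, height
feature_heights_long <- function(ft, manifest) {
  ft |>
    select("feature_id", all_of(manifest$sample_id)) |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "height")
}
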