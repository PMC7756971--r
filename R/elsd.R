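#' Filter ELSD peaks by minimum area
#'
#' Keeps peaks whose area is at or above `min_area` (inclusive). The default
#' 0.004 uV/s retains only peaks abundant enough for semi-quantitative
#' interpretation.
#'
#' @param elsd ELSD peak tibble (see [read_elsd_table()]).
#' @param min_area Minimum area (default 0.004).
#' @return The filtered tibble.
#' @export
filter_elsd_peaks <- function(elsd, min_area = 0.004) {
  stopifnot(min_area >= 0, all(elsd$area >= 0))
  elsd[elsd$area >= min_area, ]
}

#' Label ELSD peaks by herb and abundance rank
#'
#' Per herb, peaks are labeled `<herb_code><rank>` with rank 1 for the
#' largest area, descending; area ties are broken by earlier retention time.
#'
#' @param elsd Filtered ELSD peak tibble.
#' @return The tibble with its `label` column filled.
#' @export
label_elsd_peaks <- function(elsd) {
  elsd |>
    group_by(.data$herb_code) |>
    arrange(desc(.data$area), .data$rt, .by_group = TRUE) |>
    mutate(label = paste0(.data$herb_code, row_number())) |>
    ungroup() |>
    arrange(.data$herb_code, .data$label)
}

#' Assign ELSD peaks to HRMS features
#'
#' For each ELSD peak, candidate features are those of the same herb's
#' specific set (default) — or all formula-detected features
#' (`scope = "formula"`) — within `rt_tol` of the ELSD retention time. When
#' the ELSD table carries a `qms_mz` nominal mass, candidates must round to
#' it within +/- 0.5 Da. The candidate with the highest height in that herb
#' is assigned (ties by lower feature id). Unmatched peaks are reported with
#' `NA` feature ids ("not detected in the formula"), not errors. A manual
#' override mapping (`label` -> `feature_id`) always wins.
#'
#' @param elsd Labeled ELSD peak tibble (see [label_elsd_peaks()]).
#' @param ft Feature table of one ionization mode.
#' @param spec Specificity table of the same mode.
#' @param manifest Sample manifest.
#' @param rt_tol RT tolerance in minutes (default 0.1).
#' @param scope `"specific"` (default) or `"formula"`.
#' @param overrides Optional tibble (`label`, `feature_id`) of manual
#'   assignments.
#' @return Tibble `label`, `herb_code`, `rt_elsd`, `area`, `feature_id`,
#'   `rt_offset`, `matched`.
#' @export
match_elsd_to_features <- function(elsd, ft, spec, manifest, rt_tol = 0.1,
                                   scope = c("specific", "formula"),
                                   overrides = NULL) {
  scope <- match.arg(scope)
  manifest <- validate_manifest(manifest)
  herb_map <- manifest_herb_map(manifest)
  sample_of_herb <- setNames(names(herb_map), unname(herb_map))

  rows <- purrr::pmap(list(elsd$label, elsd$herb_code, elsd$rt, elsd$area,
                           elsd$qms_mz %||% rep(NA_real_, nrow(elsd))),
                      function(label, herb, rt0, area, qms) {
    if (!is.null(overrides) && label %in% overrides$label) {
      fid <- overrides$feature_id[match(label, overrides$label)]
      off <- ft$rt[match(fid, ft$feature_id)] - rt0
      return(tibble(label = label, herb_code = herb, rt_elsd = rt0,
                    area = area, feature_id = as.integer(fid),
                    rt_offset = off, matched = TRUE))
    }
    cand_ids <- if (scope == "specific") {
      spec$feature_id[!is.na(spec$specific_herb) & spec$specific_herb == herb &
                        spec$in_formula]
    } else {
      spec$feature_id[spec$in_formula]
    }
    cand <- ft[ft$feature_id %in% cand_ids & abs(ft$rt - rt0) <= rt_tol, ]
    if (!is.na(qms) && nrow(cand) > 0) {
      cand <- cand[abs(round(cand$mz) - qms) <= 0.5, ]
    }
    if (nrow(cand) == 0) {
      return(tibble(label = label, herb_code = herb, rt_elsd = rt0,
                    area = area, feature_id = NA_integer_,
                    rt_offset = NA_real_, matched = FALSE))
    }
    h <- cand[[sample_of_herb[[herb]]]]
    best <- cand[order(-h, cand$feature_id), ][1, ]
    tibble(label = label, herb_code = herb, rt_elsd = rt0, area = area,
           feature_id = best$feature_id, rt_offset = best$rt - rt0,
           matched = TRUE)
  })
  bind_rows(rows)
}

#' Map assigned ELSD areas onto features
#'
#' @param assignments Assignment tibble from [match_elsd_to_features()].
#' @return Tibble `feature_id`, `label`, `area` for matched peaks. Two ELSD
#'   peaks mapping to one feature is a conflict error listing both labels.
#' @export
assign_areas <- function(assignments) {
  hit <- assignments[assignments$matched & !is.na(assignments$feature_id), ]
  dup <- hit$feature_id[duplicated(hit$feature_id)]
  if (length(dup) > 0) {
    labs <- hit$label[hit$feature_id %in% dup]
    abort(paste0("ELSD peaks map to the same feature: ",
                 paste(labs, collapse = ", ")),
          class = "formulanet_conflict_error")
  }
  hit |> select("feature_id", "label", "area")
}
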