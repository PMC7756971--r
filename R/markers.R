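#' Pair features across ionization modes
#'
#' A positive-mode feature ([M+H]+) pairs with a negative-mode feature
#' ([M-H]-) when their retention times agree within `rt_tol` and their
#' implied neutral masses agree within `ppm_tol`. Pairing is one-to-one,
#' greedily by smallest combined (scaled) distance; unpaired features are
#' allowed.
#'
#' @param ft_pi,ft_ni Feature tables of the two modes.
#' @param rt_tol RT tolerance in minutes (default 0.05).
#' @param ppm_tol Neutral-mass tolerance in ppm (default 10).
#' @return Tibble `feature_id_pi`, `feature_id_ni`, `rt_delta`,
#'   `mass_delta_ppm`.
#' @export
pair_cross_mode <- function(ft_pi, ft_ni, rt_tol = 0.05, ppm_tol = 10) {
  empty <- tibble(feature_id_pi = integer(), feature_id_ni = integer(),
                  rt_delta = numeric(), mass_delta_ppm = numeric())
  if (nrow(ft_pi) == 0 || nrow(ft_ni) == 0) return(empty)
  m_pi <- ft_pi$mz - .proton_mass
  m_ni <- ft_ni$mz + .proton_mass
  cand <- tidyr::expand_grid(i = seq_len(nrow(ft_pi)), j = seq_len(nrow(ft_ni))) |>
    mutate(rt_delta = ft_pi$rt[.data$i] - ft_ni$rt[.data$j],
           mass_delta_ppm = 1e6 * (m_pi[.data$i] - m_ni[.data$j]) /
             ((m_pi[.data$i] + m_ni[.data$j]) / 2)) |>
    filter(abs(.data$rt_delta) <= rt_tol,
           abs(.data$mass_delta_ppm) <= ppm_tol) |>
    mutate(dist = abs(.data$rt_delta) / rt_tol +
             abs(.data$mass_delta_ppm) / ppm_tol) |>
    arrange(.data$dist, .data$i, .data$j)
  if (nrow(cand) == 0) return(empty)
  used_i <- logical(nrow(ft_pi)); used_j <- logical(nrow(ft_ni))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE; keep[k] <- TRUE
    }
  }
  cand[keep, ] |>
    transmute(feature_id_pi = ft_pi$feature_id[.data$i],
              feature_id_ni = ft_ni$feature_id[.data$j],
              .data$rt_delta, .data$mass_delta_ppm) |>
    arrange(.data$feature_id_pi)
}

#' Select abundant specific markers from ELSD-backed features
#'
#' Each labeled ELSD peak, via its per-mode feature assignments and the
#' cross-mode pairing, becomes a marker candidate. Status is `specific` when
#' the specificity share for the source herb is at or above `threshold` in
#' every ionization mode where the feature is detected (features seen in a
#' single mode are judged on that mode and flagged `single_mode`);
#' `non_specific` otherwise; `not_in_formula` when no feature was assigned
#' in either mode. An optional abundance override retains the top
#' `abundance_top_n` peaks per herb (by area) that fail the specificity
#' bar, flagging them `retained_by_abundance` rather than silently passing
#' them.
#'
#' @param assign_pi,assign_ni Assignment tibbles from
#'   [match_elsd_to_features()] for each mode (either may be `NULL`).
#' @param spec_pi,spec_ni Specificity tables for each mode.
#' @param threshold Node specificity threshold (default 90).
#' @param abundance_top_n Per-herb abundance override count (default 0 =
#'   off).
#' @return Tibble sorted by herb then area descending: `label`,
#'   `herb_code`, `area`, `feature_id_pi`, `feature_id_ni`, `share_pi`,
#'   `share_ni`, `min_share`, `single_mode`, `status`,
#'   `retained_by_abundance`.
#' @export
select_markers <- function(assign_pi, assign_ni, spec_pi, spec_ni,
                           threshold = 90, abundance_top_n = 0) {
  herb_share <- function(spec, fid, herb) {
    if (is.na(fid) || is.null(spec)) return(NA_real_)
    row <- match(fid, spec$feature_id)
    if (is.na(row)) return(NA_real_)
    col <- paste0("share_", herb)
    if (!col %in% names(spec)) return(NA_real_)
    spec[[col]][row]
  }
  base <- if (!is.null(assign_pi)) {
    assign_pi |> select("label", "herb_code", "area", feature_id_pi = "feature_id")
  } else {
    assign_ni |> select("label", "herb_code", "area") |>
      mutate(feature_id_pi = NA_integer_)
  }
  if (!is.null(assign_ni)) {
    base <- full_join(
      base,
      assign_ni |> select("label", "herb_code", "area", feature_id_ni = "feature_id"),
      by = c("label", "herb_code", "area")
    )
  } else {
    base$feature_id_ni <- NA_integer_
  }
  out <- base |>
    mutate(
      share_pi = purrr::map2_dbl(.data$feature_id_pi, .data$herb_code,
                                 ~ herb_share(spec_pi, .x, .y)),
      share_ni = purrr::map2_dbl(.data$feature_id_ni, .data$herb_code,
                                 ~ herb_share(spec_ni, .x, .y)),
      single_mode = xor(is.na(.data$feature_id_pi), is.na(.data$feature_id_ni)),
      min_share = pmin(.data$share_pi, .data$share_ni, na.rm = TRUE),
      min_share = ifelse(is.na(.data$feature_id_pi) & is.na(.data$feature_id_ni),
                         NA_real_, .data$min_share),
      status = case_when(
        is.na(.data$feature_id_pi) & is.na(.data$feature_id_ni) ~ "not_in_formula",
        !is.na(.data$min_share) & .data$min_share >= threshold ~ "specific",
        TRUE ~ "non_specific"
      )
    )
  out <- out |>
    group_by(.data$herb_code) |>
    arrange(desc(.data$area), .by_group = TRUE) |>
    mutate(retained_by_abundance = .data$status == "non_specific" &
             row_number() <= abundance_top_n) |>
    ungroup() |>
    arrange(.data$herb_code, desc(.data$area))
  out
}

#' Tabulate marker specificity bins
#'
#' Bins specific markers by their per-mode specificity share: exactly 100%,
#' 95-99%, and 90-94% (the report bins used to summarise marker quality).
#'
#' @param markers Marker tibble from [select_markers()].
#' @param mode `"pi"` or `"ni"` — which mode's share to bin.
#' @return Tibble `bin`, `n`; attribute `total` gives the summed count.
#' @export
marker_specificity_bins <- function(markers, mode = c("pi", "ni")) {
  mode <- match.arg(mode)
  sh <- markers[[paste0("share_", mode)]]
  sh <- sh[!is.na(sh) & sh >= 90]
  out <- tibble(
    bin = c("100", "95-99", "90-94"),
    n = c(sum(sh >= 100 - 1e-9),
          sum(sh >= 95 & sh < 100 - 1e-9),
          sum(sh >= 90 & sh < 95))
  )
  attr(out, "total") <- sum(out$n)
  out
}
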