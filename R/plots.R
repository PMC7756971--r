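#' Data behind a 2D feature map
#'
#' One point per formula-detected feature in RT x m/z space. Points are
#' colored by their specific herb (at the table's node threshold) or left
#' unfilled when non-specific. Size is fixed, proportional to formula
#' height, or proportional to assigned ELSD area; with ELSD sizing, points
#' above the 99th percentile of area are clamped to it and flagged
#' (`clamped`), generalizing the half-scale display of dominant peaks.
#'
#' @param spec Specificity table.
#' @param size_mode `"fixed"`, `"height"` or `"elsd"`.
#' @param areas Optional tibble (`feature_id`, `area`) from
#'   [assign_areas()]; required for `size_mode = "elsd"`.
#' @return Tibble `feature_id`, `rt`, `mz`, `herb_code` (NA = unassigned),
#'   `specific`, `size_value`, `clamped`.
#' @export
feature_map_data <- function(spec, size_mode = c("fixed", "height", "elsd"),
                             areas = NULL) {
  size_mode <- match.arg(size_mode)
  pts <- spec |>
    filter(.data$in_formula) |>
    transmute(.data$feature_id, .data$rt, .data$mz,
              herb_code = .data$specific_herb,
              specific = !is.na(.data$specific_herb),
              formula_height = .data$formula_height)
  if (size_mode == "fixed") {
    pts$size_value <- 1
    pts$clamped <- FALSE
  } else if (size_mode == "height") {
    pts$size_value <- pts$formula_height
    pts$clamped <- FALSE
  } else {
    if (is.null(areas)) {
      abort("size_mode = 'elsd' requires an areas table",
            class = "formulanet_config_error")
    }
    pts <- inner_join(pts, areas[c("feature_id", "area")], by = "feature_id")
    cap <- stats::quantile(pts$area, 0.99, names = FALSE)
    pts$clamped <- pts$area > cap
    pts$size_value <- pmin(pts$area, cap)
  }
  select(pts, "feature_id", "rt", "mz", "herb_code", "specific",
         "size_value", "clamped")
}

#' Plot a 2D feature map
#'
#' Scatter plot of formula-detected features (RT vs m/z): specific features
#' as colored dots inside a black circle, non-specific features as unfilled
#' outlined points.
#'
#' @inheritParams feature_map_data
#' @param manifest Sample manifest (supplies herb colors when present).
#' @return A ggplot object whose `$data` is the [feature_map_data()] twin.
#' @export
plot_feature_map <- function(spec, manifest, size_mode = "fixed",
                             areas = NULL) {
  pts <- feature_map_data(spec, size_mode = size_mode, areas = areas)
  pal <- herb_palette(manifest)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$rt, y = .data$mz)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$size_value),
                        shape = 21, fill = NA, color = "black") +
    ggplot2::geom_point(
      data = pts[pts$specific, ],
      ggplot2::aes(color = .data$herb_code, size = .data$size_value * 0.6)
    ) +
    ggplot2::scale_color_manual(values = pal, na.value = "grey70",
                                name = "herb") +
    ggplot2::scale_size_area(max_size = 6, guide = "none") +
    ggplot2::labs(x = "retention time (min)", y = "m/z (Da)") +
    ggplot2::theme_minimal()
  p
}

#' Plot a bar chromatogram
#'
#' Depicts a multi-component signature as bars of formula height at member
#' retention times, optionally over the full formula profile as context.
#'
#' @param signature Records from [extract_signature()].
#' @param profile Optional tibble (`rt`, `height`) of the full formula
#'   profile, drawn as grey context bars.
#' @return A ggplot object.
#' @export
plot_bar_chromatogram <- function(signature, profile = NULL) {
  p <- ggplot2::ggplot(signature,
                       ggplot2::aes(x = .data$rt, y = .data$height))
  if (!is.null(profile)) {
    p <- p + ggplot2::geom_segment(
      data = profile,
      ggplot2::aes(x = .data$rt, xend = .data$rt, y = 0, yend = .data$height),
      color = "grey80", inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$rt, y = 0,
                                       yend = .data$height),
                          linewidth = 1.1) +
    ggplot2::labs(x = "retention time (min)", y = "feature height") +
    ggplot2::theme_minimal()
}

#' Export ring-style node attributes for graph rendering
#'
#' Per-node attribute table suitable for pie/ring rendering in a graph
#' viewer: formula height (node size), per-herb share columns (ring
#' segments, summing to 100 for scored nodes), specific herb and cluster
#' id.
#'
#' @param network A `molecular_network`.
#' @param spec Specificity table.
#' @return Tibble keyed by `feature_id`.
#' @export
export_ring_attributes <- function(network, spec) {
  stopifnot(inherits(network, "molecular_network"))
  network$nodes |>
    left_join(spec, by = "feature_id") |>
    select("feature_id", "cluster_id", "mz", "rt", "in_formula",
           "formula_height", starts_with("share_"), "specific_herb")
}

# herb colors from manifest, or a deterministic fallback palette
herb_palette <- function(manifest) {
  herbs <- manifest[manifest$role == "herb", ]
  cols <- herbs$herb_color
  if (any(is.na(cols) | !nzchar(cols))) {
    fallback <- grDevices::hcl.colors(max(nrow(herbs), 3), palette = "Dark 3")
    cols <- ifelse(is.na(cols) | !nzchar(cols),
                   fallback[seq_len(nrow(herbs))], cols)
  }
  setNames(cols, herbs$herb_code)
}
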