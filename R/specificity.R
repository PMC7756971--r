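#' Blank-derived feature rule
#'
#' A feature is considered blank-derived (laboratory or solvent contaminant)
#' if its maximum blank height is at least `ratio` times its maximum herb
#' height (`method = "ratio"`), or if it is detected at all in any blank
#' (`method = "any"`). A feature detected only in blanks (all herb heights 0)
#' is always blank-derived.
#'
#' @param method `"ratio"` (default) or `"any"`.
#' @param ratio Blank/herb height ratio threshold (default 0.5).
#' @return A `blank_rule` list.
#' @export
blank_rule <- function(method = c("ratio", "any"), ratio = 0.5) {
  method <- match.arg(method)
  stopifnot(ratio >= 0)
  structure(list(method = method, ratio = ratio), class = "blank_rule")
}

#' Filter features to formula-detected, non-blank features
#'
#' Retains only aligned features with a positive height in the formula
#' sample and not flagged as blank-derived under `rule`. This is the
#' reduction applied before specificity counting: features detected in herbs
#' but not in the formula, and blank contaminants, are deleted.
#'
#' @param ft Feature table.
#' @param manifest Sample manifest.
#' @param rule A [blank_rule()].
#' @return The filtered feature table (mode attribute preserved).
#' @export
filter_features <- function(ft, manifest, rule = blank_rule()) {
  manifest <- validate_manifest(manifest)
  f_col <- manifest_formula_sample(manifest)
  herb_cols <- manifest_herb_samples(manifest)
  blank_cols <- manifest_blank_samples(manifest)
  in_formula <- ft[[f_col]] > 0
  if (length(blank_cols) > 0) {
    max_blank <- do.call(pmax, c(ft[blank_cols], list(0)))
    max_herb <- do.call(pmax, c(ft[herb_cols], list(0)))
    blank_derived <- switch(rule$method,
      ratio = max_blank > 0 & max_blank >= rule$ratio * max_herb,
      any = max_blank > 0
    )
  } else {
    blank_derived <- rep(FALSE, nrow(ft))
  }
  out <- ft[in_formula & !blank_derived, ]
  attr(out, "mode") <- attr(ft, "mode")
  out
}

#' Node specificity percentages
#'
#' For every feature, the height in each herb extract divided by the sum of
#' its heights across all herbs, times 100. The denominator includes herb
#' samples only (formula and blank heights are excluded). Features with an
#' all-zero herb total get `NA` shares and are excluded from specific
#' counts.
#'
#' @param ft Feature table (typically after [filter_features()]).
#' @param manifest Sample manifest.
#' @param node_threshold Specificity percentage at or above which a feature
#'   is called specific to its top herb (default 90, inclusive).
#' @return A specificity table: tibble with `feature_id`, `mz`, `rt`,
#'   `in_formula`, `formula_height`, one `share_<herb>` column per herb (in
#'   percent), `max_share`, and `specific_herb` (`NA` when below threshold
#'   or undefined). Attributes: `herbs`, `mode`, `node_threshold`.
#' @export
node_specificity <- function(ft, manifest, node_threshold = 90) {
  manifest <- validate_manifest(manifest)
  stopifnot(node_threshold > 0, node_threshold <= 100)
  herb_map <- manifest_herb_map(manifest)
  herbs <- unname(herb_map)
  f_col <- manifest_formula_sample(manifest)

  hmat <- as.matrix(ft[names(herb_map)])
  # sum heights of samples sharing a herb code (usually 1:1)
  if (anyDuplicated(herbs)) {
    hmat <- t(rowsum(t(hmat), group = herbs))
    herbs <- colnames(hmat)
  } else {
    colnames(hmat) <- herbs
  }
  total <- rowSums(hmat)
  # divide before scaling so a single-source feature is exactly 100
  shares <- (hmat / ifelse(total > 0, total, NA_real_)) * 100
  max_share <- apply(shares, 1, function(x) if (all(is.na(x))) NA_real_ else max(x))
  top_herb <- colnames(shares)[max.col(replace(shares, is.na(shares), -1),
                                       ties.method = "first")]
  specific <- !is.na(max_share) & max_share >= node_threshold

  out <- tibble(
    feature_id = ft$feature_id,
    mz = ft$mz,
    rt = ft$rt,
    in_formula = ft[[f_col]] > 0,
    formula_height = ft[[f_col]]
  )
  share_tbl <- as_tibble(shares)
  names(share_tbl) <- paste0("share_", colnames(shares))
  out <- bind_cols(out, share_tbl) |>
    mutate(max_share = max_share,
           specific_herb = ifelse(specific, top_herb, NA_character_))
  attr(out, "herbs") <- colnames(shares)
  attr(out, "mode") <- attr(ft, "mode")
  attr(out, "node_threshold") <- node_threshold
  out
}

spec_herbs <- function(spec) {
  attr(spec, "herbs") %||% sub("^share_", "", grep("^share_", names(spec), value = TRUE))
}

#' Count specific features per herb
#'
#' Counts formula-detected features whose top specificity share is at or
#' above `threshold`, per herb, with each herb's percentage of the total
#' specific-feature count (rounded to one decimal, matching report
#' precision).
#'
#' @param spec Specificity table from [node_specificity()].
#' @param threshold Specificity percentage threshold (default 90, inclusive).
#' @return Tibble `herb_code`, `n_specific`, `pct_of_specific`, with
#'   attribute `total` (also `sum(n_specific)`).
#' @export
count_specific <- function(spec, threshold = 90) {
  herbs <- spec_herbs(spec)
  shares <- as.matrix(spec[paste0("share_", herbs)])
  eligible <- spec$in_formula & !is.na(spec$max_share)
  counts <- vapply(seq_along(herbs), function(j) {
    sum(eligible & shares[, j] >= threshold, na.rm = TRUE)
  }, integer(1))
  total <- sum(counts)
  out <- tibble(
    herb_code = herbs,
    n_specific = counts,
    pct_of_specific = if (total > 0) round(100 * counts / total, 1) else 0
  )
  attr(out, "total") <- total
  out
}

#' Cluster specificity percentages
#'
#' For each cluster (connected component of size >= 2), the unweighted
#' arithmetic mean of its member features' specificity shares per herb. By
#' default only formula-detected members with defined shares are averaged
#' (`members = "formula"`); `members = "all"` averages every scored member.
#' A cluster's dominant herb is assigned where the maximum mean share is at
#' or above `cluster_threshold` (inclusive).
#'
#' @param spec Specificity table.
#' @param network A `molecular_network` whose nodes carry cluster ids.
#' @param cluster_threshold Mean-share percentage threshold (default 75).
#' @param members `"formula"` (default) or `"all"`.
#' @return Tibble `cluster_id`, `n_nodes` (members averaged), one
#'   `mean_share_<herb>` column per herb, `max_mean_share`, `dominant_herb`.
#'   Clusters with zero scored members are excluded with a warning.
#' @export
cluster_specificity <- function(spec, network, cluster_threshold = 75,
                                members = c("formula", "all")) {
  members <- match.arg(members)
  stopifnot(inherits(network, "molecular_network"),
            cluster_threshold > 0, cluster_threshold <= 100)
  herbs <- spec_herbs(spec)
  share_cols <- paste0("share_", herbs)

  joined <- inner_join(network$nodes, spec, by = "feature_id") |>
    filter(.data$cluster_id > 0, !is.na(.data$max_share))
  if (members == "formula") joined <- filter(joined, .data$in_formula)

  all_clusters <- sort(unique(network$nodes$cluster_id[network$nodes$cluster_id > 0]))
  ct <- joined |>
    group_by(.data$cluster_id) |>
    summarise(n_nodes = n(),
              across(all_of(share_cols), ~ mean(.x), .names = "mean_{.col}"),
              .groups = "drop")
  lost <- setdiff(all_clusters, ct$cluster_id)
  if (length(lost) > 0) {
    warn(paste0("cluster(s) with no scored member excluded: ",
                paste(lost, collapse = ", ")))
  }
  mean_cols <- paste0("mean_share_", herbs)
  mmat <- as.matrix(ct[mean_cols])
  max_mean <- apply(mmat, 1, max)
  top <- herbs[max.col(mmat, ties.method = "first")]
  ct |>
    mutate(max_mean_share = max_mean,
           dominant_herb = ifelse(max_mean >= cluster_threshold, top,
                                  NA_character_)) |>
    arrange(.data$cluster_id)
}

#' Count herb-specific clusters
#'
#' @param ct Cluster specificity table from [cluster_specificity()].
#' @param network The `molecular_network` the clusters came from.
#' @return One-row tibble: `n_specific_clusters`, `pct_of_clusters`,
#'   `n_nodes_in_specific`, `pct_of_nodes` (percentages against all clusters
#'   and all nodes, rounded to the nearest integer).
#' @export
count_specific_clusters <- function(ct, network) {
  s <- network_summary(network)
  spec_ids <- ct$cluster_id[!is.na(ct$dominant_herb)]
  n_spec <- length(spec_ids)
  n_nodes_in <- sum(network$nodes$cluster_id %in% spec_ids)
  tibble(
    n_specific_clusters = n_spec,
    pct_of_clusters = if (s$n_clusters > 0) round(100 * n_spec / s$n_clusters) else 0,
    n_nodes_in_specific = n_nodes_in,
    pct_of_nodes = if (s$n_nodes > 0) round(100 * n_nodes_in / s$n_nodes) else 0
  )
}

#' Export the member features of one cluster
#'
#' Returns the HRMS descriptors (m/z, retention time, formula height,
#' shares) of every scored member of a cluster, sorted by retention time —
#' the per-cluster export used to build bar chromatograms.
#'
#' @param spec Specificity table.
#' @param network A `molecular_network`.
#' @param cluster_id Cluster id (>= 1).
#' @return Tibble of member records sorted by RT ascending.
#' @export
export_cluster_features <- function(spec, network, cluster_id) {
  stopifnot(inherits(network, "molecular_network"))
  if (!(cluster_id %in% network$nodes$cluster_id) || cluster_id < 1) {
    abort(sprintf("unknown cluster id: %s", cluster_id),
          class = "formulanet_lookup_error")
  }
  ids <- network$nodes$feature_id[network$nodes$cluster_id == cluster_id]
  spec |>
    filter(.data$feature_id %in% ids) |>
    arrange(.data$rt)
}
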