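#' Classify clusters into multi-component-signature categories
#'
#' Assigns each qualifying cluster exactly one category:
#' \describe{
#'   \item{1}{herb-specific cluster (dominant herb set) containing at least
#'     one formally identified marker (anchor).}
#'   \item{2}{non-specific cluster containing an anchor; member list
#'     restricted to nodes specific (share at or above `node_threshold`) to
#'     the anchor's herb.}
#'   \item{3}{herb-specific cluster with no anchor but at least one
#'     taxonomically consistent annotation among its members.}
#' }
#' Clusters qualifying for none are omitted.
#'
#' @param ct Cluster specificity table from [cluster_specificity()].
#' @param network A `molecular_network`.
#' @param anchors Anchor tibble (`feature_id`, `label`, `herb_code`,
#'   `compound_class`, ...); every anchor feature must be a network node.
#' @param spec Specificity table (for category-2 member extraction).
#' @param annotations Optional annotation tibble with `feature_id` and
#'   `taxon_level` (for category 3); `NULL` disables category 3.
#' @param node_threshold Node specificity threshold (default 90).
#' @return Tibble `cluster_id`, `category`, `herb_code`, `n_members`,
#'   `anchor_ids` and `member_ids` list-columns.
#' @export
classify_signature_clusters <- function(ct, network, anchors, spec,
                                        annotations = NULL,
                                        node_threshold = 90) {
  stopifnot(inherits(network, "molecular_network"))
  missing_anchor <- setdiff(anchors$feature_id, network$nodes$feature_id)
  if (length(missing_anchor) > 0) {
    abort(paste0("anchor feature(s) absent from network: ",
                 paste(missing_anchor, collapse = ", ")),
          class = "formulanet_config_error")
  }
  anchor_cluster <- network$nodes$cluster_id[
    match(anchors$feature_id, network$nodes$feature_id)]

  rows <- purrr::map(seq_len(nrow(ct)), function(k) {
    cid <- ct$cluster_id[k]
    members <- network$nodes$feature_id[network$nodes$cluster_id == cid]
    a_idx <- which(anchor_cluster == cid)
    dominant <- ct$dominant_herb[k]
    has_anchor <- length(a_idx) > 0
    if (has_anchor && !is.na(dominant)) {
      category <- 1L
      herb <- dominant
      member_ids <- members
    } else if (has_anchor && is.na(dominant)) {
      category <- 2L
      herb <- anchors$herb_code[a_idx[1]]
      col <- paste0("share_", herb)
      sub <- spec |>
        filter(.data$feature_id %in% members,
               !is.na(.data[[col]]), .data[[col]] >= node_threshold)
      member_ids <- union(anchors$feature_id[a_idx], sub$feature_id)
    } else if (!has_anchor && !is.na(dominant) && !is.null(annotations)) {
      member_ann <- annotations |>
        filter(.data$feature_id %in% members,
               .data$taxon_level %in% c("species", "genus", "family"))
      if (nrow(member_ann) == 0) return(NULL)
      category <- 3L
      herb <- dominant
      member_ids <- members
    } else {
      return(NULL)
    }
    tibble(cluster_id = cid, category = category, herb_code = herb,
           n_members = length(member_ids),
           anchor_ids = list(anchors$feature_id[a_idx]),
           member_ids = list(sort(member_ids)))
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(tibble(cluster_id = integer(), category = integer(),
                  herb_code = character(), n_members = integer(),
                  anchor_ids = list(), member_ids = list()))
  }
  arrange(out, .data$cluster_id)
}

#' Extract a bar-chromatogram record set for a signature cluster
#'
#' Returns one record per member (retention time, formula height, label),
#' sorted by RT, with co-eluting members collapsed: among members whose RTs
#' agree within `rt_tol` (in-source fragments/adducts of one compound), only
#' the highest-formula-height member is kept.
#'
#' @param sig One row of [classify_signature_clusters()] output (or any list
#'   with `member_ids`).
#' @param spec Specificity table (provides `rt` and `formula_height`).
#' @param rt_tol In-source collapse RT tolerance in minutes (default 0.02).
#' @param labels Optional tibble (`feature_id`, `label`) of display labels.
#' @return Tibble `feature_id`, `rt`, `height`, `label`, sorted by RT.
#' @export
extract_signature <- function(sig, spec, rt_tol = 0.02, labels = NULL) {
  member_ids <- if (is.data.frame(sig)) sig$member_ids[[1]] else sig$member_ids
  rec <- spec |>
    filter(.data$feature_id %in% member_ids) |>
    arrange(.data$rt) |>
    select("feature_id", "rt", height = "formula_height")
  if (nrow(rec) == 0) return(mutate(rec, label = character(0)))
  # group runs of RTs whose consecutive gaps are within rt_tol
  grp <- cumsum(c(1, diff(rec$rt) > rt_tol))
  rec <- rec |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    arrange(desc(.data$height), .data$feature_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".grp") |>
    arrange(.data$rt)
  if (!is.null(labels)) {
    rec <- left_join(rec, labels, by = "feature_id")
  } else {
    rec$label <- NA_character_
  }
  rec
}
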