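#' Read a spectral annotation library
#'
#' A library is an MGF of reference spectra plus a CSV sidecar keyed by
#' `entry_id` with columns `name`, `molecular_formula`, `species`, `genus`,
#' `family`, `compound_class`, `adduct`. Entry spectra are matched to
#' sidecar rows by the MGF `FEATURE_ID`/`SCANS` field. The monoisotopic mass
#' implied by each formula is checked against the declared adduct precursor
#' (5 ppm) with a warning on mismatch.
#'
#' @param mgf_path MGF file of reference spectra.
#' @param csv_path CSV sidecar path.
#' @return A library tibble with one row per entry, including a `peaks`
#'   list-column, `precursor_mz` and `monoisotopic_mass`.
#' @export
read_spectral_library <- function(mgf_path, csv_path) {
  spectra <- read_mgf(mgf_path)
  meta <- readr::read_csv(csv_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  names(meta) <- tolower(names(meta))
  meta$entry_id <- as.integer(meta$entry_id)
  lib <- inner_join(meta, spectra, by = c(entry_id = "feature_id"))
  lib$monoisotopic_mass <- formula_mass(lib$molecular_formula)
  implied <- ifelse(lib$adduct == "[M-H]-",
                    lib$monoisotopic_mass - .proton_mass,
                    lib$monoisotopic_mass + .proton_mass)
  off <- abs(lib$precursor_mz - implied) / implied * 1e6
  if (any(off > 5)) {
    warn(paste0("library entries with precursor/formula mismatch > 5 ppm: ",
                paste(lib$entry_id[off > 5], collapse = ", ")))
  }
  as_tibble(lib)
}

#' Match a spectrum against a spectral library
#'
#' Candidates are library entries whose adduct precursor mass matches the
#' query precursor within `mz_tol`; they are scored by modified cosine and
#' the `top_n` best above `cosine_min` are returned with ranks.
#'
#' @param spec One-row spectra tibble (the query).
#' @param library Library tibble from [read_spectral_library()].
#' @param mz_tol Precursor tolerance in Da (default 0.005).
#' @param cosine_min Score floor (default 0.2).
#' @param top_n Candidates kept (default 6).
#' @param fragment_tol Fragment tolerance for the cosine (default 0.02).
#' @return Tibble `feature_id`, `entry_id`, `name`, `molecular_formula`,
#'   `compound_class`, `species`, `genus`, `family`, `cosine`,
#'   `matched_peaks`, `rank`.
#' @export
match_library <- function(spec, library, mz_tol = 0.005, cosine_min = 0.2,
                          top_n = 6, fragment_tol = 0.02) {
  stopifnot(nrow(library) >= 1)
  q_prec <- spec$precursor_mz[1]
  cand <- library[abs(library$precursor_mz - q_prec) <= mz_tol, ]
  empty <- tibble(feature_id = integer(), entry_id = integer(),
                  name = character(), molecular_formula = character(),
                  compound_class = character(), species = character(),
                  genus = character(), family = character(),
                  cosine = numeric(), matched_peaks = integer(),
                  rank = integer())
  if (nrow(cand) == 0) return(empty)
  scores <- purrr::map(seq_len(nrow(cand)), function(i) {
    modified_cosine(
      list(precursor_mz = q_prec, peaks = spec$peaks[[1]]),
      list(precursor_mz = cand$precursor_mz[i], peaks = cand$peaks[[i]]),
      fragment_tol = fragment_tol
    )
  })
  cand$cosine <- purrr::map_dbl(scores, "cosine")
  cand$matched_peaks <- purrr::map_int(scores, "matched_peaks")
  cand <- cand[cand$cosine >= cosine_min, ]
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(-cand$cosine, cand$entry_id), ]
  cand <- head(cand, top_n)
  tibble(
    feature_id = spec$feature_id[1],
    entry_id = cand$entry_id,
    name = cand$name,
    molecular_formula = cand$molecular_formula,
    compound_class = cand$compound_class,
    species = cand$species,
    genus = cand$genus,
    family = cand$family,
    cosine = cand$cosine,
    matched_peaks = cand$matched_peaks,
    rank = seq_len(nrow(cand))
  )
}

#' Re-rank annotation candidates by taxonomic consistency
#'
#' Candidates whose library taxon matches the feature's specific herb are
#' promoted: species-level matches first, then genus, then family, then
#' unmatched, with the original cosine order preserved within each level
#' (stable sort). Cosine values are unchanged; when `herb_taxonomy` is
#' `NULL` (feature not specific to any herb) the order is returned as-is.
#'
#' @param cands Candidate tibble from [match_library()].
#' @param herb_taxonomy `NULL`, or a list/row with `species`, `genus`,
#'   `family` of the feature's specific herb.
#' @return The candidates with `taxon_level` added and `rank` rewritten.
#' @export
taxonomic_rerank <- function(cands, herb_taxonomy = NULL) {
  if (nrow(cands) == 0) return(mutate(cands, taxon_level = character(0)))
  level <- rep("none", nrow(cands))
  if (!is.null(herb_taxonomy)) {
    tx <- herb_taxonomy
    match_at <- function(cand_val, herb_val) {
      !is.na(cand_val) & nzchar(cand_val) & !is.null(herb_val) &
        !is.na(herb_val %||% NA) & cand_val == (herb_val %||% "")
    }
    level[match_at(cands$family, tx$family)] <- "family"
    level[match_at(cands$genus, tx$genus)] <- "genus"
    level[match_at(cands$species, tx$species)] <- "species"
  }
  pri <- c(species = 1, genus = 2, family = 3, none = 4)
  ord <- order(pri[level], cands$rank)
  out <- cands[ord, ]
  out$taxon_level <- level[ord]
  out$rank <- seq_len(nrow(out))
  out
}

#' Propagate anchor-point information within a cluster
#'
#' Anchor points are formally identified nodes (NMR after isolation, or
#' RT + m/z match to a pure standard). For every non-anchor member of the
#' cluster, annotation candidates whose compound class equals an anchor's
#' class are promoted ahead of the others; within each group the taxonomic
#' re-rank order applies. Members gain co-marker labels `Co-<anchor>-k`
#' numbered by retention time ascending.
#'
#' @param network A `molecular_network`.
#' @param cluster_id Cluster to annotate.
#' @param anchors Anchor tibble: `feature_id`, `name`, `label`,
#'   `molecular_formula`, `compound_class`, `herb_code`.
#' @param cands Annotation candidates for the cluster's members (rows from
#'   [match_library()], possibly after [taxonomic_rerank()]).
#' @param spec Specificity table (provides member retention times).
#' @return A list: `co_labels` (tibble `feature_id`, `co_label`, `rt`) and
#'   `annotations` (re-ranked candidates with `promoted` flag). A cluster
#'   without an anchor is a no-op with a notice.
#' @export
propagate_from_anchor <- function(network, cluster_id, anchors, cands, spec) {
  stopifnot(inherits(network, "molecular_network"))
  member_ids <- network$nodes$feature_id[network$nodes$cluster_id == cluster_id]
  anchor_here <- anchors[anchors$feature_id %in% member_ids, ]
  if (nrow(anchor_here) == 0) {
    inform(sprintf("cluster %d has no anchor point; annotations unchanged",
                   cluster_id))
    return(list(co_labels = tibble(feature_id = integer(),
                                   co_label = character(), rt = numeric()),
                annotations = mutate(cands, promoted = FALSE)))
  }
  anchor_classes <- unique(anchor_here$compound_class)
  anchor_label <- anchor_here$label[1]

  co <- spec |>
    filter(.data$feature_id %in% setdiff(member_ids, anchor_here$feature_id)) |>
    arrange(.data$rt) |>
    transmute(.data$feature_id,
              co_label = paste0("Co-", anchor_label, "-", row_number()),
              .data$rt)

  ann <- cands |>
    filter(.data$feature_id %in% member_ids) |>
    mutate(promoted = .data$compound_class %in% anchor_classes) |>
    group_by(.data$feature_id) |>
    arrange(desc(.data$promoted), .data$rank, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  list(co_labels = co, annotations = ann)
}
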