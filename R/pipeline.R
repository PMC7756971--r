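#' Workflow configuration
#'
#' Collects every stage's parameters with the workflow defaults: network
#' (0.02 Da fragment tolerance, cosine 0.7, 6 matched peaks, top-50 mutual
#' rank), specificity (90% node / 75% cluster thresholds), ELSD (0.004
#' area floor, 0.1 min RT tolerance), library annotation (0.005 Da, cosine
#' 0.2, top 6), cross-mode pairing (0.05 min, 10 ppm) and in-source
#' collapse (0.02 min). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(...) {
  defaults <- list(
    fragment_tol = 0.02, cosine_min = 0.7, min_matched = 6L, top_k = 50L,
    node_threshold = 90, cluster_threshold = 75,
    blank_ratio = 0.5,
    elsd_min_area = 0.004, elsd_rt_tol = 0.1,
    library_mz_tol = 0.005, library_cosine_min = 0.2, library_top_n = 6,
    pair_rt_tol = 0.05, pair_ppm_tol = 10,
    collapse_rt_tol = 0.02
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown workflow config key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "formulanet_config_error")
  }
  defaults[names(over)] <- over
  structure(defaults, class = "workflow_config")
}

#' Run the end-to-end workflow on an input bundle
#'
#' Executes network construction, specificity, ELSD integration, marker
#' selection and signature classification for both ionization modes, and
#' (when `out_dir` is given) writes a deterministic set of CSV reports plus
#' GraphML network exports. The run is a pure function of (inputs, config):
#' rerunning on the same bundle reproduces byte-identical reports. When the
#' bundle has no ELSD table the marker stage is skipped with a notice and
#' the specificity outputs are still produced.
#'
#' @param bundle A list with `manifest`, `features_pi`, `features_ni`,
#'   `spectra_pi`, `spectra_ni` and optionally `elsd` (as produced by
#'   [generate_dataset()] or assembled from the readers).
#' @param config A [workflow_config()].
#' @param out_dir Optional output directory for reports.
#' @param anchors Optional anchor tibble (`feature_id`, `label`,
#'   `herb_code`, `compound_class`) used for signature classification;
#'   ids refer to PI features (NI handled via cross-mode pairs).
#' @param library Optional spectral library (see
#'   [read_spectral_library()]); when supplied, every ELSD-assigned feature
#'   with a spectrum is annotated against it.
#' @return A list of per-mode results (`network`, `spec`, `cluster_spec`,
#'   `counts`, `summary`), plus `markers`, `signatures`, `pairs` and
#'   `config`.
#' @export
run_workflow <- function(bundle, config = workflow_config(), out_dir = NULL,
                         anchors = NULL, library = NULL) {
  stopifnot(inherits(config, "workflow_config"))
  manifest <- validate_manifest(bundle$manifest)
  params <- network_params(fragment_tol = config$fragment_tol,
                           cosine_min = config$cosine_min,
                           min_matched = config$min_matched,
                           top_k = config$top_k)
  rule <- blank_rule(ratio = config$blank_ratio)

  run_mode <- function(ft, spectra, mode) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("stage '%s' (%s) failed: %s", what, mode,
                      conditionMessage(e)),
              class = "formulanet_stage_error")
      })
    }
    network <- stage("network", build_network(spectra, params, mode = mode))
    kept <- stage("filter", filter_features(ft, manifest, rule))
    spec <- stage("specificity",
                  node_specificity(kept, manifest,
                                   node_threshold = config$node_threshold))
    cspec <- stage("cluster_specificity", suppressWarnings(
      cluster_specificity(spec, network,
                          cluster_threshold = config$cluster_threshold)))
    list(network = network, features = ft, spec = spec, cluster_spec = cspec,
         counts = count_specific(spec, config$node_threshold),
         cluster_counts = count_specific_clusters(cspec, network),
         summary = network_summary(network))
  }

  pi <- run_mode(bundle$features_pi, bundle$spectra_pi, "PI")
  ni <- run_mode(bundle$features_ni, bundle$spectra_ni, "NI")
  pairs <- pair_cross_mode(bundle$features_pi, bundle$features_ni,
                           rt_tol = config$pair_rt_tol,
                           ppm_tol = config$pair_ppm_tol)

  markers <- NULL
  elsd_labeled <- NULL
  if (!is.null(bundle$elsd)) {
    elsd_labeled <- bundle$elsd |>
      filter_elsd_peaks(min_area = config$elsd_min_area) |>
      label_elsd_peaks()
    a_pi <- match_elsd_to_features(elsd_labeled, bundle$features_pi, pi$spec,
                                   manifest, rt_tol = config$elsd_rt_tol)
    a_ni <- match_elsd_to_features(elsd_labeled, bundle$features_ni, ni$spec,
                                   manifest, rt_tol = config$elsd_rt_tol)
    markers <- select_markers(a_pi, a_ni, pi$spec, ni$spec,
                              threshold = config$node_threshold)
  } else {
    inform("no ELSD table in bundle; marker stage skipped")
  }

  annotations <- NULL
  if (!is.null(library) && !is.null(markers)) {
    ann_ids <- unique(stats::na.omit(c(markers$feature_id_pi,
                                       markers$feature_id_ni)))
    sp <- bind_rows(bundle$spectra_pi, bundle$spectra_ni)
    sp <- sp[sp$feature_id %in% ann_ids, ]
    annotations <- purrr::map(seq_len(nrow(sp)), function(i) {
      match_library(sp[i, ], library,
                    mz_tol = config$library_mz_tol,
                    cosine_min = config$library_cosine_min,
                    top_n = config$library_top_n,
                    fragment_tol = config$fragment_tol)
    }) |> bind_rows()
  }

  signatures <- NULL
  if (!is.null(anchors)) {
    signatures <- classify_signature_clusters(
      pi$cluster_spec, pi$network, anchors, pi$spec,
      node_threshold = config$node_threshold)
  }

  result <- list(pi = pi, ni = ni, pairs = pairs, markers = markers,
                 annotations = annotations, signatures = signatures,
                 elsd = elsd_labeled, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, name) {
      if (!is.null(x)) readr::write_csv(x, file.path(out_dir, name))
    }
    for (mode in c("pi", "ni")) {
      r <- result[[mode]]
      wr(r$summary, paste0("network_summary_", mode, ".csv"))
      wr(r$spec, paste0("specificity_", mode, ".csv"))
      wr(r$cluster_spec, paste0("cluster_specificity_", mode, ".csv"))
      wr(r$counts, paste0("specific_counts_", mode, ".csv"))
      wr(r$cluster_counts, paste0("specific_cluster_counts_", mode, ".csv"))
      write_network_graphml(
        r$network, file.path(out_dir, paste0("network_", mode, ".graphml")),
        attrs = export_ring_attributes(r$network, r$spec))
    }
    wr(pairs, "cross_mode_pairs.csv")
    if (!is.null(markers)) wr(markers, "markers.csv")
    if (!is.null(annotations)) wr(annotations, "annotations.csv")
    if (!is.null(signatures)) {
      wr(signatures |>
           mutate(anchor_ids = purrr::map_chr(.data$anchor_ids,
                                              ~ paste(.x, collapse = ";")),
                  member_ids = purrr::map_chr(.data$member_ids,
                                              ~ paste(.x, collapse = ";"))),
         "signatures.csv")
    }
  }
  result
}
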