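#' Molecular-network construction parameters
#'
#' @param fragment_tol Fragment (and precursor-shift) m/z tolerance in Da.
#' @param cosine_min Minimum modified-cosine score for an edge.
#' @param min_matched Minimum number of matched peaks for an edge.
#' @param top_k Mutual rank cut: an edge survives only if each endpoint is
#'   within the other's `top_k` most similar surviving neighbors.
#' @param strict_matched If `TRUE`, require strictly more than `min_matched`
#'   matched peaks (the literal "more than six" reading) instead of the
#'   GNPS-style `>= min_matched` default.
#' @return A `network_params` list.
#' @export
network_params <- function(fragment_tol = 0.02, cosine_min = 0.7,
                           min_matched = 6L, top_k = 50L,
                           strict_matched = FALSE) {
  stopifnot(fragment_tol > 0, cosine_min >= 0, cosine_min <= 1, top_k >= 0)
  structure(list(fragment_tol = fragment_tol, cosine_min = cosine_min,
                 min_matched = as.integer(min_matched),
                 top_k = as.integer(top_k),
                 strict_matched = isTRUE(strict_matched)),
            class = "network_params")
}

#' Build a feature-based molecular network
#'
#' Computes all pairwise modified-cosine similarities, keeps pairs passing
#' the cosine and matched-peak thresholds, prunes edges by the mutual top-K
#' rule (each endpoint must rank within the other's `top_k` most similar
#' surviving neighbors, ties broken by lower feature id), and assigns cluster
#' indices to connected components of size >= 2, numbered by descending
#' component size with ties broken by smallest member feature id. Singletons
#' carry the sentinel cluster id -1.
#'
#' @param spectra Spectra tibble (see [read_mgf()]).
#' @param params A [network_params()] list.
#' @param mode Ionization mode tag stored on the network.
#' @return A `molecular_network` object: list with `mode`, `nodes` (tibble
#'   `feature_id`, `cluster_id`), `edges` (tibble `node_a`, `node_b`,
#'   `cosine`, `matched_peaks` with `node_a < node_b`), and `params`.
#' @export
build_network <- function(spectra, params = network_params(), mode = "PI") {
  stopifnot(nrow(spectra) >= 1)
  spectra <- arrange(spectra, .data$feature_id)
  n <- nrow(spectra)
  norm <- purrr::map(spectra$peaks, normalize_spectrum)
  prec <- spectra$precursor_mz
  ids <- spectra$feature_id

  edges <- vector("list", 0)
  if (n >= 2) {
    pairs <- combn(n, 2)
    res <- purrr::map(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      cand <- .candidate_pairs(norm[[i]], norm[[j]], prec[i], prec[j],
                               params$fragment_tol)
      .greedy_assign(cand, nrow(norm[[i]]), nrow(norm[[j]]))
    })
    cos <- purrr::map_dbl(res, "cosine")
    mat <- purrr::map_int(res, "matched_peaks")
    pass <- cos >= params$cosine_min &
      (if (params$strict_matched) mat > params$min_matched
       else mat >= params$min_matched)
    edges <- tibble(
      node_a = ids[pairs[1, pass]],
      node_b = ids[pairs[2, pass]],
      cosine = cos[pass],
      matched_peaks = mat[pass]
    )
  } else {
    edges <- tibble(node_a = integer(), node_b = integer(),
                    cosine = numeric(), matched_peaks = integer())
  }

  edges <- .mutual_top_k(edges, params$top_k)
  nodes <- .assign_clusters(ids, edges)
  structure(list(mode = mode, nodes = nodes, edges = edges, params = params),
            class = "molecular_network")
}

# keep an edge iff both endpoints rank it within their top-k neighbors
# (by cosine descending, ties by lower partner feature id)
.mutual_top_k <- function(edges, top_k) {
  if (nrow(edges) == 0 || top_k == 0) {
    return(edges[0, ])
  }
  long <- bind_rows(
    tibble(node = edges$node_a, partner = edges$node_b,
           cosine = edges$cosine, edge = seq_len(nrow(edges))),
    tibble(node = edges$node_b, partner = edges$node_a,
           cosine = edges$cosine, edge = seq_len(nrow(edges)))
  ) |>
    group_by(.data$node) |>
    arrange(desc(.data$cosine), .data$partner, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  ok <- long |>
    group_by(.data$edge) |>
    summarise(keep = all(.data$rank <= top_k), .groups = "drop")
  edges[sort(ok$edge[ok$keep]), ]
}

# connected components -> cluster ids (>=2 members), numbered by size desc,
# ties by smallest member feature id; singletons get -1
.assign_clusters <- function(ids, edges) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$node_a),
                   to = as.character(edges$node_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(sort(ids)))
  )
  comp <- igraph::components(g)
  member <- comp$membership[as.character(sort(ids))]
  sizes <- comp$csize
  comp_ids <- which(sizes >= 2)
  if (length(comp_ids) > 0) {
    min_fid <- vapply(comp_ids, function(cid) {
      min(sort(ids)[member == cid])
    }, numeric(1))
    ord <- order(-sizes[comp_ids], min_fid)
    relabel <- setNames(seq_along(comp_ids), comp_ids[ord])
  } else {
    relabel <- setNames(integer(0), character(0))
  }
  cluster_id <- ifelse(sizes[member] >= 2,
                       relabel[as.character(member)],
                       -1L)
  tibble(feature_id = sort(ids), cluster_id = as.integer(cluster_id))
}

#' Summarise a molecular network
#'
#' @param network A `molecular_network`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_clusters`,
#'   `n_clustered_nodes`, `n_singletons`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "molecular_network"))
  clustered <- network$nodes$cluster_id > 0
  tibble(
    n_nodes = nrow(network$nodes),
    n_edges = nrow(network$edges),
    n_clusters = length(unique(network$nodes$cluster_id[clustered])),
    n_clustered_nodes = sum(clustered),
    n_singletons = sum(!clustered)
  )
}

#' @export
print.molecular_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<molecular_network %s> %d nodes, %d edges, %d clusters (%d clustered, %d singletons)\n",
    x$mode, s$n_nodes, s$n_edges, s$n_clusters, s$n_clustered_nodes, s$n_singletons))
  invisible(x)
}

#' Tidy a molecular network into its edge list
#'
#' @param x A `molecular_network`.
#' @param ... Unused.
#' @return The edge tibble (`node_a`, `node_b`, `cosine`, `matched_peaks`).
#' @export
tidy.molecular_network <- function(x, ...) x$edges

#' One-row network summary (broom-style)
#'
#' @param x A `molecular_network`.
#' @param ... Unused.
#' @return See [network_summary()].
#' @export
glance.molecular_network <- function(x, ...) network_summary(x)

#' Export a molecular network to GraphML
#'
#' Writes the network with per-node attributes (joined from `attrs` by
#' `feature_id`) and edge attributes `cosine` and `matched_peaks`, readable
#' by Cytoscape or igraph. Non-finite attribute values are serialized as
#' empty strings with a warning.
#'
#' @param network A `molecular_network`.
#' @param attrs Optional tibble of node attributes with a `feature_id`
#'   column (e.g. from [export_ring_attributes()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, attrs = NULL) {
  stopifnot(inherits(network, "molecular_network"))
  verts <- network$nodes |> mutate(name = as.character(.data$feature_id))
  if (!is.null(attrs)) {
    attrs <- attrs |> mutate(feature_id = as.integer(.data$feature_id))
    verts <- left_join(verts, attrs, by = "feature_id")
  }
  num_cols <- names(verts)[vapply(verts, is.numeric, logical(1))]
  bad <- FALSE
  for (cl in num_cols) {
    nf <- !is.finite(verts[[cl]])
    if (any(nf)) {
      bad <- TRUE
      verts[[cl]] <- as.character(verts[[cl]])
      verts[[cl]][nf] <- ""
    }
  }
  if (bad) warn("non-finite node attribute values serialized as empty strings")
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(network$edges$node_a),
                   to = as.character(network$edges$node_b),
                   cosine = network$edges$cosine,
                   matched_peaks = network$edges$matched_peaks),
    directed = FALSE,
    vertices = as.data.frame(verts[c("name", setdiff(names(verts), "name"))])
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
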