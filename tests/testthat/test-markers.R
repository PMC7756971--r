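test_that("cross-mode pairing agrees with proton-mass arithmetic", {
  # [M+H]+ 303.0499 and [M-H]- 301.0354 both imply neutral ~302.0427
  man <- tiny_manifest(c("A", "B"), ww = c(0.5, 0.5))
  pi_ft <- tiny_feature_table(matrix(1, 2, 4), man[-5, ],
                              mz = c(303.0499, 450.1), rt = c(5, 6))
  ni_ft <- tiny_feature_table(matrix(1, 2, 4), man[-5, ],
                              mz = c(301.0354, 448.0), rt = c(5.01, 9))
  pairs <- pair_cross_mode(pi_ft, ni_ft, rt_tol = 0.05, ppm_tol = 10)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$feature_id_pi, 1L)
  expect_equal(pairs$feature_id_ni, 1L)
  expect_lte(abs(pairs$mass_delta_ppm), 10)

  # same masses but RT 0.5 min apart: unpaired
  ni_far <- ni_ft; ni_far$rt <- c(5.5, 9)
  expect_equal(nrow(pair_cross_mode(pi_ft, ni_far, rt_tol = 0.1)), 0)

  # empty NI table: everything unpaired
  expect_equal(nrow(pair_cross_mode(pi_ft, ni_ft[0, ])), 0)
})

test_that("cross-mode pairing is one-to-one by combined distance", {
  man <- tiny_manifest(c("A", "B"), ww = c(0.5, 0.5))
  m <- 302.0427
  pi_ft <- tiny_feature_table(matrix(1, 1, 4), man[-5, ],
                              mz = m + 1.007276, rt = 5)
  # two NI candidates; the closer one (in RT) must win
  ni_ft <- tiny_feature_table(matrix(1, 2, 4), man[-5, ],
                              mz = rep(m - 1.007276, 2), rt = c(5.04, 5.005))
  pairs <- pair_cross_mode(pi_ft, ni_ft, rt_tol = 0.05, ppm_tol = 10)
  expect_equal(pairs$feature_id_ni, 2L)
})

test_that("marker status reflects specificity in every detected mode", {
  b <- small_bundle()
  res <- run_workflow(b, workflow_config(top_k = 10))
  m <- res$markers
  tm <- b$truth$metabolites

  # planted single-herb markers: all specific
  planted <- tm$met_id[tm$is_planted_marker]
  pred <- m$feature_id_pi[m$status == "specific"]
  pred[is.na(pred)] <- m$feature_id_ni[m$status == "specific"][is.na(pred)]
  expect_setequal(pred, planted)

  # ubiquitous ELSD peaks have no specific feature to attach to
  expect_true(all(m$status %in% c("specific", "non_specific",
                                  "not_in_formula")))
  ubi_ids <- tm$met_id[tm$is_ubiquitous]
  expect_false(any(ubi_ids %in% pred))

  # single-mode features are flagged, not hidden
  one_mode <- tm$met_id[xor(tm$in_pi, tm$in_ni) & tm$is_planted_marker]
  if (length(one_mode) > 0) {
    rows <- m[!is.na(m$feature_id_pi) & m$feature_id_pi %in% one_mode |
                !is.na(m$feature_id_ni) & m$feature_id_ni %in% one_mode, ]
    expect_true(all(rows$single_mode))
  }

  # lowering the threshold never removes a specific marker
  m80 <- select_markers(
    match_elsd_to_features(res$elsd, b$features_pi, res$pi$spec, b$manifest),
    match_elsd_to_features(res$elsd, b$features_ni, res$ni$spec, b$manifest),
    res$pi$spec, res$ni$spec, threshold = 80)
  expect_true(all(m$label[m$status == "specific"] %in%
                    m80$label[m80$status == "specific"]))
})

test_that("specificity bins partition markers at 100 / 95-99 / 90-94", {
  m <- tibble::tibble(share_pi = c(rep(100, 26), rep(97, 12), rep(92, 2), 85),
                      share_ni = c(rep(100, 24), rep(96, 8), rep(91, 2),
                                   rep(NA, 7)))
  bp <- marker_specificity_bins(m, "pi")
  expect_equal(bp$n, c(26L, 12L, 2L))
  expect_equal(attr(bp, "total"), 40L)
  bn <- marker_specificity_bins(m, "ni")
  expect_equal(bn$n, c(24L, 8L, 2L))
  expect_equal(attr(bn, "total"), 34L)
})

test_that("signature clusters classify into the three categories", {
  net <- structure(list(
    mode = "PI",
    nodes = tibble::tibble(
      feature_id = c(1:3, 4:6, 7:9),
      cluster_id = c(rep(1L, 3), rep(2L, 3), rep(3L, 3))),
    edges = tibble::tibble(node_a = c(1L, 4L, 7L), node_b = c(2L, 5L, 8L),
                           cosine = 0.9, matched_peaks = 7L),
    params = network_params()
  ), class = "molecular_network")
  ct <- tibble::tibble(
    cluster_id = 1:3, n_nodes = 3L,
    dominant_herb = c("SM", NA, "O"))
  spec <- tibble::tibble(
    feature_id = 1:9,
    rt = 1:9 / 2,
    share_PR = c(0, 0, 0, 100, 95, 20, 0, 0, 0),
    formula_height = 10)
  anchors <- tibble::tibble(feature_id = c(1L, 4L), label = c("SM1", "PR1"),
                            herb_code = c("SM", "PR"),
                            compound_class = c("flavanone", "rosmarinic lignan"))
  ann <- tibble::tibble(feature_id = 8L, taxon_level = "species")
  out <- classify_signature_clusters(ct, net, anchors, spec,
                                     annotations = ann, node_threshold = 90)
  expect_equal(out$category, c(1L, 2L, 3L))
  expect_equal(out$herb_code, c("SM", "PR", "O"))
  # category 2 restricted to nodes specific to the anchor's herb
  expect_equal(out$member_ids[[2]], c(4L, 5L))
  # anchors must exist in the network
  bad <- anchors; bad$feature_id[1] <- 999L
  expect_error(classify_signature_clusters(ct, net, bad, spec),
               "999", class = "formulanet_config_error")
  # without annotations, category 3 cannot be assigned
  out2 <- classify_signature_clusters(ct, net, anchors, spec,
                                      annotations = NULL)
  expect_equal(out2$category, c(1L, 2L))
})

test_that("signature extraction collapses co-eluting in-source features", {
  spec <- tibble::tibble(
    feature_id = c(1L, 2L, 3L),
    rt = c(2.00, 2.01, 5.00),
    formula_height = c(50, 80, 30))
  sig <- list(member_ids = c(1L, 2L, 3L))
  out <- extract_signature(sig, spec, rt_tol = 0.02)
  expect_equal(nrow(out), 2)
  expect_equal(out$feature_id, c(2L, 3L))  # max height of the co-eluting pair
  expect_equal(out$rt, c(2.01, 5.00))

  # all distinct RTs: identity
  spec2 <- spec; spec2$rt <- c(1, 2, 3)
  out2 <- extract_signature(sig, spec2, rt_tol = 0.02)
  expect_equal(out2$feature_id, 1:3)

  # at least one bar always remains
  spec3 <- spec; spec3$rt <- c(2.00, 2.005, 2.01)
  expect_equal(nrow(extract_signature(sig, spec3, rt_tol = 0.02)), 1)
})
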