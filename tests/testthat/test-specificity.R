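test_that("feature filtering keeps formula-detected, non-blank features", {
  man <- tiny_manifest()
  # cols: F, H_A, H_B, H_C, BLK
  h <- rbind(
    c(0, 100, 0, 0, 0),    # in herbs but not formula -> removed
    c(10, 100, 0, 0, 0),   # clean -> retained
    c(10, 100, 0, 0, 60),  # blank 0.6x max herb height -> removed
    c(10, 100, 0, 0, 40),  # blank 0.4x max herb height -> retained
    c(10, 0, 0, 0, 1)      # blank-only detection -> removed
  )
  ft <- tiny_feature_table(h, man)
  kept <- filter_features(ft, man)
  expect_equal(kept$feature_id, c(2L, 4L))
  # strict any-blank mode
  strict <- filter_features(ft, man, blank_rule("any"))
  expect_equal(strict$feature_id, 2L)
})

test_that("filtering requires a formula sample", {
  man <- tiny_manifest()
  herbs_only <- man[man$role != "formula", ]
  ft <- tiny_feature_table(matrix(1, 1, 5), man)
  expect_error(filter_features(ft, herbs_only),
               class = "formulanet_validation_error")
})

test_that("node specificity shares follow the herb-height ratios", {
  man <- tiny_manifest(herbs = c("A", "B", "C"))
  h <- rbind(
    c(5, 100, 0, 0, 0),
    c(5, 10, 10, 10, 0),
    c(5, 30, 10, 60, 0),
    c(5, 0, 0, 0, 0)  # undefined shares
  )
  spec <- node_specificity(tiny_feature_table(h, man), man)
  expect_equal(unname(unlist(spec[1, c("share_A", "share_B", "share_C")])),
               c(100, 0, 0))
  expect_equal(unname(unlist(spec[2, c("share_A", "share_B", "share_C")])),
               rep(100 / 3, 3))
  expect_equal(unname(unlist(spec[3, c("share_A", "share_B", "share_C")])),
               c(30, 10, 60))
  expect_true(is.na(spec$max_share[4]))
  expect_equal(spec$specific_herb, c("A", NA, NA, NA))
})

test_that("shares sum to 100 and are scale-invariant across random tables", {
  man <- tiny_manifest(herbs = paste0("H", 1:10),
                       ww = rep(0.1, 10))
  set.seed(123)
  n <- 10000
  h <- cbind(runif(n, 1, 10),
             matrix(rexp(n * 10), n, 10),
             0)
  spec <- node_specificity(tiny_feature_table(h, man), man)
  sums <- rowSums(as.matrix(spec[paste0("share_H", 1:10)]))
  expect_true(all(abs(sums - 100) <= 1e-6))
  # global rescaling of herb heights leaves shares unchanged
  h2 <- h; h2[, 2:11] <- h2[, 2:11] * 1000
  spec2 <- node_specificity(tiny_feature_table(h2, man), man)
  expect_equal(spec2[paste0("share_H", 1:10)], spec[paste0("share_H", 1:10)],
               tolerance = 1e-12)
})

test_that("specific counts are threshold-monotone and recover planted features", {
  b <- small_bundle()
  kept <- filter_features(b$features_pi, b$manifest)
  spec <- node_specificity(kept, b$manifest)
  totals <- vapply(seq(50, 100, by = 10), function(th) {
    attr(count_specific(spec, th), "total")
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
  # zero cross-herb leakage: threshold 100 recovers exactly the planted
  # single-herb features present in this mode
  tm <- b$truth$metabolites
  planted <- tm |>
    dplyr::filter(!is.na(herb_code), in_pi) |>
    dplyr::count(herb_code)
  at100 <- count_specific(spec, 100)
  expect_equal(at100$n_specific[match(planted$herb_code, at100$herb_code)],
               planted$n)
})

test_that("cluster specificity averages member shares with inclusive threshold", {
  man <- tiny_manifest(herbs = c("A", "B", "C"))
  h <- rbind(
    c(5, 100, 0, 0, 0),
    c(5, 50, 50, 0, 0),
    c(5, 100, 0, 0, 0),
    c(5, 10, 80, 10, 0)
  )
  spec <- node_specificity(tiny_feature_table(h, man), man)
  net <- structure(list(
    mode = "PI",
    nodes = tibble::tibble(feature_id = 1:4,
                           cluster_id = c(1L, 1L, 2L, 2L)),
    edges = tibble::tibble(node_a = c(1L, 3L), node_b = c(2L, 4L),
                           cosine = c(0.9, 0.9), matched_peaks = c(7L, 7L)),
    params = network_params()
  ), class = "molecular_network")
  ct <- cluster_specificity(spec, net, cluster_threshold = 75)
  # cluster 1: (100% A) and (50% A, 50% B) -> A 75, B 25; dominant at 75 (inclusive)
  expect_equal(ct$mean_share_A[1], 75)
  expect_equal(ct$mean_share_B[1], 25)
  expect_equal(ct$dominant_herb[1], "A")
  # cluster 2: A 55, B 40 -> top mean 55 < 75, no dominant herb
  expect_equal(ct$mean_share_A[2], 55)
  expect_true(is.na(ct$dominant_herb[2]))
  # means bounded by member-wise min/max
  expect_gte(ct$mean_share_A[1], 50)
  expect_lte(ct$mean_share_A[1], 100)
})

test_that("a cluster averaging below threshold is non-specific", {
  # mirrors a mixed cluster whose top herb only reaches 68.9%
  man <- tiny_manifest(herbs = c("PR", "SC", "SO"))
  h <- rbind(
    c(5, 100, 0, 0, 0),
    c(5, 67.8, 32.2, 0, 0),
    c(5, 38.9, 0, 61.1, 0)
  )
  spec <- node_specificity(tiny_feature_table(h, man), man)
  net <- structure(list(
    mode = "NI",
    nodes = tibble::tibble(feature_id = 1:3, cluster_id = rep(1L, 3)),
    edges = tibble::tibble(node_a = c(1L, 2L), node_b = c(2L, 3L),
                           cosine = c(0.8, 0.8), matched_peaks = c(7L, 7L)),
    params = network_params()
  ), class = "molecular_network")
  ct <- cluster_specificity(spec, net, cluster_threshold = 75)
  expect_equal(ct$mean_share_PR, mean(c(100, 67.8, 38.9)), tolerance = 1e-9)
  expect_equal(round(ct$mean_share_PR, 1), 68.9)
  expect_true(is.na(ct$dominant_herb))
})

test_that("specific-cluster counting reports integer percentages", {
  ct <- tibble::tibble(cluster_id = 1:4, n_nodes = c(3L, 2L, 2L, 5L),
                       dominant_herb = c("A", NA, "B", NA))
  net <- structure(list(
    mode = "PI",
    nodes = tibble::tibble(
      feature_id = 1:15,
      cluster_id = c(rep(1L, 3), rep(2L, 2), rep(3L, 2), rep(4L, 5),
                     rep(-1L, 3))),
    edges = tibble::tibble(node_a = integer(), node_b = integer(),
                           cosine = numeric(), matched_peaks = integer()),
    params = network_params()
  ), class = "molecular_network")
  out <- count_specific_clusters(ct, net)
  expect_equal(out$n_specific_clusters, 2)
  expect_equal(out$pct_of_clusters, 50)
  expect_equal(out$n_nodes_in_specific, 5)
  expect_equal(out$pct_of_nodes, 33)  # 5/15
})

test_that("cluster export is RT-sorted and rejects unknown clusters", {
  man <- tiny_manifest()
  h <- matrix(c(5, 9, 1, 0, 0,
                5, 8, 2, 0, 0,
                5, 7, 3, 0, 0), 3, 5, byrow = TRUE)
  ft <- tiny_feature_table(h, man, rt = c(3.2, 1.1, 2.4))
  spec <- node_specificity(ft, man)
  net <- structure(list(
    mode = "PI",
    nodes = tibble::tibble(feature_id = 1:3, cluster_id = rep(1L, 3)),
    edges = tibble::tibble(node_a = c(1L, 2L), node_b = c(2L, 3L),
                           cosine = c(0.8, 0.8), matched_peaks = c(7L, 7L)),
    params = network_params()
  ), class = "molecular_network")
  out <- export_cluster_features(spec, net, 1)
  expect_equal(out$feature_id, c(2L, 3L, 1L))
  expect_error(export_cluster_features(spec, net, 99),
               class = "formulanet_lookup_error")
  expect_error(export_cluster_features(spec, net, -1),
               class = "formulanet_lookup_error")
  # CSV round trip preserves values
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(out, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$rt, out$rt)
  expect_equal(back$share_A, out$share_A)
})
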