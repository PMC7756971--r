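test_that("manifest validation enforces its invariants", {
  man <- tiny_manifest()
  expect_silent(validate_manifest(man))

  dup <- man; dup$sample_id[2] <- "F"
  expect_error(validate_manifest(dup), class = "formulanet_validation_error")

  two_f <- dplyr::bind_rows(man, man[1, ] |> dplyr::mutate(sample_id = "F2"))
  expect_error(validate_manifest(two_f), class = "formulanet_validation_error")

  bad_ww <- man; bad_ww$ww_proportion[man$role == "herb"] <- c(0.5, 0.4, 0.2)
  expect_error(validate_manifest(bad_ww), class = "formulanet_validation_error")
})

test_that("manifest round-trips through CSV and YAML", {
  man <- tiny_manifest(c("A", "B"), ww = c(0.3, 0.7))
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(man, csv)
  expect_equal(read_manifest(csv)$ww_proportion, man$ww_proportion)

  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(purrr::transpose(man), yml)
  man2 <- read_manifest(yml)
  expect_equal(man2$sample_id, man$sample_id)
  expect_equal(man2$herb_code, man$herb_code)
})

test_that("feature tables parse in both dialects and validate", {
  man <- tiny_manifest()
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "row ID,row m/z,row retention time,F Peak height,H_A Peak height,H_B Peak height,H_C Peak height,BLK Peak height",
    "1,301.1,2.5,100,90,10,0,0",
    "2,455.2,5.1,50,,25,25,0",
    "3,512.9,8.0,10,0,0,9,1"
  ), csv)
  ft <- read_feature_table(csv, man, "PI")
  expect_equal(nrow(ft), 3)
  expect_equal(ft$H_A[2], 0)  # empty cell read as "not detected"
  expect_equal(ft$mz, c(301.1, 455.2, 512.9))
  expect_equal(attr(ft, "mode"), "PI")

  plain <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,mz,rt,F,H_A,H_B,H_C,BLK",
    "1,301.1,2.5,100,90,10,0,0",
    "2,455.2,5.1,50,0,25,25,0"
  ), plain)
  ft2 <- read_feature_table(plain, man, "NI")
  expect_equal(ft2$F, c(100, 50))
})

test_that("feature table reader flags format problems", {
  man <- tiny_manifest()
  no_rt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mz,F,H_A,H_B,H_C,BLK", "1,301.1,1,1,1,1,0"), no_rt)
  expect_error(read_feature_table(no_rt, man), class = "formulanet_format_error")

  extra <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mz,rt,F,H_A,H_B,H_C,BLK,H_X",
               "1,301.1,2.5,1,1,1,1,0,5"), extra)
  expect_warning(ft <- read_feature_table(extra, man), "H_X")
  expect_false("H_X" %in% names(ft))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mz,rt,F,H_A,H_B,H_C,BLK",
               "1,301.1,2.5,1,1,1,1,0", "1,302.1,2.6,1,1,1,1,0"), dup)
  expect_error(read_feature_table(dup, man), class = "formulanet_validation_error")
})

test_that("feature table parsing is row-order independent", {
  man <- tiny_manifest()
  rows <- sprintf("%d,%0.1f,%0.1f,%d,%d,%d,%d,0", 1:6, 300 + 1:6, 1:6,
                  1:6 * 10, 1:6, 6:1, rep(1, 6))
  a <- withr::local_tempfile(fileext = ".csv")
  b <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mz,rt,F,H_A,H_B,H_C,BLK", rows), a)
  writeLines(c("id,mz,rt,F,H_A,H_B,H_C,BLK", rev(rows)), b)
  expect_equal(read_feature_table(a, man), read_feature_table(b, man))
})

test_that("MGF spectra round-trip and are normalized on read", {
  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "FEATURE_ID=7", "PEPMASS=301.1", "CHARGE=1+",
    "150.0 5", "100.0 10", "120.0 0",
    "END IONS", "",
    "BEGIN IONS", "SCANS=9", "PEPMASS=455.2 1e5", "CHARGE=1-",
    "200.0 1",
    "END IONS"
  ), mgf)
  sp <- read_mgf(mgf)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$precursor_mz, c(301.1, 455.2))
  expect_equal(sp$charge, c(1L, -1L))
  # unsorted peaks sorted, zero-intensity dropped
  expect_equal(sp$peaks[[1]][, "mz"], c(100, 150))

  set.seed(11)
  many <- dplyr::bind_rows(lapply(1:50, random_spectrum))
  out <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(many, out)
  back <- read_mgf(out)
  expect_equal(back$feature_id, many$feature_id)
  for (i in 1:50) {
    expect_equal(back$peaks[[i]], many$peaks[[i]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("MGF blocks without a feature id are parse errors", {
  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=301.1", "100 1", "END IONS"), mgf)
  expect_error(read_mgf(mgf), "block 1", class = "formulanet_parse_error")
})

test_that("ELSD tables read, validate, and reject unknown herbs", {
  man <- tiny_manifest()
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("herb,rt,area", sprintf("A,%0.1f,%0.3f", 1:47 / 4, 1:47 / 100)), csv)
  expect_equal(nrow(read_elsd_table(csv, man)), 47)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("herb,rt,area", "Z,1.0,0.5"), bad)
  expect_error(read_elsd_table(bad, man), class = "formulanet_validation_error")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("herb,rt,area", "A,1.0,-0.5"), neg)
  expect_error(read_elsd_table(neg, man), class = "formulanet_validation_error")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("herb,rt,area", empty)
  expect_equal(nrow(read_elsd_table(empty, man)), 0)
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  skip_if_not_installed("xml2")
  set.seed(3)
  sp <- dplyr::bind_rows(lapply(1:2, random_spectrum))
  # hand-built 5-node path network (4 edges)
  net <- structure(list(
    mode = "PI",
    nodes = tibble::tibble(feature_id = 1:5,
                           cluster_id = c(1L, 1L, 1L, 1L, 1L)),
    edges = tibble::tibble(node_a = 1:4, node_b = 2:5,
                           cosine = c(0.9, 0.8, 0.85, 0.75),
                           matched_peaks = c(7L, 8L, 6L, 9L)),
    params = network_params()
  ), class = "molecular_network")
  path <- withr::local_tempfile(fileext = ".graphml")
  attrs <- tibble::tibble(feature_id = 1:5, mz = 100 + 1:5, note = letters[1:5])
  write_network_graphml(net, path, attrs = attrs)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  expect_equal(sort(igraph::E(g)$cosine), sort(net$edges$cosine))
  expect_equal(sort(igraph::V(g)$mz), 101:105)

  # empty network still yields a readable file
  empty_net <- structure(list(
    mode = "PI",
    nodes = tibble::tibble(feature_id = integer(), cluster_id = integer()),
    edges = tibble::tibble(node_a = integer(), node_b = integer(),
                           cosine = numeric(), matched_peaks = integer()),
    params = network_params()
  ), class = "molecular_network")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(empty_net, p2)
  expect_equal(igraph::vcount(igraph::read_graph(p2, format = "graphml")), 0)

  # non-finite attributes serialized as empty with a warning
  attrs$mz[2] <- NaN
  p3 <- withr::local_tempfile(fileext = ".graphml")
  expect_warning(write_network_graphml(net, p3, attrs = attrs), "non-finite")
})
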