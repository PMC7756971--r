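# shared fixtures and independent oracles

tiny_manifest <- function(herbs = c("A", "B", "C"), ww = NULL) {
  if (is.null(ww)) ww <- rep(1 / length(herbs), length(herbs))
  dplyr::bind_rows(
    tibble::tibble(sample_id = "F", role = "formula", herb_code = NA_character_,
                   herb_color = NA_character_, ww_proportion = NA_real_),
    tibble::tibble(sample_id = paste0("H_", herbs), role = "herb",
                   herb_code = herbs, herb_color = NA_character_,
                   ww_proportion = ww),
    tibble::tibble(sample_id = "BLK", role = "blank",
                   herb_code = NA_character_, herb_color = NA_character_,
                   ww_proportion = NA_real_)
  )
}

# feature table from a matrix of heights (rows = features, cols = samples)
tiny_feature_table <- function(heights, manifest, mz = NULL, rt = NULL,
                               mode = "PI") {
  n <- nrow(heights)
  ft <- tibble::tibble(
    feature_id = seq_len(n),
    mz = mz %||% (100 + seq_len(n)),
    rt = rt %||% seq_len(n)
  )
  hm <- tibble::as_tibble(as.data.frame(heights), .name_repair = "minimal")
  names(hm) <- manifest$sample_id
  validate_feature_table(dplyr::bind_cols(ft, hm), manifest, mode)
}

random_spectrum <- function(id, n_peaks = sample(3:8, 1),
                            mz_range = c(50, 500), prec = runif(1, 400, 600)) {
  spectrum_record(id, prec,
                  cbind(sort(runif(n_peaks, mz_range[1], mz_range[2])),
                        runif(n_peaks, 0.1, 1)))
}

# a related pair: b shares some of a's peaks (jittered within tol), some
# shifted by the precursor difference, plus noise peaks
related_spectrum_pair <- function(id_a = 1L, id_b = 2L, tol = 0.02) {
  n <- sample(4:8, 1)
  a <- random_spectrum(id_a, n_peaks = n)
  prec_b <- a$precursor_mz + runif(1, -80, 80)
  pk <- a$peaks[[1]]
  shared <- sample(c(TRUE, FALSE), n, replace = TRUE)
  shift <- prec_b - a$precursor_mz
  mz_b <- ifelse(shared, pk[, 1], pk[, 1] + shift) + runif(n, -tol / 2, tol / 2)
  keep <- sample(n, sample(2:n, 1))
  extra <- sample(0:2, 1)
  mz_b <- c(mz_b[keep], runif(extra, 50, 500))
  int_b <- c(pk[keep, 2] * runif(length(keep), 0.5, 1.5), runif(extra, 0.1, 1))
  b <- spectrum_record(id_b, prec_b, cbind(mz_b, int_b))
  list(a = a, b = b)
}

# exhaustive maximum-weight one-to-one assignment of candidate peak pairs,
# enumerating per-peak partner choices: the independent oracle for the
# greedy modified-cosine assignment
brute_force_cosine <- function(a, b, fragment_tol = 0.02) {
  na <- normalize_spectrum(a$peaks[[1]])
  nb <- normalize_spectrum(b$peaks[[1]])
  d <- outer(na[, "mz"], nb[, "mz"], `-`)
  hit <- abs(d) <= fragment_tol |
    abs(d - (a$precursor_mz - b$precursor_mz)) <= fragment_tol
  cand <- lapply(seq_len(nrow(na)), function(i) which(hit[i, ]))
  best_score <- 0; best_matched <- 0L
  recurse <- function(i, used_b, score, matched) {
    if (i > nrow(na)) {
      if (score > best_score + 1e-15 ||
          (abs(score - best_score) <= 1e-15 && matched > best_matched)) {
        best_score <<- score; best_matched <<- matched
      }
      return(invisible())
    }
    recurse(i + 1, used_b, score, matched)  # peak i unmatched
    for (j in cand[[i]]) {
      if (!used_b[j]) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, score + na[i, "weight"] * nb[j, "weight"],
                matched + 1L)
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1, logical(nrow(nb)), 0, 0L)
  list(cosine = min(best_score, 1), matched_peaks = best_matched)
}

# small synthetic bundle for fast end-to-end tests
small_bundle <- function(seed = 7) {
  generate_dataset(synth_config(
    n_herbs = 4, families_per_herb = 2, members_per_family = 3,
    n_ubiquitous = 2, n_contaminants = 2, seed = seed
  ))
}
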