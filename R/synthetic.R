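#' Synthetic multi-herb dataset configuration
#'
#' Describes the generative model used for end-to-end validation: per-herb
#' metabolite families sharing fragmentation templates, ubiquitous
#' metabolites present in every herb, a formula whose feature heights are a
#' w/w-weighted mixture of herb signals with multiplicative lognormal noise,
#' ELSD areas decoupled from MS response through per-metabolite ionization
#' factors, and blank contaminants.
#'
#' @param n_herbs Number of herbs (default 10).
#' @param families_per_herb Analogue families per herb (default 4).
#' @param members_per_family Members per family (default 5).
#' @param n_ubiquitous Metabolites shared equally by all herbs (default 6).
#' @param n_contaminants Blank contaminants (default 5).
#' @param ww_proportions Herb w/w proportions; default mirrors a typical
#'   10-herb decoction recipe (normalized to sum 1). Length `n_herbs`.
#' @param herb_codes Herb codes; defaults to the standard letter codes for
#'   10 herbs, else `H01`, `H02`, ...
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on every height/area (default 0.1).
#' @param conc_meanlog,conc_sdlog Lognormal concentration distribution
#'   (arbitrary mass units).
#' @param ion_meanlog,ion_sdlog Lognormal per-metabolite, per-mode
#'   ionization factor (counts per mass unit), decoupling MS height from
#'   ELSD area.
#' @param elsd_response Area per unit concentration (ionization-independent).
#' @param elsd_min_area Area floor used to flag planted markers (default
#'   0.004, the workflow's ELSD filter).
#' @param mode_exclusive_frac Fraction of herb metabolites emitted in only
#'   one ionization mode (default 0.1).
#' @param cross_herb_leakage Fraction of a single-herb metabolite's
#'   concentration leaking into every other herb (default 0: strictly
#'   herb-specific metabolites). Positive values emulate trace cross-herb
#'   occurrence of nominally specific components.
#' @param n_fragments Fragment peaks per spectrum (default 8).
#' @param rt_range,mz_range Retention time (min) and neutral-mass (Da)
#'   ranges.
#' @param seed RNG seed; the full dataset is a pure function of the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_herbs = 10, families_per_herb = 4,
                         members_per_family = 5, n_ubiquitous = 6,
                         n_contaminants = 5, ww_proportions = NULL,
                         herb_codes = NULL, noise_cv = 0.1,
                         conc_meanlog = log(5e4), conc_sdlog = 1.2,
                         ion_meanlog = log(10), ion_sdlog = 0.8,
                         elsd_response = 1e-6, elsd_min_area = 0.004,
                         mode_exclusive_frac = 0.1,
                         cross_herb_leakage = 0, n_fragments = 8,
                         rt_range = c(0.5, 12), mz_range = c(250, 900),
                         seed = 42) {
  if (is.null(herb_codes)) {
    herb_codes <- if (n_herbs == 10) {
      c("A", "C", "G", "I", "O", "PO", "PR", "SC", "SM", "SO")
    } else {
      sprintf("H%02d", seq_len(n_herbs))
    }
  }
  if (is.null(ww_proportions)) {
    ww_proportions <- if (n_herbs == 10) {
      w <- c(3.4, 6.9, 3.4, 6.9, 20.7, 10.3, 13.8, 6.9, 20.7, 6.9)
      w / sum(w)
    } else {
      rep(1 / n_herbs, n_herbs)
    }
  }
  stopifnot(length(herb_codes) == n_herbs,
            length(ww_proportions) == n_herbs,
            abs(sum(ww_proportions) - 1) < 1e-6,
            families_per_herb >= 0, members_per_family >= 1,
            n_ubiquitous >= 0, n_contaminants >= 0, noise_cv >= 0,
            cross_herb_leakage >= 0, cross_herb_leakage < 1)
  structure(list(
    n_herbs = n_herbs, families_per_herb = families_per_herb,
    members_per_family = members_per_family, n_ubiquitous = n_ubiquitous,
    n_contaminants = n_contaminants, ww_proportions = ww_proportions,
    herb_codes = herb_codes, noise_cv = noise_cv,
    conc_meanlog = conc_meanlog, conc_sdlog = conc_sdlog,
    ion_meanlog = ion_meanlog, ion_sdlog = ion_sdlog,
    elsd_response = elsd_response, elsd_min_area = elsd_min_area,
    mode_exclusive_frac = mode_exclusive_frac,
    cross_herb_leakage = cross_herb_leakage, n_fragments = n_fragments,
    rt_range = rt_range, mz_range = mz_range, seed = seed
  ), class = "synth_config")
}

# multiplicative lognormal noise factors with mean 1 and given cv
.noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic multi-herb dataset with ground truth
#'
#' Emits the full input bundle of the workflow: aligned feature tables for
#' both ionization modes, MS/MS spectra, an ELSD peak table, a sample
#' manifest and a ground-truth record. Members of one analogue family share
#' a fragmentation template (half of the fragments fixed, half shifted with
#' the precursor), so the modified cosine within a family is high by
#' construction while across families no systematic matches exist.
#' Retention times of the metabolites of any one herb are placed on
#' jittered, well-separated slots so ELSD-to-feature assignment is
#' identifiable; ubiquitous metabolites occupy a reserved early RT window.
#'
#' @param config A [synth_config()].
#' @return A list: `manifest`, `features_pi`, `features_ni`, `spectra_pi`,
#'   `spectra_ni`, `elsd`, `truth` (metabolite-level tibble plus expected
#'   per-mode cluster bookkeeping), `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$families_per_herb > 0 && config$members_per_family < 1) {
    abort("families must have at least one member", class = "formulanet_config_error")
  }
  withr::with_seed(config$seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(config) {
  herbs <- config$herb_codes
  nH <- config$n_herbs
  n_per_herb <- config$families_per_herb * config$members_per_family

  # --- manifest -------------------------------------------------------------
  pal <- grDevices::hcl.colors(max(nH, 3), palette = "Dark 3")[seq_len(nH)]
  manifest <- bind_rows(
    tibble(sample_id = "F", role = "formula", herb_code = NA_character_,
           herb_color = NA_character_, ww_proportion = NA_real_),
    tibble(sample_id = paste0("H_", herbs), role = "herb", herb_code = herbs,
           herb_color = pal, ww_proportion = config$ww_proportions),
    tibble(sample_id = "BLK", role = "blank", herb_code = NA_character_,
           herb_color = NA_character_, ww_proportion = NA_real_)
  )

  # --- metabolite catalog ---------------------------------------------------
  fam_counter <- 0
  mets <- list()
  for (h in seq_len(nH)) {
    for (f in seq_len(config$families_per_herb)) {
      fam_counter <- fam_counter + 1
      mets[[length(mets) + 1]] <- tibble(
        herb_code = herbs[h], family_id = fam_counter,
        member = seq_len(config$members_per_family),
        is_ubiquitous = FALSE, is_contaminant = FALSE
      )
    }
  }
  if (config$n_ubiquitous > 0) {
    mets[[length(mets) + 1]] <- tibble(
      herb_code = NA_character_,
      family_id = fam_counter + seq_len(config$n_ubiquitous),
      member = 1L, is_ubiquitous = TRUE, is_contaminant = FALSE
    )
    fam_counter <- fam_counter + config$n_ubiquitous
  }
  if (config$n_contaminants > 0) {
    mets[[length(mets) + 1]] <- tibble(
      herb_code = NA_character_,
      family_id = fam_counter + seq_len(config$n_contaminants),
      member = 1L, is_ubiquitous = FALSE, is_contaminant = TRUE
    )
  }
  mets <- bind_rows(mets)
  mets$met_id <- seq_len(nrow(mets))
  nM <- nrow(mets)

  # --- retention times ------------------------------------------------------
  rt_lo <- config$rt_range[1]; rt_hi <- config$rt_range[2]
  ubi_hi <- rt_lo + 0.8
  mets$rt <- NA_real_
  ubi_idx <- which(mets$is_ubiquitous)
  if (length(ubi_idx) > 0) {
    mets$rt[ubi_idx] <- seq(rt_lo, ubi_hi, length.out = length(ubi_idx) + 1)[-1]
  }
  for (h in herbs) {
    idx <- which(!is.na(mets$herb_code) & mets$herb_code == h)
    n <- length(idx)
    if (n == 0) next
    slots <- seq(ubi_hi + 0.4, rt_hi, length.out = n)
    width <- if (n > 1) diff(slots[1:2]) else 1
    mets$rt[idx] <- slots + runif(n, -0.3, 0.3) * width * 0.5
  }
  cont_idx <- which(mets$is_contaminant)
  mets$rt[cont_idx] <- runif(length(cont_idx), rt_lo, rt_hi)

  # --- neutral masses and family fragment templates -------------------------
  delta_ch2 <- 14.01565
  fam_base <- runif(max(mets$family_id), config$mz_range[1],
                    config$mz_range[2] - config$members_per_family * delta_ch2)
  mets$neutral_mass <- fam_base[mets$family_id] + (mets$member - 1) * delta_ch2

  n_frag <- config$n_fragments
  fam_frag_mz <- lapply(seq_len(max(mets$family_id)), function(f) {
    sort(runif(n_frag, 50, fam_base[f] * 0.8))
  })
  fam_frag_int <- lapply(seq_len(max(mets$family_id)), function(f) {
    runif(n_frag, 0.2, 1)
  })

  # --- abundances -----------------------------------------------------------
  mets$conc <- rlnorm(nM, config$conc_meanlog, config$conc_sdlog)
  mets$ion_pi <- rlnorm(nM, config$ion_meanlog, config$ion_sdlog)
  mets$ion_ni <- rlnorm(nM, config$ion_meanlog, config$ion_sdlog)

  # mode occupancy: a fraction of herb metabolites is mode-exclusive
  mets$in_pi <- TRUE
  mets$in_ni <- TRUE
  herb_idx <- which(!is.na(mets$herb_code))
  n_excl <- floor(length(herb_idx) * config$mode_exclusive_frac)
  if (n_excl > 0) {
    excl <- sample(herb_idx, n_excl)
    drop_pi <- as.logical(sample(c(TRUE, FALSE), n_excl, replace = TRUE))
    mets$in_pi[excl[drop_pi]] <- FALSE
    mets$in_ni[excl[!drop_pi]] <- FALSE
  }

  # --- per-sample heights ---------------------------------------------------
  # concentration of metabolite m in herb h
  conc_mat <- matrix(0, nrow = nM, ncol = nH, dimnames = list(NULL, herbs))
  for (k in seq_len(nM)) {
    if (!is.na(mets$herb_code[k])) {
      if (config$cross_herb_leakage > 0) {
        conc_mat[k, ] <- mets$conc[k] * config$cross_herb_leakage
      }
      conc_mat[k, mets$herb_code[k]] <- mets$conc[k]
    } else if (mets$is_ubiquitous[k]) {
      conc_mat[k, ] <- mets$conc[k]
    }
  }

  height_tables <- lapply(c("PI", "NI"), function(mode) {
    ion <- if (mode == "PI") mets$ion_pi else mets$ion_ni
    present <- if (mode == "PI") mets$in_pi else mets$in_ni
    herb_heights <- conc_mat * ion *
      matrix(.noise_factor(nM * nH, config$noise_cv), nM, nH)
    formula_signal <- as.numeric(conc_mat %*% config$ww_proportions) * ion
    formula_h <- formula_signal * .noise_factor(nM, config$noise_cv)
    blank_h <- ifelse(mets$is_contaminant,
                      mets$conc * ion * .noise_factor(nM, config$noise_cv), 0)
    # contaminants appear in the formula run too (instrument background)
    formula_h <- formula_h + ifelse(mets$is_contaminant,
                                    mets$conc * ion *
                                      .noise_factor(nM, config$noise_cv), 0)
    ft <- tibble(
      feature_id = mets$met_id,
      mz = mets$neutral_mass + if (mode == "PI") .proton_mass else -.proton_mass,
      rt = mets$rt,
      F = formula_h
    )
    hh <- as_tibble(herb_heights)
    names(hh) <- paste0("H_", herbs)
    ft <- bind_cols(ft, hh)
    ft$BLK <- blank_h
    ft <- ft[present, ]
    validate_feature_table(ft, manifest, mode)
  })
  names(height_tables) <- c("PI", "NI")

  # --- spectra --------------------------------------------------------------
  make_spectra <- function(mode) {
    present <- if (mode == "PI") mets$in_pi else mets$in_ni
    charge <- if (mode == "PI") 1L else -1L
    rows <- lapply(which(present), function(k) {
      f <- mets$family_id[k]
      base_mz <- fam_frag_mz[[f]]
      shift <- mets$neutral_mass[k] - fam_base[f]
      half <- seq_len(n_frag) > n_frag / 2
      frag_mz <- ifelse(half, base_mz + shift, base_mz)
      spectrum_record(
        feature_id = mets$met_id[k],
        precursor_mz = mets$neutral_mass[k] +
          if (mode == "PI") .proton_mass else -.proton_mass,
        peaks = cbind(frag_mz, fam_frag_int[[f]]),
        charge = charge
      )
    })
    bind_rows(rows)
  }
  spectra_pi <- make_spectra("PI")
  spectra_ni <- make_spectra("NI")

  # --- ELSD table (herb extracts; response independent of ionization) -------
  elsd_rows <- list()
  for (h in herbs) {
    idx <- which((!is.na(mets$herb_code) & mets$herb_code == h) |
                   mets$is_ubiquitous)
    area <- conc_mat[idx, h] * config$elsd_response *
      .noise_factor(length(idx), config$noise_cv)
    elsd_rows[[h]] <- tibble(herb_code = h, rt = mets$rt[idx],
                             area = area, met_id = mets$met_id[idx])
  }
  elsd_all <- bind_rows(elsd_rows)
  elsd <- elsd_all |>
    transmute(.data$herb_code, .data$rt, .data$area,
              label = NA_character_, qms_mz = NA_real_)

  # --- ground truth ---------------------------------------------------------
  own_area <- elsd_all |>
    filter(!is.na(.data$herb_code)) |>
    inner_join(mets |> select("met_id", true_herb = "herb_code"),
               by = "met_id") |>
    filter(.data$herb_code == .data$true_herb) |>
    select("met_id", elsd_area = "area")
  truth <- mets |>
    left_join(own_area, by = "met_id") |>
    mutate(is_planted_marker = !is.na(.data$herb_code) &
             !is.na(.data$elsd_area) &
             .data$elsd_area >= config$elsd_min_area)
  # anchors: per family containing >= 1 planted marker, the top-area member
  truth <- truth |>
    group_by(.data$family_id) |>
    mutate(is_anchor = .data$is_planted_marker &
             .data$elsd_area == max(.data$elsd_area[.data$is_planted_marker],
                                    -Inf)) |>
    ungroup()

  expected_clusters <- function(present) {
    fam <- mets$family_id[present & !mets$is_ubiquitous & !mets$is_contaminant]
    sizes <- table(fam)
    tibble(
      n_clusters = sum(sizes >= 2),
      n_clustered_nodes = sum(sizes[sizes >= 2])
    )
  }

  list(
    manifest = manifest,
    features_pi = height_tables$PI,
    features_ni = height_tables$NI,
    spectra_pi = spectra_pi,
    spectra_ni = spectra_ni,
    elsd = elsd,
    truth = list(
      metabolites = truth,
      expected_pi = expected_clusters(mets$in_pi),
      expected_ni = expected_clusters(mets$in_ni)
    ),
    config = config
  )
}

#' Write a synthetic bundle to a directory
#'
#' Writes the feature tables, MGF spectra, ELSD table and manifest of a
#' generated bundle as the plain-text inputs the workflow consumes.
#'
#' @param bundle Output of [generate_dataset()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(bundle$features_pi, file.path(dir, "features_pi.csv"))
  write_feature_table(bundle$features_ni, file.path(dir, "features_ni.csv"))
  write_mgf(bundle$spectra_pi, file.path(dir, "spectra_pi.mgf"))
  write_mgf(bundle$spectra_ni, file.path(dir, "spectra_ni.mgf"))
  readr::write_csv(bundle$elsd |> select(herb = "herb_code", "rt", "area"),
                   file.path(dir, "elsd.csv"))
  readr::write_csv(bundle$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Evaluate marker recovery against ground truth
#'
#' Standard precision/recall of predicted specific markers against the
#' planted-marker flags of the generator.
#'
#' @param markers Marker tibble from [select_markers()].
#' @param truth Ground truth (`$truth$metabolites` of a bundle, or the
#'   bundle itself).
#' @return A list: `overall` (one-row tibble `precision`, `recall`,
#'   `n_predicted`, `n_planted`) and `per_herb`.
#' @export
evaluate_recovery <- function(markers, truth) {
  if (!is.data.frame(truth)) truth <- truth$truth$metabolites
  pred <- markers |>
    filter(.data$status == "specific") |>
    mutate(met_id = coalesce(.data$feature_id_pi, .data$feature_id_ni))
  if (any(!pred$met_id %in% truth$met_id)) {
    abort("predicted marker ids absent from ground truth",
          class = "formulanet_validation_error")
  }
  planted <- truth[truth$is_planted_marker, ]
  tp <- sum(pred$met_id %in% planted$met_id)
  overall <- tibble(
    precision = if (nrow(pred) > 0) tp / nrow(pred) else NA_real_,
    recall = if (nrow(planted) > 0) tp / nrow(planted) else NA_real_,
    n_predicted = nrow(pred), n_planted = nrow(planted)
  )
  per_herb <- planted |>
    group_by(.data$herb_code) |>
    summarise(n_planted = n(),
              n_recovered = sum(.data$met_id %in% pred$met_id),
              recall = .data$n_recovered / .data$n_planted,
              .groups = "drop")
  list(overall = overall, per_herb = per_herb)
}

#' Adjusted Rand index between two labelings
#'
#' Agreement between two partitions of the same items, corrected for
#' chance; 1 means identical partitions.
#'
#' @param x,y Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
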