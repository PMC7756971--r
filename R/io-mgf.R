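#' Read MS/MS spectra from an MGF file
#'
#' Each `BEGIN IONS`/`END IONS` block must carry a feature id (`FEATURE_ID=`
#' or `SCANS=`) and a `PEPMASS=` precursor. Peaks are re-sorted by fragment
#' m/z ascending and zero-intensity peaks are dropped.
#'
#' @param path MGF file path.
#' @return A spectra tibble: `feature_id`, `precursor_mz`, `charge`, and a
#'   `peaks` list-column of two-column matrices (`mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    abort("unbalanced BEGIN IONS/END IONS blocks", class = "formulanet_format_error")
  }
  recs <- purrr::map2(seq_along(starts), seq_along(ends), function(bi, ei) {
    block <- lines[(starts[bi] + 1):(ends[ei] - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*$", "", block[kv]))
    vals <- sub("^[^=]*=", "", block[kv])
    fid <- vals[match(c("FEATURE_ID", "SCANS"), keys)]
    fid <- fid[!is.na(fid)][1]
    if (is.na(fid)) {
      abort(sprintf("MGF block %d has no FEATURE_ID or SCANS field", bi),
            class = "formulanet_parse_error")
    }
    pep <- vals[match("PEPMASS", keys)]
    if (is.na(pep)) {
      abort(sprintf("MGF block %d has no PEPMASS", bi),
            class = "formulanet_parse_error")
    }
    charge <- vals[match("CHARGE", keys)]
    charge_int <- if (is.na(charge)) 1L else {
      sign <- if (grepl("-", charge)) -1L else 1L
      sign * as.integer(gsub("[^0-9]", "", charge))
    }
    peak_lines <- block[!kv]
    peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
    if (length(peak_lines) > 0) {
      parts <- strsplit(trimws(peak_lines), "[ \t]+")
      pk <- matrix(as.numeric(unlist(lapply(parts, `[`, 1:2))),
                   ncol = 2, byrow = TRUE)
    } else {
      pk <- matrix(numeric(0), ncol = 2)
    }
    colnames(pk) <- c("mz", "intensity")
    pk <- pk[pk[, 2] > 0, , drop = FALSE]
    pk <- pk[order(pk[, 1]), , drop = FALSE]
    list(
      feature_id = as.integer(fid),
      precursor_mz = as.numeric(strsplit(pep, "[ \t]+")[[1]][1]),
      charge = charge_int,
      peaks = pk
    )
  })
  tibble(
    feature_id = purrr::map_int(recs, "feature_id"),
    precursor_mz = purrr::map_dbl(recs, "precursor_mz"),
    charge = purrr::map_int(recs, "charge"),
    peaks = purrr::map(recs, "peaks")
  )
}

#' Write spectra to an MGF file
#'
#' @param spectra Spectra tibble as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    pk <- spectra$peaks[[i]]
    writeLines(c(
      "BEGIN IONS",
      sprintf("FEATURE_ID=%d", spectra$feature_id[i]),
      sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]),
      sprintf("CHARGE=%d%s", abs(spectra$charge[i]),
              if (spectra$charge[i] < 0) "-" else "+"),
      sprintf("SCANS=%d", spectra$feature_id[i]),
      sprintf("%.6f %.6f", pk[, 1], pk[, 2]),
      "END IONS",
      ""
    ), con)
  }
  invisible(path)
}

#' Construct a single spectrum record
#'
#' @param feature_id Integer feature id.
#' @param precursor_mz Precursor m/z (Da).
#' @param peaks Two-column matrix or data frame of fragment m/z and intensity.
#' @param charge Signed charge (default +1).
#' @return A one-row spectra tibble.
#' @export
spectrum_record <- function(feature_id, precursor_mz, peaks, charge = 1L) {
  pk <- as.matrix(peaks)
  colnames(pk) <- c("mz", "intensity")
  stopifnot(precursor_mz > 0, all(pk[, 2] > 0))
  pk <- pk[order(pk[, 1]), , drop = FALSE]
  tibble(
    feature_id = as.integer(feature_id),
    precursor_mz = as.numeric(precursor_mz),
    charge = as.integer(charge),
    peaks = list(pk)
  )
}
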