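#' Square-root and L2-normalize a peak list
#'
#' Standard preprocessing for the modified cosine: intensities are replaced
#' by their square roots, then scaled so the weight vector has unit
#' Euclidean norm. The square root damps the dominance of base peaks.
#'
#' @param peaks Two-column matrix (`mz`, `intensity`) with positive
#'   intensities, or a one-row spectra tibble.
#' @return Matrix with columns `mz` and `weight`, unit L2 norm.
#' @export
#' @examples
#' normalize_spectrum(cbind(c(100, 150), c(4, 1)))
normalize_spectrum <- function(peaks) {
  if (is.data.frame(peaks) && "peaks" %in% names(peaks)) {
    peaks <- peaks$peaks[[1]]
  }
  pk <- as.matrix(peaks)
  if (nrow(pk) == 0) {
    abort("cannot normalize an empty spectrum", class = "formulanet_degenerate_error")
  }
  stopifnot(all(pk[, 2] > 0))
  w <- sqrt(pk[, 2])
  w <- w / sqrt(sum(w^2))
  out <- cbind(mz = pk[, 1], weight = w)
  out[order(out[, 1]), , drop = FALSE]
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' Computes the modified cosine score used in molecular networking. Candidate
#' peak pairs are those whose fragment m/z agree within `fragment_tol`
#' directly, or after shifting by the precursor mass difference (which aligns
#' fragments that retain a structural modification). A one-to-one assignment
#' of candidate pairs is chosen greedily by descending weight product
#' (GNPS-compatible); the score is the sum of weight products over chosen
#' pairs.
#'
#' @param a,b Spectra: one-row spectra tibbles (see [spectrum_record()]) or
#'   lists with elements `precursor_mz` and `peaks`.
#' @param fragment_tol Fragment m/z tolerance in Da (default 0.02).
#' @return A list with `cosine` (in `[0, 1]`) and `matched_peaks` (count).
#' @export
#' @examples
#' a <- spectrum_record(1, 200, cbind(c(100, 150), c(1, 0.5)))
#' b <- spectrum_record(2, 250, cbind(c(100, 200), c(1, 0.5)))
#' modified_cosine(a, b)  # one direct + one shifted match -> cosine 1
modified_cosine <- function(a, b, fragment_tol = 0.02) {
  pa <- .spec_precursor(a); pb <- .spec_precursor(b)
  na <- normalize_spectrum(.spec_peaks(a))
  nb <- normalize_spectrum(.spec_peaks(b))
  cand <- .candidate_pairs(na, nb, pa, pb, fragment_tol)
  .greedy_assign(cand, nrow(na), nrow(nb))
}

.spec_peaks <- function(s) {
  if (is.data.frame(s) && "peaks" %in% names(s)) s$peaks[[1]] else s$peaks
}
.spec_precursor <- function(s) {
  if (is.data.frame(s)) s$precursor_mz[1] else s$precursor_mz
}

# candidate peak pairs (direct + precursor-shifted) with weight products
.candidate_pairs <- function(na, nb, prec_a, prec_b, tol) {
  d <- outer(na[, "mz"], nb[, "mz"], `-`)
  hit <- abs(d) <= tol | abs(d - (prec_a - prec_b)) <= tol
  idx <- which(hit, arr.ind = TRUE)
  if (length(idx) == 0) {
    return(tibble(i = integer(), j = integer(), product = numeric()))
  }
  tibble(
    i = idx[, 1],
    j = idx[, 2],
    product = na[idx[, 1], "weight"] * nb[idx[, 2], "weight"]
  )
}

# greedy one-to-one assignment by descending product; ties by peak indices
.greedy_assign <- function(cand, n_a, n_b) {
  if (nrow(cand) == 0) return(list(cosine = 0, matched_peaks = 0L))
  ord <- order(-cand$product, cand$i, cand$j)
  used_a <- logical(n_a); used_b <- logical(n_b)
  score <- 0; matched <- 0L
  for (k in ord) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      score <- score + cand$product[k]
      matched <- matched + 1L
    }
  }
  list(cosine = min(score, 1), matched_peaks = matched)
}
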