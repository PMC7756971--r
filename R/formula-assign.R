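#' Monoisotopic mass of a molecular formula
#'
#' @param formula Molecular formula string over C, H, N, O, S, P
#'   (e.g. `"C21H18O11"`).
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' formula_mass("C6H12O6")
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    toks <- toks[nzchar(toks)]
    total <- 0
    for (tk in toks) {
      el <- gsub("[0-9]", "", tk)
      n <- gsub("[^0-9]", "", tk)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(.element_mass)) {
        abort(paste0("unsupported element: ", el), class = "formulanet_format_error")
      }
      total <- total + n * .element_mass[[el]]
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Neutral mass from a precursor m/z and adduct
#'
#' @param mz Precursor m/z.
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(mz, adduct = c("[M+H]+", "[M-H]-")) {
  adduct <- match.arg(adduct)
  if (adduct == "[M+H]+") mz - .proton_mass else mz + .proton_mass
}

#' Assign molecular formulas to a neutral mass
#'
#' Exhaustively enumerates CHNO formulas within element bounds whose
#' monoisotopic mass lies within `ppm_tol` of `mass`, subject to ring and
#' double bond equivalents (RDBE = C - H/2 + N/2 + 1) being an integer in
#' `rdbe_range` (integrality is the even-electron parity rule for neutral
#' molecules). Candidates are ranked by absolute mass error.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param ppm_tol Mass tolerance in ppm (default 5).
#' @param bounds Named upper bounds for C, H, N, O
#'   (defaults `c(C = 60, H = 120, N = 10, O = 30)`).
#' @param rdbe_range Allowed RDBE interval (default `c(0, 40)`).
#' @return Tibble `formula`, `C`, `H`, `N`, `O`, `mass`, `error_ppm`,
#'   ranked by `abs(error_ppm)`; zero rows when nothing fits.
#' @export
#' @examples
#' assign_molecular_formula(formula_mass("C6H12O6"))
assign_molecular_formula <- function(mass, ppm_tol = 5,
                                     bounds = c(C = 60, H = 120, N = 10, O = 30),
                                     rdbe_range = c(0, 40)) {
  stopifnot(mass > 0, ppm_tol >= 0)
  b <- c(C = 60, H = 120, N = 10, O = 30)
  b[names(bounds)] <- bounds
  tol_da <- mass * ppm_tol * 1e-6
  mC <- .element_mass[["C"]]; mH <- .element_mass[["H"]]
  mN <- .element_mass[["N"]]; mO <- .element_mass[["O"]]

  cmax <- min(b[["C"]], floor(mass / mC))
  grid <- expand.grid(C = 1:max(cmax, 1), N = 0:b[["N"]], O = 0:b[["O"]])
  rem <- mass - grid$C * mC - grid$N * mN - grid$O * mO
  h <- round(rem / mH)
  # nearest integer H plus neighbors, in case the window straddles
  cand <- bind_rows(
    tibble(C = grid$C, N = grid$N, O = grid$O, H = h),
    tibble(C = grid$C, N = grid$N, O = grid$O, H = h - 1),
    tibble(C = grid$C, N = grid$N, O = grid$O, H = h + 1)
  ) |>
    filter(.data$H >= 0, .data$H <= b[["H"]])
  cand$mass <- cand$C * mC + cand$H * mH + cand$N * mN + cand$O * mO
  cand$rdbe <- cand$C - cand$H / 2 + cand$N / 2 + 1
  cand <- cand |>
    filter(abs(.data$mass - !!mass) <= tol_da,
           .data$rdbe >= rdbe_range[1], .data$rdbe <= rdbe_range[2],
           .data$rdbe == floor(.data$rdbe)) |>
    distinct(.data$C, .data$H, .data$N, .data$O, .keep_all = TRUE)
  if (nrow(cand) == 0) {
    return(tibble(formula = character(), C = integer(), H = integer(),
                  N = integer(), O = integer(), mass = numeric(),
                  error_ppm = numeric()))
  }
  cand |>
    mutate(error_ppm = 1e6 * (.data$mass - !!mass) / !!mass,
           formula = paste0(
             "C", .data$C, "H", .data$H,
             ifelse(.data$N > 0, paste0("N", .data$N), ""),
             ifelse(.data$O > 0, paste0("O", .data$O), "")
           )) |>
    arrange(abs(.data$error_ppm), .data$formula) |>
    select("formula", "C", "H", "N", "O", "mass", "error_ppm")
}
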