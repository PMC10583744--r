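#' @useDynLib lucj, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# STO-6G contracted Gaussian expansions (Hehre-Stewart-Pople least-squares
# fits of Slater functions, scaled by the standard molecular zeta values:
# H 1s zeta = 1.24; C 1s zeta = 5.67, C 2sp zeta = 1.72).  Exponents in
# bohr^-2, coefficients for unit-normalized primitives.
.sto6g <- list(
  H = list(
    list(l = 0L,
         exps = c(35.52322122, 6.513143725, 1.822142904,
                  0.625955266, 0.243076747, 0.100112428),
         coefs = c(0.00916359628, 0.04936149294, 0.16853830490,
                   0.37056279970, 0.41649152980, 0.13033408410))
  ),
  C = list(
    list(l = 0L,
         exps = c(742.7370491, 136.1800249, 38.09826352,
                  13.08778129, 5.082368240, 2.093200076),
         coefs = c(0.00916359628, 0.04936149294, 0.16853830490,
                   0.37056279970, 0.41649152980, 0.13033408410)),
    list(l = 0L,
         exps = c(30.49723950, 6.036199601, 1.876046337,
                  0.7217826470, 0.3134706954, 0.1436865550),
         coefs = c(-0.01325278809, -0.04699171014, -0.03378537151,
                   0.25024178610, 0.59511725260, 0.24070617630)),
    list(l = 1L,
         exps = c(30.49723950, 6.036199601, 1.876046337,
                  0.7217826470, 0.3134706954, 0.1436865550),
         coefs = c(0.00375969645, 0.03767936984, 0.17389674110,
                   0.41803643070, 0.42585954770, 0.10170829100))
  )
)

.element_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
                F = 9, Ne = 10)

.bohr_per_angstrom <- 1 / 0.52917721092

#' Build a contracted Gaussian basis for a molecule
#'
#' Expands the shipped STO-6G shell data into a list of Cartesian basis
#' functions (one entry per component, e.g. three p functions per p shell).
#'
#' @param mol a molecule as returned by [molecule()].
#' @param basis basis set name; only `"sto-6g"` is shipped.
#' @return list of basis functions, each with `center` (bohr), `l`
#'   (Cartesian powers), `exps`, `coefs`.
#' @keywords internal
build_basis <- function(mol, basis = "sto-6g") {
  if (!identical(tolower(basis), "sto-6g"))
    stop("only the STO-6G basis is shipped with this package")
  fns <- list()
  cart <- list(`0` = list(c(0L, 0L, 0L)),
               `1` = list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))
  for (ia in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[ia]
    shells <- .sto6g[[el]]
    if (is.null(shells))
      stop("no STO-6G data shipped for element ", el)
    cen <- as.numeric(mol$atoms[ia, c("x", "y", "z")]) * .bohr_per_angstrom
    for (sh in shells) {
      for (lv in cart[[as.character(sh$l)]]) {
        fns[[length(fns) + 1L]] <- list(center = cen, l = lv,
                                        exps = sh$exps, coefs = sh$coefs)
      }
    }
  }
  fns
}
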