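#' Define a molecule from elements and Cartesian coordinates
#'
#' @param elements character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of coordinates in Angstrom.
#' @param charge total molecular charge.
#' @return an object of class `lucj_molecule`.
#' @export
molecule <- function(elements, xyz, charge = 0L) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(elements) == nrow(xyz))
  Z <- .element_Z[elements]
  if (anyNA(Z)) stop("unknown element(s): ",
                     paste(elements[is.na(Z)], collapse = ", "))
  atoms <- data.frame(element = elements, Z = as.numeric(Z),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  n_elec <- sum(atoms$Z) - charge
  structure(list(atoms = atoms, charge = charge, n_electrons = n_elec),
            class = "lucj_molecule")
}

#' @export
print.lucj_molecule <- function(x, ...) {
  cat("Molecule:", nrow(x$atoms), "atoms,", x$n_electrons, "electrons\n")
  print(x$atoms[, c("element", "x", "y", "z")], digits = 6)
  invisible(x)
}

#' Square cyclobutadiene fixture geometry
#'
#' Four carbons on a square of the given side length, hydrogens bonded
#' radially outward along the square diagonals (planar, D4h).
#'
#' @param side C-C side length in Angstrom.
#' @param ch C-H bond length in Angstrom.
#' @return a [molecule()].
#' @export
cyclobutadiene_molecule <- function(side = 1.456, ch = 1.069) {
  h <- side / 2
  cpos <- rbind(c(h, h, 0), c(-h, h, 0), c(-h, -h, 0), c(h, -h, 0))
  rc <- sqrt(2) * h
  hpos <- cpos * (1 + ch / rc)
  molecule(c(rep("C", 4), rep("H", 4)), rbind(cpos, hpos))
}

#' Hydrogen molecule fixture at a given bond length
#'
#' @param r H-H distance in Angstrom.
#' @return a [molecule()].
#' @export
h2_molecule <- function(r = 0.7414) {
  molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)))
}

#' Nuclear repulsion energy in Hartree
#' @param mol a [molecule()].
#' @keywords internal
nuclear_repulsion <- function(mol) {
  at <- mol$atoms
  n <- nrow(at)
  e <- 0
  if (n < 2) return(0)
  xyz <- as.matrix(at[, c("x", "y", "z")]) * .bohr_per_angstrom
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    e <- e + at$Z[i] * at$Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  e
}
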