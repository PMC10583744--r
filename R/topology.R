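# Qubit-connectivity models and the parameter masks they induce on the
# Jastrow couplings: on-site opposite-spin couplings are allowed only on the
# orbital set S determined by the device lattice, same-spin couplings only
# between adjacent orbitals (p, p+1), and the all-to-all model is
# unrestricted.

.topology_names <- c("all-to-all", "linear", "square", "hex",
                     "heavy-hex-zigzag", "heavy-hex-loop")

#' Construct a qubit-topology model
#'
#' Spatial orbital `p` maps to qubit `p` (spin up) and qubit `p + N`
#' (spin down).  The opposite-spin coupling set `s_set` lists the orbitals
#' whose up and down qubits are device-adjacent (possibly through an
#' ancilla): every orbital for `square`, even orbitals for `hex`
#' (`S = {2k}`), every fourth orbital for the heavy-hex lattices (one
#' ancilla serves four orbitals), only orbital 0 for `linear`, and all
#' orbitals for `all-to-all`.  The same-spin pair set is always the chain
#' `{(p, p+1)}`.
#'
#' @param name one of `"all-to-all"`, `"linear"`, `"square"`, `"hex"`,
#'   `"heavy-hex-zigzag"`, `"heavy-hex-loop"`.
#' @param n_orb number of spatial orbitals N.
#' @return object of class `lucj_topology` with fields `name`, `n_orb`,
#'   `s_set` (0-based orbital indices), `s_prime` (0-based pair matrix),
#'   `ancilla_map` (orbital -> ancilla qubit, heavy-hex only), and
#'   `n_qubits`.
#' @export
make_topology <- function(name, n_orb) {
  name <- match.arg(name, .topology_names)
  n_orb <- as.integer(n_orb)
  if (n_orb < 1) stop("n_orb must be >= 1")
  s_set <- switch(name,
    "all-to-all" = 0:(n_orb - 1L),
    "square" = 0:(n_orb - 1L),
    "hex" = seq(0L, n_orb - 1L, by = 2L),
    "linear" = 0L,
    "heavy-hex-zigzag" = ,
    "heavy-hex-loop" = seq(0L, n_orb - 1L, by = 4L))
  s_prime <- if (n_orb >= 2)
    cbind(0:(n_orb - 2L), 1:(n_orb - 1L)) else
    matrix(integer(0), 0, 2)
  ancilla_map <- integer(0)
  if (grepl("^heavy-hex", name)) {
    ancilla_map <- stats::setNames(2L * n_orb + seq_along(s_set) - 1L,
                                   as.character(s_set))
  }
  structure(list(name = name, n_orb = n_orb, s_set = s_set,
                 s_prime = s_prime, ancilla_map = ancilla_map,
                 n_qubits = 2L * n_orb + length(ancilla_map)),
            class = "lucj_topology")
}

#' @export
print.lucj_topology <- function(x, ...) {
  cat(sprintf("Topology %s: N = %d, S = {%s}, %d ancillas\n", x$name, x$n_orb,
              paste(x$s_set, collapse = ","), length(x$ancilla_map)))
  invisible(x)
}

#' Qubit index of a spin orbital
#' @param top a [make_topology()] result.
#' @param orbital 0-based spatial orbital index.
#' @param spin `"alpha"` or `"beta"`.
#' @return 0-based qubit index.
#' @export
qubit_of <- function(top, orbital, spin = c("alpha", "beta")) {
  spin <- match.arg(spin)
  stopifnot(all(orbital >= 0), all(orbital < top$n_orb))
  as.integer(orbital + if (spin == "beta") top$n_orb else 0L)
}

#' Boolean parameter masks induced by a topology
#'
#' `mask_os` marks allowed opposite-spin couplings `J[p,q]` between spin-up
#' orbital p and spin-down orbital q; for local lattices only the on-site
#' entries `(p,p)` with `p` in `s_set` survive, while `all-to-all` allows
#' the full symmetric matrix.  `mask_ss` marks same-spin couplings: the
#' diagonal plus nearest-neighbor pairs `(p, p+1)` for local lattices, all
#' entries for `all-to-all`.
#'
#' @param top a [make_topology()] result.
#' @return list with symmetric logical matrices `mask_os` and `mask_ss`.
#' @export
parameter_masks <- function(top) {
  n <- top$n_orb
  if (top$name == "all-to-all") {
    m <- matrix(TRUE, n, n)
    return(list(mask_os = m, mask_ss = m))
  }
  mask_os <- matrix(FALSE, n, n)
  for (p in top$s_set) mask_os[p + 1L, p + 1L] <- TRUE
  mask_ss <- diag(n) > 0
  if (nrow(top$s_prime)) for (k in seq_len(nrow(top$s_prime))) {
    p <- top$s_prime[k, 1] + 1L; q <- top$s_prime[k, 2] + 1L
    mask_ss[p, q] <- mask_ss[q, p] <- TRUE
  }
  list(mask_os = mask_os, mask_ss = mask_ss)
}

#' Serialize a topology to JSON
#' @param top a [make_topology()] result.
#' @return JSON string.
#' @export
topology_json <- function(top) {
  jsonlite::toJSON(list(name = top$name, n_orb = top$n_orb,
                        s_set = top$s_set,
                        s_prime = apply(top$s_prime, 1, as.list),
                        ancilla_map = as.list(top$ancilla_map)),
                   auto_unbox = TRUE)
}
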