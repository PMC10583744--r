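#' Restricted Hartree-Fock in a shipped Gaussian basis
#'
#' Closed-shell RHF with DIIS acceleration.  Returns canonical molecular
#' orbitals ordered by increasing orbital energy, together with the AO
#' integrals needed for subsequent active-space work.
#'
#' @param mol a [molecule()]; must have an even number of electrons.
#' @param basis basis set name (only `"sto-6g"` shipped).
#' @param max_iter maximum SCF iterations.
#' @param conv_tol convergence threshold on the DIIS error norm and energy.
#' @param level_shift virtual-orbital level shift in Hartree, applied while
#'   the DIIS error is large; helps near-degenerate cases such as square
#'   cyclobutadiene, where the frontier orbitals are exactly degenerate at
#'   the symmetric geometry.
#' @return a list of class `lucj_scf` with total `energy` (Hartree),
#'   `mo_coeff`, `mo_energy`, AO integral matrices `S`, `hcore`, the AO
#'   two-electron array `eri` in chemist (pq|rs) convention, `n_occ`,
#'   `e_nuc`, and the iteration `trace`.
#' @export
rhf <- function(mol, basis = "sto-6g", max_iter = 200, conv_tol = 1e-10,
                level_shift = 0.2) {
  if (mol$n_electrons %% 2 != 0)
    stop("RHF requires an even electron count")
  fns <- build_basis(mol, basis)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) * .bohr_per_angstrom
  ints <- .one_electron_ints(fns, xyz, mol$atoms$Z)
  eri <- .two_electron_ints(fns)
  n <- nrow(ints$S)
  S <- ints$S
  h <- ints$T + ints$V
  e_nuc <- nuclear_repulsion(mol)
  n_occ <- mol$n_electrons %/% 2

  eriJ <- matrix(eri, n * n, n * n)                 # (mu nu | la si)
  eriK <- matrix(aperm(array(eri, rep(n, 4)), c(1, 3, 2, 4)), n * n, n * n)

  se <- eigen(S, symmetric = TRUE)
  if (min(se$values) < 1e-10) stop("AO overlap matrix is near-singular")
  X <- se$vectors %*% diag(1 / sqrt(se$values)) %*% t(se$vectors)

  fock_build <- function(D) {
    J <- matrix(eriJ %*% as.vector(D), n, n)
    K <- matrix(eriK %*% as.vector(D), n, n)
    h + 2 * J - K
  }

  # core guess
  Fm <- h
  err_list <- list(); fock_list <- list()
  D <- NULL; e_old <- Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Fp <- t(X) %*% Fm %*% X
    es <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(es$values)                      # ascending orbital energy
    es$values <- es$values[ord]
    es$vectors <- es$vectors[, ord, drop = FALSE]
    C <- X %*% es$vectors
    Cocc <- C[, seq_len(n_occ), drop = FALSE]
    D <- Cocc %*% t(Cocc)
    Fm <- fock_build(D)
    e_el <- sum(D * (h + Fm))
    e_tot <- e_el + e_nuc
    trace <- c(trace, e_tot)
    err <- Fm %*% D %*% S - S %*% D %*% Fm
    err_n <- max(abs(err))
    if (err_n < conv_tol && abs(e_tot - e_old) < conv_tol) {
      mo_e <- es$values
      return(structure(list(energy = e_tot, mo_coeff = C, mo_energy = mo_e,
                            S = S, hcore = h, eri = array(eri, rep(n, 4)),
                            n_occ = n_occ, n_ao = n, e_nuc = e_nuc,
                            converged = TRUE, trace = trace, basis = fns,
                            molecule = mol),
                       class = "lucj_scf"))
    }
    e_old <- e_tot
    # DIIS on the shifted Fock
    if (err_n < 10) {
      err_list[[length(err_list) + 1L]] <- as.vector(t(X) %*% err %*% X)
      fock_list[[length(fock_list) + 1L]] <- Fm
      if (length(err_list) > 8) { err_list <- err_list[-1]; fock_list <- fock_list[-1] }
      m <- length(err_list)
      if (m > 1) {
        B <- matrix(0, m + 1, m + 1)
        for (a in 1:m) for (b in 1:m)
          B[a, b] <- sum(err_list[[a]] * err_list[[b]])
        B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
        rhs <- c(rep(0, m), -1)
        cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
        if (!is.null(cf)) {
          Fm <- Reduce(`+`, Map(`*`, fock_list, cf))
        }
      }
    }
    if (err_n > 1e-4 && level_shift > 0) {
      # shift virtuals: F -> F + shift * S (I - D S)  (projected)
      Fm <- Fm + level_shift * (S - S %*% D %*% S)
    }
  }
  stop(structure(class = c("lucj_scf_error", "error", "condition"),
                 list(message = sprintf(
                        "SCF failed to converge in %d iterations (last E = %.8f)",
                        max_iter, e_old),
                      call = sys.call(-1), trace = trace)))
}

#' @export
print.lucj_scf <- function(x, ...) {
  cat(sprintf("RHF energy: %.8f Hartree (%d AOs, %d occupied)\n",
              x$energy, x$n_ao, x$n_occ))
  invisible(x)
}
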