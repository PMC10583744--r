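# Active-space construction on top of an RHF solution: orbital selection,
# core folding into an effective one-body term, MO integral transforms, and
# t2 amplitudes (MP2 or CCSD) within the active space.

#' Select an active orbital window
#'
#' Two selection rules are offered. `"canonical-window"` takes a HOMO-centred
#' window of canonical orbitals in energy-ascending order (ties broken by the
#' original orbital index, stable).  `"ao-overlap"` picks the molecular
#' orbitals with the largest Mulliken population on a target set of atomic
#' orbitals (e.g. the carbon 2pz set for a pi space) and keeps them in
#' energy-ascending order; an ambiguous selection (two candidate orbitals
#' with population difference below `tie_tol` straddling the cut) is an
#' error rather than a silent choice.  `"mp2-natural"` diagonalizes the
#' (closed-shell, unrelaxed) MP2 one-particle density and returns natural
#' orbitals in occupation-descending order.
#'
#' @param scf an [rhf()] result.
#' @param n_active number of active orbitals.
#' @param rule `"canonical-window"`, `"ao-overlap"` or `"mp2-natural"`.
#' @param target_aos integer indices of AOs defining the overlap target
#'   (required for `"ao-overlap"`).
#' @param tie_tol population tie tolerance for `"ao-overlap"`.
#' @return list with `orbitals` (column indices into `scf$mo_coeff`),
#'   `ordering` tag, and for `"mp2-natural"` the natural-orbital
#'   coefficients in `mo_coeff`.
#' @export
select_active_space <- function(scf, n_active,
                                rule = c("canonical-window", "ao-overlap",
                                         "mp2-natural"),
                                target_aos = NULL, tie_tol = 1e-6) {
  rule <- match.arg(rule)
  nocc <- scf$n_occ; n <- scf$n_ao
  if (rule == "canonical-window") {
    n_occ_act <- min(nocc, ceiling(n_active / 2))
    n_vir_act <- n_active - n_occ_act
    orbs <- c((nocc - n_occ_act + 1L):nocc,
              if (n_vir_act > 0) (nocc + 1L):(nocc + n_vir_act))
    ord <- order(scf$mo_energy[orbs], orbs)   # stable: energy then index
    return(list(orbitals = orbs[ord], ordering = "energy-ascending"))
  }
  if (rule == "ao-overlap") {
    if (is.null(target_aos)) stop("target_aos required for ao-overlap rule")
    C <- scf$mo_coeff; S <- scf$S
    SC <- S %*% C
    pop <- colSums((C[target_aos, , drop = FALSE]) * (SC[target_aos, , drop = FALSE]))
    ord <- order(pop, decreasing = TRUE)
    cut_in <- pop[ord[n_active]]; cut_out <- pop[ord[n_active + 1L]]
    if (!is.na(cut_out) && abs(cut_in - cut_out) < tie_tol)
      stop(sprintf(paste0("ambiguous active-space selection: orbitals %d and %d ",
                          "have target populations %.6f and %.6f"),
                   ord[n_active], ord[n_active + 1L], cut_in, cut_out))
    orbs <- sort(ord[seq_len(n_active)])
    return(list(orbitals = orbs, ordering = "energy-ascending"))
  }
  # mp2-natural
  dm <- .mp2_density(scf)
  ev <- eigen((dm + t(dm)) / 2, symmetric = TRUE)
  ordd <- order(ev$values, decreasing = TRUE)
  no_coeff <- scf$mo_coeff %*% ev$vectors[, ordd]
  occ_no <- ev$values[ordd]
  list(orbitals = seq_len(n_active), ordering = "occupation-descending",
       mo_coeff = no_coeff, occupations = occ_no)
}

# unrelaxed closed-shell MP2 one-particle density in the MO basis
.mp2_density <- function(scf) {
  n <- scf$n_ao; nocc <- scf$n_occ; nvir <- n - nocc
  mo <- .ao2mo(scf$eri, scf$mo_coeff)
  eps <- scf$mo_energy
  occ <- 1:nocc; vir <- (nocc + 1):n
  t2 <- array(0, c(nocc, nocc, nvir, nvir))
  for (i in occ) for (j in occ) for (a in seq_len(nvir)) for (b in seq_len(nvir))
    t2[i, j, a, b] <- mo[i, vir[a], j, vir[b]] /
      (eps[i] + eps[j] - eps[vir[a]] - eps[vir[b]])
  dm <- diag(c(rep(2, nocc), rep(0, nvir)))
  # occupied-occupied and virtual-virtual correlation corrections
  for (i in occ) for (j in occ) {
    s <- 0
    for (k in occ) for (a in seq_len(nvir)) for (b in seq_len(nvir))
      s <- s + t2[i, k, a, b] * (2 * t2[j, k, a, b] - t2[j, k, b, a])
    dm[i, j] <- dm[i, j] - 2 * s
  }
  for (a in seq_len(nvir)) for (b in seq_len(nvir)) {
    s <- 0
    for (i in occ) for (j in occ) for (c2 in seq_len(nvir))
      s <- s + t2[i, j, a, c2] * (2 * t2[i, j, b, c2] - t2[j, i, b, c2])
    dm[vir[a], vir[b]] <- dm[vir[a], vir[b]] + 2 * s
  }
  dm
}

# four-index transform of an AO eri array to an MO coefficient block
.ao2mo <- function(eri, C) {
  n <- dim(eri)[1]; m <- ncol(C)
  x <- matrix(eri, n, n^3)
  x <- t(C) %*% x                                    # (m, n^3): first index
  x <- array(x, c(m, n, n, n))
  x <- aperm(x, c(2, 3, 4, 1))                       # rotate target axis back
  x <- matrix(x, n, n^2 * m); x <- t(C) %*% x
  x <- array(x, c(m, n, n, m)); x <- aperm(x, c(2, 3, 4, 1))
  x <- matrix(x, n, n * m^2); x <- t(C) %*% x
  x <- array(x, c(m, n, m, m)); x <- aperm(x, c(2, 3, 4, 1))
  x <- matrix(x, n, m^3); x <- t(C) %*% x
  # axis order is now (s,p,q,r)-transformed; one more cycle restores (p,q,r,s)
  x <- array(x, c(m, m, m, m))
  aperm(x, c(2, 3, 4, 1))
}

#' Active-space Hamiltonian from an RHF solution
#'
#' Folds all doubly occupied orbitals outside the active window into the
#' scalar offset and an effective one-body term (standard closed-shell core
#' contraction), and transforms the two-electron integrals into the active
#' MO basis.
#'
#' @param scf an [rhf()] result.
#' @param active integer vector of active orbital column indices.
#' @param mo_coeff optional orbital coefficients overriding `scf$mo_coeff`
#'   (e.g. natural orbitals).
#' @param orbital_order ordering tag stored on the result.
#' @return a [molecular_hamiltonian()].
#' @export
active_hamiltonian <- function(scf, active, mo_coeff = NULL,
                               orbital_order = "energy-ascending") {
  C <- if (is.null(mo_coeff)) scf$mo_coeff else mo_coeff
  n <- scf$n_ao
  occ_all <- seq_len(scf$n_occ)
  core <- setdiff(occ_all, active)
  if (length(intersect(core, active))) stop("core/active overlap")
  n_act_el <- scf$molecule$n_electrons - 2L * length(core)
  if (n_act_el < 0) stop("active window excludes occupied electrons inconsistently")
  Ccore <- C[, core, drop = FALSE]
  Dcore <- Ccore %*% t(Ccore)
  eriJ <- matrix(scf$eri, n * n, n * n)
  eriK <- matrix(aperm(scf$eri, c(1, 3, 2, 4)), n * n, n * n)
  Jc <- matrix(eriJ %*% as.vector(Dcore), n, n)
  Kc <- matrix(eriK %*% as.vector(Dcore), n, n)
  heff_ao <- scf$hcore + 2 * Jc - Kc
  e_core <- sum(Dcore * (scf$hcore + heff_ao))
  Cact <- C[, active, drop = FALSE]
  h1 <- t(Cact) %*% heff_ao %*% Cact
  g2 <- .ao2mo(scf$eri, Cact)
  na <- n_act_el %/% 2L
  molecular_hamiltonian((h1 + t(h1)) / 2, g2,
                        e_const = scf$e_nuc + e_core,
                        n_alpha = na, n_beta = n_act_el - na,
                        orbital_order = orbital_order)
}

#' t2 amplitude container
#' @param t2 occ x occ x virt x virt amplitude array (closed shell, spatial).
#' @param source `"CCSD"` or `"MP2"`.
#' @return object of class `lucj_t2`.
#' @export
t2_amplitudes <- function(t2, source = c("CCSD", "MP2")) {
  source <- match.arg(source)
  d <- dim(t2)
  stopifnot(length(d) == 4, d[1] == d[2], d[3] == d[4])
  if (length(t2) && max(abs(t2 - aperm(t2, c(2, 1, 4, 3)))) > 1e-12)
    stop("t2 violates restricted closed-shell symmetry t[i,j,a,b] == t[j,i,b,a]")
  structure(list(n_occ = d[1], n_virt = d[3], t2 = t2, source = source),
            class = "lucj_t2")
}

# MP2 amplitudes within an active-space Hamiltonian (closed shell)
.active_mp2_t2 <- function(H) {
  n <- H$n_orb; no <- H$n_alpha; nv <- n - no
  if (no == 0 || nv == 0 || H$n_alpha != H$n_beta || H$n_alpha + H$n_beta < 2)
    return(t2_amplitudes(array(0, c(no, no, nv, nv)), "MP2"))
  f <- .active_fock(H)
  eps <- diag(f)
  occ <- 1:no; vir <- (no + 1):n
  t2 <- array(0, c(no, no, nv, nv))
  for (i in occ) for (j in occ) for (a in seq_len(nv)) for (b in seq_len(nv))
    t2[i, j, a, b] <- H$g2[i, vir[a], j, vir[b]] /
      (eps[i] + eps[j] - eps[vir[a]] - eps[vir[b]])
  t2_amplitudes(t2, "MP2")
}

# closed-shell Fock matrix of the active space at the aufbau reference
.active_fock <- function(H) {
  n <- H$n_orb; no <- H$n_alpha
  f <- H$h1
  if (no > 0) for (j in 1:no)
    f <- f + 2 * H$g2[, , j, j] - H$g2[, j, j, ]
  (f + t(f)) / 2
}

# reference (aufbau determinant) energy of the active Hamiltonian
.reference_energy <- function(H) {
  no <- H$n_alpha
  e <- H$e_const
  if (no > 0) {
    e <- e + 2 * sum(diag(H$h1)[1:no])
    for (i in 1:no) for (j in 1:no)
      e <- e + 2 * H$g2[i, i, j, j] - H$g2[i, j, j, i]
  }
  e
}
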