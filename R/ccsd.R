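# Spin-orbital CCSD for small active-space Hamiltonians, used to generate
# t2 amplitudes for the double-factorization initializer.  Standard
# intermediate (Stanton-style) formulation, DIIS-accelerated, with a
# denominator level shift for quasi-degenerate references (the converged
# amplitudes are shift-independent because updates use the true residual).

# tensor contraction: contract axes axA of A with axes axB of B; result has
# the free axes of A (original order) followed by the free axes of B
.tcontract <- function(A, B, axA, axB) {
  da <- dim(A); db <- dim(B)
  fa <- setdiff(seq_along(da), axA); fb <- setdiff(seq_along(db), axB)
  Am <- matrix(aperm(A, c(fa, axA)), prod(da[fa]), prod(da[axA]))
  Bm <- matrix(aperm(B, c(axB, fb)), prod(db[axB]), prod(db[fb]))
  array(Am %*% Bm, c(da[fa], db[fb]))
}

# spin-orbital antisymmetrized integrals <pq||rs> (physicist) and Fock
# matrix; spin orbitals blocked (all alpha, then all beta)
.so_integrals <- function(H) {
  n <- H$n_orb
  nso <- 2L * n
  spat <- c(1:n, 1:n)
  spin <- c(rep(1L, n), rep(2L, n))
  phys <- array(0, rep(nso, 4))
  for (p in 1:nso) for (q in 1:nso) for (r in 1:nso) for (s in 1:nso)
    if (spin[p] == spin[r] && spin[q] == spin[s])
      phys[p, q, r, s] <- H$g2[spat[p], spat[r], spat[q], spat[s]]
  anti <- phys - aperm(phys, c(1, 2, 4, 3))
  hso <- matrix(0, nso, nso)
  for (p in 1:nso) for (q in 1:nso)
    if (spin[p] == spin[q]) hso[p, q] <- H$h1[spat[p], spat[q]]
  occ <- c(seq_len(H$n_alpha), n + seq_len(H$n_beta))
  f <- hso
  for (i in occ) f <- f + anti[, i, , i]
  list(anti = anti, fock = f, occ = occ,
       vir = setdiff(seq_len(nso), occ), nso = nso)
}

#' CCSD t2 amplitudes in an active space
#'
#' Solves the spin-orbital CCSD amplitude equations for the active-space
#' Hamiltonian and returns the closed-shell spatial doubles
#' `t2[i,j,a,b] = t(i alpha, j beta -> a alpha, b beta)`.
#'
#' @param H a [molecular_hamiltonian()] with `n_alpha == n_beta`.
#' @param max_iter iteration limit.
#' @param conv_tol convergence threshold on the amplitude change.
#' @param shift denominator level shift (Hartree) stabilizing
#'   quasi-degenerate references.
#' @param diis_dim DIIS subspace size.
#' @return a [t2_amplitudes()] object with attributes `energy` (CCSD
#'   correlation energy, Hartree), `t1` (spin-orbital singles) and
#'   `converged`.
#' @export
ccsd_t2 <- function(H, max_iter = 300, conv_tol = 1e-10, shift = 0.2,
                    diis_dim = 8) {
  stopifnot(H$n_alpha == H$n_beta)
  n <- H$n_orb; no_sp <- H$n_alpha; nv_sp <- n - no_sp
  if (no_sp == 0 || nv_sp == 0) {
    out <- t2_amplitudes(array(0, c(no_sp, no_sp, nv_sp, nv_sp)), "CCSD")
    attr(out, "energy") <- 0; attr(out, "converged") <- TRUE
    return(out)
  }
  so <- .so_integrals(H)
  occ <- so$occ; vir <- so$vir
  no <- length(occ); nv <- length(vir)
  f <- so$fock; W <- so$anti
  foo <- f[occ, occ, drop = FALSE]; fvv <- f[vir, vir, drop = FALSE]
  fov <- f[occ, vir, drop = FALSE]
  Woooo <- W[occ, occ, occ, occ, drop = FALSE]
  Wooov <- W[occ, occ, occ, vir, drop = FALSE]
  Woovo <- W[occ, occ, vir, occ, drop = FALSE]
  Woovv <- W[occ, occ, vir, vir, drop = FALSE]
  Wovov <- W[occ, vir, occ, vir, drop = FALSE]
  Wovvo <- W[occ, vir, vir, occ, drop = FALSE]
  Wovoo <- W[occ, vir, occ, occ, drop = FALSE]
  Wovvv <- W[occ, vir, vir, vir, drop = FALSE]
  Wvovv <- W[vir, occ, vir, vir, drop = FALSE]
  Wvvvo <- W[vir, vir, vir, occ, drop = FALSE]
  Wvvvv <- W[vir, vir, vir, vir, drop = FALSE]
  eps_o <- diag(foo); eps_v <- diag(fvv)
  D1 <- outer(eps_o, eps_v, `-`)
  D2 <- outer(outer(eps_o, eps_o, `+`), outer(eps_v, eps_v, `+`), `-`)
  D1s <- D1 - shift; D2s <- D2 - shift
  P_ab <- function(x) x - aperm(x, c(1, 2, 4, 3))
  P_ij <- function(x) x - aperm(x, c(2, 1, 3, 4))
  t1 <- matrix(0, no, nv)
  t2 <- Woovv / D2s
  diis_v <- list(); diis_r <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ot <- .tcontract(t1, t1, integer(0), integer(0))        # (i,a,j,b)
    o1 <- aperm(ot, c(1, 3, 2, 4))                          # t1_ia t1_jb
    o2 <- aperm(ot, c(1, 3, 4, 2))                          # t1_ib t1_ja
    tau_t <- t2 + 0.5 * (o1 - o2)
    tau <- t2 + o1 - o2
    Fae <- fvv - diag(diag(fvv), nv, nv) -
      0.5 * .tcontract(t1, fov, 1, 1) +
      .tcontract(t1, Wovvv, c(1, 2), c(1, 3)) -
      0.5 * .tcontract(tau_t, Woovv, c(1, 2, 4), c(1, 2, 4))
    Fmi <- foo - diag(diag(foo), no, no) +
      0.5 * .tcontract(fov, t1, 2, 2) +
      .tcontract(t1, Wooov, c(1, 2), c(2, 4)) +
      0.5 * t(.tcontract(tau_t, Woovv, c(2, 3, 4), c(2, 3, 4)))
    Fme <- fov + .tcontract(t1, Woovv, c(1, 2), c(2, 4))
    Wmnij <- Woooo +
      P_ij_34(.tcontract(Wooov, t1, 4, 2)) +
      0.25 * aperm(.tcontract(Woovv, tau, c(3, 4), c(3, 4)), c(1, 2, 3, 4))
    Wabef <- Wvvvv -
      P_ab_12(aperm(.tcontract(Wvovv, t1, 2, 1), c(1, 4, 2, 3))) +
      0.25 * aperm(.tcontract(tau, Woovv, c(1, 2), c(1, 2)), c(3, 4, 1, 2))
    Xjnfb <- 0.5 * t2 + o1                                  # (j,n,f,b)
    Wmbej <- Wovvo +
      .tcontract(Wovvv, t1, 4, 2) -
      aperm(.tcontract(Woovo, t1, 2, 1), c(1, 4, 2, 3)) -
      aperm(.tcontract(Xjnfb, Woovv, c(2, 3), c(2, 4)), c(3, 2, 4, 1))
    # singles residual
    rhs1 <- fov +
      .tcontract(t1, Fae, 2, 2) -
      .tcontract(Fmi, t1, 1, 1) +
      .tcontract(t2, Fme, c(2, 4), c(1, 2)) -
      t(.tcontract(t1, Wovov, c(1, 2), c(1, 4))) -
      0.5 * .tcontract(t2, Wovvv, c(2, 3, 4), c(1, 3, 4)) -
      0.5 * t(.tcontract(t2, Woovo, c(1, 2, 4), c(2, 1, 3)))
    # doubles residual
    Gbe <- Fae - 0.5 * .tcontract(t1, Fme, 1, 1)
    Hmj <- Fmi + 0.5 * .tcontract(Fme, t1, 2, 2)
    rhs2 <- Woovv +
      P_ab(.tcontract(t2, Gbe, 4, 2)) -
      P_ij(aperm(.tcontract(t2, Hmj, 2, 1), c(1, 4, 2, 3))) +
      0.5 * aperm(.tcontract(tau, Wmnij, c(1, 2), c(1, 2)), c(3, 4, 1, 2)) +
      0.5 * .tcontract(tau, Wabef, c(3, 4), c(3, 4)) +
      P_ij(P_ab(aperm(.tcontract(t2, Wmbej, c(2, 4), c(1, 3)), c(1, 4, 2, 3)))) -
      P_ij(P_ab(aperm(.tcontract(t1, .tcontract(t1, Wovvo, 1, 1), 2, 3),
                      c(1, 4, 2, 3)))) +
      P_ij(aperm(.tcontract(t1, Wvvvo, 2, 3), c(1, 4, 2, 3))) -
      P_ab(aperm(.tcontract(t1, Wovoo, 1, 1), c(3, 4, 1, 2)))
    res1 <- rhs1 - t1 * D1
    res2 <- rhs2 - t2 * D2
    t1n <- t1 + res1 / D1s
    t2n <- t2 + res2 / D2s
    dmax <- max(max(abs(t1n - t1)), max(abs(t2n - t2)))
    t1 <- t1n; t2 <- t2n
    # DIIS
    diis_v[[length(diis_v) + 1L]] <- c(t1, t2)
    diis_r[[length(diis_r) + 1L]] <- c(res1 / D1s, res2 / D2s)
    if (length(diis_v) > diis_dim) { diis_v <- diis_v[-1]; diis_r <- diis_r[-1] }
    m <- length(diis_v)
    if (m > 1) {
      B <- matrix(0, m + 1, m + 1)
      for (a in 1:m) for (b in 1:m) B[a, b] <- sum(diis_r[[a]] * diis_r[[b]])
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      cf <- tryCatch(solve(B, c(rep(0, m), -1))[1:m], error = function(e) NULL)
      if (!is.null(cf)) {
        v <- Reduce(`+`, Map(`*`, diis_v, cf))
        t1 <- matrix(v[seq_len(no * nv)], no, nv)
        t2 <- array(v[-seq_len(no * nv)], c(no, no, nv, nv))
      }
    }
    if (dmax < conv_tol) { converged <- TRUE; break }
  }
  e_cc <- sum(fov * t1) +
    0.25 * sum(Woovv * t2) +
    0.5 * sum(Woovv * aperm(.tcontract(t1, t1, integer(0), integer(0)),
                            c(1, 3, 2, 4)))
  # closed-shell spatial doubles: alpha-beta block
  i_a <- seq_len(no_sp); j_b <- no_sp + seq_len(no_sp)
  a_a <- seq_len(nv_sp); b_b <- nv_sp + seq_len(nv_sp)
  t2_sp <- t2[i_a, j_b, a_a, b_b, drop = FALSE]
  out <- t2_amplitudes(array(t2_sp, c(no_sp, no_sp, nv_sp, nv_sp)), "CCSD")
  attr(out, "energy") <- e_cc
  attr(out, "t1") <- t1
  attr(out, "converged") <- converged
  if (!converged)
    warning("CCSD did not converge to ", conv_tol, " in ", max_iter,
            " iterations (last change ", signif(dmax, 3), ")")
  out
}

# permutation helpers on specific axis pairs (used by the intermediates)
P_ij_34 <- function(x) x - aperm(x, c(1, 2, 4, 3))
P_ab_12 <- function(x) x - aperm(x, c(2, 1, 3, 4))
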