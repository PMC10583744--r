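# Hamiltonian containers, Hubbard models, FCIDUMP round trips, Cholesky
# factorization and the FCI reference solver.

test_that("Hubbard dimer ground state matches the closed-form singlet energy", {
  # E0 = (U - sqrt(U^2 + 16 t^2)) / 2 for 2 sites, (1,1) electrons
  set.seed(42)
  for (k in 1:20) {
    t <- runif(1, 0.2, 2); u <- runif(1, 0, 8)
    H <- build_hubbard(2, t = t, u = u, n_alpha = 1, n_beta = 1)
    expect_equal(fci_solve(H)$energy, (u - sqrt(u^2 + 16 * t^2)) / 2,
                 tolerance = 1e-10)
  }
  # free fermions fill the bonding orbital
  H0 <- build_hubbard(2, t = 1, u = 0, n_alpha = 1, n_beta = 1)
  expect_equal(fci_solve(H0)$energy, -2, tolerance = 1e-12)
  # single doubly occupied site
  H1 <- build_hubbard(1, t = 1, u = 5, n_alpha = 1, n_beta = 1)
  expect_equal(fci_solve(H1)$energy, 5, tolerance = 1e-12)
  expect_error(build_hubbard(2, boundary = "periodic", n_alpha = 1, n_beta = 1),
               "periodic")
})

test_that("FCIDUMP round trip is lossless and header errors are caught", {
  H <- rand_hamiltonian(3, 2, 1, seed = 1)
  path <- tempfile(fileext = ".fcidump")
  write_fcidump(H, path)
  H2 <- load_fcidump(path)
  expect_equal(H2$h1, H$h1, tolerance = 1e-12)
  expect_equal(H2$g2, H$g2, tolerance = 1e-12)
  expect_equal(H2$e_const, H$e_const, tolerance = 1e-12)
  expect_equal(H2$n_alpha, H$n_alpha)
  expect_equal(fci_solve(H2)$energy, fci_solve(H)$energy, tolerance = 1e-10)
  # Hubbard export/reload preserves the FCI energy
  Hh <- build_hubbard(3, t = 0.7, u = 2.5, n_alpha = 2, n_beta = 1)
  ph <- tempfile(); write_fcidump(Hh, ph)
  expect_equal(fci_solve(load_fcidump(ph))$energy, fci_solve(Hh)$energy,
               tolerance = 1e-10)
  # constant-only file: 0-electron energy equals the constant
  pc <- tempfile()
  writeLines(c(" &FCI NORB=2,NELEC=0,MS2=0,", " &END",
               sprintf("%23.16E %3d %3d %3d %3d", 1.25, 0, 0, 0, 0)), pc)
  Hc <- load_fcidump(pc)
  expect_equal(fci_solve(Hc, 0, 0)$energy, 1.25, tolerance = 1e-12)
  # missing header
  pb <- tempfile()
  writeLines(c(" &FCI NELEC=2,", " &END", " 1.0 0 0 0 0"), pb)
  expect_error(load_fcidump(pb), "NORB")
  # index out of range
  pi2 <- tempfile()
  writeLines(c(" &FCI NORB=2,NELEC=2,MS2=0,", " &END",
               " 1.0 3 1 1 1"), pi2)
  expect_error(load_fcidump(pi2), "exceeds")
})

test_that("pivoted Cholesky reconstructs the integrals with few factors", {
  # zero interaction: no factors
  Hz <- build_hubbard(2, t = 1, u = 0, n_alpha = 1, n_beta = 1)
  expect_length(cholesky_factorize(Hz)$factors, 0)
  # rank-1: a single factor recovering L up to sign
  n <- 3
  set.seed(3)
  L <- matrix(rnorm(n * n), n, n); L <- (L + t(L)) / 2
  H1 <- molecular_hamiltonian(diag(n), outer(L, L), 0, 1, 1)
  ch <- cholesky_factorize(H1)
  expect_length(ch$factors, 1)
  sgn <- sign(sum(ch$factors[[1]] * L))
  expect_equal(sgn * ch$factors[[1]], L, tolerance = 1e-10)
  # molecular integrals: reconstruction to 1e-10 with at most N^2 factors,
  # residual non-increasing in factor count
  Hm <- h2_system_at(0.7414)$H
  chm <- cholesky_factorize(Hm, tol = 1e-10)
  expect_lte(length(chm$factors), Hm$n_orb^2)
  rec <- Reduce(`+`, lapply(chm$factors, function(f) outer(f, f)))
  expect_lt(max(abs(rec - Hm$g2)), 1e-8)
  resid <- sapply(seq_along(chm$factors), function(k) {
    r <- Hm$g2 - Reduce(`+`, lapply(chm$factors[1:k], function(f) outer(f, f)))
    sum(abs(r))
  })
  expect_true(all(diff(resid) < 1e-12))
})

test_that("FCI energy is invariant under a consistent orbital rotation", {
  H <- h2_system_at(0.7414)$H
  e0 <- fci_solve(H)$energy
  set.seed(5)
  for (k in 1:3) {
    K <- rand_K(H$n_orb, 0.7)
    K <- Re(K)                       # real rotation keeps integrals real
    es <- eigen(1i * K, symmetric = TRUE)
    U <- Re(es$vectors %*% (exp(-1i * es$values) * Conj(t(es$vectors))))
    h1 <- t(U) %*% H$h1 %*% U
    g2 <- lucj:::.ao2mo(H$g2, U)
    Hr <- molecular_hamiltonian((h1 + t(h1)) / 2, g2, H$e_const,
                                H$n_alpha, H$n_beta)
    expect_equal(fci_solve(Hr)$energy, e0, tolerance = 1e-10)
  }
})

test_that("aufbau reference reproduces the determinant energy by direct contraction", {
  sys <- h2_system_at(0.7414)
  H <- sys$H
  ref <- hf_reference(H)
  prob <- lucj_problem(H)
  e_det <- Re(sum(Conj(ref$amp) * (prob$Hs %*% ref$amp))) + H$e_const
  expect_equal(e_det, lucj:::.reference_energy(H), tolerance = 1e-12)
  expect_equal(e_det, sys$scf$energy, tolerance = 1e-10)
  # 0-electron sector: vacuum amplitude one
  sp0 <- ci_space(2, 0, 0)
  expect_equal(Mod(hf_reference(sp0)$amp), 1)
})

test_that("sector FCI agrees with dense Fock-space diagonalization", {
  H <- h2_system_at(0.7414)$H
  A <- fock_annihilators(4)
  dimf <- 16
  Hf <- fock_one_body(H$h1, A)
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    g <- H$g2[p, q, r, s]
    if (g == 0) next
    for (sg in c(0L, 2L)) for (tu in c(0L, 2L)) {
      Hf <- Hf + 0.5 * g * (t(A[[p + sg]]) %*% (t(A[[r + tu]]) %*% A[[s + tu]]) %*% A[[q + sg]])
    }
  }
  Hf <- (Hf + Conj(t(Hf))) / 2
  # project onto the (1,1) sector and take the lowest eigenvalue
  nmat <- Reduce(`+`, lapply(1:2, function(p) t(A[[p]]) %*% A[[p]]))
  nmat_b <- Reduce(`+`, lapply(3:4, function(p) t(A[[p]]) %*% A[[p]]))
  sel <- which(abs(diag(Re(nmat)) - 1) < 1e-12 & abs(diag(Re(nmat_b)) - 1) < 1e-12)
  e_dense <- min(eigen(Hf[sel, sel], symmetric = TRUE)$values) + H$e_const
  expect_equal(fci_solve(H)$energy, e_dense, tolerance = 1e-10)
})

test_that("orbital permutation of a Hamiltonian preserves spectra", {
  H <- rand_hamiltonian(3, 2, 1, seed = 9)
  Hp <- permute_hamiltonian(H, c(2L, 3L, 1L))
  expect_equal(fci_solve(Hp)$energy, fci_solve(H)$energy, tolerance = 1e-10)
})
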