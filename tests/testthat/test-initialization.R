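# Double factorization of t2 amplitudes, layer construction and projection
# onto restricted topologies.

test_that("degenerate and empty amplitude sets factorize trivially", {
  z <- t2_amplitudes(array(0, c(2, 2, 2, 2)), "MP2")
  fd <- double_factorize_t2(z)
  expect_length(fd$terms, 0)
  expect_equal(fd$reconstruction_error, 0)
  expect_equal(layers_from_factorization(fd)$n_layers, 0L)
})

test_that("a rank-1 amplitude tensor yields one eigenvalue, recovered exactly", {
  set.seed(31)
  no <- 2; nv <- 2
  v <- matrix(rnorm(nv * no), nv, no)
  lam <- 0.37
  Tm <- lam * sum(v^2) * outer(as.vector(v) / sqrt(sum(v^2)),
                               as.vector(v) / sqrt(sum(v^2)))
  t2a <- aperm(array(Tm, c(nv, no, nv, no)), c(2, 4, 1, 3))
  fd <- double_factorize_t2(t2_amplitudes(t2a, "MP2"))
  expect_length(fd$terms, 1)
  expect_equal(fd$terms[[1]]$lambda, lam * sum(v^2), tolerance = 1e-12)
})

test_that("untruncated factorization rebuilds the doubles generator exactly", {
  # T2 - T2^dag = (i/2) sum_g lambda_g [(S+A)^2 - (S-A)^2] as sector
  # operators, with T2 assembled by direct tensor contraction
  set.seed(32)
  no <- 2; nv <- 2; n <- 4
  t2r <- array(rnorm(no * no * nv * nv, 0, 0.2), c(no, no, nv, nv))
  t2r <- (t2r + aperm(t2r, c(2, 1, 4, 3))) / 2
  fd <- double_factorize_t2(t2_amplitudes(t2r, "MP2"))
  sp <- ci_space(n, 2, 2)
  E <- function(p, q) as.matrix(lucj:::.sector_Epq(sp, p, q))
  T2op <- matrix(0, sp$dim, sp$dim)
  for (i in 1:no) for (j in 1:no) for (a in 1:nv) for (b in 1:nv)
    T2op <- T2op + 0.5 * t2r[i, j, a, b] * (E(no + a, i) %*% E(no + b, j))
  G <- T2op - t(T2op)
  onebody <- function(B) sector_one_body(sp, B)
  Grec <- matrix(0i, sp$dim, sp$dim)
  for (tm in fd$terms) {
    Bp <- onebody(tm$plus_generator); Bm <- onebody(tm$minus_generator)
    Grec <- Grec + (1i * tm$lambda / 2) * (Bp %*% Bp - Bm %*% Bm)
  }
  expect_lt(max(Mod(Grec - G)), 1e-10)
  expect_lte(length(fd$terms), no * nv)
})

test_that("two layers per eigenvalue realize the factorized product exactly", {
  # the layer pair equals e^{-i(lam/2)(S-A)^2-exponential} after the
  # e^{+i(lam/2)(S+A)^2} factor (plus applied first); the deviation from
  # e^{T2 - T2dag} is a genuine second-order splitting error
  set.seed(33)
  no <- 2; nv <- 2; n <- 4
  v <- matrix(rnorm(nv * no), nv, no)
  mk <- function(scale) {
    Tm <- scale * outer(as.vector(v), as.vector(v))
    aperm(array(Tm, c(nv, no, nv, no)), c(2, 4, 1, 3))
  }
  sp <- ci_space(n, 2, 2)
  ref <- hf_reference(sp)
  E <- function(p, q) as.matrix(lucj:::.sector_Epq(sp, p, q))
  devs <- sapply(c(0.4, 0.04), function(sc) {
    t2a <- mk(sc)
    fd <- double_factorize_t2(t2_amplitudes(t2a, "MP2"))
    par <- layers_from_factorization(fd)
    expect_equal(par$n_layers, 2L)
    tm <- fd$terms[[1]]
    Bp <- sector_one_body(sp, tm$plus_generator)
    Bm <- sector_one_body(sp, tm$minus_generator)
    P <- fock_expm(Bp %*% Bp, 1i * tm$lambda / 2)
    Q <- fock_expm(Bm %*% Bm, -1i * tm$lambda / 2)
    st <- prepare_state(par, ref)
    expect_lt(max(Mod(st$amp - Q %*% (P %*% ref$amp))), 1e-11)
    T2op <- matrix(0, sp$dim, sp$dim)
    for (i in 1:no) for (j in 1:no) for (a in 1:nv) for (b in 1:nv)
      T2op <- T2op + 0.5 * t2a[i, j, a, b] * (E(no + a, i) %*% E(no + b, j))
    G <- T2op - t(T2op)
    esG <- eigen(1i * G, symmetric = TRUE)
    w <- esG$vectors %*% (exp(-1i * esG$values) *
                            crossprod(Conj(esG$vectors), ref$amp))
    max(Mod(st$amp - w))
  })
  # quadratic scaling of the splitting error with the amplitude norm
  expect_lt(devs[2], devs[1] / 50)
})

test_that("structural layer counts follow the eigenvalue budget", {
  # a nondegenerate (6e,6o) amplitude tensor has N_o N_v = 9 eigenvalues,
  # hence 18 layers untruncated
  set.seed(34)
  t2r <- array(rnorm(81, 0, 0.1), c(3, 3, 3, 3))
  t2r <- (t2r + aperm(t2r, c(2, 1, 4, 3))) / 2
  fd <- double_factorize_t2(t2_amplitudes(t2r, "MP2"))
  expect_length(fd$terms, 9)
  expect_equal(2 * length(fd$terms), 18)
  # truncation keeps the largest |lambda| and reports the residual
  lam <- sapply(fd$terms, function(t) abs(t$lambda))
  expect_true(all(diff(lam) <= 1e-14))
  fd2 <- double_factorize_t2(t2_amplitudes(t2r, "MP2"), tol = lam[5])
  expect_lte(length(fd2$terms), 5)
  expect_gt(fd2$reconstruction_error, 0)
})

test_that("t2 initialization lowers the energy below the mean-field reference", {
  sys <- h2_system_at(0.7414)
  par <- layers_from_factorization(double_factorize_t2(sys$t2))
  e0 <- lucj_energy(par, sys$H, hf_reference(sys$H))
  expect_lt(e0, sys$scf$energy)
  expect_gte(e0, sys$fci$energy - 1e-9)
})

test_that("projection permutes the largest on-site couplings onto S", {
  n <- 4
  top_a <- make_topology("all-to-all", n)
  w <- c(0.1, 0.9, 0.8, 0.05)
  J <- diag(w)
  par <- lucj_parameters(list(list(K = matrix(0i, n, n),
                                   J_ss = matrix(0, n, n), J_os = J)),
                         topology = top_a)
  hex <- make_topology("hex", n)
  pj <- project_to_topology(par, hex)
  perm <- attr(pj, "permutation")
  # brute-force oracle: permutation maximizing the |J_pp| weight on S
  best <- -Inf; s_pos <- hex$s_set + 1
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ]
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    val <- sum(w[which(p %in% s_pos)])
    best <- max(best, val)
  }
  expect_equal(sum(w[which(perm %in% s_pos)]), best, tolerance = 1e-12)
  # orbitals 1 and 2 (0-based) carry the big weights -> they land on S
  expect_true(all(perm[c(2, 3)] %in% s_pos))
  # projected couplings obey the hex masks
  mh <- parameter_masks(hex)
  expect_true(all(abs(pj$layers[[1]]$J_os[!mh$mask_os]) < 1e-14))
  # all-to-all -> all-to-all is the identity operation
  pid <- project_to_topology(par, top_a)
  expect_equal(attr(pid, "permutation"), 1:n)
  expect_equal(pid$layers[[1]]$J_os, J)
  # square keeps every orbital in S: masking only, no reordering gain
  psq <- project_to_topology(par, make_topology("square", n))
  expect_equal(sort(attr(psq, "permutation")), 1:n)
})
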