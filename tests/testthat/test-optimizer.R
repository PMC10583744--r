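# Variational optimization: driver correctness, zero-point stationarity,
# determinism, warm-start monotonicity.

test_that("the shared BFGS driver reaches a known quadratic minimum", {
  A <- matrix(c(4, 1, 0, 1, 3, -1, 0, -1, 2), 3, 3)
  b <- c(1, -2, 0.5)
  fn <- function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x)
  res <- minimize_objective(fn, c(0, 0, 0), optimizer_settings())
  xstar <- solve(A, b)
  expect_equal(res$par, xstar, tolerance = 1e-7)
  expect_equal(res$value, fn(xstar), tolerance = 1e-10)
  expect_true(res$converged)
  expect_true(all(c("energy", "grad_norm", "step_norm") %in%
                    names(res$trace)))
})

test_that("H2 at a single geometry reaches FCI with one layer plus X", {
  sys <- h2_system_at(0.7414)
  prob <- lucj_problem(sys$H)
  ref <- hf_reference(sys$H)
  init <- layers_from_factorization(double_factorize_t2(sys$t2), l_max = 2)
  opt <- lucj_minimize(prob, ref, init, optimizer_settings(seed = 2))
  expect_lte(abs(opt$best_energy - sys$fci$energy), 1e-8)
  expect_gte(opt$best_energy, sys$fci$energy - 1e-9)
  expect_equal(utils::tail(opt$trace$energy, 1), opt$best_energy,
               tolerance = 1e-9)
})

test_that("the zero-parameter configuration is a stationary point at an aufbau reference", {
  sys <- h2_system_at(1.0)
  ref <- hf_reference(sys$H)
  g <- stationarity_report(sys$H, ref, make_topology("all-to-all", 2), 1)
  expect_lte(g, 1e-7)
  # the K/J stationarity holds for any determinant reference, even one
  # that is far from the mean field (Hubbard site basis)
  Hh <- build_hubbard(3, t = 1, u = 4, n_alpha = 2, n_beta = 1)
  g2 <- stationarity_report(Hh, hf_reference(Hh),
                            make_topology("square", 3), 1)
  expect_lte(as.numeric(g2), 1e-7)
  # ... but the orbital-optimization gradient only vanishes when the
  # reference satisfies the Brillouin condition; an excited determinant
  # of an asymmetric system leaves it finite
  Hr <- rand_hamiltonian(3, 1, 1, seed = 44)
  sp <- ci_space(3, 1, 1)
  exc <- determinant_reference(sp, 2, 2)
  gexc <- stationarity_report(Hr, exc, make_topology("all-to-all", 3), 1)
  expect_lte(attr(gexc, "max_kj"), 1e-7)
  expect_gt(attr(gexc, "max_x"), 1e-4)
  # diagonal one-body Hamiltonian commutes with every Jastrow operator
  Hd <- molecular_hamiltonian(diag(c(-1, 0.5)), array(0, rep(2, 4)),
                              0, 1, 1)
  expect_lte(stationarity_report(Hd, hf_reference(Hd),
                                 make_topology("all-to-all", 2), 1), 1e-9)
})

test_that("a zero initialization warns and escapes via a seeded perturbation", {
  sys <- h2_system_at(0.9)
  prob <- lucj_problem(sys$H)
  ref <- hf_reference(sys$H)
  init <- lucj_zero_parameters(make_topology("all-to-all", 2), 1)
  expect_warning(opt <- lucj_minimize(prob, ref, init,
                                      optimizer_settings(seed = 5)),
                 "stationary")
  expect_lt(opt$best_energy, sys$scf$energy - 1e-6)
})

test_that("fixed seeds reproduce optimization traces exactly", {
  sys <- h2_system_at(0.7414)
  prob <- lucj_problem(sys$H)
  ref <- hf_reference(sys$H)
  init <- layers_from_factorization(double_factorize_t2(sys$t2), l_max = 2)
  o1 <- lucj_minimize(prob, ref, init, optimizer_settings(seed = 11))
  o2 <- lucj_minimize(prob, ref, init, optimizer_settings(seed = 11))
  expect_equal(o1$trace$energy, o2$trace$energy, tolerance = 1e-12)
  expect_equal(o1$best_energy, o2$best_energy, tolerance = 1e-12)
})

test_that("warm-started deeper ansatzes never end higher (bootstrap audit)", {
  H <- build_hubbard(4, t = 1, u = 4, n_alpha = 2, n_beta = 2)
  # a Hubbard aufbau reference in the site basis is not the mean field;
  # rotate to the non-interacting band basis (ascending band energy) first
  es <- eigen(H$h1, symmetric = TRUE)
  ordb <- order(es$values)
  U <- es$vectors[, ordb]
  h1 <- t(U) %*% H$h1 %*% U
  g2 <- lucj:::.ao2mo(H$g2, U)
  Hb <- molecular_hamiltonian((h1 + t(h1)) / 2, g2, 0, 2, 2)
  fdp <- double_factorize_t2(lucj:::.active_mp2_t2(Hb))
  plan <- list(
    list(topology = "square", L = 1L,
         init = suppressWarnings(layers_from_factorization(fdp, l_max = 1))),
    list(topology = "square", L = 2L))
  st <- optimizer_settings(seed = 4, maxit = 150)
  bs <- suppressWarnings(lucj_bootstrap(Hb, plan, st))
  e1 <- bs$stages[["square/L1"]]$opt$best_energy
  e2 <- bs$stages[["square/L2"]]$opt$best_energy
  expect_lte(e2, e1 + 1e-9)
  expect_true(bs$monotone)
  # single-stage plan on the permutation-free topology behaves exactly
  # like a direct minimization
  plan1 <- list(list(topology = "all-to-all", L = 1L,
                     init = suppressWarnings(
                       layers_from_factorization(fdp, l_max = 1))))
  bs1 <- suppressWarnings(lucj_bootstrap(Hb, plan1, st))
  opt1 <- suppressWarnings(lucj_minimize(
    lucj_problem(Hb), hf_reference(Hb), plan1[[1]]$init, st))
  expect_equal(bs1$stages[[1]]$opt$best_energy, opt1$best_energy,
               tolerance = 1e-9)
})

test_that("adversarial starts show the rugged-optimization diagnostics", {
  # deliberately bad starting parameters on a Hubbard chain produce the
  # characteristic non-monotone energy trace with oscillating gradient and
  # step norms (qualitative signature only)
  H <- build_hubbard(4, t = 1, u = 8, n_alpha = 2, n_beta = 2)
  prob <- lucj_problem(H)
  ref <- hf_reference(H)
  top <- make_topology("linear", 4)
  set.seed(666)
  par <- rand_params(top, 1, scale = 2.5)
  opt <- lucj_minimize(prob, ref, par, optimizer_settings(maxit = 40))
  tr <- opt$trace
  expect_gt(nrow(tr), 5)
  # gradient norm is not monotonically decreasing (oscillations)
  expect_gt(sum(diff(tr$grad_norm) > 0), 0)
  expect_gt(max(tr$step_norm), 0)
})
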