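# Memoized fixtures shared across test files.  Everything is generated in
# code at test time; the heavier electronic-structure objects are built
# once per session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

h2_system_at <- function(r) {
  fixture(sprintf("h2_%.4f", r), function() {
    s <- rhf(h2_molecule(r))
    H <- active_hamiltonian(s, 1:2)
    list(scf = s, H = H, fci = fci_solve(H),
         t2 = lucj:::.active_mp2_t2(H))
  })
}

cb_system <- function() {
  fixture("cyclobutadiene", function() cyclobutadiene_system())
}

cb_bootstrap <- function() {
  fixture("cb_bootstrap", function() {
    sys <- cb_system()
    fd <- double_factorize_t2(sys$t2, tol = 1e-12)
    plan <- list(
      list(topology = "all-to-all", L = 2L,
           init = layers_from_factorization(fd, l_max = 2)),
      list(topology = "square", L = 2L),
      list(topology = "hex", L = 3L),
      list(topology = "heavy-hex-zigzag", L = 4L))
    lucj_bootstrap(sys$H, plan, optimizer_settings(seed = 7L))
  })
}

# random symmetric masked J matrix
rand_J <- function(n, mask, scale = 0.5) {
  J <- matrix(stats::rnorm(n * n, 0, scale), n, n)
  J <- (J + t(J)) / 2
  J[!mask] <- 0
  J
}

# random complex anti-Hermitian generator
rand_K <- function(n, scale = 0.4) {
  Kr <- matrix(stats::rnorm(n * n, 0, scale), n, n) +
    1i * matrix(stats::rnorm(n * n, 0, scale), n, n)
  (Kr - Conj(t(Kr))) / 2
}

# random LUCJ parameter set on a topology
rand_params <- function(top, n_layers, scale = 0.4, with_X = TRUE) {
  n <- top$n_orb
  m <- parameter_masks(top)
  layers <- replicate(n_layers, list(K = rand_K(n, scale),
                                     J_ss = rand_J(n, m$mask_ss, scale),
                                     J_os = rand_J(n, m$mask_os, scale)),
                      simplify = FALSE)
  lucj_parameters(layers, X = if (with_X) rand_K(n, scale) else NULL,
                  topology = top)
}

# random molecular Hamiltonian with exact 8-fold integral symmetry
rand_hamiltonian <- function(n, n_alpha, n_beta, n_chol = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h1 <- matrix(stats::rnorm(n * n), n, n); h1 <- (h1 + t(h1)) / 2
  g2 <- array(0, rep(n, 4))
  for (k in seq_len(n_chol)) {
    L <- matrix(stats::rnorm(n * n), n, n); L <- (L + t(L)) / 2
    g2 <- g2 + outer(L, L)
  }
  molecular_hamiltonian(h1, g2, e_const = stats::rnorm(1),
                        n_alpha = n_alpha, n_beta = n_beta)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
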