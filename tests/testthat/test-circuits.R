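# Circuit compilation: gate counts, depths, and statevector equivalence
# with the fermionic simulator under the Jordan-Wigner mapping.

test_that("compiled orbital rotations carry the canonical gate counts", {
  set.seed(51)
  for (N in c(3, 4, 6)) {
    circ <- compile_orbital_rotation(rand_K(N))
    gc <- gate_counts(circ)
    expect_equal(unname(gc["Rz"]), 2L * N)
    expect_equal(unname(gc["G"]), N * (N - 1L))
    expect_equal(circuit_depth(circ), 1L + N)
  }
  # K = 0 compiles to an identity-angle circuit
  circ0 <- compile_orbital_rotation(matrix(0i, 3, 3))
  v <- simulate_circuit(circ0, c(1, 0, 1, 0, 0, 0))
  expect_equal(Mod(v[sum(c(1, 0, 1, 0, 0, 0) * 2^(0:5)) + 1]), 1,
               tolerance = 1e-12)
})

test_that("compiled rotations reproduce the fermionic one-body action", {
  set.seed(52)
  for (rep in 1:3) {
    N <- 3
    K <- rand_K(N)
    circ <- compile_orbital_rotation(K)
    sp <- ci_space(N, 2, 1)
    v0 <- complex(sp$dim); v0[] <- rnorm(sp$dim) + 1i * rnorm(sp$dim)
    cv <- civector(v0 / sqrt(sum(Mod(v0)^2)), sp)
    out <- apply_orbital_rotation(cv, K)
    wsim <- simulate_circuit(circ, fock_embed(cv))
    expect_lt(max(Mod(wsim - fock_embed(out))), 1e-10)
  }
})

test_that("Jastrow blocks have the canonical counts and constant depth", {
  set.seed(53)
  for (N in c(4, 6, 8)) {
    for (tp in c("square", "hex", "linear")) {
      top <- make_topology(tp, N)
      m <- parameter_masks(top)
      circ <- compile_jastrow(rand_J(N, m$mask_ss), rand_J(N, m$mask_os), top)
      expect_equal(circuit_depth(circ), 4L,
                   info = sprintf("%s N=%d", tp, N))
      n_unn <- unname(gate_counts(circ)["Unn"])
      expected <- switch(tp, square = N + 2 * (N - 1),
                         linear = 1 + 2 * (N - 1),
                         hex = ceiling(N / 2) + 2 * (N - 1))
      expect_equal(n_unn, expected)
      # locality: no SWAP gates in any local-topology circuit
      expect_false(any(vapply(circ$gates, `[[`, "", "name") %in%
                         c("SWAP", "UnnSWAP")))
    }
    # heavy-hex: depth 8 and 4 CX per ancilla-mediated coupling
    th <- make_topology("heavy-hex-zigzag", N)
    mh <- parameter_masks(th)
    ch <- compile_jastrow(rand_J(N, mh$mask_ss), rand_J(N, mh$mask_os), th)
    expect_equal(circuit_depth(ch), 8L)
    expect_equal(unname(gate_counts(ch)["CX"]), 4L * length(th$s_set))
    # all-to-all swap network: every pair exactly once, depth 1 + 4N
    ta <- make_topology("all-to-all", N)
    ma <- parameter_masks(ta)
    ca <- compile_jastrow(rand_J(N, ma$mask_ss), rand_J(N, ma$mask_os), ta)
    expect_equal(unname(gate_counts(ca)["Unn"]), N * (2 * N - 1))
    expect_equal(unname(gate_counts(ca)["SWAP"]), N * (2 * N - 1))
    expect_equal(circuit_depth(ca), 1L + 4L * N)
  }
})

test_that("Jastrow circuits reproduce the fermionic phases (incl. ancillas)", {
  set.seed(54)
  N <- 3
  sp <- ci_space(N, 1, 2)
  v0 <- complex(sp$dim); v0[] <- rnorm(sp$dim) + 1i * rnorm(sp$dim)
  cv <- civector(v0 / sqrt(sum(Mod(v0)^2)), sp)
  for (tp in c("square", "hex", "linear", "heavy-hex-zigzag")) {
    top <- make_topology(tp, N)
    m <- parameter_masks(top)
    Jss <- rand_J(N, m$mask_ss); Jos <- rand_J(N, m$mask_os)
    circ <- compile_jastrow(Jss, Jos, top)
    out <- apply_jastrow_phase(cv, Jss, Jos)
    n_extra <- top$n_qubits - 2L * N
    wsim <- simulate_circuit(circ, fock_embed(cv, n_extra))
    expect_lt(max(Mod(wsim - fock_embed(out, n_extra))), 1e-10)
    if (n_extra > 0) {
      anc_mask <- sum(2^(2 * N + seq_len(n_extra) - 1L))
      idx <- which(bitwAnd(0:(2^top$n_qubits - 1L), anc_mask) > 0)
      expect_lt(sum(Mod(wsim[idx])^2), 1e-10)   # ancilla back in |0>
    }
  }
})

test_that("a number-number gate phases only the doubly occupied state", {
  circ <- circuit(2, list(lucj:::gate("Unn", c(0, 1), 0.71)))
  v <- simulate_circuit(circ, c(1, 1))
  expect_equal(v[4], exp(-1i * 0.71), tolerance = 1e-12)
  v01 <- simulate_circuit(circ, c(1, 0))
  expect_equal(v01[2], 1 + 0i, tolerance = 1e-12)
  # empty circuit: initial basis state unchanged
  v0 <- simulate_circuit(circuit(3), c(0, 1, 0))
  expect_equal(which(Mod(v0) > 0), 3L)
})

test_that("full compiled ansatz circuits equal the fermionic statevector", {
  set.seed(55)
  N <- 3
  sp <- ci_space(N, 2, 1)
  ref <- hf_reference(sp)
  for (tp in c("square", "hex", "linear", "heavy-hex-zigzag", "all-to-all")) {
    top <- make_topology(tp, N)
    for (rep in 1:2) {
      par <- rand_params(top, 2)
      st <- prepare_state(par, ref)
      circ <- lucj_compile(par)
      n_extra <- top$n_qubits - 2L * N
      wsim <- simulate_circuit(circ, fock_embed(ref, n_extra))
      wexp <- fock_embed(st, n_extra)
      lay <- circ$metadata$layout
      if (!identical(lay, 0:(top$n_qubits - 1L)))
        wexp <- fock_relabel(wexp, lay)
      expect_lt(max_phase_aligned_diff(wsim, wexp), 1e-10)
    }
  }
})

test_that("circuits export to text and JSON listings", {
  circ <- compile_orbital_rotation(rand_K(2))
  txt <- circuit_export(circ)
  expect_match(txt, "^qubits 4\n")
  expect_match(txt, "g q\\[")
  js <- jsonlite::fromJSON(circuit_export(circ, "json"))
  expect_equal(js$n_qubits, 4)
  expect_equal(nrow(js$gates), length(circ$gates))
})

test_that("native-gate accounting follows the conversion factors", {
  df <- resource_estimate(6, "square", 2, native = "rzx")
  # one Rzx per number-number gate, two per Givens
  rot <- df[df$block == "exp(K)", ]
  expect_equal(rot$native, 2 * rot$G)
  jas <- df[df$block == "exp(iJ)", ]
  expect_equal(jas$native, jas$Unn)
  dfa <- resource_estimate(4, "all-to-all", 1, native = "rzx")
  ja <- dfa[dfa$block == "exp(iJ)", ]
  # fused number-number + SWAP costs 3 native gates
  expect_equal(ja$native, 3 * ja$Unn)
  dff <- resource_estimate(6, "hex", 1, native = "fsim")
  expect_equal(dff$native[1], dff$G[1])      # one fSim per Givens
  expect_equal(dff$native[2], dff$Unn[2])    # one fSim per number-number
})

test_that("resource formulas match the depth and counts of compiled blocks", {
  set.seed(56)
  for (N in c(4, 6)) {
    for (tp in c("square", "hex", "linear", "all-to-all", "heavy-hex-zigzag")) {
      df <- resource_estimate(N, tp, 1)
      jrow <- df[df$block == "exp(iJ)", ]
      top <- make_topology(tp, N)
      m <- parameter_masks(top)
      circ <- compile_jastrow(rand_J(N, m$mask_ss), rand_J(N, m$mask_os), top)
      expect_equal(circuit_depth(circ), jrow$depth)
      gc <- gate_counts(circ)
      expect_equal(unname(gc["Unn"]) %||% 0L, jrow$Unn)
    }
    rotrow <- resource_estimate(N, "square", 1)[1, ]
    circ <- compile_orbital_rotation(rand_K(N))
    expect_equal(circuit_depth(circ), rotrow$depth)
  }
})

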