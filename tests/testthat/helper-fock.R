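# Dense Jordan-Wigner Fock-space oracle, independent of the package's
# determinant-sector machinery: annihilation operators as explicit kronecker
# products, one-body/Jastrow operators assembled from them, exponentials by
# Hermitian eigendecomposition.

fock_annihilators <- function(n_qubits) {
  Z <- c(1, -1); I2 <- diag(2)
  sminus <- matrix(c(0, 0, 1, 0), 2, 2)     # |0><1|
  lapply(0:(n_qubits - 1), function(j) {
    M <- 1
    for (q in 0:(n_qubits - 1))
      M <- kronecker(if (q < j) diag(Z) else if (q == j) sminus else I2, M)
    M
  })
}

# spin-uniform one-body operator sum K[p,q] (a+_pa a_qa + a+_pb a_qb)
fock_one_body <- function(K, A) {
  N <- nrow(K); dim <- nrow(A[[1]])
  M <- matrix(0i, dim, dim)
  for (p in 1:N) for (q in 1:N) if (K[p, q] != 0)
    M <- M + K[p, q] * (t(A[[p]]) %*% A[[q]] + t(A[[p + N]]) %*% A[[q + N]])
  M
}

fock_jastrow <- function(J_ss, J_os, A) {
  N <- nrow(J_ss); dim <- nrow(A[[1]])
  nop <- function(j) t(A[[j]]) %*% A[[j]]
  M <- matrix(0i, dim, dim)
  for (p in 1:N) for (q in 1:N) {
    M <- M + 0.5 * J_ss[p, q] * (nop(p) %*% nop(q) + nop(p + N) %*% nop(q + N)) +
      J_os[p, q] * (nop(p) %*% nop(q + N))
  }
  M
}

# exp(fac * H) for Hermitian H
fock_expm <- function(H, fac) {
  es <- eigen(H, symmetric = TRUE)
  es$vectors %*% (exp(fac * es$values) * Conj(t(es$vectors)))
}

# embed a sector CI vector into the 2^(2N) (+ ancilla) qubit register
fock_embed <- function(cv, n_extra = 0L) {
  sp <- cv$space
  nq <- 2L * sp$n_orb + n_extra
  w <- complex(2^nq)
  nbs <- nrow(sp$strings_beta)
  for (i in seq_along(cv$amp)) {
    ia <- (i - 1) %/% nbs + 1; ib <- (i - 1) %% nbs + 1
    bits <- c(sp$strings_alpha[ia, ], sp$strings_beta[ib, ], rep(0L, n_extra))
    w[sum(bits * 2^(0:(nq - 1))) + 1] <- cv$amp[i]
  }
  w
}

# apply a qubit-relabeling layout (wire w holds logical layout[w+1]) to a
# statevector expressed in logical labels
fock_relabel <- function(w, layout) {
  nq <- length(layout)
  out <- complex(2^nq)
  for (b in 0:(2^nq - 1)) {
    bits <- bitwAnd(bitwShiftR(b, 0:(nq - 1)), 1L)
    nb <- bits[layout + 1L]
    out[sum(nb * 2^(0:(nq - 1))) + 1] <- w[b + 1]
  }
  out
}

max_phase_aligned_diff <- function(a, b) {
  ph <- sum(Conj(a) * b)
  ph <- if (Mod(ph) > 0) ph / Mod(ph) else 1
  max(Mod(b - ph * a))
}
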