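# Determinant CI machinery: occupation-string bases for a fixed
# (n_alpha, n_beta) sector, Slater-Condon representations of one- and
# two-body operators, exact diagonalization, and CI vectors.

#' Determinant basis for a fixed particle-number sector
#'
#' Enumerates alpha and beta occupation strings for `n_orb` spatial orbitals
#' and caches the single-excitation coupling tables used to represent
#' one-body operators.  Determinants are ordered alpha-major; the phase
#' convention orders creation operators by ascending spin-orbital index with
#' all alpha (qubits `0..N-1`) before all beta (`N..2N-1`), which matches the
#' Jordan-Wigner convention used by the circuit compiler.
#'
#' @param n_orb number of spatial orbitals.
#' @param n_alpha,n_beta electron counts.
#' @return object of class `lucj_cispace`.
#' @export
ci_space <- function(n_orb, n_alpha, n_beta) {
  key <- sprintf("%d_%d_%d", n_orb, n_alpha, n_beta)
  cached <- .ci_cache[[key]]
  if (!is.null(cached)) return(cached)
  strs_a <- .occ_strings(n_orb, n_alpha)
  strs_b <- .occ_strings(n_orb, n_beta)
  na <- nrow(strs_a); nb <- nrow(strs_b)
  sp <- structure(list(n_orb = n_orb, n_alpha = as.integer(n_alpha),
                       n_beta = as.integer(n_beta),
                       strings_alpha = strs_a, strings_beta = strs_b,
                       dim = na * nb,
                       exc_alpha = .excitation_tables(strs_a, n_orb),
                       exc_beta = .excitation_tables(strs_b, n_orb)),
                  class = "lucj_cispace")
  .ci_cache[[key]] <- sp
  sp
}

.ci_cache <- new.env(parent = emptyenv())

# occupation strings as a 0/1 matrix (n_strings x n_orb), lexicographic in
# the occupied index sets
.occ_strings <- function(n_orb, n_el) {
  if (n_el == 0) return(matrix(0L, 1, max(n_orb, 1L))[, seq_len(n_orb), drop = FALSE])
  if (n_el > n_orb) stop("more electrons than orbitals in one spin sector")
  cmb <- utils::combn(n_orb, n_el)
  out <- matrix(0L, ncol(cmb), n_orb)
  for (k in seq_len(ncol(cmb))) out[k, cmb[, k]] <- 1L
  out
}

# For each ordered orbital pair (p,q): sparse matrix T with
# T[i_new, i_old] = sign representing a^dag_p a_q on the strings.
.excitation_tables <- function(strs, n_orb) {
  ns <- nrow(strs)
  keys <- apply(strs, 1, paste, collapse = "")
  lookup <- new.env(parent = emptyenv(), size = ns)
  for (i in seq_len(ns)) assign(keys[i], i, envir = lookup)
  tabs <- vector("list", n_orb * n_orb)
  for (p in seq_len(n_orb)) for (q in seq_len(n_orb)) {
    ii <- integer(0); jj <- integer(0); ss <- numeric(0)
    for (i in seq_len(ns)) {
      occ <- strs[i, ]
      if (occ[q] == 0L) next
      if (p != q && occ[p] == 1L) next
      if (p == q) {
        ii <- c(ii, i); jj <- c(jj, i); ss <- c(ss, 1)
      } else {
        # sign: parity of occupied orbitals strictly between p and q
        rng <- (min(p, q) + 1L):(max(p, q) - 1L)
        nbet <- if (max(p, q) - min(p, q) > 1L) sum(occ[rng]) else 0L
        new <- occ; new[q] <- 0L; new[p] <- 1L
        j <- get(paste(new, collapse = ""), envir = lookup)
        ii <- c(ii, j); jj <- c(jj, i); ss <- c(ss, (-1)^nbet)
      }
    }
    tabs[[(p - 1L) * n_orb + q]] <- Matrix::sparseMatrix(
      i = ii, j = jj, x = ss, dims = c(ns, ns))
  }
  tabs
}

# sector matrix of the spin-summed excitation operator E_pq (1-based p,q)
.sector_Epq <- function(space, p, q) {
  na <- nrow(space$strings_alpha); nb <- nrow(space$strings_beta)
  k <- (p - 1L) * space$n_orb + q
  Matrix::kronecker(space$exc_alpha[[k]], Matrix::Diagonal(nb)) +
    Matrix::kronecker(Matrix::Diagonal(na), space$exc_beta[[k]])
}

# sector representation of a spin-uniform one-body operator sum_pq A_pq E_pq;
# A may be complex.  Returns a dense matrix.
sector_one_body <- function(space, A) {
  n <- space$n_orb
  out <- NULL
  for (p in seq_len(n)) for (q in seq_len(n)) {
    a <- A[p, q]
    if (a == 0) next
    term <- a * as.matrix(.sector_Epq(space, p, q))
    out <- if (is.null(out)) term else out + term
  }
  if (is.null(out)) out <- matrix(0, space$dim, space$dim)
  out
}

# sector Hamiltonian matrix (dense, real) from a molecular Hamiltonian,
# excluding e_const
sector_hamiltonian <- function(space, H) {
  n <- space$n_orb
  d <- space$dim
  Hs <- matrix(0, d, d)
  W <- matrix(0, n, n)
  for (p in 1:n) for (s in 1:n) W[p, s] <- sum(diag(H$g2[p, , , s]))
  h_eff <- H$h1 - 0.5 * W
  for (p in 1:n) for (q in 1:n) {
    Epq <- .sector_Epq(space, p, q)
    if (h_eff[p, q] != 0) Hs <- Hs + h_eff[p, q] * as.matrix(Epq)
    Gpq <- matrix(0, d, d)
    nz <- FALSE
    for (r in 1:n) for (s in 1:n) {
      g <- H$g2[p, q, r, s]
      if (g != 0) { Gpq <- Gpq + g * as.matrix(.sector_Epq(space, r, s)); nz <- TRUE }
    }
    if (nz) Hs <- Hs + 0.5 * as.matrix(Epq %*% Gpq)
  }
  (Hs + t(Hs)) / 2
}

#' CI vector in a fixed particle-number sector
#'
#' @param amplitudes complex vector over determinants (alpha-major order).
#' @param space a [ci_space()].
#' @return object of class `lucj_civector`.
#' @export
civector <- function(amplitudes, space) {
  stopifnot(length(amplitudes) == space$dim)
  structure(list(amp = as.complex(amplitudes), space = space),
            class = "lucj_civector")
}

#' @export
print.lucj_civector <- function(x, ...) {
  cat(sprintf("CI vector: %d determinants (%d orbitals, %d alpha, %d beta), norm %.6f\n",
              x$space$dim, x$space$n_orb, x$space$n_alpha, x$space$n_beta,
              sqrt(sum(Mod(x$amp)^2))))
  invisible(x)
}

#' Hartree-Fock (aufbau) reference determinant
#'
#' Unit CI vector on the determinant occupying the first `n_alpha` and
#' `n_beta` orbitals, assuming orbitals are ordered so that the aufbau
#' filling is the mean-field ground configuration.
#'
#' @param H a [molecular_hamiltonian()], or a [ci_space()].
#' @return a [civector()].
#' @export
hf_reference <- function(H) {
  space <- if (inherits(H, "lucj_cispace")) H else
    ci_space(H$n_orb, H$n_alpha, H$n_beta)
  amp <- complex(space$dim)
  ia <- .string_index(space$strings_alpha, space$n_alpha)
  ib <- .string_index(space$strings_beta, space$n_beta)
  amp[(ia - 1L) * nrow(space$strings_beta) + ib] <- 1 + 0i
  civector(amp, space)
}

#' Reference determinant with explicit occupations
#'
#' @param space a [ci_space()].
#' @param occ_alpha,occ_beta 1-based occupied orbital indices per spin.
#' @return a [civector()] with unit amplitude on that determinant.
#' @export
determinant_reference <- function(space, occ_alpha, occ_beta) {
  stopifnot(length(occ_alpha) == space$n_alpha,
            length(occ_beta) == space$n_beta)
  mk <- function(strs, occ) {
    tgt <- integer(ncol(strs)); tgt[occ] <- 1L
    which(apply(strs, 1, function(r) all(r == tgt)))[1]
  }
  ia <- mk(space$strings_alpha, occ_alpha)
  ib <- mk(space$strings_beta, occ_beta)
  amp <- complex(space$dim)
  amp[(ia - 1L) * nrow(space$strings_beta) + ib] <- 1 + 0i
  civector(amp, space)
}

.string_index <- function(strs, nel) {
  target <- c(rep(1L, nel), rep(0L, ncol(strs) - nel))
  which(apply(strs, 1, function(r) all(r == target)))[1]
}

#' Particle numbers and spin projection of a CI vector
#'
#' @param v a [civector()].
#' @return list with `n_alpha`, `n_beta` and `S_z`.
#' @export
spin_and_number <- function(v) {
  list(n_alpha = v$space$n_alpha, n_beta = v$space$n_beta,
       S_z = (v$space$n_alpha - v$space$n_beta) / 2)
}

#' Full configuration interaction in a particle-number sector
#'
#' Exact ground state of the Hamiltonian in the `(n_alpha, n_beta)` sector:
#' dense diagonalization for small sector dimensions, Lanczos with full
#' reorthogonalization above.
#'
#' @param H a [molecular_hamiltonian()].
#' @param n_alpha,n_beta electron counts; default from `H`.
#' @param dense_cutoff sector dimension above which Lanczos is used.
#' @return list with `energy` (Hartree, includes `e_const`) and `civec`.
#' @export
fci_solve <- function(H, n_alpha = H$n_alpha, n_beta = H$n_beta,
                      dense_cutoff = 2000) {
  space <- ci_space(H$n_orb, n_alpha, n_beta)
  if (space$dim > 1e6)
    stop("sector dimension ", space$dim,
         " too large; reduce the active space or electron count")
  Hs <- sector_hamiltonian(space, H)
  if (space$dim <= dense_cutoff) {
    es <- eigen(Hs, symmetric = TRUE)
    k <- which.min(es$values)
    e0 <- es$values[k]
    vec <- es$vectors[, k]
  } else {
    lz <- .lanczos_ground(Hs, max_iter = 300, tol = 1e-12)
    e0 <- lz$value
    vec <- lz$vector
  }
  vec <- vec / sqrt(sum(vec^2))
  list(energy = e0 + H$e_const, civec = civector(vec, space))
}

.lanczos_ground <- function(A, max_iter = 300, tol = 1e-12) {
  d <- nrow(A)
  set.seed(1)
  q <- rnorm(d); q <- q / sqrt(sum(q^2))
  Q <- matrix(q, d, 1)
  alpha <- numeric(0); beta <- numeric(0)
  e_old <- Inf
  for (k in seq_len(min(max_iter, d))) {
    w <- as.vector(A %*% Q[, k])
    a <- sum(w * Q[, k]); alpha <- c(alpha, a)
    w <- w - a * Q[, k] - if (k > 1) beta[k - 1] * Q[, k - 1] else 0
    w <- w - Q %*% (t(Q) %*% w)  # full reorthogonalization
    b <- sqrt(sum(w^2))
    Tm <- diag(alpha, length(alpha))
    if (length(alpha) > 1)
      for (i in seq_len(length(alpha) - 1)) Tm[i, i + 1] <- Tm[i + 1, i] <- beta[i]
    es <- eigen(Tm, symmetric = TRUE)
    e_new <- min(es$values)
    if (abs(e_new - e_old) < tol || b < 1e-13) {
      y <- es$vectors[, which.min(es$values)]
      return(list(value = e_new, vector = as.vector(Q %*% y)))
    }
    e_old <- e_new
    beta <- c(beta, b)
    Q <- cbind(Q, w / b)
  }
  y <- es$vectors[, which.min(es$values)]
  list(value = e_new, vector = as.vector(Q %*% y))
}
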