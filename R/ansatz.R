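# The LUCJ ansatz on CI vectors.  A layer acts as
#   exp(K_mu) exp(i J_mu) exp(-K_mu)
# (change of orbital basis, diagonal Jastrow phases, change back), layers are
# applied in ascending mu, and a final one-body orbital-optimization
# generator X is applied outermost:
#   |psi> = e^X  U_L ... U_1 |ref>.
# The Jastrow phase of a determinant with occupations n is
#   theta = 1/2 sum_pq Jss[p,q] (n_pa n_qa + n_pb n_qb)
#         +     sum_pq Jos[p,q] n_pa n_qb .

#' LUCJ parameter set
#'
#' @param layers list of layers, each a list with `K` (N x N complex
#'   anti-Hermitian generator), `J_ss` and `J_os` (N x N real symmetric,
#'   nonzero only where the topology masks allow).  With the spin constraint
#'   (always imposed here) a single `J_ss` stands for both same-spin blocks
#'   and a single `J_os` for both opposite-spin blocks, so the ansatz
#'   commutes with S_z.
#' @param X N x N complex anti-Hermitian orbital-optimization generator.
#' @param topology a [make_topology()] model fixing the masks.
#' @param real_k restrict `K` and `X` to real antisymmetric generators.
#' @return object of class `lucj_parameters`.
#' @export
lucj_parameters <- function(layers, X = NULL, topology, real_k = FALSE) {
  n <- topology$n_orb
  masks <- parameter_masks(topology)
  if (is.null(X)) X <- matrix(0i, n, n)
  X <- .check_antihermitian(X, "X")
  layers <- lapply(layers, function(ly) {
    ly$K <- .check_antihermitian(ly$K, "K")
    for (nm in c("J_ss", "J_os")) {
      J <- as.matrix(ly[[nm]])
      if (max(abs(J - t(J))) > 1e-10) stop(nm, " must be symmetric")
      mask <- if (nm == "J_ss") masks$mask_ss else masks$mask_os
      if (any(abs(J[!mask]) > 1e-12))
        stop(nm, " has nonzero entries outside the ", topology$name, " mask")
      ly[[nm]] <- (J + t(J)) / 2
    }
    ly
  })
  structure(list(layers = layers, X = X, topology = topology,
                 masks = masks, real_k = real_k,
                 n_orb = n, n_layers = length(layers)),
            class = "lucj_parameters")
}

.check_antihermitian <- function(K, nm) {
  K <- as.matrix(K)
  if (!is.complex(K)) K <- K + 0i
  if (max(abs(K + Conj(t(K)))) > 1e-8)
    stop(nm, " must be anti-Hermitian (|K + K^dagger| > 1e-8)")
  (K - Conj(t(K))) / 2
}

#' Zero-initialized LUCJ parameters
#' @param topology a [make_topology()] model.
#' @param n_layers number of layers L.
#' @param real_k restrict generators to real antisymmetric matrices.
#' @return a [lucj_parameters()] object with all parameters zero.
#' @export
lucj_zero_parameters <- function(topology, n_layers, real_k = FALSE) {
  n <- topology$n_orb
  z <- matrix(0, n, n)
  layers <- replicate(n_layers,
                      list(K = z + 0i, J_ss = z, J_os = z), simplify = FALSE)
  lucj_parameters(layers, X = z + 0i, topology = topology, real_k = real_k)
}

#' @export
print.lucj_parameters <- function(x, ...) {
  cat(sprintf("LUCJ parameters: L = %d layers, N = %d, topology %s, %d free parameters\n",
              x$n_layers, x$n_orb, x$topology$name,
              length(flatten_parameters(x))))
  invisible(x)
}

# ---- fast sector machinery -------------------------------------------------

# problem object: cached sector representations for one Hamiltonian sector
#' Precomputed sector workspace for LUCJ simulation
#'
#' Builds the determinant space, the sector Hamiltonian matrix and the
#' one-body assembly operator once, so that repeated energy evaluations
#' during optimization are cheap.
#'
#' @param H a [molecular_hamiltonian()].
#' @return object of class `lucj_problem`.
#' @export
lucj_problem <- function(H) {
  space <- ci_space(H$n_orb, H$n_alpha, H$n_beta)
  n <- H$n_orb
  d <- space$dim
  cols <- vector("list", n * n)
  for (p in 1:n) for (q in 1:n) {
    E <- .sector_Epq(space, p, q)
    cols[[(p - 1L) * n + q]] <- E
  }
  tr <- lapply(cols, function(E) {
    E <- methods::as(E, "TsparseMatrix")
    cbind(E@i + 1L, E@j + 1L, E@x)
  })
  nnz <- vapply(tr, nrow, 1L)
  colidx <- rep(seq_len(n * n), nnz)
  allt <- do.call(rbind, tr)
  Cmat <- Matrix::sparseMatrix(i = allt[, 1] + (allt[, 2] - 1) * d,
                               j = colidx, x = allt[, 3],
                               dims = c(d * d, n * n))
  nb <- nrow(space$strings_beta); na <- nrow(space$strings_alpha)
  Oa <- space$strings_alpha[rep(seq_len(na), each = nb), , drop = FALSE]
  Ob <- space$strings_beta[rep(seq_len(nb), times = na), , drop = FALSE]
  Hs <- sector_hamiltonian(space, H)
  structure(list(H = H, space = space, dim = d, n_orb = n,
                 Cmat = Cmat, Oa = Oa, Ob = Ob, Hs = Hs,
                 e_const = H$e_const),
            class = "lucj_problem")
}

#' @export
print.lucj_problem <- function(x, ...) {
  cat(sprintf("LUCJ problem: %d orbitals, sector (%d,%d), %d determinants\n",
              x$n_orb, x$H$n_alpha, x$H$n_beta, x$dim))
  invisible(x)
}

# sector matrix of a (possibly complex) spin-uniform one-body operator
.prob_one_body <- function(prob, A) {
  d <- prob$dim
  # Cmat columns are ordered (p-1)*n + q (row-major in (p,q))
  vr <- as.vector(prob$Cmat %*% as.vector(t(Re(A))))
  if (is.complex(A) && any(Im(A) != 0)) {
    vi <- as.vector(prob$Cmat %*% as.vector(t(Im(A))))
    matrix(complex(real = vr, imaginary = vi), d, d)
  } else matrix(vr, d, d)
}

# action of exp(sector(K)) with K anti-Hermitian; returns function of sign
# so e^{+K} and e^{-K} share one eigendecomposition
.orbital_rotation_action <- function(prob, K) {
  M <- .prob_one_body(prob, K)          # anti-Hermitian
  Hm <- 1i * M                          # Hermitian
  es <- eigen(Hm, symmetric = TRUE)
  V <- es$vectors
  lam <- es$values
  function(v, sign = 1) {
    w <- crossprod(Conj(V), v)
    as.vector(V %*% (exp(-1i * sign * lam) * w))
  }
}

#' Apply a one-body orbital rotation to a CI vector
#'
#' Computes `exp(K_hat) v` where `K_hat` applies the same spatial generator
#' `K` to both spin sectors.
#'
#' @param v a [civector()].
#' @param K N x N complex anti-Hermitian matrix.
#' @param prob optional [lucj_problem()] matching the sector of `v`.
#' @return a [civector()].
#' @export
apply_orbital_rotation <- function(v, K, prob = NULL) {
  K <- .check_antihermitian(K, "K")
  if (is.null(prob)) prob <- .bare_problem(v$space)
  act <- .orbital_rotation_action(prob, K)
  civector(act(v$amp, 1), v$space)
}

# problem-like object without a Hamiltonian (for standalone rotations)
.bare_problem <- function(space) {
  n <- space$n_orb; d <- space$dim
  key <- sprintf("bare_%d_%d_%d", n, space$n_alpha, space$n_beta)
  cached <- .ci_cache[[key]]
  if (!is.null(cached)) return(cached)
  cols <- vector("list", n * n)
  tr <- list()
  for (p in 1:n) for (q in 1:n) {
    E <- methods::as(.sector_Epq(space, p, q), "TsparseMatrix")
    tr[[(p - 1L) * n + q]] <- cbind(E@i + 1L, E@j + 1L, E@x)
  }
  nnz <- vapply(tr, nrow, 1L)
  allt <- do.call(rbind, tr)
  Cmat <- Matrix::sparseMatrix(i = allt[, 1] + (allt[, 2] - 1) * d,
                               j = rep(seq_len(n * n), nnz), x = allt[, 3],
                               dims = c(d * d, n * n))
  nb <- nrow(space$strings_beta); na <- nrow(space$strings_alpha)
  out <- structure(list(space = space, dim = d, n_orb = n, Cmat = Cmat,
                        Oa = space$strings_alpha[rep(seq_len(na), each = nb), , drop = FALSE],
                        Ob = space$strings_beta[rep(seq_len(nb), times = na), , drop = FALSE]),
                   class = "lucj_problem")
  .ci_cache[[key]] <- out
  out
}

#' Apply diagonal Jastrow phases to a CI vector
#'
#' Each determinant acquires the phase
#' `exp(i (1/2 sum Jss (n_pa n_qa + n_pb n_qb) + sum Jos n_pa n_qb))`;
#' amplitude moduli are unchanged.
#'
#' @param v a [civector()].
#' @param J_ss,J_os N x N real symmetric coupling matrices.
#' @param prob optional [lucj_problem()].
#' @return a [civector()].
#' @export
apply_jastrow_phase <- function(v, J_ss, J_os, prob = NULL) {
  if (max(abs(J_ss - t(J_ss))) > 1e-12 || max(abs(J_os - t(J_os))) > 1e-12)
    stop("Jastrow coupling matrices must be symmetric")
  if (is.null(prob)) prob <- .bare_problem(v$space)
  th <- .jastrow_angles(prob, J_ss, J_os)
  civector(v$amp * exp(1i * th), v$space)
}

.jastrow_angles <- function(prob, J_ss, J_os) {
  Oa <- prob$Oa; Ob <- prob$Ob
  0.5 * (rowSums((Oa %*% J_ss) * Oa) + rowSums((Ob %*% J_ss) * Ob)) +
    rowSums((Oa %*% J_os) * Ob)
}

#' Prepare an LUCJ state
#'
#' Applies the layered ansatz to a reference CI vector:
#' `e^X prod_{mu=L..1} [e^{K_mu} e^{iJ_mu} e^{-K_mu}] |ref>` (layer 1 acts
#' first).  Norm, particle number and S_z of the reference are preserved.
#'
#' @param params a [lucj_parameters()] set.
#' @param ref reference [civector()] (normalized).
#' @param prob optional [lucj_problem()].
#' @return a [civector()].
#' @export
prepare_state <- function(params, ref, prob = NULL) {
  if (is.null(prob)) prob <- .bare_problem(ref$space)
  v <- ref$amp
  for (ly in params$layers) {
    if (max(Mod(ly$K)) > 0) {
      act <- .orbital_rotation_action(prob, ly$K)
      v <- act(v, -1)
      v <- v * exp(1i * .jastrow_angles(prob, ly$J_ss, ly$J_os))
      v <- act(v, 1)
    } else {
      v <- v * exp(1i * .jastrow_angles(prob, ly$J_ss, ly$J_os))
    }
  }
  if (max(Mod(params$X)) > 0) {
    act <- .orbital_rotation_action(prob, params$X)
    v <- act(v, 1)
  }
  nrm <- sqrt(sum(Mod(v)^2))
  if (abs(nrm - 1) > 1e-8 && abs(nrm - sqrt(sum(Mod(ref$amp)^2))) > 1e-8)
    stop("norm drifted during state preparation")
  civector(v, ref$space)
}

#' Variational energy of an LUCJ state
#'
#' `<psi|H|psi> + e_const` with `|psi> = prepare_state(params, ref)`.
#' The imaginary part must vanish to 1e-10 (a broken Hermiticity invariant
#' otherwise) and is discarded after the check.
#'
#' @param params a [lucj_parameters()] set.
#' @param H a [molecular_hamiltonian()] or a [lucj_problem()].
#' @param ref reference [civector()].
#' @return energy in Hartree.
#' @export
lucj_energy <- function(params, H, ref) {
  prob <- if (inherits(H, "lucj_problem")) H else lucj_problem(H)
  v <- prepare_state(params, ref, prob)$amp
  ev <- sum(Conj(v) * (prob$Hs %*% v))
  if (abs(Im(ev)) > 1e-10)
    stop("non-real energy expectation (", Im(ev), "): Hermiticity broken")
  Re(ev) + prob$e_const
}

# ---- parameter flattening --------------------------------------------------

# ordering: per layer K real strict-upper (row-major), K imag upper incl
# diagonal (row-major; omitted in real_k mode), masked J_ss upper incl diag,
# masked J_os upper incl diag; then X like K.
.upper_idx <- function(n, diag = FALSE) {
  which(upper.tri(matrix(0, n, n), diag = diag))
}

.flatten_K <- function(K, real_k) {
  n <- nrow(K)
  out <- Re(K)[.upper_idx(n)]
  if (!real_k) out <- c(out, Im(K)[.upper_idx(n, diag = TRUE)])
  out
}

.unflatten_K <- function(vec, n, real_k) {
  iu <- .upper_idx(n)
  K <- matrix(0, n, n)
  K[iu] <- vec[seq_along(iu)]
  K <- K - t(K)
  if (!real_k) {
    iud <- .upper_idx(n, diag = TRUE)
    Ki <- matrix(0, n, n)
    Ki[iud] <- vec[length(iu) + seq_along(iud)]
    Ki <- (Ki + t(Ki)) - diag(diag(Ki))
    K <- K + 1i * Ki
  }
  K + 0i
}

.n_K_params <- function(n, real_k) {
  if (real_k) n * (n - 1) / 2 else n * n
}

.mask_upper <- function(mask) {
  mask & upper.tri(mask, diag = TRUE)
}

.flatten_J <- function(J, mask) J[.mask_upper(mask)]

.unflatten_J <- function(vec, mask) {
  n <- nrow(mask)
  J <- matrix(0, n, n)
  J[.mask_upper(mask)] <- vec
  J <- J + t(J) - diag(diag(J))
  J
}

#' Flatten LUCJ parameters into a real vector
#'
#' The documented ordering is, per layer: real parts of the strict upper
#' triangle of `K` (row-major as stored), imaginary parts of the upper
#' triangle of `K` including the diagonal (omitted in real-restricted
#' mode), masked upper-triangle entries of `J_ss`, masked entries of
#' `J_os`; after all layers, `X` with the same layout as `K`.
#'
#' @param params a [lucj_parameters()] set.
#' @return numeric vector.
#' @export
flatten_parameters <- function(params) {
  m <- params$masks
  unlist(c(lapply(params$layers, function(ly)
    c(.flatten_K(ly$K, params$real_k),
      .flatten_J(ly$J_ss, m$mask_ss),
      .flatten_J(ly$J_os, m$mask_os))),
    list(.flatten_K(params$X, params$real_k))))
}

#' Rebuild LUCJ parameters from a flat vector
#'
#' @param vec numeric vector in [flatten_parameters()] ordering.
#' @param template a [lucj_parameters()] set fixing topology, layer count
#'   and mode.
#' @return a [lucj_parameters()] set.
#' @export
unflatten_parameters <- function(vec, template) {
  n <- template$n_orb
  m <- template$masks
  nk <- .n_K_params(n, template$real_k)
  nss <- sum(.mask_upper(m$mask_ss))
  nos <- sum(.mask_upper(m$mask_os))
  pos <- 0L
  take <- function(k) {
    out <- vec[pos + seq_len(k)]; pos <<- pos + k; out
  }
  layers <- lapply(template$layers, function(ly) {
    K <- .unflatten_K(take(nk), n, template$real_k)
    J_ss <- .unflatten_J(take(nss), m$mask_ss)
    J_os <- .unflatten_J(take(nos), m$mask_os)
    list(K = K, J_ss = J_ss, J_os = J_os)
  })
  X <- .unflatten_K(take(nk), n, template$real_k)
  if (pos != length(vec)) stop("parameter vector length mismatch")
  lucj_parameters(layers, X, template$topology, template$real_k)
}

#' Export a CI state as a determinant table
#'
#' @param v a [civector()].
#' @param tol drop amplitudes below this modulus.
#' @return data.frame with alpha/beta occupation bitstrings and complex
#'   amplitudes.
#' @export
state_table <- function(v, tol = 1e-12) {
  sp <- v$space
  nb <- nrow(sp$strings_beta)
  idx <- which(Mod(v$amp) > tol)
  ia <- (idx - 1L) %/% nb + 1L
  ib <- (idx - 1L) %% nb + 1L
  data.frame(
    alpha = apply(sp$strings_alpha[ia, , drop = FALSE], 1, paste, collapse = ""),
    beta = apply(sp$strings_beta[ib, , drop = FALSE], 1, paste, collapse = ""),
    re = Re(v$amp[idx]), im = Im(v$amp[idx]))
}
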