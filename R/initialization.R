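# Initialization of LUCJ layers from a doubly factorized low-rank
# decomposition of closed-shell t2 amplitudes:
#   T2 = 1/2 sum_g lambda_g V_g^2 ,  V_g = sum_ia v_g[ia] E_{ai}
# with T[(ia),(jb)] = t2[i,j,a,b] symmetric and eigendecomposed.  Writing
# V = S + iA with S, A Hermitian gives
#   T2 - T2^dag = (i/2) sum_g lambda_g [ (S+A)^2 - (S-A)^2 ] ,
# so each eigenvalue contributes two layers, one per Hermitian square:
# e^{i(lambda/2) B^2} = e^K e^{iJ} e^{-K} with e^K the eigenbasis rotation
# of B and J = lambda d d^T (spin-uniform) from the eigenvalues d of B.

#' Double factorization of t2 amplitudes
#'
#' Eigendecomposes the symmetric `(N_o N_v) x (N_o N_v)` amplitude matrix
#' and returns, per retained eigenvalue, the Hermitian "plus" and "minus"
#' one-body generators whose squares rebuild the anti-Hermitian doubles
#' generator exactly when untruncated.
#'
#' @param t2 a [t2_amplitudes()] object.
#' @param tol discard eigenvalues with `|lambda| < tol`.
#' @return object of class `lucj_factorized_doubles`: list of `terms`
#'   (each with `lambda`, `plus_generator`, `minus_generator`, all N x N
#'   with N = N_o + N_v), sorted by `|lambda|` descending, plus
#'   `reconstruction_error`.
#' @export
double_factorize_t2 <- function(t2, tol = 1e-12) {
  no <- t2$n_occ; nv <- t2$n_virt; n <- no + nv
  if (no == 0 || nv == 0 || length(t2$t2) == 0)
    return(structure(list(terms = list(), reconstruction_error = 0,
                          n_orb = n, n_occ = no),
                     class = "lucj_factorized_doubles"))
  Tm <- matrix(aperm(t2$t2, c(3, 1, 4, 2)), no * nv, no * nv)
  # row index (a,i) flattened with a fastest: element ((a,i),(b,j)) = t2[i,j,a,b]
  if (max(abs(Tm - t(Tm))) > 1e-10)
    stop("t2 amplitude matrix is not symmetric; closed-shell symmetry violated")
  Tm <- (Tm + t(Tm)) / 2
  es <- eigen(Tm, symmetric = TRUE)
  keep <- which(abs(es$values) >= tol)
  keep <- keep[order(abs(es$values[keep]), decreasing = TRUE)]
  terms <- lapply(keep, function(k) {
    v <- matrix(es$vectors[, k], nv, no)      # v[a,i]
    M <- matrix(0, n, n)
    M[no + seq_len(nv), seq_len(no)] <- v     # occ -> virt block
    S <- (M + t(M)) / 2
    A <- (M - t(M)) / (2i)                    # Hermitian (imaginary antisym)
    list(lambda = es$values[k],
         plus_generator = S + A,
         minus_generator = S - A)
  })
  err <- if (length(keep) < length(es$values))
    sqrt(sum(es$values[setdiff(seq_along(es$values), keep)]^2)) else 0
  structure(list(terms = terms, reconstruction_error = err,
                 n_orb = n, n_occ = no),
            class = "lucj_factorized_doubles")
}

#' @export
print.lucj_factorized_doubles <- function(x, ...) {
  cat(sprintf("Doubly factorized t2: %d eigenvalues (=> %d UCJ layers), residual %.2e\n",
              length(x$terms), 2 * length(x$terms), x$reconstruction_error))
  if (length(x$terms))
    cat("  |lambda|:", sprintf("%.3e", sapply(x$terms, function(t) abs(t$lambda))), "\n")
  invisible(x)
}

#' LUCJ layers from a factorized doubles generator
#'
#' Builds two layers per retained eigenvalue (largest first, "plus" before
#' "minus"), each of the form `e^K e^{iJ} e^{-K}` with `K` the logarithm of
#' the eigenbasis rotation of the Hermitian generator and spin-uniform
#' couplings `J_ss = J_os = +/- lambda d d^T`, then truncates to at most
#' `l_max` layers.  The all-to-all layer list is returned; project with
#' [project_to_topology()] for restricted connectivities.
#'
#' @param fd a [double_factorize_t2()] result.
#' @param l_max maximum layer count (2 per eigenvalue retained).
#' @return a [lucj_parameters()] set on the all-to-all topology.
#' @export
layers_from_factorization <- function(fd, l_max = 2L * length(fd$terms)) {
  n <- fd$n_orb
  top <- make_topology("all-to-all", n)
  if (!length(fd$terms) || l_max == 0)
    return(lucj_zero_parameters(top, 0L))
  if (l_max < 2 && length(fd$terms))
    warning("a single layer cannot represent a factorized eigenvalue pair; ",
            "expect poor initial energies with l_max = ", l_max)
  layers <- list()
  for (tm in fd$terms) {
    for (sgn in c(1, -1)) {
      B <- if (sgn > 0) tm$plus_generator else tm$minus_generator
      es <- eigen(B, symmetric = TRUE)         # Hermitian: U exactly unitary
      U <- es$vectors
      d <- es$values
      K <- .matrix_log_unitary(U)
      J <- sgn * tm$lambda * outer(d, d)
      layers[[length(layers) + 1L]] <- list(K = K, J_ss = J, J_os = J)
      if (length(layers) >= l_max) break
    }
    if (length(layers) >= l_max) break
  }
  lucj_parameters(layers, X = matrix(0i, n, n), topology = top)
}

# principal logarithm of a unitary matrix (anti-Hermitian result).
# eigen() on a normal matrix can return non-orthogonal vectors within a
# degenerate eigenvalue cluster; orthonormalize cluster-wise before use.
.matrix_log_unitary <- function(U, tol = 1e-8) {
  n <- nrow(U)
  es <- eigen(U)
  lam <- es$values
  V <- es$vectors
  ord <- order(Arg(lam))
  lam <- lam[ord]; V <- V[, ord, drop = FALSE]
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && Mod(lam[j + 1L] - lam[i]) < tol) j <- j + 1L
    if (j > i) {
      Q <- qr.Q(qr(V[, i:j, drop = FALSE]))
      V[, i:j] <- Q
    } else {
      V[, i] <- V[, i] / sqrt(sum(Mod(V[, i])^2))
    }
    i <- j + 1L
  }
  K <- V %*% (1i * Arg(lam) * Conj(t(V)))
  K <- (K - Conj(t(K))) / 2
  # verify the principal log actually reproduces U
  esK <- eigen(1i * K, symmetric = TRUE)
  Urec <- esK$vectors %*% (exp(-1i * esK$values) * Conj(t(esK$vectors)))
  if (max(Mod(Urec - U)) > 1e-9)
    stop("unitary logarithm failed (residual ", signif(max(Mod(Urec - U)), 3), ")")
  K
}

#' Project all-to-all LUCJ parameters onto a restricted topology
#'
#' Chooses the orbital permutation that places the orbitals carrying the
#' largest layer-summed on-site opposite-spin couplings `|J_os[p,p]|` onto
#' the topology's coupling set `S` (greedy assignment, ties broken by the
#' original index), applies it consistently to every `K`, `J` and `X`, and
#' zeroes couplings outside the target masks.
#'
#' @param params a [lucj_parameters()] set.
#' @param top target [make_topology()].
#' @return a [lucj_parameters()] set on `top`; attribute `permutation`
#'   records the applied orbital permutation (new index of each old
#'   orbital, 1-based).
#' @export
project_to_topology <- function(params, top) {
  n <- params$n_orb
  stopifnot(top$n_orb == n)
  if (top$name == "all-to-all" && params$topology$name == "all-to-all") {
    out <- params
    attr(out, "permutation") <- seq_len(n)
    return(out)
  }
  weight <- rep(0, n)
  for (ly in params$layers) weight <- weight + abs(diag(ly$J_os))
  s_pos <- top$s_set + 1L
  # greedy: largest weights onto S positions (S positions in given order),
  # remaining orbitals keep relative order on the remaining slots
  ord <- order(-weight, seq_len(n))
  perm <- integer(n)                           # perm[old] = new position
  perm[ord[seq_along(s_pos)]] <- s_pos
  rest_old <- ord[-seq_along(s_pos)]
  rest_new <- setdiff(seq_len(n), s_pos)
  perm[sort(rest_old)] <- rest_new
  P <- matrix(0, n, n)
  for (old in seq_len(n)) P[perm[old], old] <- 1
  masks <- parameter_masks(top)
  remap <- function(M) P %*% M %*% t(P)
  layers <- lapply(params$layers, function(ly) {
    J_ss <- remap(ly$J_ss); J_os <- remap(ly$J_os)
    J_ss[!masks$mask_ss] <- 0
    J_os[!masks$mask_os] <- 0
    list(K = remap(ly$K), J_ss = J_ss, J_os = J_os)
  })
  out <- lucj_parameters(layers, remap(params$X), top, params$real_k)
  attr(out, "permutation") <- perm
  out
}
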