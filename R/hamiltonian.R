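#' Molecular Hamiltonian container
#'
#' Active-space electronic Hamiltonian in an ordered molecular-orbital basis:
#' a scalar offset (nuclear repulsion plus any folded core energy), Hermitian
#' one-body integrals and chemist-convention two-body integrals (pq|rs), all
#' in Hartree, with the electron counts of the sector of interest.
#'
#' @param h1 N x N symmetric one-body integral matrix (Hartree).
#' @param g2 N x N x N x N two-body integral array, chemist (pq|rs).
#' @param e_const scalar energy offset (Hartree).
#' @param n_alpha,n_beta electron counts.
#' @param orbital_order tag describing the orbital-to-qubit ordering
#'   convention: `"energy-ascending"`, `"occupation-descending"` or
#'   `"custom"`.
#' @return object of class `lucj_hamiltonian`.
#' @export
molecular_hamiltonian <- function(h1, g2, e_const = 0, n_alpha, n_beta,
                                  orbital_order = "custom") {
  h1 <- as.matrix(h1)
  n <- nrow(h1)
  stopifnot(ncol(h1) == n, length(dim(g2)) == 4, all(dim(g2) == n))
  if (max(abs(h1 - t(h1))) > 1e-12)
    stop("h1 must be Hermitian (symmetric) to 1e-12")
  # 8-fold permutational symmetry check on a random sample of indices
  idx <- expand.grid(p = 1:n, q = 1:n)
  smp <- idx[sample.int(nrow(idx), min(16L, nrow(idx))), , drop = FALSE]
  for (k in seq_len(nrow(smp))) {
    p <- smp$p[k]; q <- smp$q[k]
    if (max(abs(g2[p, q, , ] - g2[q, p, , ])) > 1e-10 ||
        max(abs(g2[p, q, , ] - t(g2[, , p, q]))) > 1e-10)
      stop("g2 lacks 8-fold permutational symmetry to 1e-10")
  }
  if (n_alpha + n_beta > 2 * n) stop("too many electrons for ", n, " orbitals")
  structure(list(n_orb = n, n_alpha = as.integer(n_alpha),
                 n_beta = as.integer(n_beta), e_const = e_const,
                 h1 = h1, g2 = g2, orbital_order = orbital_order),
            class = "lucj_hamiltonian")
}

#' @export
print.lucj_hamiltonian <- function(x, ...) {
  cat(sprintf("Molecular Hamiltonian: %d orbitals, (%de,%de), e_const = %.8f\n",
              x$n_orb, x$n_alpha + x$n_beta, x$n_orb, x$e_const))
  cat("orbital order:", x$orbital_order, "\n")
  invisible(x)
}

#' Fermi-Hubbard chain Hamiltonian
#'
#' Nearest-neighbor hopping `-t` with on-site repulsion `U` penalizing
#' double occupancy, expressed in the same chemist-convention integral
#' containers used for molecular systems.
#'
#' @param n_sites number of lattice sites.
#' @param t hopping amplitude (energy units).
#' @param u on-site repulsion (energy units).
#' @param n_alpha,n_beta electron counts.
#' @param boundary `"open"` or `"periodic"`.
#' @return a [molecular_hamiltonian()].
#' @export
build_hubbard <- function(n_sites, t = 1, u = 0, n_alpha, n_beta,
                          boundary = c("open", "periodic")) {
  boundary <- match.arg(boundary)
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (boundary == "periodic" && n_sites < 3)
    stop("periodic boundary needs at least 3 sites (bond would be double-counted)")
  h1 <- matrix(0, n_sites, n_sites)
  if (n_sites > 1)
    for (p in seq_len(n_sites - 1)) h1[p, p + 1] <- h1[p + 1, p] <- -t
  if (boundary == "periodic") h1[1, n_sites] <- h1[n_sites, 1] <- -t
  g2 <- array(0, rep(n_sites, 4))
  for (p in seq_len(n_sites)) g2[p, p, p, p] <- u
  molecular_hamiltonian(h1, g2, 0, n_alpha, n_beta, "custom")
}

#' Permute the orbital ordering of a Hamiltonian
#'
#' @param H a [molecular_hamiltonian()].
#' @param perm integer vector: `perm[old]` is the new position of orbital
#'   `old` (1-based).
#' @return a [molecular_hamiltonian()] with permuted integrals.
#' @export
permute_hamiltonian <- function(H, perm) {
  n <- H$n_orb
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- order(perm)                # inv[new] = old
  h1 <- H$h1[inv, inv]
  g2 <- H$g2[inv, inv, inv, inv]
  molecular_hamiltonian(h1, g2, H$e_const, H$n_alpha, H$n_beta, "custom")
}

#' Write a Hamiltonian to an FCIDUMP file
#'
#' Standard FCIDUMP dialect: 1-based indices, chemist notation, an `&FCI`
#' namelist header with `NORB`, `NELEC`, `MS2`, then one record per unique
#' integral and a final record carrying the scalar offset.
#'
#' @param H a [molecular_hamiltonian()].
#' @param path output file path.
#' @export
write_fcidump <- function(H, path) {
  n <- H$n_orb
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=%d,", n,
                     H$n_alpha + H$n_beta, H$n_alpha - H$n_beta), con)
  writeLines(sprintf("  ORBSYM=%s", paste(rep("1,", n), collapse = "")), con)
  writeLines("  ISYM=1,", con)
  writeLines(" &END", con)
  fmt <- function(v, p, q, r, s) sprintf("%23.16E %3d %3d %3d %3d", v, p, q, r, s)
  lines <- character(0)
  for (p in 1:n) for (q in 1:p) for (r in 1:p) {
    smax <- if (r == p) q else r
    for (s in 1:smax) {
      v <- H$g2[p, q, r, s]
      if (abs(v) > 1e-14) lines <- c(lines, fmt(v, p, q, r, s))
    }
  }
  for (p in 1:n) for (q in 1:p) {
    v <- H$h1[p, q]
    if (abs(v) > 1e-14) lines <- c(lines, fmt(v, p, q, 0, 0))
  }
  lines <- c(lines, fmt(H$e_const, 0, 0, 0, 0))
  writeLines(lines, con)
  invisible(path)
}

#' Read a Hamiltonian from an FCIDUMP file
#'
#' @param path FCIDUMP file path.
#' @param n_alpha,n_beta optional electron counts; when omitted they are
#'   derived from the `NELEC` and `MS2` header fields.
#' @return a [molecular_hamiltonian()].
#' @export
load_fcidump <- function(path, n_alpha = NULL, n_beta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path)
  hdr_end <- grep("&END|/\\s*$", txt)[1]
  if (is.na(hdr_end)) stop("FCIDUMP format error: no &END terminator in header")
  hdr <- paste(txt[1:hdr_end], collapse = " ")
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), hdr))
    if (!length(m)) return(NA_integer_)
    as.integer(sub(paste0(key, "\\s*=\\s*"), "", m))
  }
  norb <- grab("NORB"); nelec <- grab("NELEC"); ms2 <- grab("MS2")
  if (is.na(norb) || is.na(nelec))
    stop("FCIDUMP format error: missing NORB or NELEC header field")
  if (is.na(ms2)) ms2 <- 0L
  if (is.null(n_alpha)) n_alpha <- (nelec + ms2) %/% 2L
  if (is.null(n_beta)) n_beta <- (nelec - ms2) %/% 2L
  h1 <- matrix(0, norb, norb)
  g2 <- array(0, rep(norb, 4))
  e_const <- 0
  body <- txt[-(1:hdr_end)]
  body <- body[nzchar(trimws(body))]
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    v <- as.numeric(sub("[dD]", "E", f[1]))
    ii <- as.integer(f[2:5])
    if (any(ii > norb)) stop("FCIDUMP format error: index exceeds NORB")
    p <- ii[1]; q <- ii[2]; r <- ii[3]; s <- ii[4]
    if (p == 0) {
      e_const <- v
    } else if (r == 0) {
      h1[p, q] <- h1[q, p] <- v
    } else {
      for (pq in list(c(p, q), c(q, p))) for (rs in list(c(r, s), c(s, r))) {
        g2[pq[1], pq[2], rs[1], rs[2]] <- v
        g2[rs[1], rs[2], pq[1], pq[2]] <- v
      }
    }
  }
  molecular_hamiltonian(h1, g2, e_const, n_alpha, n_beta, "custom")
}

#' Pivoted Cholesky factorization of the two-electron integrals
#'
#' Decomposes the (pq),(rs) matrix of chemist-convention integrals into a sum
#' of squares of Hermitian one-body matrices, the representation behind the
#' low-rank Hamiltonian forms used by factorized ansatz constructions.
#'
#' @param H a [molecular_hamiltonian()].
#' @param tol target reconstruction tolerance (Hartree).
#' @return list of class `lucj_cholesky` with `factors` (list of N x N
#'   symmetric matrices) and `residual`.
#' @export
cholesky_factorize <- function(H, tol = 1e-10) {
  n <- H$n_orb
  M <- matrix(H$g2, n * n, n * n)
  d <- diag(M)
  factors <- list()
  resid <- sum(abs(d))
  L <- matrix(0, n * n, 0)
  while (resid > tol && ncol(L) < n * n) {
    piv <- which.max(d)
    if (d[piv] < -tol)
      stop(sprintf("g2 not positive semidefinite: pivot %g at %d", d[piv], piv))
    if (d[piv] <= tol * 1e-2 && resid > tol)
      stop(sprintf("Cholesky residual stalled at %g (most negative pivot %g)",
                   resid, min(d)))
    col <- M[, piv] - if (ncol(L)) L %*% L[piv, ] else 0
    col <- col / sqrt(d[piv])
    L <- cbind(L, as.vector(col))
    d <- d - as.vector(col)^2
    resid <- sum(pmax(d, 0))
  }
  factors <- lapply(seq_len(ncol(L)), function(k) {
    Fk <- matrix(L[, k], n, n)
    (Fk + t(Fk)) / 2
  })
  structure(list(factors = factors, residual = resid), class = "lucj_cholesky")
}
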