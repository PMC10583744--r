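# Compilation of LUCJ layers to explicit gate sequences and a brute-force
# qubit statevector engine for cross-validation against the fermionic
# simulator.  Jordan-Wigner convention: spin-up orbital p on qubit p,
# spin-down on qubit p+N; heavy-hex ancillas after the data qubits.
#
# Gate vocabulary (angles in radians):
#   Rz(theta)      single-qubit phase diag(1, e^{i theta})
#   G(theta, phi)  number-conserving Givens on adjacent modes: the
#                  single-particle block [[e^{-i phi} cos, e^{-i phi} sin],
#                  [-sin, cos]] on (first qubit, second qubit)
#   Unn(phi)       diag(1, 1, 1, e^{-i phi})
#   SWAP, UnnSWAP(phi) = Unn(phi) * SWAP
#   CX             controlled-X (control = first qubit)
#   UnZn(phi)      exp(-i phi n Z n) on (data, ancilla, data)
# The first listed qubit of a gate is the least-significant bit of its
# local basis, so gate orientation travels with the qubit list.

gate <- function(name, qubits, params = numeric(0)) {
  list(name = name, qubits = as.integer(qubits), params = as.numeric(params))
}

#' Quantum circuit container
#' @param n_qubits register size.
#' @param gates list of gates.
#' @param metadata free-form list (topology, layer tags, final qubit layout).
#' @return object of class `lucj_circuit`.
#' @export
circuit <- function(n_qubits, gates = list(), metadata = list()) {
  structure(list(n_qubits = as.integer(n_qubits), gates = gates,
                 metadata = metadata),
            class = "lucj_circuit")
}

#' @export
print.lucj_circuit <- function(x, ...) {
  cnt <- table(vapply(x$gates, `[[`, "", "name"))
  cat(sprintf("Circuit on %d qubits: %d gates (depth %d)\n", x$n_qubits,
              length(x$gates), circuit_depth(x)))
  if (length(cnt)) print(cnt)
  invisible(x)
}

#' Gate counts of a circuit
#' @param circ a [circuit()].
#' @return named integer vector of counts per gate name.
#' @export
gate_counts <- function(circ) {
  tab <- table(vapply(circ$gates, `[[`, "", "name"))
  out <- as.integer(tab); names(out) <- names(tab)
  out
}

#' Greedy-layered circuit depth
#'
#' Packs gates, in circuit order, into the earliest layer where all their
#' qubits are free.  By default every gate occupies a layer slot (a layer
#' of parallel single-qubit rotations counts as one layer, the convention
#' under which the canonical depth formulas hold); set
#' `multi_qubit_only = TRUE` to ignore single-qubit gates.
#'
#' @param circ a [circuit()].
#' @param multi_qubit_only count only gates acting on 2 or more qubits.
#' @return integer depth.
#' @export
circuit_depth <- function(circ, multi_qubit_only = FALSE) {
  avail <- integer(circ$n_qubits)        # next free layer per qubit (0-based)
  depth <- 0L
  for (g in circ$gates) {
    if (multi_qubit_only && length(g$qubits) < 2) next
    q <- g$qubits + 1L
    lay <- max(avail[q]) + 1L
    avail[q] <- lay
    depth <- max(depth, lay)
  }
  depth
}

# ---- gate unitaries and simulation ----------------------------------------

.gate_unitary <- function(g) {
  p <- g$params
  switch(g$name,
    Rz = diag(c(1, exp(1i * p[1]))),
    G = {
      B <- .g_block(p[1], p[2], if (length(p) > 2) p[3] else 0)
      U <- diag(4) + 0i
      U[2:3, 2:3] <- B
      U[4, 4] <- B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1]
      U
    },
    Unn = diag(c(1, 1, 1, exp(-1i * p[1]))),
    SWAP = matrix(c(1, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 1), 4, 4),
    UnnSWAP = diag(c(1, 1, 1, exp(-1i * p[1]))) %*%
      matrix(c(1, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 1), 4, 4),
    CX = matrix(c(1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0, 1, 0, 0), 4, 4),
    UnZn = {
      # qubits (data1, ancilla, data2); diagonal exp(-i phi n1 Za n2)
      d <- complex(8, modulus = 1, argument = 0)
      for (b in 0:7) {
        n1 <- bitwAnd(b, 1L); za <- 1 - 2 * bitwAnd(bitwShiftR(b, 1L), 1L)
        n2 <- bitwAnd(bitwShiftR(b, 2L), 1L)
        d[b + 1] <- exp(-1i * p[1] * n1 * za * n2)
      }
      diag(d)
    },
    stop("unknown gate: ", g$name))
}

#' Simulate a circuit by dense statevector evolution
#'
#' @param circ a [circuit()] (at most 16 qubits).
#' @param init initial state: either a 0/1 bit vector of length `n_qubits`
#'   (qubit 0 first) or a complex statevector of length `2^n_qubits`.
#' @return complex statevector (qubit 0 is the least significant bit).
#' @export
simulate_circuit <- function(circ, init) {
  nq <- circ$n_qubits
  if (nq > 16) stop("register too large for dense simulation (", nq, " qubits)")
  dim <- 2^nq
  if (length(init) == nq && all(init %in% c(0, 1))) {
    v <- complex(dim)
    v[sum(init * 2^(seq_len(nq) - 1)) + 1] <- 1 + 0i
  } else if (length(init) == dim) {
    v <- as.complex(init)
  } else stop("init must be a bit pattern or a full statevector")
  idx_all <- 0:(dim - 1)
  for (g in circ$gates) {
    U <- .gate_unitary(g)
    k <- length(g$qubits)
    mask <- sum(2^g$qubits)
    base <- idx_all[bitwAnd(idx_all, mask) == 0L]
    offs <- vapply(0:(2^k - 1), function(t) {
      bits <- bitwAnd(bitwShiftR(t, seq_len(k) - 1L), 1L)
      sum(bits * 2^g$qubits)
    }, numeric(1))
    M <- matrix(0i, 2^k, length(base))
    for (t in seq_len(2^k)) M[t, ] <- v[base + offs[t] + 1]
    M <- U %*% M
    for (t in seq_len(2^k)) v[base + offs[t] + 1] <- M[t, ]
  }
  v
}

# ---- orbital-rotation compilation (Clements scheme) ------------------------

# T(theta, phi) acting on coordinates (m, m+1) of an N-dim space
.tmat <- function(n, m, th, ph) {
  M <- diag(n) + 0i
  M[m, m] <- exp(1i * ph) * cos(th); M[m, m + 1] <- -sin(th)
  M[m + 1, m] <- exp(1i * ph) * sin(th); M[m + 1, m + 1] <- cos(th)
  M
}

# Clements-style two-sided nulling of a unitary U:
#   (prod T_left) U (prod Tinv_right) = D
# giving U = Tinv_left-rev ... D ... T_right-rev, i.e. a circuit that
# applies the right-list inverses first, then the diagonal, then the
# left-list inverses.  Returns gate parameter lists and the diagonal.
.clements_decompose <- function(U) {
  n <- nrow(U)
  V <- U + 0i
  left <- list(); right <- list()
  for (i in seq_len(n - 1)) {          # 1-based anti-diagonal counter
    if (i %% 2 == 1) {
      for (j in 0:(i - 1)) {
        r <- n - j; cc <- i - j        # element (r, cc), 1-based
        m <- cc                        # columns (m, m+1)
        a <- V[r, m]; b <- V[r, m + 1]
        if (Mod(a) < 1e-14) { th <- 0; ph <- 0 } else {
          th <- atan2(Mod(a), Mod(b))
          ph <- Arg(a) - Arg(b)
        }
        Ti <- Conj(t(.tmat(n, m, th, ph)))
        V <- V %*% Ti
        right[[length(right) + 1L]] <- list(m = m, th = th, ph = ph)
      }
    } else {
      for (j in 0:(i - 1)) {
        r <- n - i + j; cc <- 1 + j    # element (r+1?, cc): null (r+1, cc)
        m <- r                         # rows (m, m+1): null element (m+1, cc)
        a <- V[m, cc]; b <- V[m + 1, cc]
        if (Mod(b) < 1e-14) { th <- 0; ph <- 0 } else {
          th <- atan2(Mod(b), Mod(a))
          ph <- Arg(-b / (a + (Mod(a) < 1e-300)))
        }
        V <- .tmat(n, m, th, ph) %*% V
        left[[length(left) + 1L]] <- list(m = m, th = th, ph = ph)
      }
    }
  }
  list(left = left, right = right, diag = diag(V))
}

# compile exp(K) for one spin sector onto qubits offset..offset+N-1.
# Returns list(gates, check) where the gate order applies right-list
# inverses first, then Rz of the diagonal, then left-list inverses.
.rotation_gates <- function(K, offset) {
  es <- eigen(1i * K, symmetric = TRUE)
  U <- es$vectors %*% (exp(-1i * es$values) * Conj(t(es$vectors)))
  n <- nrow(U)
  dec <- .clements_decompose(U)
  gates <- list()
  # U = Tinv_l1 ... Tinv_lk  D  T_rm ... T_r1: the rightmost factor (first
  # recorded right rotation) acts first, so emit the right list in
  # recording order (form-1 blocks), then the diagonal as Rz, then the
  # left-list inverses in reverse recording order (form-0 blocks)
  for (g in dec$right)
    gates[[length(gates) + 1L]] <- gate("G", offset + c(g$m - 1L, g$m),
                                        c(g$th, g$ph, 1))
  for (p in seq_len(n))
    gates[[length(gates) + 1L]] <- gate("Rz", offset + p - 1L,
                                        Arg(dec$diag[p]))
  for (g in rev(dec$left))
    gates[[length(gates) + 1L]] <- gate("G", offset + c(g$m - 1L, g$m),
                                        c(g$th, g$ph, 0))
  gates
}

# single-particle matrix realized by a G gate.  Two frames differing in
# phase placement arise from the two-sided nulling; both are XX+YY Givens
# rotations up to single-qubit phase frames (form 0: phases on the first
# row; form 1: phases on the first column).
.g_block <- function(th, ph, form = 0) {
  if (form == 0)
    matrix(c(exp(-1i * ph) * cos(th), -sin(th),
             exp(-1i * ph) * sin(th), cos(th)), 2, 2)
  else
    matrix(c(exp(1i * ph) * cos(th), exp(1i * ph) * sin(th),
             -sin(th), cos(th)), 2, 2)
}

#' Compile a one-body orbital rotation to gates
#'
#' Decomposes `exp(K)` into a network of `N(N-1)` two-qubit Givens
#' rotations (both spin sectors) in the economical two-sided pattern plus
#' `2N` Rz phase gates, acting on adjacent qubits only.  The compiled
#' single-particle unitary is verified against `exp(K)` to 1e-10.
#'
#' @param K N x N complex anti-Hermitian generator (applied to both spin
#'   sectors).
#' @param n_qubits optional register size (defaults to 2N).
#' @return a [circuit()].
#' @export
compile_orbital_rotation <- function(K, n_qubits = 2L * nrow(K)) {
  K <- .check_antihermitian(K, "K")
  n <- nrow(K)
  ga <- .rotation_gates(K, 0L)
  gb <- .rotation_gates(K, n)
  # interleave sector gate lists so parallel columns share layers
  gates <- list()
  la <- length(ga)
  for (k in seq_len(la)) {
    gates[[length(gates) + 1L]] <- ga[[k]]
    gates[[length(gates) + 1L]] <- gb[[k]]
  }
  circ <- circuit(n_qubits, gates, metadata = list(block = "orbital-rotation"))
  # verification on the single-particle level
  es <- eigen(1i * K, symmetric = TRUE)
  U <- es$vectors %*% (exp(-1i * es$values) * Conj(t(es$vectors)))
  Urec <- .single_particle_unitary(circ, n, 0L)
  if (max(Mod(Urec - U)) > 1e-10)
    stop("orbital-rotation compilation residual ",
         signif(max(Mod(Urec - U)), 3), " exceeds 1e-10")
  circ
}

# reconstruct the single-particle unitary realized by the G/Rz gates of one
# spin sector (qubits offset..offset+n-1)
.single_particle_unitary <- function(circ, n, offset) {
  U <- diag(n) + 0i
  for (g in circ$gates) {
    qs <- g$qubits
    if (!all(qs >= offset & qs < offset + n)) next
    if (g$name == "Rz") {
      D <- diag(n) + 0i
      D[qs[1] - offset + 1, qs[1] - offset + 1] <- exp(1i * g$params[1])
      U <- D %*% U
    } else if (g$name == "G") {
      M <- diag(n) + 0i
      idx <- qs - offset + 1
      M[idx, idx] <- .g_block(g$params[1], g$params[2],
                              if (length(g$params) > 2) g$params[3] else 0)
      U <- M %*% U
    } else stop("unexpected gate in rotation block: ", g$name)
  }
  U
}

# ---- Jastrow compilation ---------------------------------------------------

#' Compile a Jastrow phase operator to gates
#'
#' Local topologies use one layer of on-site opposite-spin number-number
#' gates across the ladder (through an ancilla gadget on heavy-hex) plus a
#' brickwork of nearest-neighbor same-spin gates and a layer of Rz gates
#' carrying the one-body phase pieces.  The all-to-all model compiles to a
#' generalized swap network on the 2N-qubit line (alternating number-number
#' and SWAP layers) in which every qubit pair interacts exactly once; the
#' final qubit layout is reversed and recorded in the metadata.
#'
#' @param J_ss,J_os N x N real symmetric coupling matrices obeying the
#'   topology masks.
#' @param top a [make_topology()] model.
#' @return a [circuit()]; `metadata$layout` maps wire position to the
#'   logical qubit living there after the block.
#' @export
compile_jastrow <- function(J_ss, J_os, top) {
  n <- top$n_orb
  masks <- parameter_masks(top)
  if (any(abs(J_ss[!masks$mask_ss]) > 1e-12) ||
      any(abs(J_os[!masks$mask_os]) > 1e-12))
    stop("J entries outside the ", top$name, " topology mask")
  nq <- top$n_qubits
  gates <- list()
  # one-body phases: theta += 1/2 Jss[p,p] n_ps  per spin
  for (p in 1:n) {
    phz <- 0.5 * J_ss[p, p]
    if (top$name == "heavy-hex-zigzag" || top$name == "heavy-hex-loop") {
      # data-qubit halves of the decomposed opposite-spin gadget:
      # e^{ia n1 n2} = e^{i(a/2) n1} e^{i(a/2) n2} e^{-i(a/2)(n1 xor n2)}
      if ((p - 1L) %in% top$s_set) phz <- phz + 0.5 * J_os[p, p]
    }
    if (phz != 0) {
      gates[[length(gates) + 1L]] <- gate("Rz", p - 1L, phz)
      gates[[length(gates) + 1L]] <- gate("Rz", n + p - 1L, phz)
    }
  }
  layout <- 0:(nq - 1L)
  if (top$name == "all-to-all") {
    # phase angle between logical qubits (0-based, alpha 0..N-1, beta N..2N-1)
    ang <- function(q1, q2) {
      p1 <- q1 %% n; s1 <- q1 %/% n
      p2 <- q2 %% n; s2 <- q2 %/% n
      if (s1 == s2) {
        if (p1 == p2) 0 else J_ss[p1 + 1, p2 + 1]
      } else J_os[p1 + 1, p2 + 1]
    }
    pos <- 0:(2L * n - 1L)               # pos[wire+1] = logical qubit
    for (round in seq_len(2L * n)) {
      start <- if (round %% 2 == 1) 1L else 2L
      pairs <- seq(start, 2L * n - 1L, by = 2L)
      for (w in pairs) {                 # wires (w-1, w) 0-based
        q1 <- pos[w]; q2 <- pos[w + 1]
        a <- ang(q1, q2)
        gates[[length(gates) + 1L]] <- gate("Unn", c(w - 1L, w), -a)
      }
      for (w in pairs) {
        gates[[length(gates) + 1L]] <- gate("SWAP", c(w - 1L, w))
        tmp <- pos[w]; pos[w] <- pos[w + 1]; pos[w + 1] <- tmp
      }
    }
    layout <- pos
  } else {
    # opposite-spin on-site couplings
    for (p0 in top$s_set) {
      p <- p0 + 1L
      a <- J_os[p, p]
      if (grepl("^heavy-hex", top$name)) {
        anc <- top$ancilla_map[[as.character(p0)]]
        # e^{i a n1 n2} = Rz(a/2 on both, folded above) x parity phase:
        # CX, CX, Rz(-a/2) on ancilla, CX, CX
        gates[[length(gates) + 1L]] <- gate("CX", c(p - 1L, anc))
        gates[[length(gates) + 1L]] <- gate("CX", c(n + p - 1L, anc))
        gates[[length(gates) + 1L]] <- gate("Rz", anc, -a / 2)
        gates[[length(gates) + 1L]] <- gate("CX", c(n + p - 1L, anc))
        gates[[length(gates) + 1L]] <- gate("CX", c(p - 1L, anc))
      } else {
        gates[[length(gates) + 1L]] <- gate("Unn", c(p - 1L, n + p - 1L), -a)
      }
    }
    # same-spin nearest neighbors: even then odd brickwork, both sectors
    for (par in c(1L, 0L)) {
      for (p in seq_len(n - 1)) {
        if (p %% 2 != par) next
        a <- J_ss[p, p + 1]
        gates[[length(gates) + 1L]] <- gate("Unn", c(p - 1L, p), -a)
        gates[[length(gates) + 1L]] <- gate("Unn", c(n + p - 1L, n + p), -a)
      }
    }
  }
  circuit(nq, gates, metadata = list(block = "jastrow", topology = top$name,
                                     layout = layout))
}

# ---- full ansatz compilation ----------------------------------------------

#' Compile a full LUCJ ansatz circuit
#'
#' Concatenates, per layer, the compiled `exp(-K)`, Jastrow and `exp(K)`
#' blocks, then the final `exp(X)` block.  When a swap-network Jastrow
#' block permutes the wire layout, subsequent blocks are re-targeted
#' through the current layout; `metadata$layout` records the final
#' wire-to-logical map.
#'
#' @param params a [lucj_parameters()] set.
#' @return a [circuit()].
#' @export
lucj_compile <- function(params) {
  top <- params$topology
  n <- top$n_orb
  nq <- top$n_qubits
  layout <- 0:(nq - 1L)                  # layout[wire+1] = logical qubit
  gates <- list()
  retarget <- function(gs) {
    wire_of <- integer(nq); wire_of[layout + 1L] <- 0:(nq - 1L)
    lapply(gs, function(g) { g$qubits <- wire_of[g$qubits + 1L]; g })
  }
  add <- function(circ_or_gates) {
    gs <- if (inherits(circ_or_gates, "lucj_circuit")) circ_or_gates$gates
          else circ_or_gates
    for (g in retarget(gs)) gates[[length(gates) + 1L]] <<- g
  }
  for (ly in params$layers) {
    add(compile_orbital_rotation(-ly$K, nq))
    jc <- compile_jastrow(ly$J_ss, ly$J_os, top)
    add(jc$gates)
    if (!identical(jc$metadata$layout, 0:(nq - 1L))) {
      # compose layouts: new wire w holds logical layout[jlayout[w]+1]
      layout <- layout[jc$metadata$layout + 1L]
    }
    add(compile_orbital_rotation(ly$K, nq))
  }
  if (max(Mod(params$X)) > 0) add(compile_orbital_rotation(params$X, nq))
  circuit(nq, gates, metadata = list(topology = top$name, layout = layout))
}

#' Export a circuit as plain text or JSON
#'
#' One gate per line: name, qubit indices, angles — an assembly-style
#' listing in the spirit of open quantum-circuit interchange formats.
#'
#' @param circ a [circuit()].
#' @param format `"text"` or `"json"`.
#' @return character scalar.
#' @export
circuit_export <- function(circ, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(n_qubits = circ$n_qubits,
           gates = lapply(circ$gates, function(g)
             list(name = g$name, qubits = g$qubits, params = g$params)),
           metadata = circ$metadata), auto_unbox = TRUE, digits = NA)))
  }
  lines <- vapply(circ$gates, function(g) {
    sprintf("%s q[%s]%s", tolower(g$name),
            paste(g$qubits, collapse = ","),
            if (length(g$params))
              sprintf(" (%s)", paste(signif(g$params, 12), collapse = ", "))
            else "")
  }, "")
  paste(c(sprintf("qubits %d", circ$n_qubits), lines), collapse = "\n")
}

# ---- resource estimation ---------------------------------------------------

#' Gate-count and depth estimates for LUCJ building blocks
#'
#' Canonical per-block costs in terms of the spatial orbital count `N`: the
#' orbital-rotation block needs `2N` Rz and `N(N-1)` Givens gates at depth
#' `1+N`; the Jastrow block needs `2N` Rz plus topology-dependent
#' number-number gates at depth 4 for the square, hex and linear lattices
#' (one opposite-spin layer, two same-spin layers, one Rz layer), depth 8
#' for heavy-hex (the ancilla gadget costs four CX layers plus one Rz
#' layer, `4|S| ~ N` CX gates in total), and depth `1 + 4N` with
#' `N(2N-1)` number-number and as many SWAP gates for the all-to-all swap
#' network.  Native two-qubit gate totals use one Rzx per number-number
#' gate, two per Givens and three per fused number-number-SWAP on
#' fixed-frequency hardware, and one fSim per number-number or Givens gate
#' on tunable-coupler hardware.
#'
#' @param n_orb number of spatial orbitals N (>= 2).
#' @param topology topology name.
#' @param n_layers layer count L (an L-layer ansatz uses L Jastrow blocks
#'   and L+1 rotation blocks after merging adjacent rotations).
#' @param native `"logical"`, `"rzx"` or `"fsim"`.
#' @return data.frame with per-block and total gate counts and depths.
#' @export
resource_estimate <- function(n_orb, topology, n_layers = 1,
                              native = c("logical", "rzx", "fsim")) {
  native <- match.arg(native)
  N <- as.integer(n_orb)
  if (N < 2) stop("resource model needs N >= 2")
  topology <- match.arg(topology, .topology_names)
  s_size <- length(make_topology(topology, N)$s_set)
  rot <- list(block = "exp(K)", Rz = 2L * N, G = N * (N - 1L), Unn = 0L,
              SWAP = 0L, CX = 0L, depth = 1L + N)
  jas <- switch(topology,
    "all-to-all" = list(block = "exp(iJ)", Rz = 2L * N, G = 0L,
                        Unn = N * (2L * N - 1L), SWAP = N * (2L * N - 1L),
                        CX = 0L, depth = 1L + 4L * N),
    "square" = list(block = "exp(iJ)", Rz = 2L * N, G = 0L,
                    Unn = N + 2L * (N - 1L), SWAP = 0L, CX = 0L, depth = 4L),
    "hex" = list(block = "exp(iJ)", Rz = 2L * N, G = 0L,
                 Unn = as.integer(ceiling(N / 2)) + 2L * (N - 1L),
                 SWAP = 0L, CX = 0L, depth = 4L),
    "linear" = list(block = "exp(iJ)", Rz = 2L * N, G = 0L,
                    Unn = 1L + 2L * (N - 1L), SWAP = 0L, CX = 0L, depth = 4L),
    list(block = "exp(iJ)", Rz = 2L * N + s_size, G = 0L,
         Unn = 2L * (N - 1L), SWAP = 0L, CX = 4L * s_size, depth = 8L))
  blocks <- list(rot, jas)
  df <- do.call(rbind, lapply(blocks, as.data.frame))
  tot <- df[1, ]
  tot$block <- sprintf("total (L=%d)", n_layers)
  for (cn in c("Rz", "G", "Unn", "SWAP", "CX"))
    tot[[cn]] <- (n_layers + 1L) * df[[cn]][1] + n_layers * df[[cn]][2]
  tot$depth <- (n_layers + 1L) * df$depth[1] + n_layers * df$depth[2]
  df <- rbind(df, tot)
  if (native != "logical") {
    conv <- if (native == "rzx")
      c(G = 2, Unn = 1, UnnSWAP = 3, SWAP = 3, CX = 1) else
      c(G = 1, Unn = 1, UnnSWAP = 1, SWAP = 1, CX = 2)
    fuse_swap <- topology == "all-to-all"
    df$native <- vapply(seq_len(nrow(df)), function(r) {
      if (fuse_swap) {
        # number-number and SWAP pairs fuse to UnnSWAP gates
        nn_fused <- min(df$Unn[r], df$SWAP[r])
        rest_u <- df$Unn[r] - nn_fused
        rest_s <- df$SWAP[r] - nn_fused
        nn_fused * conv[["UnnSWAP"]] + rest_u * conv[["Unn"]] +
          rest_s * conv[["SWAP"]] + df$G[r] * conv[["G"]] +
          df$CX[r] * conv[["CX"]]
      } else {
        df$G[r] * conv[["G"]] + df$Unn[r] * conv[["Unn"]] +
          df$SWAP[r] * conv[["SWAP"]] + df$CX[r] * conv[["CX"]]
      }
    }, numeric(1))
  }
  df
}
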