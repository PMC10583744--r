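---
title: "The local unitary cluster Jastrow ansatz: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The local unitary cluster Jastrow ansatz: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package simulates the (local) unitary cluster Jastrow wavefunction for
an active-space electronic Hamiltonian

$$\hat H = E_0 + \sum_{pq} h_{pq}\,\hat E_{pq}
  + \tfrac12 \sum_{pqrs} (pq|rs)\,
    (\hat E_{pq}\hat E_{rs} - \delta_{qr}\hat E_{ps}),$$

with spin-summed excitation operators $\hat E_{pq}$ and chemist-convention
two-electron integrals.  The ansatz is a product of $L$ layers acting on a
reference determinant $|\Phi_0\rangle$ (normally the restricted
Hartree--Fock configuration), followed by a one-body orbital-optimization
factor:

$$|\psi\rangle = e^{\hat X}\,
  \prod_{\mu=L}^{1} e^{\hat K_\mu}\, e^{i\hat J_\mu}\, e^{-\hat K_\mu}\,
  |\Phi_0\rangle .$$

Each $\hat K_\mu$ is a complex anti-Hermitian one-body generator applied
identically to both spin sectors; each $\hat J_\mu$ is a density--density
correlator, diagonal in the occupation basis:

$$\theta(\mathbf n) = \tfrac12 \sum_{pq} J^{ss}_{pq}
   (n_{p\alpha}n_{q\alpha} + n_{p\beta}n_{q\beta})
   + \sum_{pq} J^{os}_{pq}\, n_{p\alpha} n_{q\beta}.$$

Storing a single $J^{ss}$ for both same-spin blocks and a single $J^{os}$
for both opposite-spin blocks enforces commutation with $S_z$ by
construction.  The opposite-spin correlator penalizing double occupancy is
exactly the physics of the repulsive Hubbard interaction, which is why the
ansatz dissociates closed-shell bonds correctly where restricted mean-field
theory cannot.

The *local* variants restrict the couplings to what a qubit lattice can
realize without SWAP gates: same-spin couplings on nearest-neighbor
orbitals $(p, p\pm 1)$ plus the diagonal, and on-site opposite-spin
couplings $J^{os}_{pp}$ only on the orbital set $S$ fixed by the lattice
(`square`: every orbital; `hex`: even orbitals; `heavy-hex`: every fourth
orbital, coupled through an ancilla; `linear`: orbital 0 only;
`all-to-all`: unrestricted).  `parameter_masks()` materializes these rules
as boolean matrices, and the mask hierarchy (heavy-hex ⊆ hex ⊆ square ⊆
all-to-all) is what makes bootstrapped energies monotone.

Two conventions are fixed here because the source material leaves them
open, and all tests pin them: layers act in ascending $\mu$ (layer 1
first), and $e^{\hat X}$ is applied outermost.  Both choices relabel
parameters without changing the variational family.

## Simulation strategy

States live in the determinant sector of fixed $(n_\alpha, n_\beta)$.  A
`lucj_problem` caches the sector Hamiltonian matrix, the Slater--Condon
coupling tables of every $\hat E_{pq}$, and determinant occupation tables.
One-body exponentials are applied through the eigendecomposition of the
sector representation of $i\hat K$ (a Hermitian matrix); Jastrow factors
are exact diagonal phases.  A fully independent oracle — dense
Jordan--Wigner operators on the $2^{2N}$-dimensional qubit space,
exponentiated by Hermitian eigendecomposition — lives in the test suite
and never shares code with this path.

The phase convention orders creation operators by ascending spin orbital
with all spin-up before all spin-down, matching the qubit layout of the
circuit compiler (orbital $p$ on qubit $p$, spin-down partner on qubit
$p+N$), so compiled circuits and sector states can be compared amplitude
by amplitude.

## Electronic-structure layer

All molecular inputs are built internally: McMurchie--Davidson Gaussian
integrals over the shipped STO-6G basis (compiled code), restricted
Hartree--Fock with DIIS, MP2 and spin-orbital CCSD amplitudes, and exact
diagonalization in the active space.  Three numerical choices matter:

* **Level shift in the SCF.**  Square cyclobutadiene has an exactly
  degenerate frontier pair at the symmetric geometry and several
  broken-symmetry stationary points a few tens of mHa apart.  A virtual
  level shift of 0.2 Ha (released once the DIIS error is small) makes the
  iteration converge deterministically to the aufbau solution that a
  standard quantum-chemistry run reaches from a superposition-of-atoms
  guess; its total energy is the benchmark value quoted in the README.
* **Core folding.**  Orbitals below the active window contribute a closed
  shell folded into the scalar offset and an effective one-body term (the
  standard inactive-Fock contraction), so the active Hamiltonian is exact
  within its sector.
* **CCSD with a shifted-denominator update.**  The quasi-degenerate
  (4e,4o) pi space makes bare amplitude iterations oscillate; updates use
  the true residual divided by level-shifted denominators plus DIIS, which
  changes the iteration path but not the fixed point.

Active spaces are selected either as a HOMO-centred canonical window
(energy-ascending, ties broken by the stable original index), by Mulliken
population on target AOs (used for the pi space: carbon 2p$_z$ weight
separates the four pi orbitals exactly in a planar molecule; ties within
`1e-6` raise an error instead of silently picking), or as MP2
natural orbitals in occupation-descending order (closed-shell unrelaxed
density).

## Initialization by double factorization

With $T_{(ia),(jb)} = t_2^{ij\,ab}$ symmetric, the eigendecomposition
$T = \sum_\gamma \lambda_\gamma v_\gamma v_\gamma^T$ and the split of the
one-body excitation matrix $M_\gamma$ into Hermitian parts
$S_\gamma \pm A_\gamma$ give the exact operator identity

$$\hat T_2 - \hat T_2^\dagger = \frac{i}{2} \sum_\gamma \lambda_\gamma
  \left[(\hat S_\gamma + \hat A_\gamma)^2 -
        (\hat S_\gamma - \hat A_\gamma)^2\right],$$

so each retained eigenvalue produces two layers: the eigenbasis rotation
of the Hermitian generator supplies $K$, and the generator's eigenvalues
$d$ supply spin-uniform couplings $J^{ss} = J^{os} = \pm\lambda\, d d^T$.
One point deserves emphasis: the two squares do *not* commute, even for a
rank-1 amplitude tensor, so the two-layer product differs from
$e^{\hat T_2 - \hat T_2^\dagger}$ by a genuine second-order splitting
error (measured to scale quadratically with the amplitude norm).  The
package treats the construction as what it is — an initializer whose error
the optimizer removes — and the tests assert the exact statements: the
generator identity above to $10^{-10}$, exact equality with the ordered
product of the two square-exponentials, and the quadratic error scaling.

Projection onto a restricted topology permutes orbitals so that the
largest layer-summed $|J^{os}_{pp}|$ land on the coupling set $S$ (greedy,
ties by original index; verified against brute-force enumeration of all
permutations at small $N$), applies the permutation to every generator and
to the Hamiltonian, then zeroes masked-out couplings.

## Optimization

Energies are minimized with BFGS over the flat parameter vector
(documented ordering in `flatten_parameters()`), with central
finite-difference gradients at step `1e-6`.  Defaults: 300 iterations,
relative tolerance `1e-13`, targeting the 1.6 mHa benchmark accuracy with
room to spare; the H2 curve converges to $10^{-14}$ Ha under the same
settings.  The hot path re-exponentiates only layers whose $K$ slice
changed, so a finite-difference sweep over Jastrow parameters skips the
eigensolver.

The zero-parameter configuration is a stationary point at any determinant
reference: layers with $J=0$ are the identity regardless of $K$, and a
determinant is an eigenstate of every diagonal correlator, so the $K$ and
$J$ gradients vanish identically; at a true mean-field reference the
Brillouin condition kills the $\hat X$ gradient too.
`stationarity_report()` documents the trap and separates the two blocks.
A zero start therefore warns and applies a seeded perturbation.  The
perturbation covers *all* generator blocks at scale `1e-2`: a J-only kick
(the most literal reading of the usual recipe) leaves the energy flat to
first order at a mean-field reference, because the escape direction is a
coupled $K$--$J$ second-order mode; perturbing $K$ and $X$ as well makes
the escape robust, which is why the package deviates from a J-only
scheme.

Bootstrapping runs an ordered stage list (connectivity never increasing),
warm-starts each stage from the projected previous solution, pads added
layers with identity layers, and audits monotonicity afterwards: a stage
whose masks contain another stage's masks and whose layer count is at
least as large must not end higher (tolerance `1e-9` Ha).  Violations
re-run the weaker stage from the better comparator, up to 5 restarts;
persistent violations are flagged on the result rather than hidden.

## Circuit compilation

Orbital rotations compile to $2N$ Rz phase gates and $N(N-1)$ two-qubit
Givens rotations per spin sector pair, by two-sided adjacent-pair nulling
of the single-particle unitary (the economical rectangular pattern).  The
two-sided scheme produces Givens factors in two single-qubit phase frames;
the `G` gate therefore carries a third parameter selecting the frame, and
the diagonal phase layer sits between the two gate groups.  The compiled
single-particle unitary is verified against $e^K$ to $10^{-10}$ at
compile time, and the greedy-layered depth realizes the canonical $1+N$
for $N \ge 3$ ($N=2$ needs one fewer column).

Jastrow blocks compile per topology: one layer of on-site number--number
gates across the ladder (through a 4-CX parity gadget on heavy-hex, whose
ancilla provably returns to $|0\rangle$), a two-layer brickwork of
same-spin nearest-neighbor gates, and one layer of Rz gates carrying the
one-body phase pieces ($n^2 = n$ on the diagonal, plus the data-qubit
halves of the heavy-hex gadget).  Depth is counted over layers of
*all* gates, a layer of parallel single-qubit rotations costing one; this
is the convention under which the canonical depth table holds exactly
(rotation block $1+N$; square/hex/linear Jastrow block $4$; heavy-hex $8$
— one Rz layer, two same-spin layers, and the gadget's four CX layers plus
its ancilla phase; all-to-all $1+4N$).  A multi-qubit-only count is
available as an option; under it the local Jastrow block is 3 deep, since
single-qubit phases are free.

The all-to-all correlator uses a generalized swap network: $2N$ rounds of
alternating number--number and SWAP layers on the qubit line, in which
every one of the $N(2N-1)$ qubit pairs interacts exactly once and the
final wire order is reversed.  The compiler tracks the wire-to-logical
layout and re-targets subsequent blocks through it, so the full compiled
ansatz equals the Jordan--Wigner embedding of the simulator state (up to
global phase and the recorded final layout) for every topology — an
equivalence the tests enforce at $10^{-10}$.

Resource estimates report the canonical per-block formulas, totals with
$L$ Jastrow blocks and $L+1$ rotation blocks (adjacent rotations merge),
and native-gate conversions: on fixed-frequency hardware one Rzx per
number--number gate, two per Givens, three per fused number--number+SWAP;
on tunable-coupler hardware one fSim per number--number or Givens gate.

## Benchmark conditions and what the tests show

The shipped benchmarks run at desk scale: square cyclobutadiene (C--C
1.456 Å, C--H 1.069 Å along the diagonals, planar) in STO-6G with the
(4e,4o) pi space (CI dimension 36), a six-point H2 scan in the full
minimal-basis (2e,2o) space, Hubbard chains of 2--4 sites, and oracle
comparisons at $N \le 4$ spatial orbitals.  These sizes keep the complete
suite and the benchmark script within a few minutes on one core while
exercising every code path at full accuracy.

Passing tests demonstrate exact-arithmetic correctness of the simulator,
compiler and optimizer on noiseless statevectors and small active spaces.
They do not speak to shot noise, decoherence, hardware calibration, basis
sets beyond the shipped minimal one, or the behaviour of the optimizer on
much larger parameter counts, where the rugged-landscape diagnostics
(cusps in the energy trace, oscillating gradient and step norms —
reproducible here from adversarial starts on a Hubbard chain) are known to
become more serious.

## Known limitations

* Only H and C carry shipped basis data; other elements need an FCIDUMP
  or externally supplied integrals.
* RHF references only (closed shell); open-shell sectors are simulated
  exactly but start from a specified determinant rather than a UHF/ROHF
  solution.
* The FCI solver is dense up to sector dimension 2000 and a
  reorthogonalized Lanczos above; it targets reference energies for small
  actives, not production CI.
* Heavy-hex post-selection is bookkeeping only: the noiseless simulator
  proves the ancilla returns to $|0\rangle$, so there is nothing to
  post-select on.
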