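Package: lucj
Title: Local Unitary Cluster Jastrow Ansatz Simulation for Molecular
    Electronic Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical statevector simulation of the local unitary cluster
    Jastrow (LUCJ) family of variational ansatzes for correlated electronic
    states on qubit devices with restricted connectivity. Provides a minimal
    electronic-structure backend (Gaussian integrals in the STO-6G basis,
    restricted Hartree-Fock, MP2 and CCSD amplitudes, active-space full
    configuration interaction), Hubbard model Hamiltonians, FCIDUMP input and
    output, topology-restricted parameter masks for all-to-all, linear,
    square, hex and heavy-hex qubit lattices, initialization of ansatz layers
    from a doubly factorized low-rank decomposition of t2 amplitudes,
    variational optimization with bootstrapping across connectivities and
    layer counts, and a compiler from ansatz layers to explicit quantum gate
    sequences with resource estimation and brute-force statevector
    verification.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
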