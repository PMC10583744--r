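# Configuration-driven drivers reproducing the package's benchmark
# experiments: single-point LUCJ energies across topologies and layer
# counts, and potential-energy curves with warm-started optimizations.

#' Assemble a molecular system for LUCJ simulation
#'
#' Runs RHF, selects the active space, builds the folded active Hamiltonian
#' and computes t2 amplitudes.
#'
#' @param mol a [molecule()], or one of the fixture names
#'   `"cyclobutadiene"`, `"h2"`.
#' @param n_active active orbital count (default: all orbitals).
#' @param rule active-space rule passed to [select_active_space()].
#' @param target_aos AO indices for the `"ao-overlap"` rule.
#' @param t2_source `"CCSD"` or `"MP2"`.
#' @param r bond length in Angstrom for the `"h2"` fixture.
#' @return list with `scf`, `H` (active Hamiltonian), `t2`, `fci`.
#' @export
ab_initio_system <- function(mol, n_active = NULL,
                             rule = "canonical-window", target_aos = NULL,
                             t2_source = c("CCSD", "MP2"), r = 0.7414) {
  t2_source <- match.arg(t2_source)
  if (is.character(mol)) {
    mol <- switch(mol,
      cyclobutadiene = cyclobutadiene_molecule(),
      h2 = h2_molecule(r),
      stop("unknown fixture: ", mol))
  }
  scf <- rhf(mol)
  if (is.null(n_active)) n_active <- scf$n_ao
  mo_coeff <- NULL
  if (n_active < scf$n_ao || identical(rule, "mp2-natural")) {
    sel <- select_active_space(scf, n_active, rule, target_aos = target_aos)
    active <- sel$orbitals
    ordering <- sel$ordering
    mo_coeff <- sel$mo_coeff
  } else {
    active <- seq_len(scf$n_ao)
    ordering <- "energy-ascending"
  }
  H <- active_hamiltonian(scf, active, mo_coeff = mo_coeff,
                          orbital_order = ordering)
  t2 <- if (t2_source == "CCSD") ccsd_t2(H) else .active_mp2_t2(H)
  fci <- fci_solve(H)
  list(scf = scf, H = H, t2 = t2, fci = fci, active = active)
}

#' The shipped cyclobutadiene benchmark system
#'
#' Square cyclobutadiene (side 1.456 A, C-H 1.069 A) in STO-6G with the
#' (4e,4o) pi active space of carbon-2pz-dominant orbitals.
#'
#' @param t2_source `"CCSD"` or `"MP2"`.
#' @return as [ab_initio_system()].
#' @export
cyclobutadiene_system <- function(t2_source = "CCSD") {
  mol <- cyclobutadiene_molecule()
  scf <- rhf(mol)
  # pz AOs: fifth function of each carbon block (1s, 2s, px, py, pz)
  pz <- c(5L, 10L, 15L, 20L)
  sel <- select_active_space(scf, 4, "ao-overlap", target_aos = pz)
  H <- active_hamiltonian(scf, sel$orbitals)
  t2 <- if (t2_source == "CCSD") ccsd_t2(H) else .active_mp2_t2(H)
  list(scf = scf, H = H, t2 = t2, fci = fci_solve(H), active = sel$orbitals)
}

#' Single-point LUCJ report across topologies and layer counts
#'
#' Runs the bootstrap chain over the requested stages and reports SCF,
#' per-stage LUCJ and FCI energies with deviations, plus per-stage
#' resource estimates.
#'
#' @param system an [ab_initio_system()]-style list.
#' @param plan bootstrap plan (see [lucj_bootstrap()]); when the first
#'   stage carries no `init`, a t2 double-factorization initialization is
#'   attached automatically.
#' @param settings an [optimizer_settings()] list.
#' @param t2_tol truncation threshold of the initializing factorization.
#' @return list of class `lucj_report` with `energies` (data.frame),
#'   `bootstrap`, `resources`, `config`.
#' @export
run_single_point <- function(system, plan, settings = optimizer_settings(),
                             t2_tol = 1e-12) {
  H <- system$H
  if (length(plan) && is.null(plan[[1]]$init)) {
    fd <- double_factorize_t2(system$t2, tol = t2_tol)
    plan[[1]]$init <- layers_from_factorization(fd, l_max = plan[[1]]$L)
  }
  efci <- system$fci$energy
  escf <- if (!is.null(system$scf)) system$scf$energy else
    .reference_energy(H)
  if (!length(plan)) {
    df <- data.frame(stage = c("SCF", "FCI"), energy = c(escf, efci),
                     dev_mHa = c((escf - efci) * 1000, 0))
    return(structure(list(energies = df, bootstrap = NULL,
                          resources = NULL,
                          config = list(plan = plan, settings = settings)),
                     class = "lucj_report"))
  }
  bs <- lucj_bootstrap(H, plan, settings)
  stages <- names(bs$stages)
  df <- data.frame(
    stage = c("SCF", stages, "FCI"),
    energy = c(escf, vapply(bs$stages, function(s) s$opt$best_energy, 0),
               efci))
  df$dev_mHa <- (df$energy - efci) * 1000
  res <- do.call(rbind, lapply(seq_along(plan), function(k)
    cbind(stage = stages[k],
          resource_estimate(H$n_orb, plan[[k]]$topology, plan[[k]]$L))))
  structure(list(energies = df, bootstrap = bs, resources = res,
                 config = list(plan = lapply(plan, function(p)
                   p[c("topology", "L")]), settings = settings)),
            class = "lucj_report")
}

#' @export
print.lucj_report <- function(x, ...) {
  print(x$energies, digits = 10)
  invisible(x)
}

#' Potential-energy curve with warm-started LUCJ optimizations
#'
#' Optimizes the ansatz at each geometry of a scan, warm-starting each
#' point from the previous point's converged parameters (disable with
#' `warm_start = FALSE` for independence checks).
#'
#' @param geometries list of [molecule()] objects (scan order).
#' @param topology topology name.
#' @param n_layers layer count L.
#' @param n_active active orbital count (default: all).
#' @param t2_source `"MP2"` or `"CCSD"` initialization at the first point.
#' @param settings an [optimizer_settings()] list.
#' @param warm_start reuse the previous point's parameters.
#' @return data.frame with per-point SCF, LUCJ and FCI energies and the
#'   maximum absolute LUCJ-FCI deviation as attribute `max_dev`.
#' @export
run_curve <- function(geometries, topology = "all-to-all", n_layers = 1L,
                      n_active = NULL, t2_source = "MP2",
                      settings = optimizer_settings(), warm_start = TRUE) {
  rows <- list()
  params_prev <- NULL
  for (i in seq_along(geometries)) {
    sys <- ab_initio_system(geometries[[i]], n_active = n_active,
                            t2_source = t2_source)
    top <- make_topology(topology, sys$H$n_orb)
    prob <- lucj_problem(sys$H)
    ref <- hf_reference(sys$H)
    init <- if (warm_start && !is.null(params_prev)) params_prev else {
      fd <- double_factorize_t2(sys$t2)
      p0 <- layers_from_factorization(fd, l_max = n_layers)
      p0 <- project_to_topology(p0, top)
      # pad to requested layer count
      .adapt_parameters(p0, seq_len(sys$H$n_orb), top, n_layers, settings)
    }
    opt <- tryCatch(lucj_minimize(prob, ref, init, settings),
                    error = function(e) e)
    if (inherits(opt, "error")) {
      rows[[i]] <- data.frame(point = i, scf = sys$scf$energy,
                              lucj = NA_real_, fci = sys$fci$energy,
                              error = conditionMessage(opt))
      next
    }
    params_prev <- opt$best_params
    rows[[i]] <- data.frame(point = i, scf = sys$scf$energy,
                            lucj = opt$best_energy, fci = sys$fci$energy,
                            error = "")
  }
  out <- do.call(rbind, rows)
  attr(out, "max_dev") <- max(abs(out$lucj - out$fci), na.rm = TRUE)
  out
}
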