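#' One-site binding parameters
#'
#' @param n stoichiometry (sites per macromolecule)
#' @param kd dissociation constant (M)
#' @param dh molar binding enthalpy (cal/mol)
#' @param baseline constant per-injection heat offset (ucal)
#' @return a `binding_params` object
#' @export
binding_params <- function(n = 1, kd, dh = -10000, baseline = 0) {
  if (kd <= 0) abort("kd must be > 0", class = "nrpsdock_value_error")
  if (n <= 0) abort("n must be > 0", class = "nrpsdock_value_error")
  structure(list(n = n, kd = kd, dh = dh, baseline = baseline),
            class = "binding_params")
}

#' ITC injection protocol
#'
#' Defaults reproduce the standard small-volume protocol used for these
#' docking domains: 50 uM macromolecule in a 200 ul cell titrated with 1 mM
#' peptide, one 0.2 ul priming injection followed by 19 x 2 ul injections.
#'
#' @param cell_conc macromolecule concentration in the cell (M)
#' @param syringe_conc titrant concentration in the syringe (M)
#' @param cell_volume active cell volume (L)
#' @param first_volume volume of the first (priming) injection (L)
#' @param inj_volume volume of each serial injection (L)
#' @param n_inj total number of injections including the first
#' @return an `itc_protocol` object
#' @export
itc_protocol <- function(cell_conc = 50e-6, syringe_conc = 1e-3,
                         cell_volume = 200e-6, first_volume = 0.2e-6,
                         inj_volume = 2e-6, n_inj = 20L) {
  vals <- c(cell_conc, syringe_conc, cell_volume, first_volume, inj_volume)
  if (any(vals <= 0) || n_inj < 1) {
    abort("all protocol concentrations/volumes must be > 0 and n_inj >= 1",
          class = "nrpsdock_value_error")
  }
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume, first_volume = first_volume,
                 inj_volume = inj_volume, n_inj = as.integer(n_inj)),
            class = "itc_protocol")
}

#' Injection volumes of a protocol (L)
#' @param protocol an [itc_protocol()]
#' @export
injection_volumes <- function(protocol) {
  stopifnot(inherits(protocol, "itc_protocol"))
  c(protocol$first_volume, rep(protocol$inj_volume, protocol$n_inj - 1L))
}

protocols_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Fraction of macromolecule bound under ligand depletion
#'
#' Exact physical root of the 1:1 equilibrium quadratic,
#' `f = (P + L + Kd - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)`,
#' evaluated in the numerically stable form `f = 2L / (b + sqrt(b^2 - 4PL))`.
#'
#' @param p_total total macromolecule concentration (M), > 0
#' @param l_total total ligand concentration (M), >= 0
#' @param kd dissociation constant (M), > 0
#' @return fraction bound in \[0, 1\]; vectorised over `l_total`
#' @export
fraction_bound <- function(p_total, l_total, kd) {
  if (any(p_total <= 0) || any(kd <= 0)) {
    abort("p_total and kd must be > 0", class = "nrpsdock_value_error")
  }
  if (any(l_total < 0)) {
    abort("l_total must be >= 0", class = "nrpsdock_value_error")
  }
  b <- p_total + l_total + kd
  disc <- pmax(b^2 - 4 * p_total * l_total, 0)
  complex <- 2 * p_total * l_total / (b + sqrt(disc))
  pmin(pmax(complex / p_total, 0), 1)
}

#' Wiseman c-value of an ITC experiment
#'
#' `c = n * Ka * [M]_T = n * [M]_T / Kd`. Dissociation constants are only
#' reliably determined from titrations with c > 1; below that the isotherm is
#' too shallow to pin down Kd and fits are reported as qualitative only.
#'
#' @param n stoichiometry
#' @param kd dissociation constant (M)
#' @param m_total total macromolecule (cell) concentration (M)
#' @return dimensionless c
#' @export
c_value <- function(n, kd, m_total) {
  if (any(c(n, kd, m_total) <= 0)) {
    abort("n, kd and m_total must all be > 0", class = "nrpsdock_value_error")
  }
  n * m_total / kd
}

#' Fast-exchange population-averaged chemical shift
#'
#' In the fast-exchange regime the observed shift is the population-weighted
#' average of the free and bound shifts: `d_obs = d_free + f (d_bound - d_free)`
#' per dimension, so each residue traces a straight line in the (1H, 15N)
#' plane across a titration.
#'
#' @param delta_free,delta_bound numeric vectors (ppm), matched element-wise
#' @param f_bound fraction bound in \[0, 1\]
#' @return observed shifts (ppm)
#' @export
csp_forward <- function(delta_free, delta_bound, f_bound) {
  if (any(f_bound < 0 | f_bound > 1)) {
    abort("f_bound must lie in [0, 1]", class = "nrpsdock_value_error")
  }
  delta_free + f_bound * (delta_bound - delta_free)
}

#' Forward model for one-site ITC injection heats
#'
#' Perfusion (overflow) cell bookkeeping: the active volume `V0` is constant
#' and each injection of volume `v` displaces an equal volume of current cell
#' contents. Per injection:
#'
#' * totals are diluted by `d = 1 - v/V0` and the syringe titrant adds
#'   `L_syr * v/V0`;
#' * the complex concentration `C` is re-solved from the site-level quadratic
#'   with site concentration `n * M`;
#' * the measured heat uses the mean-concentration correction for material
#'   displaced during the injection:
#'   `q = dH * V0 * ((C_i - C_{i-1}) + (v/V0) * (C_i + C_{i-1}) / 2)`.
#'
#' @param params a [binding_params()]
#' @param protocol an [itc_protocol()]
#' @return tibble with one row per injection: `injection`, `volume_ul`,
#'   `molar_ratio` (ligand:macromolecule in the cell after the injection),
#'   `heat_ucal`, `first` (flag for the priming injection). The trace of cell
#'   totals and complex is attached as attribute `"trace"`, and the cumulative
#'   moles of complex formed (including displaced material) as
#'   attribute `"complex_formed_mol"`.
#' @export
itc_heats <- function(params, protocol = itc_protocol()) {
  stopifnot(inherits(params, "binding_params"),
            inherits(protocol, "itc_protocol"))
  v0 <- protocol$cell_volume
  vols <- injection_volumes(protocol)
  m <- protocol$cell_conc
  l <- 0
  c_prev <- 0
  heats <- numeric(length(vols))
  trace <- vector("list", length(vols))
  formed <- 0
  for (i in seq_along(vols)) {
    v <- vols[i]
    d <- 1 - v / v0
    m <- m * d
    l <- l * d + protocol$syringe_conc * v / v0
    sites <- params$n * m
    b <- sites + l + params$kd
    cmplx <- 2 * sites * l / (b + sqrt(pmax(b^2 - 4 * sites * l, 0)))
    dq_mol <- (cmplx - c_prev) + (v / v0) * (cmplx + c_prev) / 2
    formed <- formed + dq_mol * v0
    heats[i] <- params$dh * v0 * dq_mol * 1e6 + params$baseline
    trace[[i]] <- c(m_total = m, l_total = l, complex = cmplx)
    c_prev <- cmplx
  }
  tr <- as_tibble(do.call(rbind, trace))
  out <- tibble(
    injection = seq_along(vols),
    volume_ul = vols * 1e6,
    molar_ratio = tr$l_total / tr$m_total,
    heat_ucal = heats,
    first = seq_along(vols) == 1L
  )
  attr(out, "trace") <- tr
  attr(out, "complex_formed_mol") <- formed
  out
}
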