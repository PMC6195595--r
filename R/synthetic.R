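# Synthetic-data generators with known ground truth for every analysis
# stage. Each generator is a pure function of (seed, parameters): the RNG is
# seeded locally (no global state is touched) so re-invocation reproduces
# outputs exactly.

#' Ground-truth record attached to generated data
#'
#' @param generator generator name
#' @param seed integer seed used
#' @param parameters named list of all generating parameters
#' @return a `synthetic_truth` object
#' @export
synthetic_truth <- function(generator, seed, parameters) {
  structure(list(generator = generator, seed = seed, parameters = parameters),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %s (seed %d)\n", x$generator, x$seed))
  invisible(x)
}

#' Write/read a ground-truth sidecar in key=value form
#' @param truth a [synthetic_truth()]
#' @param path file path
#' @export
write_truth <- function(truth, path) {
  flat <- unlist(truth$parameters)
  lines <- c(paste0("generator=", truth$generator),
             paste0("seed=", truth$seed),
             paste0(names(flat), "=", vapply(flat, format, "", digits = 15)))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a fast-exchange CSP titration
#'
#' Per-residue 1H/15N trajectories across ligand:protein molar ratios under
#' the exact 1:1 depletion equilibrium: contact residues move linearly from
#' their free to their bound shifts with the fraction bound; all peaks carry
#' additive Gaussian noise. Residues in `broadened` emulate
#' intermediate-exchange broadening: once substantially bound (fraction
#' bound > 0.3) their peaks vanish and stay unobservable through the
#' endpoint, as exchange-broadened interface residues do in practice.
#'
#' Defaults reproduce the study conditions for these docking domains:
#' 100 uM protein titrated to ratios 0.25/1/2.5/5, Kd = 8 uM, and a contact
#' patch on strand beta2 and helix alpha2 of a 70-residue domain.
#'
#' @param seed integer seed
#' @param kd dissociation constant (M)
#' @param p_total protein concentration (M)
#' @param ratios ligand:protein molar ratios (the free reference, ratio 0, is
#'   always included)
#' @param n_residues length of the observed domain
#' @param contacts tibble with `residue`, `d_h`, `d_n` (bound-state shift
#'   changes, ppm); default: a beta2/alpha2-like patch
#' @param sigma_h,sigma_n Gaussian noise SDs (ppm)
#' @param broadened residues that vanish at intermediate saturation
#' @return list with `data` (titration tibble) and `truth`
#' @export
gen_csp_titration <- function(seed, kd = 8e-6, p_total = 100e-6,
                              ratios = c(0.25, 1, 2.5, 5), n_residues = 70L,
                              contacts = NULL, sigma_h = 0.005,
                              sigma_n = 0.03, broadened = integer(0)) {
  stopifnot(length(ratios) > 0)
  withr::local_preserve_seed()
  set.seed(seed)
  if (is.null(contacts)) {
    contact_res <- c(22:28, 39:43)  # beta2 strand + alpha2 face
    contacts <- tibble(
      residue = contact_res,
      d_h = runif(length(contact_res), 0.08, 0.25) *
        sample(c(-1, 1), length(contact_res), replace = TRUE),
      d_n = runif(length(contact_res), 0.4, 1.5) *
        sample(c(-1, 1), length(contact_res), replace = TRUE)
    )
  }
  free <- tibble(
    residue = seq_len(n_residues),
    h_free = runif(n_residues, 7.5, 9.5),
    n_free = runif(n_residues, 105, 130)
  ) |>
    dplyr::left_join(contacts, by = "residue") |>
    dplyr::mutate(d_h = dplyr::coalesce(.data$d_h, 0),
                  d_n = dplyr::coalesce(.data$d_n, 0))
  all_ratios <- sort(unique(c(0, ratios)))
  data <- purrr::map_dfr(all_ratios, function(r) {
    f <- if (r == 0) 0 else fraction_bound(p_total, r * p_total, kd)
    free |>
      dplyr::mutate(
        ratio = r,
        h_ppm = csp_forward(.data$h_free, .data$h_free + .data$d_h, f) +
          rnorm(dplyr::n(), 0, sigma_h),
        n_ppm = csp_forward(.data$n_free, .data$n_free + .data$d_n, f) +
          rnorm(dplyr::n(), 0, sigma_n),
        observable = !(.data$residue %in% broadened & f > 0.3)
      ) |>
      dplyr::select("residue", "ratio", "h_ppm", "n_ppm", "observable")
  })
  truth <- synthetic_truth("gen_csp_titration", seed, list(
    kd = kd, p_total = p_total, ratios = ratios, n_residues = n_residues,
    contact_residues = contacts$residue, sigma_h = sigma_h, sigma_n = sigma_n,
    broadened = broadened
  ))
  list(data = data, contacts = contacts, truth = truth)
}

#' Simulate a one-site ITC thermogram
#'
#' Forward-model heats from [itc_heats()] plus i.i.d. Gaussian noise. The
#' default protocol is the bundled docking-domain protocol (50 uM cell,
#' 1 mM syringe, 0.2 ul + 19 x 2 ul injections) and the default noise SD of
#' 0.2 ucal is a plausible small-volume-calorimeter scale (a package choice,
#' not a measured value).
#'
#' @param seed integer seed
#' @param params a [binding_params()]
#' @param protocol an [itc_protocol()]
#' @param sigma_heat Gaussian noise SD (ucal)
#' @param label thermogram label
#' @return an [itc_thermogram()] with the truth attached as attribute
#'   `"truth"`
#' @export
gen_itc_thermogram <- function(seed, params = binding_params(kd = 8e-6),
                               protocol = itc_protocol(), sigma_heat = 0.2,
                               label = "synthetic") {
  withr::local_preserve_seed()
  set.seed(seed)
  ideal <- itc_heats(params, protocol)
  heats <- ideal$heat_ucal + rnorm(nrow(ideal), 0, sigma_heat)
  out <- itc_thermogram(heats, protocol, label)
  attr(out, "truth") <- synthetic_truth("gen_itc_thermogram", seed, list(
    n = params$n, kd = params$kd, dh = params$dh, baseline = params$baseline,
    sigma_heat = sigma_heat, cell_conc = protocol$cell_conc,
    syringe_conc = protocol$syringe_conc
  ))
  out
}

#' Simulate a heteronuclear NOE profile
#'
#' Intensity pairs (saturated/reference) for residue ranges with stated true
#' NOE ratios, e.g. a rigid domain core next to a flexible linker. Reference
#' intensities are drawn uniformly and both channels carry fractional
#' Gaussian noise.
#'
#' @param seed integer seed
#' @param ranges tibble with `start`, `end`, `ratio` (true NOE ratio per
#'   residue range); ranges must not overlap
#' @param sigma_i fractional intensity noise SD
#' @return list with `data` (tibble `residue`, `i_sat`, `i_ref`) and `truth`
#' @export
gen_hetnoe_profile <- function(seed, ranges, sigma_i = 0.02) {
  stopifnot(all(c("start", "end", "ratio") %in% names(ranges)))
  res_list <- purrr::pmap(ranges, function(start, end, ratio) {
    tibble(residue = seq(start, end), true_ratio = ratio)
  })
  all_res <- dplyr::bind_rows(res_list)
  if (anyDuplicated(all_res$residue)) {
    abort("residue ranges overlap", class = "nrpsdock_value_error")
  }
  withr::local_preserve_seed()
  set.seed(seed)
  data <- all_res |>
    dplyr::mutate(
      i_ref = runif(dplyr::n(), 0.8, 1.2) * 1e5 *
        (1 + rnorm(dplyr::n(), 0, sigma_i)),
      i_sat = .data$true_ratio * .data$i_ref *
        (1 + rnorm(dplyr::n(), 0, sigma_i))
    ) |>
    dplyr::select("residue", "i_sat", "i_ref")
  truth <- synthetic_truth("gen_hetnoe_profile", seed,
                           list(ranges = ranges, sigma_i = sigma_i))
  list(data = data, ranges = all_res, truth = truth)
}

#' Systematic single-substitution peptide panel
#'
#' All single substitutions of a CDD at the given register positions, the
#' in-silico counterpart of a synthesised variant panel (for the short Kj12B
#' CDD peptide this includes the studied variants such as L1564A, R1565E,
#' G1566A and the register -1/-2 replacements).
#'
#' @param base a CDD [dd_seq()]
#' @param positions register positions to vary (subset of -5..-1)
#' @param alphabet replacement residues
#' @return list of mutated [dd_seq()] objects (empty when `positions` is
#'   empty)
#' @export
gen_peptide_panel <- function(base, positions, alphabet = AA_CODES) {
  if (length(positions) == 0) return(list())
  reg <- beta3_register(base)
  if (!all(positions %in% reg$position)) {
    abort("positions must lie within the beta3 register",
          class = "nrpsdock_value_error")
  }
  out <- list()
  for (pos in positions) {
    row <- reg[reg$position == pos, ]
    for (aa in setdiff(alphabet, row$aa)) {
      spec <- paste0(row$aa, row$residue_number, aa)
      out[[spec]] <- apply_mutations(base, spec)
    }
  }
  out
}

#' Generate decoy protein sequences for terminus scanning
#'
#' Random uniform-composition sequences, optionally with one sequence whose
#' C-terminus is replaced by a planted beta3 register (recorded in the
#' truth), or with all termini forced charge-incompatible with a given NDD
#' (same-charge partners at the electrostatic register positions, bulky -3,
#' polar -1/-5).
#'
#' @param seed integer seed
#' @param n number of sequences
#' @param length_range min/max sequence length
#' @param planted optional [beta3_register()] to plant on one sequence
#' @param incompatible_with optional [ndd_features()]; forces every terminus
#'   to be charge-incompatible with this NDD
#' @return list with `sequences` (named character vector) and `truth`
#' @export
gen_decoy_sequences <- function(seed, n, length_range = c(40L, 80L),
                                planted = NULL, incompatible_with = NULL) {
  stopifnot(n >= 1)
  withr::local_preserve_seed()
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste(sample(AA_CODES, l, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- sprintf("decoy_%02d", seq_len(n))
  planted_id <- NA_character_
  if (!is.null(incompatible_with)) {
    ndd <- incompatible_with
    same_charge <- function(aa) {
      q <- aa_charge(aa)
      if (q > 0) sample(AA_BASIC, 1)
      else if (q < 0) sample(AA_ACIDIC, 1)
      else sample(c("N", "Q", "S"), 1)
    }
    termini <- vapply(seq_len(n), function(i) {
      paste0(sample(c("N", "Q", "S"), 1),       # -5: polar, no pocket fit
             same_charge(ndd$res28),            # -4: clashes/neutral vs 28
             "W",                               # -3: bulky, steric block
             same_charge(ndd$res24),            # -2: clashes/neutral vs 24
             sample(c("N", "Q", "S"), 1))       # -1: polar, no pocket fit
    }, "")
    seqs <- vapply(seq_len(n), function(i) {
      paste0(substr(seqs[i], 1, lens[i] - 5), termini[i])
    }, "")
    names(seqs) <- sprintf("decoy_%02d", seq_len(n))
  }
  if (!is.null(planted)) {
    stopifnot(inherits(planted, "beta3_register"))
    k <- sample.int(n, 1)
    reg_str <- paste(planted$aa[order(planted$position)], collapse = "")
    seqs[k] <- paste0(substr(seqs[k], 1, lens[k] - 5), reg_str)
    names(seqs)[k] <- "planted"
    planted_id <- "planted"
  }
  truth <- synthetic_truth("gen_decoy_sequences", seed, list(
    n = n, length_range = length_range, planted_id = planted_id
  ))
  list(sequences = seqs, truth = truth)
}
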