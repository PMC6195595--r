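# Amino-acid constants shared across the package.

#' Canonical one-letter amino-acid codes
#' @keywords internal
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Monoisotopic residue masses (Da), i.e. the mass each residue contributes to a
# peptide chain (water subtracted). IUPAC/CODATA standard values.
AA_MONOISOTOPIC <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276

# Side-chain chemistry classes at the experimental pH (6.5, phosphate buffer).
AA_BASIC <- c("K", "R")             # formally positive; H optional via switch
AA_ACIDIC <- c("D", "E")            # formally negative
AA_POLAR_HBOND <- c("S", "T", "N", "Q", "Y", "H", "W")  # uncharged H-bond donors/acceptors
AA_LARGE_HYDROPHOBIC <- c("I", "L", "V", "M", "F")

#' Formal side-chain charge at pH 6.5
#'
#' Histidine is treated as neutral but hydrogen-bond capable by default; set
#' `his_charged = TRUE` to count it as protonated (+1).
#' @param aa character vector of one-letter codes
#' @param his_charged logical; treat histidine as positively charged
#' @return integer vector in \{-1, 0, +1\}
#' @keywords internal
aa_charge <- function(aa, his_charged = FALSE) {
  basic <- if (his_charged) c(AA_BASIC, "H") else AA_BASIC
  ifelse(aa %in% basic, 1L, ifelse(aa %in% AA_ACIDIC, -1L, 0L))
}

#' @keywords internal
aa_hbond_polar <- function(aa, his_charged = FALSE) {
  polar <- if (his_charged) setdiff(AA_POLAR_HBOND, "H") else AA_POLAR_HBOND
  aa %in% polar
}

check_canonical <- function(sequence, arg = "sequence") {
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters, AA_CODES)
  if (length(bad) > 0) {
    abort(
      sprintf("%s contains non-canonical letters: %s", arg,
              paste(unique(bad), collapse = ", ")),
      class = "nrpsdock_alphabet_error"
    )
  }
  invisible(letters)
}
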