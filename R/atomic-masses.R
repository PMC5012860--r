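# Atomic mass constants (versioned here; nowhere else).
#
# Average masses are the IUPAC conventional atomic weights; monoisotopic
# masses are the principal-isotope masses (AME, >= 6 decimals).

#' Atomic mass table
#'
#' Returns the immutable per-element mass table used throughout the package:
#' conventional (IUPAC) average atomic weights and monoisotopic masses of the
#' principal isotope, both in Da.
#'
#' @return A data frame with columns `element`, `average`, `monoisotopic`,
#'   one row per supported element (C, H, N, O, S, P).
#' @export
#' @examples
#' atomic_masses()
atomic_masses <- function() {
  tab <- data.frame(
    element      = c("C", "H", "N", "O", "S", "P"),
    average      = c(12.011, 1.008, 14.007, 15.999, 32.06, 30.973761998),
    monoisotopic = c(12.0, 1.0078250319, 14.0030740052, 15.9949146221,
                     31.97207069, 30.97376151),
    stringsAsFactors = FALSE
  )
  stopifnot(all(tab$monoisotopic <= tab$average | tab$element == "H"))
  tab
}

#' Monoisotopic residue masses of the twenty standard amino acids
#'
#' @return Named numeric vector of residue (dehydrated) monoisotopic masses
#'   in Da, keyed by one-letter code.
#' @keywords internal
residue_masses <- function() {
  c(G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,
    V = 99.06841,  T = 101.04768, C = 103.00919, L = 113.08406,
    I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
    K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
    F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
}

# monoisotopic mass of H2O, for peptide termini
WATER_MONO <- 18.0105646863
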