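# Residue-level lookup tables shared across modules.

#' The 20 natural amino acids (one-letter codes)
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Fauchere-Pliska side-chain hydrophobicity scale
#'
#' Octanol/water side-chain transfer free energies (pi values) from
#' Fauchere & Pliska (1983), Eur. J. Med. Chem. 18:369-375. Positive values
#' are hydrophobic. Used for the mean-hydrophobicity descriptor and, for
#' internal consistency, inside the hydrophobic moment as well.
#'
#' @return Named numeric vector over the 20 natural amino acids.
#' @export
fauchere_pliska <- function() {
  c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
    Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
    L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
    S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)
}

#' Side-chain charge rule
#'
#' K and R count +1, D and E count -1, histidine 0, termini uncharged. The
#' free-energy model was parameterized on fixed-length peptides whose
#' termini were not varied, so terminal charges are deliberately excluded;
#' override by supplying a different named vector where a protonated
#' histidine (H = +1) or other convention is needed.
#'
#' @return Named numeric vector over the 20 natural amino acids.
#' @export
charge_rules <- function() {
  z <- stats::setNames(numeric(20), amino_acids())
  z[c("K", "R")] <- 1
  z[c("D", "E")] <- -1
  z
}

# Coarse physicochemical class per residue, used for helical-wheel plotting.
residue_classes <- function() {
  cls <- stats::setNames(rep("polar", 20), amino_acids())
  cls[c("A", "C", "F", "I", "L", "M", "V", "W", "Y")] <- "hydrophobic"
  cls[c("D", "E", "K", "R")] <- "charged"
  cls
}
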