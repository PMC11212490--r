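#' Validate and normalize a peptide sequence
#'
#' Strips whitespace, uppercases, and checks that every character is one of
#' the 20 natural amino-acid one-letter codes. Ambiguity and non-natural
#' codes (B, J, O, U, X, Z) are rejected with the offending position named.
#' Direct peptide queries must be 7-24 residues long; internal callers
#' (window fragments) relax the bounds.
#'
#' @param raw Input text.
#' @param min_length,max_length Admissible length range (defaults 7 and 24,
#'   the range the sequence-to-free-energy model accepts).
#' @return The validated uppercase sequence string.
#' @examples
#' validate_sequence("gigavlkvl")
#' @export
validate_sequence <- function(raw, min_length = 7L, max_length = 24L) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw))
    stop("sequence must be a single character string", call. = FALSE)
  s <- toupper(gsub("[[:space:]]", "", raw))
  if (!nzchar(s)) stop("sequence is empty", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% amino_acids())
  if (length(bad) > 0)
    stop(sprintf("illegal residue code '%s' at position %d (allowed: %s)",
                 chars[bad[1]], bad[1], paste(amino_acids(), collapse = "")),
         call. = FALSE)
  n <- nchar(s)
  if (n < min_length || n > max_length)
    stop(sprintf("sequence length %d outside the admissible range [%d, %d]",
                 n, min_length, max_length), call. = FALSE)
  s
}

#' Net side-chain charge of a peptide
#'
#' Sum of per-residue side-chain charges: K, R = +1; D, E = -1; H = 0;
#' termini uncharged (see [charge_rules()]).
#'
#' @param sequence Validated peptide sequence.
#' @param rules Named charge vector, default [charge_rules()].
#' @return Integer net charge.
#' @export
net_charge <- function(sequence, rules = charge_rules()) {
  chars <- strsplit(sequence, "")[[1]]
  as.integer(round(sum(rules[chars])))
}

#' Mean hydrophobicity of a peptide
#'
#' Arithmetic mean of per-residue Fauchere-Pliska hydrophobicities.
#'
#' @param sequence Validated peptide sequence.
#' @param scale Named hydrophobicity vector, default [fauchere_pliska()].
#' @return Dimensionless mean hydrophobicity.
#' @export
mean_hydrophobicity <- function(sequence, scale = fauchere_pliska()) {
  chars <- strsplit(sequence, "")[[1]]
  mean(scale[chars])
}

#' Hydrophobic moment of a peptide (ideal alpha-helix)
#'
#' Magnitude of the vector sum of per-residue hydrophobicities placed at
#' 100-degree increments around an ideal alpha-helix, divided by the number
#' of residues (per-residue mean, the common web-tool convention):
#' \deqn{\mu_H = \frac{1}{N}\left| \sum_k h_k
#'   (\cos k\theta, \sin k\theta) \right|, \quad \theta = 100^\circ}
#' A large moment indicates amphipathicity: hydrophobic residues clustered
#' on one helix face.
#'
#' @param sequence Validated peptide sequence.
#' @param angle_per_residue Helical twist per residue in degrees (100 for an
#'   ideal alpha-helix).
#' @param scale Named hydrophobicity vector, default [fauchere_pliska()].
#' @param total If `TRUE` return the total magnitude instead of the
#'   per-residue mean.
#' @return Non-negative moment.
#' @export
hydrophobic_moment <- function(sequence, angle_per_residue = 100,
                               scale = fauchere_pliska(), total = FALSE) {
  chars <- strsplit(sequence, "")[[1]]
  h <- scale[chars]
  k <- seq_along(h) - 1
  theta <- k * angle_per_residue * pi / 180
  mag <- sqrt(sum(h * cos(theta))^2 + sum(h * sin(theta))^2)
  if (total) mag else mag / length(h)
}

#' Helical-wheel coordinates of a peptide
#'
#' Angular position of each residue on an ideal alpha-helix wheel
#' (100 degrees per residue, modulo 360), with the residue identity and a
#' coarse hydrophobic/charged/polar class tag for plotting.
#'
#' @param sequence Validated peptide sequence.
#' @param angle_per_residue Degrees per residue (default 100).
#' @return A data.frame with columns `position` (1-based), `residue`,
#'   `angle` (degrees in \[0, 360)), and `class`.
#' @export
helical_wheel <- function(sequence, angle_per_residue = 100) {
  chars <- strsplit(sequence, "")[[1]]
  k <- seq_along(chars) - 1
  data.frame(
    position = k + 1L,
    residue = chars,
    angle = (k * angle_per_residue) %% 360,
    class = unname(residue_classes()[chars]),
    stringsAsFactors = FALSE
  )
}

#' Read peptide sequences from a FASTA file
#'
#' One record per peptide; each sequence is validated against the peptide
#' contract (7-24 natural residues).
#'
#' @param path FASTA file path.
#' @param min_length,max_length Length bounds passed to
#'   [validate_sequence()].
#' @return Named character vector of validated sequences.
#' @export
read_peptide_fasta <- function(path, min_length = 7L, max_length = 24L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  out <- vapply(seqs, validate_sequence, character(1),
                min_length = min_length, max_length = max_length)
  stats::setNames(out, names(set))
}

#' Physicochemical descriptor set for a peptide
#'
#' Length, net charge, mean hydrophobicity and hydrophobic moment in one
#' row, matching the descriptors reported alongside free-energy
#' predictions.
#'
#' @param sequence Validated peptide sequence.
#' @return One-row data.frame with columns `sequence`, `length`, `charge`,
#'   `mean_hydrophobicity`, `hydrophobic_moment`.
#' @export
peptide_descriptors <- function(sequence) {
  data.frame(
    sequence = sequence,
    length = nchar(sequence),
    charge = net_charge(sequence),
    mean_hydrophobicity = mean_hydrophobicity(sequence),
    hydrophobic_moment = hydrophobic_moment(sequence),
    stringsAsFactors = FALSE
  )
}
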