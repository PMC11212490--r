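# Residue tokens are 1..20 in amino_acids() order; the padding token is 21.

PAD_TOKEN <- 21L

#' Tokenize a peptide sequence to a fixed-length integer vector
#'
#' Residues map to integers 1-20 (alphabetical one-letter order); sequences
#' shorter than `max_length` are right-padded with the padding token (21).
#'
#' @param sequence Validated peptide sequence of length <= `max_length`.
#' @param max_length Fixed output length (default 24).
#' @return Integer vector of length `max_length`.
#' @export
tokenize <- function(sequence, max_length = 24L) {
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) > max_length)
    stop(sprintf("sequence length %d exceeds the maximum of %d",
                 length(chars), max_length), call. = FALSE)
  idx <- match(chars, amino_acids())
  if (anyNA(idx))
    stop("sequence contains non-natural residues; validate first", call. = FALSE)
  c(idx, rep(PAD_TOKEN, max_length - length(idx)))
}

#' Recover the sequence from a token vector
#'
#' Inverse of [tokenize()] on the residue portion; padding is dropped.
#'
#' @param tokens Integer token vector.
#' @return Peptide sequence string.
#' @export
detokenize <- function(tokens) {
  tokens <- tokens[tokens != PAD_TOKEN]
  if (any(tokens < 1 | tokens > 20))
    stop("invalid token outside 1..20", call. = FALSE)
  paste(amino_acids()[tokens], collapse = "")
}
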