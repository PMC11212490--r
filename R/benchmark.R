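#' Split a sequence into consecutive non-overlapping fragments
#'
#' Consecutive fragments of `size` residues; a trailing remainder shorter
#' than `size` is dropped (with a message naming how many residues).
#'
#' @param x A sequence string or an integer sequence length.
#' @param size Fragment size in residues (default 15, the screening window
#'   default).
#' @return A data.frame with columns `start`, `end` (1-based inclusive).
#' @export
fragment_sequence <- function(x, size = 15L) {
  stopifnot(size >= 1)
  size <- as.integer(size)
  L <- if (is.character(x)) nchar(x) else as.integer(x)
  n <- L %/% size
  if (n == 0) {
    warning(sprintf("sequence of length %d yields no fragment of size %d",
                    L, size), call. = FALSE)
    return(data.frame(start = integer(), end = integer()))
  }
  if (L %% size != 0)
    message(sprintf("trailing %d residue(s) dropped (not a full fragment)",
                    L %% size))
  starts <- (seq_len(n) - 1L) * size + 1L
  data.frame(start = starts, end = starts + size - 1L)
}

#' Label fragments positive/negative from per-residue hit flags
#'
#' A fragment is positive when it contains at least `min_hits` flagged
#' residues, negative otherwise. The default `min_hits = 1` resolves the
#' boundary case of a single hit as positive; set `min_hits = 2` for the
#' stricter reading.
#'
#' @param flags Logical vector of per-residue hits, aligned to the sequence
#'   the fragments were cut from.
#' @param fragments Data.frame from [fragment_sequence()].
#' @param min_hits Minimum flagged residues for a positive call (>= 1).
#' @return Logical vector, one element per fragment.
#' @export
label_fragments <- function(flags, fragments, min_hits = 1L) {
  stopifnot(is.logical(flags), min_hits >= 1)
  if (nrow(fragments) > 0 && max(fragments$end) > length(flags))
    stop("fragment positions extend beyond the flag vector (misaligned lengths)",
         call. = FALSE)
  vapply(seq_len(nrow(fragments)), function(k) {
    sum(flags[fragments$start[k]:fragments$end[k]], na.rm = TRUE) >= min_hits
  }, logical(1))
}

#' Confusion-matrix summary with MCC, FDR and FOR
#'
#' Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' false discovery rate \eqn{FP/(FP+TP)} and false omission rate
#' \eqn{FN/(FN+TN)}. Degenerate denominators (any zero factor) yield 0
#' together with a `degenerate` flag naming the statistic.
#'
#' @param predicted Logical vector of predicted positives.
#' @param reference Logical vector of reference positives, same length
#'   (>= 1).
#' @return An object of class `confusion_summary`: list with `tp`, `fp`,
#'   `tn`, `fn`, `mcc`, `fdr`, `for_`, and `degenerate` (character vector,
#'   possibly empty).
#' @export
confusion_stats <- function(predicted, reference) {
  stopifnot(is.logical(predicted), is.logical(reference))
  if (length(predicted) == 0)
    stop("no fragments to score", call. = FALSE)
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length", call. = FALSE)
  tp <- sum(predicted & reference)
  fp <- sum(predicted & !reference)
  tn <- sum(!predicted & !reference)
  fn <- sum(!predicted & reference)
  degenerate <- character()
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    mcc <- 0
    degenerate <- c(degenerate, "mcc")
  } else {
    mcc <- (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  }
  if (fp + tp == 0) {
    fdr <- 0; degenerate <- c(degenerate, "fdr")
  } else fdr <- fp / (fp + tp)
  if (fn + tn == 0) {
    for_ <- 0; degenerate <- c(degenerate, "for")
  } else for_ <- fn / (fn + tn)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 mcc = mcc, fdr = fdr, for_ = for_, degenerate = degenerate),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("MCC %.3f  FDR %.3f  FOR %.3f\n", x$mcc, x$fdr, x$for_))
  if (length(x$degenerate) > 0)
    cat("degenerate denominator(s):", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Read reference membrane-interaction regions
#'
#' Delimited text (tab- or comma-separated, header required) with columns
#' `chain`, `start`, `end` giving author residue-number ranges of known
#' membrane-interaction regions.
#'
#' @param path File path.
#' @return A data.frame with columns `chain`, `start`, `end`.
#' @export
read_reference_regions <- function(path) {
  if (!file.exists(path)) stop("reference-region file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("chain", "start", "end")
  if (!all(need %in% names(d)))
    stop("reference regions must have columns chain, start, end", call. = FALSE)
  d$chain <- as.character(d$chain)
  if (any(d$end < d$start)) stop("region with end < start", call. = FALSE)
  d[, need]
}

#' Segment-based benchmark of a structure screen against reference regions
#'
#' Cuts each chain's screened residue series into consecutive fragments,
#' marks a fragment predicted-positive when it contains at least
#' `min_hits` residues labelled as membrane-interacting (sensor or binder
#' by default; binder-only with `include_sensors = FALSE`), marks it
#' reference-positive when it overlaps a known membrane-interaction region
#' by at least `min_hits` residues, and summarizes agreement as MCC, FDR
#' and FOR.
#'
#' @param residues The `residues` table of a `screen_result` (or a
#'   compatible data.frame with columns `chain`, `resno`, `label`).
#' @param regions Reference regions data.frame (see
#'   [read_reference_regions()]).
#' @param fragment_size Fragment size in residues (default 15).
#' @param min_hits Minimum hit residues for a positive fragment (default 1).
#' @param include_sensors Count sensor residues as predicted hits
#'   (default `TRUE`).
#' @return A list with the `confusion_summary` (`summary`) and the
#'   per-fragment table (`fragments`).
#' @export
benchmark_screen <- function(residues, regions, fragment_size = 15L,
                             min_hits = 1L, include_sensors = TRUE) {
  if (inherits(residues, "screen_result")) residues <- residues$residues
  stopifnot(all(c("chain", "resno", "label") %in% names(residues)))
  pos_labels <- if (include_sensors) c("sensor", "binder") else "binder"
  frag_rows <- list()
  for (ch in unique(residues$chain)) {
    sub <- residues[residues$chain == ch, , drop = FALSE]
    sub <- sub[order(sub$resno), , drop = FALSE]
    pred_flags <- as.character(sub$label) %in% pos_labels
    reg <- regions[regions$chain == ch, , drop = FALSE]
    ref_flags <- rep(FALSE, nrow(sub))
    for (k in seq_len(nrow(reg)))
      ref_flags <- ref_flags | (sub$resno >= reg$start[k] &
                                  sub$resno <= reg$end[k])
    fr <- fragment_sequence(nrow(sub), fragment_size)
    if (nrow(fr) == 0) next
    frag_rows[[length(frag_rows) + 1L]] <- data.frame(
      chain = ch,
      resno_start = sub$resno[fr$start], resno_end = sub$resno[fr$end],
      predicted = label_fragments(pred_flags, fr, min_hits),
      reference = label_fragments(ref_flags, fr, min_hits),
      stringsAsFactors = FALSE)
  }
  if (length(frag_rows) == 0)
    stop("no chain long enough to fragment", call. = FALSE)
  fragments <- do.call(rbind, frag_rows)
  list(summary = confusion_stats(fragments$predicted, fragments$reference),
       fragments = fragments)
}
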