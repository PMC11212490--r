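#' Configuration for structure screening
#'
#' @param window Sliding-window size in residues, 7-24 (default 15, a
#'   typical secondary-structure element length).
#' @param sasa_threshold Smoothed per-residue SASA (nm^2) above which a
#'   residue counts as solvent-exposed (default 0.8).
#' @param smoothing_half_width Half-width of the SASA smoothing window
#'   (default 4, i.e. the 9-residue vicinity n-4..n+4).
#' @param membrane Target membrane: `"neutral"` (no charge correction) or
#'   `"anionic"` (per-window charge correction applied).
#' @param probe_radius SASA probe radius in Angstrom (default 1.4).
#' @param sphere_points Shrake-Rupley test points per atom (default 960).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(window = 15L, sasa_threshold = 0.8,
                          smoothing_half_width = 4L,
                          membrane = c("neutral", "anionic"),
                          probe_radius = 1.4, sphere_points = 960L) {
  membrane <- match.arg(membrane)
  if (window < 7 || window > 24)
    stop("window must be between 7 and 24 residues", call. = FALSE)
  if (sasa_threshold < 0) stop("sasa_threshold must be >= 0", call. = FALSE)
  if (smoothing_half_width < 0)
    stop("smoothing_half_width must be >= 0", call. = FALSE)
  structure(list(window = as.integer(window), sasa_threshold = sasa_threshold,
                 smoothing_half_width = as.integer(smoothing_half_width),
                 membrane = membrane, probe_radius = probe_radius,
                 sphere_points = as.integer(sphere_points)),
            class = "screen_config")
}

#' Sliding windows over a fragment sequence
#'
#' All `L - w + 1` consecutive windows of size `w` (stride 1). A fragment
#' shorter than the window but at least 7 residues long is scored as a
#' single segment of its own length; fragments below the 7-residue
#' predictor minimum are skipped with a warning.
#'
#' @param sequence Fragment sequence (one-letter codes).
#' @param window Window size.
#' @return A data.frame with columns `start`, `end` (1-based inclusive
#'   positions in the fragment) and `sequence`; zero rows if skipped.
#' @export
sliding_segments <- function(sequence, window) {
  window <- as.integer(window)
  L <- nchar(sequence)
  if (L < 7) {
    warning(sprintf("fragment of length %d is below the 7-residue minimum; skipped",
                    L), call. = FALSE)
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  if (L < window) {
    message(sprintf("fragment of length %d is shorter than the window (%d); %s",
                    L, window, "scored as a single segment of its own length"))
    return(data.frame(start = 1L, end = L, sequence = sequence,
                      stringsAsFactors = FALSE))
  }
  starts <- seq_len(L - window + 1L)
  data.frame(start = starts, end = starts + window - 1L,
             sequence = substring(sequence, starts, starts + window - 1L),
             stringsAsFactors = FALSE)
}

#' Average overlapping segment scores onto residues
#'
#' Residue n receives the unweighted mean of the effective free energies of
#' all segments covering it; interior residues are covered by up to
#' min(window, L - window + 1) segments, termini by fewer (terminal values
#' are therefore averaged over fewer windows and less precise).
#'
#' @param segments A data.frame with columns `start`, `end` and a score
#'   column named by `score_col`.
#' @param length Fragment length L.
#' @param score_col Which column to average (default `"ddf_eff"`).
#' @return Numeric vector of length L with per-residue mean scores.
#' @export
per_residue_score <- function(segments, length, score_col = "ddf_eff") {
  stopifnot(all(c("start", "end", score_col) %in% names(segments)))
  total <- numeric(length)
  count <- integer(length)
  for (k in seq_len(nrow(segments))) {
    idx <- segments$start[k]:segments$end[k]
    total[idx] <- total[idx] + segments[[score_col]][k]
    count[idx] <- count[idx] + 1L
  }
  out <- rep(NA_real_, length)
  out[count > 0] <- total[count > 0] / count[count > 0]
  out
}

#' Screen a protein structure for membrane-interaction regions
#'
#' The full screening pipeline: extract chain sequences, score every
#' sliding window with the sequence predictor, extrapolate each window
#' score to the 24-residue reference length (and apply the per-window
#' charge correction when the target membrane is anionic), average
#' overlapping windows onto residues, compute and smooth per-residue SASA,
#' and classify each residue — gated by solvent exposure. The
#' classification thresholds act on the length-extrapolated (and
#' charge-adjusted) free energy, never on the raw window score.
#'
#' @param structure A structure file path or a `bio3d` pdb object from
#'   [read_structure()].
#' @param config A [screen_config()].
#' @param predictor A predictor accepted by [predict_ddf()].
#' @param constants A [pmi_constants()] object.
#' @return An object of class `screen_result`: list with `residues` (one
#'   row per screened residue: chain, author residue number, residue code,
#'   per-residue free energy, raw and smoothed SASA, exposure, label, and
#'   the output B-factor 0.0/0.5/1.0) and `segments` (one row per scored
#'   window with its free energies and class), plus the config used.
#' @export
annotate_structure <- function(structure, config = screen_config(),
                               predictor, constants = pmi_constants()) {
  pdb <- if (is.character(structure)) read_structure(structure) else structure
  frags <- extract_chain_sequences(pdb)
  sasa <- compute_sasa(pdb, probe_radius = config$probe_radius,
                       sphere_points = config$sphere_points)
  sasa_key <- paste(sasa$chain, sasa$resno, sep = "|")
  res_rows <- list()
  seg_rows <- list()
  for (fi in seq_along(frags)) {
    fr <- frags[[fi]]
    L <- nchar(fr$sequence)
    segs <- sliding_segments(fr$sequence, config$window)
    if (nrow(segs) == 0) next
    segs$ddf <- predict_ddf(predictor, segs$sequence)
    seg_len <- nchar(segs$sequence)
    ddf24 <- length_extrapolate(segs$ddf, seg_len, constants)
    if (config$membrane == "anionic") {
      z <- vapply(segs$sequence, net_charge, integer(1), USE.NAMES = FALSE)
      segs$ddf_eff <- charge_adjust(ddf24, z, constants)
    } else {
      segs$ddf_eff <- ddf24
    }
    segs$label <- classify_ddf(segs$ddf_eff, constants)
    per_res <- per_residue_score(segs, L)
    raw <- sasa$sasa[match(paste(fr$chain, fr$resno, sep = "|"), sasa_key)]
    smoothed <- smooth_sasa(raw, config$smoothing_half_width)
    exposed <- !is.na(smoothed) & smoothed >= config$sasa_threshold
    cls <- as.character(classify_ddf(per_res, constants))
    label <- ifelse(exposed, cls, "not accessible")
    bfac <- ifelse(!exposed | cls == "non-binder", 0,
                   ifelse(cls == "sensor", 0.5, 1))
    res_rows[[length(res_rows) + 1L]] <- data.frame(
      chain = fr$chain, resno = fr$resno,
      residue = strsplit(fr$sequence, "")[[1]],
      fragment = fi, position = seq_len(L),
      ddf = per_res, sasa_raw = raw, sasa_smoothed = smoothed,
      exposed = exposed,
      label = factor(label, levels = c("non-binder", "sensor", "binder",
                                       "not accessible")),
      bfactor = bfac, stringsAsFactors = FALSE)
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      chain = fr$chain, fragment = fi,
      start = segs$start, end = segs$end,
      resno_start = fr$resno[segs$start], resno_end = fr$resno[segs$end],
      sequence = segs$sequence, ddf = segs$ddf, ddf_eff = segs$ddf_eff,
      label = segs$label, stringsAsFactors = FALSE)
  }
  if (length(res_rows) == 0)
    stop("no fragment long enough to screen (all below 7 residues)",
         call. = FALSE)
  structure(list(residues = do.call(rbind, res_rows),
                 segments = do.call(rbind, seg_rows),
                 config = config),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  tab <- table(x$residues$label)
  cat(sprintf("Structure screen: %d residues in %d fragment(s), window = %d, membrane = %s\n",
              nrow(x$residues), length(unique(x$residues$fragment)),
              x$config$window, x$config$membrane))
  cat(sprintf("  %-15s %d\n", names(tab), as.integer(tab)), sep = "")
  invisible(x)
}

#' Write an annotated PDB with class-coded B-factors
#'
#' Replaces the B-factor column (columns 61-66) of every ATOM/HETATM record
#' with the residue's class code — 0.00 for non-binding or inaccessible
#' residues, 0.50 for exposed sensors, 1.00 for exposed binders — so any
#' molecular viewer can colour the structure by predicted activity. All
#' other columns of a PDB input are preserved byte-for-byte; mmCIF inputs
#' are re-emitted as PDB.
#'
#' @param structure_path Path to the original structure file.
#' @param annotations A `screen_result` or its `residues` data.frame.
#' @param path Output PDB path.
#' @return The output path, invisibly.
#' @export
write_annotated_pdb <- function(structure_path, annotations, path) {
  res <- if (inherits(annotations, "screen_result")) annotations$residues
         else annotations
  stopifnot(all(c("chain", "resno", "bfactor") %in% names(res)))
  bmap <- stats::setNames(res$bfactor, paste(res$chain, res$resno, sep = "|"))
  ext <- tolower(tools::file_ext(structure_path))
  if (!ext %in% c("pdb", "ent")) {
    pdb <- read_structure(structure_path)
    key <- paste(pdb$atom$chain, pdb$atom$resno, sep = "|")
    b <- unname(bmap[key]); b[is.na(b)] <- 0
    bio3d::write.pdb(pdb, file = path, b = b)
    return(invisible(path))
  }
  lines <- readLines(structure_path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (any(is_atom)) {
    al <- lines[is_atom]
    al <- formatC(al, width = -80)  # pad short lines to full record width
    key <- paste(trimws(substr(al, 22, 22)),
                 as.integer(substr(al, 23, 26)), sep = "|")
    b <- unname(bmap[key]); b[is.na(b)] <- 0
    substr(al, 61, 66) <- sprintf("%6.2f", b)
    lines[is_atom] <- al
  }
  out <- tryCatch(writeLines(lines, path),
                  error = function(e) stop("cannot write annotated PDB to ",
                                           path, ": ", conditionMessage(e),
                                           call. = FALSE))
  invisible(path)
}
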