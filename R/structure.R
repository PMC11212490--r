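#' Read a protein structure from a PDB or mmCIF file
#'
#' Dispatches on the file extension: `.pdb`/`.ent` are parsed as fixed-width
#' PDB, `.cif`/`.mmcif` as mmCIF.
#'
#' @param path Structure file path.
#' @return A `bio3d` pdb object with an added `file` attribute recording
#'   the source path and format.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    switch(ext,
           pdb = , ent = bio3d::read.pdb(path, verbose = FALSE),
           cif = , mmcif = bio3d::read.cif(path, verbose = FALSE),
           stop("unrecognized structure format '.", ext,
                "' (expected .pdb or .cif)", call. = FALSE)),
    error = function(e) stop("failed to parse structure file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  attr(pdb, "source_file") <- normalizePath(path)
  attr(pdb, "source_format") <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  pdb
}

# Parent mapping for common modified residues beyond what the three-to-one
# table handles; anything still unknown splits the chain at that point.
MODRES_PARENT <- c(MSE = "M", SEC = "C", CSO = "C", CME = "C", OCS = "C",
                   SEP = "S", TPO = "T", PTR = "Y", MLY = "K", KCX = "K",
                   HYP = "P", PCA = "Q", FME = "M", MLE = "L")

#' Extract per-chain one-letter sequences from a structure
#'
#' Walks the polymer (ATOM) residues of each chain in author order and
#' returns contiguous fragments. A fragment is broken at: (i) a gap in the
#' author residue numbering (missing residues cannot be scored as part of a
#' continuous window), and (ii) a residue that cannot be mapped to a
#' standard parent amino acid. Common modified residues (MSE, SEP, PTR,
#' ...) are mapped to their parents.
#'
#' @param pdb A `bio3d` pdb object from [read_structure()].
#' @return A list of fragments; each is a list with elements `chain`,
#'   `sequence` (one-letter string), and `resno` (integer author residue
#'   numbers, one per residue).
#' @export
extract_chain_sequences <- function(pdb) {
  atoms <- pdb$atom
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  # drop altLoc duplicates: keep first CA per (chain, resno)
  key <- paste(ca$chain, ca$resno, sep = "|")
  ca <- ca[!duplicated(key), , drop = FALSE]
  if (nrow(ca) == 0)
    stop("structure contains no polymer (protein) chains", call. = FALSE)
  frags <- list()
  for (ch in unique(ca$chain)) {
    sub <- ca[ca$chain == ch, , drop = FALSE]
    sub <- sub[order(sub$resno), , drop = FALSE]
    one <- suppressWarnings(bio3d::aa321(sub$resid))
    unk <- one == "X" | is.na(one)
    mapped <- MODRES_PARENT[sub$resid[unk]]
    one[unk][!is.na(mapped)] <- mapped[!is.na(mapped)]
    bad <- one == "X" | is.na(one)
    # fragment break before any residue with a numbering gap or unmappable id
    gap <- c(FALSE, diff(sub$resno) != 1L)
    frag_id <- cumsum(gap | bad | c(FALSE, bad[-length(bad)]))
    for (f in unique(frag_id)) {
      sel <- frag_id == f & !bad
      if (!any(sel)) next
      frags[[length(frags) + 1L]] <- list(
        chain = ch,
        sequence = paste(one[sel], collapse = ""),
        resno = sub$resno[sel]
      )
    }
  }
  if (length(frags) == 0)
    stop("no mappable polymer residues found in structure", call. = FALSE)
  frags
}
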