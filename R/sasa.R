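#' Van der Waals radii by element
#'
#' Bondi (1964, J. Phys. Chem. 68:441) radii in Angstrom for the elements
#' common in protein structures; unknown elements fall back to 1.70 (carbon).
#'
#' @return Named numeric vector (Angstrom).
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    ZN = 1.39, MG = 1.73, FE = 1.70, MN = 1.73, CU = 1.40, CA = 2.31,
    `NA` = 2.27, K = 2.75)
}

# Quasi-uniform points on the unit sphere (Fibonacci / golden-spiral
# lattice), the test-sphere construction of the Shrake-Rupley algorithm.
sphere_lattice <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, a quasi-uniform lattice of test points is placed on the
#' sphere of radius (vdW + probe); the accessible fraction is the share of
#' points not occluded by any neighbouring atom's expanded sphere, and the
#' atom's SASA is that fraction times the sphere area.
#'
#' @param xyz n x 3 matrix of atom coordinates (Angstrom).
#' @param radii Per-atom van der Waals radii (Angstrom), length n.
#' @param probe_radius Probe sphere radius (Angstrom, default 1.4 — a water
#'   molecule).
#' @param sphere_points Number of test points per atom (default 960).
#' @return Numeric vector of per-atom SASA in Angstrom^2.
#' @export
sasa_atoms <- function(xyz, radii, probe_radius = 1.4, sphere_points = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(ncol(xyz) == 3, length(radii) == n, probe_radius >= 0,
            sphere_points >= 12)
  pts <- sphere_lattice(sphere_points)
  r_exp <- radii + probe_radius
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- r_exp[i]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ri + r_exp)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, sphere_points)
    # nearest occluders first: buried points are culled early
    nb <- nb[order(d2[nb])]
    for (j in nb) {
      rj2 <- r_exp[j]^2
      idx <- which(free)
      if (length(idx) == 0) break
      dd <- (p[idx, 1] - xyz[j, 1])^2 + (p[idx, 2] - xyz[j, 2])^2 +
        (p[idx, 3] - xyz[j, 3])^2
      free[idx[dd < rj2]] <- FALSE
    }
    out[i] <- 4 * pi * ri^2 * sum(free) / sphere_points
  }
  out
}

#' Per-residue solvent-accessible surface area of a structure
#'
#' Computes Shrake-Rupley SASA over all heavy atoms of the assembly
#' (hydrogens are ignored; waters are excluded; other hetero atoms and
#' ligands are excluded from the reported residues but, by default, kept as
#' occluders since they genuinely bury protein surface) and sums atom
#' values per protein residue. Values are reported in nm^2 (1 nm^2 =
#' 100 Angstrom^2), the unit of the exposure threshold.
#'
#' @param pdb A `bio3d` pdb object (from [read_structure()]).
#' @param probe_radius Probe radius in Angstrom (default 1.4).
#' @param sphere_points Test points per atom (default 960).
#' @param radii Named element radii table, default [vdw_radii()].
#' @param hetero_occluders Keep non-water hetero atoms as occluders
#'   (default `TRUE`).
#' @return A data.frame with columns `chain`, `resno`, `sasa` (nm^2).
#' @export
compute_sasa <- function(pdb, probe_radius = 1.4, sphere_points = 960L,
                         radii = vdw_radii(), hetero_occluders = TRUE) {
  atoms <- pdb$atom
  elem <- toupper(trimws(atoms$elesy))
  miss <- is.na(elem) | !nzchar(elem)
  elem[miss] <- toupper(substr(trimws(atoms$elety[miss]), 1, 1))
  keep <- elem != "H" & !(atoms$resid %in% c("HOH", "WAT", "DOD"))
  if (!hetero_occluders) keep <- keep & atoms$type == "ATOM"
  atoms <- atoms[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(atoms) == 0) stop("no heavy atoms found in structure", call. = FALSE)
  r <- unname(radii[elem])
  r[is.na(r)] <- 1.70
  a_sasa <- sasa_atoms(cbind(atoms$x, atoms$y, atoms$z), r,
                       probe_radius = probe_radius,
                       sphere_points = sphere_points)
  prot <- atoms$type == "ATOM"
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  agg <- rowsum(a_sasa[prot], key[prot])
  parts <- strsplit(rownames(agg), "|", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, character(1), 1),
    resno = as.integer(vapply(parts, `[`, character(1), 2)),
    sasa = as.vector(agg) / 100,
    stringsAsFactors = FALSE
  )
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Smooth per-residue SASA over the local sequence vicinity
#'
#' Each residue receives the mean SASA of the window n-h .. n+h along its
#' fragment (default h = 4, the 9-residue vicinity), truncated at the
#' fragment ends; missing values are excluded from the mean. Smoothing
#' reflects that membrane insertion is a property of a local stretch, not
#' of a single side chain.
#'
#' @param sasa Numeric vector of per-residue SASA for one contiguous
#'   fragment (NA allowed).
#' @param half_width Half-width h of the smoothing window (default 4).
#' @return Numeric vector of smoothed SASA, same length.
#' @export
smooth_sasa <- function(sasa, half_width = 4L) {
  stopifnot(half_width >= 0)
  n <- length(sasa)
  vapply(seq_len(n), function(i) {
    w <- sasa[max(1, i - half_width):min(n, i + half_width)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}
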