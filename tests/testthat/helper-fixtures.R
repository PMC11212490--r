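# Programmatic fixtures: no binary or stored structure files — everything
# is generated in code at test time.

# One-letter -> three-letter residue names for fixture PDB writing.
aa3_table <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
               G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
               M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
               S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

# Ideal alpha-helix CA trace: 100 degrees twist and 1.5 A rise per residue,
# 2.3 A helix radius.
helix_ca_coords <- function(n, origin = c(0, 0, 0)) {
  k <- seq_len(n) - 1
  theta <- k * 100 * pi / 180
  cbind(2.3 * cos(theta) + origin[1],
        2.3 * sin(theta) + origin[2],
        1.5 * k + origin[3])
}

pdb_atom_line <- function(serial, atom, res3, chain, resno, xyz,
                          b = 0, element = "C") {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", atom), res3, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.00, b, element)
}

# Write a CA-only PDB for the given sequence(s). `chains` is a named list:
# chain id -> list(sequence=, resno= (optional; default 1..n), origin=).
write_fixture_pdb <- function(chains, path) {
  lines <- character()
  serial <- 0L
  for (ch in names(chains)) {
    spec <- chains[[ch]]
    seqchars <- strsplit(spec$sequence, "")[[1]]
    n <- length(seqchars)
    resno <- if (!is.null(spec$resno)) spec$resno else seq_len(n)
    origin <- if (!is.null(spec$origin)) spec$origin else c(0, 0, 0)
    xyz <- helix_ca_coords(n, origin)
    for (i in seq_len(n)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, "CA", aa3_table[seqchars[i]],
                                      ch, resno[i], xyz[i, ]))
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %s%4d", serial + 1L,
                              aa3_table[seqchars[n]], ch, resno[n]))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Independent Monte-Carlo SASA oracle: uniform random points on each
# atom's expanded sphere, accessibility checked against all other spheres.
mc_sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 1e5,
                          seed = 1) {
  set.seed(seed)
  n <- nrow(xyz)
  r_exp <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    z <- stats::runif(n_points, -1, 1)
    phi <- stats::runif(n_points, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    p <- cbind(s * cos(phi), s * sin(phi), z) * r_exp[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= r_exp[j]^2
    }
    out[i] <- 4 * pi * r_exp[i]^2 * mean(free)
  }
  out
}

# Small deterministic dataset for quick model tests.
tiny_dataset <- function(n = 60, seed = 5, noise_sd = 0) {
  generate_peptide_dataset(synthetic_spec(n_examples = n, seed = seed,
                                          noise_sd = noise_sd))
}
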