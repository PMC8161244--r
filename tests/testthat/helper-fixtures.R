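# Small in-code fixtures shared across test files.

# PDB text for a minimal system: protein residues at given CA positions,
# plus optional water oxygens and lipid atoms
fixture_pdb_lines <- function(ca, waters = NULL, lipids = NULL,
                              resnames = NULL) {
  n <- nrow(ca)
  if (is.null(resnames)) resnames <- rep("GLY", n)
  fmt <- function(serial, name, res, chain, seq, p, elem, het = FALSE)
    sprintf("%-6s%5d  %-3s %-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            if (het) "HETATM" else "ATOM", serial, name, res, chain, seq,
            p[1], p[2], p[3], elem)
  lines <- character()
  s <- 0L
  for (i in seq_len(n)) {
    s <- s + 1L
    lines <- c(lines, fmt(s, "CA", resnames[i], "A", i, ca[i, ], "C"))
  }
  seqn <- n
  if (!is.null(waters)) for (i in seq_len(nrow(waters))) {
    s <- s + 1L; seqn <- seqn + 1L
    lines <- c(lines, fmt(s, "OH2", "TIP3", "W", seqn, waters[i, ], "O", TRUE))
  }
  if (!is.null(lipids)) for (i in seq_len(nrow(lipids))) {
    s <- s + 1L; seqn <- seqn + 1L
    lines <- c(lines, fmt(s, "C2", "POPC", "L", seqn, lipids[i, ], "C", TRUE))
  }
  c(lines, "END")
}

write_fixture_pdb <- function(ca, ..., file = tempfile(fileext = ".pdb")) {
  writeLines(fixture_pdb_lines(ca, ...), file)
  file
}

# two-residue, single-atom-per-residue topology at a given separation
two_residue_top <- function(d) {
  path <- write_fixture_pdb(rbind(c(0, 0, 0), c(d, 0, 0)))
  list(top = load_topology(path), coords = rbind(c(0, 0, 0), c(d, 0, 0)))
}

# ideal straight helix CA trace along z
ideal_helix <- function(m, rise = 1.5, twist_deg = 100, radius = 2.3) {
  i <- seq_len(m) - 1
  th <- i * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * i)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# archetype matrix with unit diagonal and a set of disjoint contact pairs
# (1-based pairs), realizable as toy geometry
matching_archetype <- function(R, pairs) {
  A <- diag(1L, R)
  for (p in pairs) {
    A[p[1], p[2]] <- 1L
    A[p[2], p[1]] <- 1L
  }
  A
}

# deterministic two-state matching series for toy-trajectory tests
toy_matching_series <- function(R = 10, n = 6, seed = 7) {
  arch <- list(matching_archetype(R, list(c(1, 4), c(6, 9))),
               matching_archetype(R, list(c(2, 8))))
  generate_contact_series(R = R, n = n, archetypes = arch,
                          transition_frames = floor(n / 2),
                          flip_noise_rate = 0, ramp_frames = 0, seed = seed)
}
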