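# Shared fixtures, all built in code.

# a minimal PDB text: `residues` rows of (resname, chain, resno) each with
# the given atom names; coordinates supplied per atom
write_fixture_pdb <- function(path, residues, coords, atom_names = NULL,
                              elements = NULL) {
  lines <- character(0)
  serial <- 0
  for (r in seq_len(nrow(residues))) {
    nms <- atom_names[[r]]
    for (a in seq_along(nms)) {
      serial <- serial + 1
      xyz <- coords[[r]][a, ]
      el <- if (is.null(elements)) substr(nms[a], 1, 1) else elements[[r]][a]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, nms[a], residues$resname[r], residues$chain[r],
        residues$resno[r], xyz[1], xyz[2], xyz[3], el))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# 3 residues x 5 atoms on a non-clashing grid
fixture_pdb_3x5 <- function(path = tempfile(fileext = ".pdb")) {
  residues <- data.frame(resname = c("ALA", "GLY", "ALA"),
                         chain = "A", resno = 1:3)
  atom_names <- rep(list(c("N", "CA", "C", "O", "CB")), 3)
  coords <- lapply(1:3, function(r) {
    base <- c((r - 1) * 6, 0, 0)
    rbind(base, base + c(1.4, 0.4, 0), base + c(2.4, -0.4, 0.4),
          base + c(2.6, -1.5, 0.6), base + c(1.5, 1.6, 0.8))
  })
  write_fixture_pdb(path, residues, coords, atom_names)
}

# two bonded beads in a square-well: simplest conservative system
two_bead_system <- function(d = 3.8) {
  atoms <- tibble::tibble(name = "CA", element = "C", charge = 0, mass = 10,
                          resname = "GLY", chain = "A", resno = 1:2,
                          x = c(0, d), y = 0, z = 0)
  molecular_system(atoms, rbind(c(1, 2)))
}

two_bead_table <- function(system, tol = 0.1) {
  d <- sqrt(sum((system_coords(system)[1, ] - system_coords(system)[2, ])^2))
  interaction_table(
    constraints = tibble::tibble(i = 1L, j = 2L, rmin = d * (1 - tol),
                                 rmax = d * (1 + tol), type = "bond"))
}

# n free beads with pure hard-sphere interactions in a loose bonded ring
free_bead_system <- function(n = 4, spacing = 6) {
  atoms <- tibble::tibble(name = "CA", element = "C", charge = 0, mass = 10,
                          resname = "GLY", chain = "A", resno = seq_len(n),
                          x = (seq_len(n) - 1) * spacing, y = 0, z = 0)
  molecular_system(atoms, cbind(seq_len(n - 1), 2:n))
}

# an 8-bead printed toy with hand-checkable native contacts
printed_8bead <- function() {
  coords <- rbind(
    c(0.0, 0.0, 0.0), c(3.8, 0.0, 0.0), c(7.0, 2.0, 0.0), c(7.0, 5.8, 0.2),
    c(3.6, 7.2, 0.3), c(0.2, 6.0, 0.1), c(-1.5, 2.8, 0.0), c(2.0, 3.4, 1.8))
  atoms <- tibble::tibble(name = "CA", element = "C", charge = 0, mass = 10,
                          resname = "GLY", chain = "A", resno = 1:8,
                          x = coords[, 1], y = coords[, 2], z = coords[, 3])
  molecular_system(atoms, cbind(1:7, 2:8))
}

# brute-force native-contact count at a cutoff (|i-j| >= 3)
count_contacts_brute <- function(system, cutoff) {
  coords <- system_coords(system)
  n <- nrow(coords)
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) < 3) next
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) cnt <- cnt + 1
  }
  cnt
}
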