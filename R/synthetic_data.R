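#' Analytic two-level system with exact thermodynamics
#'
#' A ground level at `E0` with degeneracy `g0` and an excited level at
#' `E1` with degeneracy `g1`. Its partition function, mean energy and
#' specific heat have closed forms, which makes it the package's exact
#' oracle for WHAM and specific-heat code: with a large degeneracy
#' ratio it produces a Schottky peak analogous to a folding transition.
#'
#' @param E0,E1 Level energies (kcal/mol), `E1 > E0`.
#' @param g0,g1 Level degeneracies (>= 1).
#' @return An object of class `two_state_system` with closed-form
#'   functions `Z(T)`, `mean_energy(T)`, `cv(T)` and a
#'   `sample(T, n)` draw of level energies (uses the session RNG; seed
#'   with `set.seed()`).
#' @export
make_two_state <- function(E0 = 0, E1 = 2, g0 = 1, g1 = 50) {
  if (g0 < 1 || g1 < 1) stop("degeneracies must be >= 1")
  if (E1 <= E0) stop("need E1 > E0")
  Z <- function(T) g0 * exp(-E0 / T) + g1 * exp(-E1 / T)
  p1 <- function(T) g1 * exp(-E1 / T) / Z(T)
  mean_energy <- function(T) E0 + (E1 - E0) * p1(T)
  cv <- function(T) {
    p <- p1(T)
    (E1 - E0)^2 * p * (1 - p) / T^2
  }
  sample_fn <- function(T, n) {
    lev <- stats::rbinom(n, 1, p1(T))
    ifelse(lev == 1, E1, E0)
  }
  structure(list(E0 = E0, E1 = E1, g0 = g0, g1 = g1,
                 Z = Z, mean_energy = mean_energy, cv = cv,
                 sample = sample_fn),
            class = "two_state_system")
}

#' @export
print.two_state_system <- function(x, ...) {
  cat("<two_state_system> E0 = ", x$E0, " (g0 = ", x$g0, "), E1 = ", x$E1,
      " (g1 = ", x$g1, ")\n", sep = "")
  invisible(x)
}

# Deterministic bead-chain geometries. Both are compact, self-avoiding
# and give |i-j| >= 3 native contacts under the default 7.5 A cutoff.
.fold_coords <- function(n_residues, fold) {
  i <- seq_len(n_residues)
  if (fold == "helix") {
    # ideal alpha-helix-like Calpha spiral: ~3.8 A virtual bonds
    theta <- (i - 1) * 100 * pi / 180
    cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
  } else if (fold == "hairpin") {
    half <- ceiling(n_residues / 2)
    z <- ifelse(i <= half, (i - 1) * 3.8, (n_residues - i) * 3.8)
    x <- ifelse(i <= half, 0, 5.0)
    # stagger the return strand half a rise so cross-strand contacts
    # are unambiguous
    z <- z + ifelse(i <= half, 0, 1.9)
    cbind(x, 0 * i, z)
  } else {
    stop("unknown fold template: ", fold)
  }
}

#' Generate a foldable Go-model peptide
#'
#' Builds a compact self-avoiding bead chain (one bead per residue),
#' wraps it in a [molecular_system()] and derives its Go interaction
#' table from the native contacts via [build_go_model()]. The melting
#' temperature increases with the native well depth `eps`. A small
#' seeded jitter breaks exact symmetry so different seeds give
#' different (deterministically reproducible) native structures.
#'
#' @param n_residues Number of beads (>= 8).
#' @param fold `"hairpin"` or `"helix"`.
#' @param eps Native well depth (kcal/mol).
#' @param seed Integer seed controlling the jitter.
#' @param cutoff Native-contact cutoff (Angstrom); defaults to 8.8
#'   for the helix template (three contact shells) and 7.2 for the
#'   hairpin.
#' @param jitter Coordinate jitter standard deviation (Angstrom).
#' @param out_dir Optional directory: when given, the native structure
#'   (PDB) and interaction table (plain text) are written there so the
#'   file-based pipeline entry points can be exercised end to end.
#' @return A list of class `go_peptide` with elements `system` (the
#'   [molecular_system()]), `table` (the [interaction_table()]),
#'   `contacts` (native-contact tibble), `eps`, `fold`, `seed` and
#'   `modified_site` (`NA` for the unmodified peptide).
#' @export
make_go_peptide <- function(n_residues = 20, fold = c("helix", "hairpin"),
                            eps = 1.2, seed = 1, cutoff = NULL,
                            jitter = 0.05, out_dir = NULL) {
  fold <- match.arg(fold)
  if (n_residues < 8) stop("need at least 8 residues")
  # default contact shells chosen per template so both fold types carry
  # enough native energy to melt inside the standard ladder
  if (is.null(cutoff)) cutoff <- if (fold == "helix") 8.8 else 7.2
  base <- .fold_coords(n_residues, fold)
  attempt <- 0
  repeat {
    set.seed(seed + 1000L * attempt)
    coords <- base + matrix(stats::rnorm(3 * n_residues, sd = jitter),
                            n_residues, 3)
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    bonded <- abs(row(d) - col(d)) == 1
    if (min(d[!bonded]) > 3.8) break
    attempt <- attempt + 1
    if (attempt > 20) stop("could not build an overlap-free conformation")
    message("regenerating with seed offset ", attempt,
            " (steric overlap in jittered conformation)")
  }
  atoms <- tibble::tibble(
    name = "CA", element = "C", charge = 0, mass = 100,
    resname = "GLY", chain = "A", resno = seq_len(n_residues),
    x = coords[, 1], y = coords[, 2], z = coords[, 3])
  bonds <- cbind(seq_len(n_residues - 1), 2:n_residues)
  system <- molecular_system(atoms, bonds)
  table <- build_go_model(system, cutoff = cutoff, eps = eps)
  pep <- structure(list(system = system, table = table,
                        contacts = native_contacts(table),
                        eps = eps, fold = fold, seed = seed,
                        cutoff = cutoff, modified_site = NA_integer_),
                   class = "go_peptide")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pdb(system, file.path(out_dir, "native.pdb"))
    write_interaction_table(table, file.path(out_dir, "table.txt"))
  }
  pep
}

#' @export
print.go_peptide <- function(x, ...) {
  cat("<go_peptide> ", nrow(x$system$atoms), " beads (", x$fold,
      "), ", nrow(x$contacts), " native contacts, eps = ", x$eps,
      if (!is.na(x$modified_site)) paste0(", modified at bead ",
                                          x$modified_site) else "",
      "\n", sep = "")
  invisible(x)
}

#' Destabilized variant of a Go peptide
#'
#' Coarse-grained analogue of substituting a bulkier, charge-carrying
#' residue at one site: the site bead's effective radius grows by
#' `delta_radius` (all its hard cores move outward) and every native
#' well involving the site is shallowed by the factor
#' `(1 - delta_eps)`. Nothing else changes. The intended physics:
#' higher mean potential energy in the folded state, a lower melting
#' temperature, and increased local flexibility around the site.
#'
#' @param peptide A `go_peptide` from [make_go_peptide()].
#' @param site Bead index to modify.
#' @param delta_radius Effective radius increase at the site (Angstrom).
#' @param delta_eps Fractional well shallowing in [0, 1).
#' @return A modified `go_peptide`.
#' @export
make_modified_variant <- function(peptide, site = NULL,
                                  delta_radius = 0.1, delta_eps = 0.6) {
  stopifnot(inherits(peptide, "go_peptide"))
  n <- nrow(peptide$system$atoms)
  if (is.null(site)) site <- .core_site(peptide)
  if (!is.numeric(site) || site < 1 || site > n) {
    stop("invalid site: must be a bead index in 1..", n)
  }
  if (delta_eps < 0 || delta_eps >= 1) stop("`delta_eps` must be in [0, 1)")
  table <- peptide$table
  nb <- table$nonbonded
  touch <- which(nb$i == site | nb$j == site)
  for (k in touch) {
    nm <- nb$pot[k]
    pot <- table$potentials[[nm]]
    radii <- pot$radii
    energies <- pot$energies
    if (grepl("^nat_", nm)) {
      # shallow the well and push its inner edge outward with the
      # bead radius: the bulkier bead strains native packing (narrower
      # well, possibly excluding the native distance) on top of the
      # weakened attraction
      energies[energies < 0] <- energies[energies < 0] * (1 - delta_eps)
      radii[1] <- radii[1] + delta_radius
      radii[2] <- min(radii[2] + delta_radius, radii[1] + 0.999 *
                        (radii[3] - radii[1]))
      radii[2] <- max(radii[2], radii[1] * 1.0001)
      new_nm <- sprintf("%s_mod", nm)
    } else {
      radii[1] <- radii[1] + delta_radius
      new_nm <- sprintf("hard_mod_%d_%d", nb$i[k], nb$j[k])
    }
    table$potentials[[new_nm]] <- step_potential(radii, energies)
    nb$pot[k] <- new_nm
  }
  table$nonbonded <- nb
  out <- peptide
  out$table <- table
  out$contacts <- native_contacts(table)
  out$modified_site <- as.integer(site)
  out
}

# Most buried bead: the one with the highest native-contact degree
# (ties broken toward the chain center).
.core_site <- function(peptide) {
  n <- nrow(peptide$system$atoms)
  deg <- tabulate(c(peptide$contacts$i, peptide$contacts$j), nbins = n)
  cand <- which(deg == max(deg))
  cand[which.min(abs(cand - (n + 1) / 2))]
}

#' Native-contact degree of each bead
#' @param peptide A `go_peptide`.
#' @return Integer vector of per-bead native-contact counts.
#' @export
contact_degree <- function(peptide) {
  n <- nrow(peptide$system$atoms)
  tabulate(c(peptide$contacts$i, peptide$contacts$j), nbins = n)
}

#' Crowded-pocket fixture for stability-scan tests
#'
#' A serine-bearing peptide whose second residue points into a shell
#' of fixed cage atoms: carbon spheres on a Fibonacci sphere of radius
#' `cage_radius` around the site's beta carbon, keeping only positions
#' clear of the peptide itself. Short side chains (serine, or the
#' conservative same-charge control DAP) fit the pocket; the
#' methylated BMAA side chain reaches the cage and pays a steric
#' penalty, which is how the fixture reproduces the
#' bulky-substitution-destabilizes pattern at desk scale.
#'
#' @param cage_radius Cage shell radius around the site CB (Angstrom).
#' @param n_cage Number of candidate cage positions before clearance
#'   filtering.
#' @param clearance Minimum distance from cage atoms to peptide atoms
#'   (Angstrom).
#' @return List with `system` (the [molecular_system()]), `chain`,
#'   `resno` (the repackable site).
#' @export
make_packed_pocket <- function(cage_radius = 5.0, n_cage = 14,
                               clearance = 3.3) {
  sys <- make_ser_peptide()
  at <- sys$atoms
  cb <- unlist(at[at$resno == 2 & at$name == "CB", c("x", "y", "z")])
  scaffold <- system_coords(sys)
  # Fibonacci sphere directions
  k <- seq_len(n_cage)
  phi_g <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * k / phi_g
  zs <- 1 - (2 * k - 1) / n_cage
  rs <- sqrt(pmax(0, 1 - zs^2))
  dirs <- cbind(rs * cos(theta), rs * sin(theta), zs)
  keep <- list()
  for (r in seq_len(n_cage)) {
    pos <- cb + cage_radius * dirs[r, ]
    if (min(sqrt(colSums((t(scaffold) - pos)^2))) >= clearance) {
      keep[[length(keep) + 1L]] <- pos
    }
  }
  if (length(keep) == 0) stop("no cage position clears the scaffold")
  cage <- do.call(rbind, keep)
  pocket <- tibble::tibble(
    name = paste0("C", seq_len(nrow(cage))), element = "C", charge = 0,
    mass = 12.011, resname = "CAG", chain = "X",
    resno = seq_len(nrow(cage)),
    x = cage[, 1], y = cage[, 2], z = cage[, 3])
  system <- molecular_system(dplyr::bind_rows(at, pocket), sys$bonds)
  list(system = system, chain = "A", resno = 2)
}
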