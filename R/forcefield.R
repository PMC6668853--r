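#' Step (square-well) pair potential
#'
#' A piecewise-constant pair potential: below `radii[1]` lies an
#' impenetrable hard core; `energies[k]` is the energy of the shell
#' between `radii[k]` and `radii[k + 1]`, and the final entry is the
#' energy beyond the outermost radius, which must be exactly zero so
#' that well-separated particles do not interact.
#'
#' @param radii Strictly increasing positive wall radii (Angstrom).
#' @param energies Shell energies (kcal/mol), one per radius; the last
#'   entry is the energy beyond the outermost radius and must be 0.
#' @return An object of class `step_potential`.
#' @examples
#' # a single square well of depth -1 between 4 and 6 A, hard core at 3 A
#' step_potential(c(3, 4, 6), c(0, -1, 0))
#' @export
step_potential <- function(radii, energies) {
  stopifnot(is.numeric(radii), is.numeric(energies))
  if (length(radii) != length(energies)) {
    stop("`radii` and `energies` must have equal length ",
         "(one shell energy per wall, last = beyond the outermost wall)")
  }
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    stop("`radii` must be strictly increasing and positive")
  }
  if (any(!is.finite(energies))) stop("shell energies must be finite")
  if (utils::tail(energies, 1) != 0) {
    stop("outermost shell energy must be exactly 0")
  }
  structure(list(radii = as.numeric(radii), energies = as.numeric(energies)),
            class = "step_potential")
}

#' Evaluate a step potential at given distances
#'
#' @param pot A [step_potential()].
#' @param r Distances (Angstrom).
#' @return Energies (kcal/mol); `Inf` inside the hard core.
#' @export
step_energy_at <- function(pot, r) {
  stopifnot(inherits(pot, "step_potential"))
  idx <- findInterval(r, pot$radii)
  out <- ifelse(idx == 0, Inf, pot$energies[pmax(idx, 1)])
  as.numeric(out)
}

#' @export
print.step_potential <- function(x, ...) {
  cat("<step_potential> ", length(x$radii), " walls, hard core at ",
      format(x$radii[1], digits = 4), " A, range ",
      format(utils::tail(x$radii, 1), digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Discretize a continuous pair potential into a step potential
#'
#' Converts sampled values of a continuous potential (for example
#' Lennard-Jones plus an implicit-solvation term) into a multi-step
#' square-well approximation, as used by event-driven discrete
#' molecular dynamics. The hard core is placed at the innermost sampled
#' radius where the potential drops back below `hard_cap`; each of the
#' `n_steps` shells between the hard core and `r_cut` takes the mean of
#' the sampled potential over the shell, and the energy beyond `r_cut`
#' is forced to zero.
#'
#' @param samples A two-column data frame or matrix of (r, U) samples,
#'   sorted by increasing r (Angstrom, kcal/mol).
#' @param n_steps Number of shells between the hard core and `r_cut`.
#' @param r_cut Outer cutoff (Angstrom); must not exceed the largest
#'   sampled radius.
#' @param hard_cap Energies above this value (kcal/mol) are treated as
#'   part of the hard core. Default 100.
#' @return A [step_potential()] with `n_steps + 1` walls.
#' @export
discretize_potential <- function(samples, n_steps, r_cut, hard_cap = 100) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 2) stop("`samples` must have two columns (r, U)")
  r <- samples[, 1]
  U <- samples[, 2]
  if (is.unsorted(r, strictly = TRUE)) stop("`samples` must be sorted by increasing r")
  if (!is.numeric(n_steps) || n_steps < 1) stop("`n_steps` must be >= 1")
  if (r_cut > max(r) + 1e-12) stop("`r_cut` must lie within the sampled range")
  # hard core: first radius from the outside in where U exceeds the cap
  soft <- which(U <= hard_cap & r <= r_cut)
  if (length(soft) == 0) stop("potential exceeds `hard_cap` everywhere below r_cut")
  r_core <- r[soft[1]]
  if (r_core >= r_cut) stop("hard core at or beyond `r_cut`; nothing to discretize")
  edges <- seq(r_core, r_cut, length.out = n_steps + 1)
  energies <- numeric(n_steps + 1)
  for (k in seq_len(n_steps)) {
    inside <- r >= edges[k] & r < edges[k + 1] & U <= hard_cap
    energies[k] <- if (any(inside)) mean(U[inside]) else {
      # no sample in the shell: interpolate at its center
      stats::approx(r, U, xout = (edges[k] + edges[k + 1]) / 2, rule = 2)$y
    }
  }
  energies[n_steps + 1] <- 0
  step_potential(edges, energies)
}

#' Lennard-Jones potential sampled on a grid
#'
#' Convenience sampler for [discretize_potential()] and for tests:
#' \eqn{U(r) = 4 \epsilon [(\sigma/r)^{12} - (\sigma/r)^6]}.
#'
#' @param eps Well depth (kcal/mol).
#' @param sigma Zero-crossing distance (Angstrom).
#' @param r Radii at which to evaluate.
#' @return A two-column matrix (r, U).
#' @export
lj_samples <- function(eps, sigma, r) {
  sr6 <- (sigma / r)^6
  cbind(r = r, U = 4 * eps * (sr6^2 - sr6))
}

#' Interaction table: the discrete force field of a system
#'
#' Bundles everything the engine needs: explicit nonbonded pair
#' assignments to step potentials, bonded square-well constraints
#' (bond / 1-3 angle / 1-4 dihedral distance wells, plus disulfide,
#' metal and peptide links), and excluded pairs.
#'
#' @param potentials Named list of [step_potential()] objects.
#' @param nonbonded Tibble with columns `i`, `j` (1-based atom indices,
#'   i < j) and `pot` (name into `potentials`).
#' @param constraints Tibble with columns `i`, `j`, `rmin`, `rmax`,
#'   `type` (one of bond, angle13, dihedral14, disulfide, metal,
#'   peptide).
#' @param exclusions Optional tibble with columns `i`, `j` of pairs
#'   that do not interact at all.
#' @return An object of class `interaction_table`.
#' @export
interaction_table <- function(potentials = list(),
                              nonbonded = NULL,
                              constraints = NULL,
                              exclusions = NULL) {
  empty_pairs <- tibble::tibble(i = integer(), j = integer())
  if (is.null(nonbonded)) nonbonded <- tibble::tibble(i = integer(), j = integer(), pot = character())
  if (is.null(constraints)) {
    constraints <- tibble::tibble(i = integer(), j = integer(),
                                  rmin = numeric(), rmax = numeric(),
                                  type = character())
  }
  if (is.null(exclusions)) exclusions <- empty_pairs
  norm <- function(d) {
    sw <- d$i > d$j
    tmp <- d$i[sw]; d$i[sw] <- d$j[sw]; d$j[sw] <- tmp
    d
  }
  nonbonded <- norm(nonbonded)
  constraints <- norm(constraints)
  exclusions <- norm(exclusions)
  if (any(constraints$rmin >= constraints$rmax)) {
    stop("every bonded constraint needs rmin < rmax")
  }
  missing_pot <- setdiff(nonbonded$pot, names(potentials))
  if (length(missing_pot)) {
    stop("nonbonded rows reference unknown potentials: ",
         paste(missing_pot, collapse = ", "))
  }
  keyify <- function(d) paste(d$i, d$j)
  overlap <- intersect(keyify(nonbonded), keyify(constraints))
  if (length(overlap)) {
    stop("pairs assigned both bonded and nonbonded interactions: ",
         paste(overlap, collapse = "; "))
  }
  structure(list(potentials = potentials, nonbonded = nonbonded,
                 constraints = constraints, exclusions = exclusions),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> ", nrow(x$nonbonded), " nonbonded pairs, ",
      nrow(x$constraints), " bonded constraints, ",
      length(x$potentials), " potentials\n", sep = "")
  invisible(x)
}

# Flatten an interaction table into the per-pair records the C++ engine
# consumes (0-based indices; bonded wells become [rmin, rmax] boxes with
# an infinite outer shell).
.compile_pairs <- function(table) {
  recs <- list()
  nb <- table$nonbonded
  for (k in seq_len(nrow(nb))) {
    pot <- table$potentials[[nb$pot[k]]]
    recs[[length(recs) + 1L]] <- list(i = nb$i[k] - 1L, j = nb$j[k] - 1L,
                                      radii = pot$radii, energies = pot$energies)
  }
  cs <- table$constraints
  for (k in seq_len(nrow(cs))) {
    recs[[length(recs) + 1L]] <- list(i = cs$i[k] - 1L, j = cs$j[k] - 1L,
                                      radii = c(cs$rmin[k], cs$rmax[k]),
                                      energies = c(0, Inf))
  }
  recs
}

#' Static step-potential energy of a configuration
#'
#' Sums the shell energies of every nonbonded pair in `table` at the
#' given coordinates. Bonded constraints contribute zero inside their
#' wells and `Inf` outside; a hard-core overlap returns `Inf`.
#'
#' @param coords Numeric n x 3 coordinate matrix (Angstrom).
#' @param table An [interaction_table()].
#' @return Total potential energy (kcal/mol).
#' @export
configuration_energy <- function(coords, table) {
  .step_energy_cpp(as.matrix(coords), .compile_pairs(table))
}

#' Bonded square-well constraints from a molecular topology
#'
#' For every 1-2 bond, a distance well of fractional half-width `tol`
#' about the current distance; for every 1-3 (angle) and 1-4 (dihedral)
#' path through the bond graph, analogous wells with their own default
#' tolerances (5% and 10%). Special constraints recorded on the system
#' (disulfide, metal-ligand, peptide links created by substitution) are
#' emitted as type-labelled wells with the bond tolerance.
#'
#' @param system A [molecular_system()].
#' @param tol Fractional half-width for 1-2 bonds, in (0, 0.5).
#' @param tol13,tol14 Fractional half-widths for 1-3 and 1-4 wells.
#' @return Tibble of constraints (columns `i`, `j`, `rmin`, `rmax`,
#'   `type`).
#' @export
bonded_constraints <- function(system, tol = 0.02, tol13 = 0.05, tol14 = 0.10) {
  for (t in c(tol, tol13, tol14)) {
    if (!is.numeric(t) || t <= 0 || t >= 0.5) {
      stop("tolerances must lie strictly between 0 and 0.5")
    }
  }
  bonds <- system$bonds
  if (is.null(bonds) || nrow(bonds) == 0) stop("system has no bonds")
  coords <- system_coords(system)
  n <- nrow(coords)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist_ij <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  rows <- list()
  add <- function(i, j, frac, type) {
    d <- dist_ij(i, j)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      i = min(i, j), j = max(i, j),
      rmin = d * (1 - frac), rmax = d * (1 + frac), type = type)
  }
  seen <- new.env(hash = TRUE)
  key <- function(i, j) paste(min(i, j), max(i, j))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (is.null(seen[[key(i, j)]])) { add(i, j, tol, "bond"); seen[[key(i, j)]] <- TRUE }
  }
  # 1-3 and 1-4 paths through the bond graph
  for (a in seq_len(n)) {
    for (b in adj[[a]]) {
      for (c in adj[[b]]) {
        if (c == a) next
        if (c > a && is.null(seen[[key(a, c)]])) {
          add(a, c, tol13, "angle13"); seen[[key(a, c)]] <- TRUE
        }
        for (d in adj[[c]]) {
          if (d == b || d == a) next
          if (d > a && is.null(seen[[key(a, d)]])) {
            add(a, d, tol14, "dihedral14"); seen[[key(a, d)]] <- TRUE
          }
        }
      }
    }
  }
  sc <- system$special_constraints
  if (!is.null(sc) && nrow(sc) > 0) {
    for (k in seq_len(nrow(sc))) {
      i <- sc$i[k]; j <- sc$j[k]
      if (is.null(seen[[key(i, j)]])) {
        add(i, j, tol, sc$type[k]); seen[[key(i, j)]] <- TRUE
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Build a Go-model interaction table from a native structure
#'
#' In a Go model only contacts present in the native structure attract:
#' residue pairs separated by at least 3 positions along the chain and
#' within `cutoff` in the reference structure receive a square well of
#' depth `-eps` around their native distance; every other nonbonded
#' pair is a pure hard sphere. Chain connectivity comes from
#' [bonded_constraints()]. This is the package's desk-scale surrogate
#' for a transferable all-atom force field: it preserves the two-state
#' folding cooperativity that melting analysis probes while remaining
#' small enough to sample exhaustively.
#'
#' @param system A single-bead-per-residue [molecular_system()] (one
#'   atom per residue, e.g. from [make_go_peptide()]).
#' @param cutoff Native-contact distance cutoff (Angstrom).
#' @param eps Native well depth (kcal/mol, positive).
#' @param well_width Fractional half-width of the native well
#'   (default 0.12: well spans 88%--112% of the native distance;
#'   narrow wells keep the folded state well-defined so that
#'   per-residue fluctuations report on interaction strength).
#' @param hard_core Hard-sphere contact distance for non-native pairs
#'   (Angstrom).
#' @return An [interaction_table()].
#' @export
build_go_model <- function(system, cutoff = 7.5, eps = 1.2,
                           well_width = 0.12, hard_core = 3.6) {
  if (cutoff <= 0 || eps <= 0) stop("`cutoff` and `eps` must be positive")
  coords <- system_coords(system)
  n <- nrow(coords)
  if (n < 4) stop("Go model needs at least 4 residues")
  # chain connectivity only: 1-2 bond wells (plus any special
  # constraints). Angle/dihedral wells would pin the bead chain to its
  # native shape and suppress unfolding; excluded volume plus the
  # native wells carry the folding physics in a Go model.
  constraints <- bonded_constraints(system)
  constraints <- constraints[constraints$type %in%
                               c("bond", "disulfide", "metal", "peptide"), ,
                             drop = FALSE]
  cons_key <- paste(constraints$i, constraints$j)
  potentials <- list(hard = step_potential(hard_core, 0))
  nb <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (paste(i, j) %in% cons_key) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (abs(i - j) >= 3 && d <= cutoff) {
        lo <- max(hard_core * 0.9, d * (1 - well_width))
        hi <- d * (1 + well_width)
        nm <- sprintf("nat_%d_%d", i, j)
        potentials[[nm]] <- step_potential(c(min(hard_core, lo * 0.999), lo, hi),
                                           c(0, -eps, 0))
        nb[[length(nb) + 1L]] <- tibble::tibble(i = i, j = j, pot = nm)
      } else {
        nb[[length(nb) + 1L]] <- tibble::tibble(i = i, j = j, pot = "hard")
      }
    }
  }
  interaction_table(potentials = potentials,
                    nonbonded = dplyr::bind_rows(nb),
                    constraints = constraints)
}

#' Native contacts of a Go interaction table
#'
#' @param table An [interaction_table()] built by [build_go_model()].
#' @return Tibble of native-contact pairs `i`, `j` with their well
#'   depths.
#' @export
native_contacts <- function(table) {
  nat <- table$nonbonded[grepl("^nat_", table$nonbonded$pot), ]
  depth <- unname(vapply(nat$pot, function(p)
    min(table$potentials[[p]]$energies), numeric(1)))
  tibble::tibble(i = nat$i, j = nat$j, depth = depth)
}

#' Serialize an interaction table to a plain-text file
#'
#' @param table An [interaction_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# stepfold interaction table", con)
  writeLines("[potentials]", con)
  for (nm in names(table$potentials)) {
    p <- table$potentials[[nm]]
    writeLines(paste(nm,
                     paste(sprintf("%.10g", p$radii), collapse = ","),
                     paste(sprintf("%.10g", p$energies), collapse = ",")), con)
  }
  writeLines("[nonbonded]", con)
  nb <- table$nonbonded
  writeLines(paste(nb$i, nb$j, nb$pot), con)
  writeLines("[constraints]", con)
  cs <- table$constraints
  writeLines(paste(cs$i, cs$j, sprintf("%.10g", cs$rmin),
                   sprintf("%.10g", cs$rmax), cs$type), con)
  invisible(path)
}

#' Read an interaction table written by [write_interaction_table()]
#'
#' @param path File path.
#' @return An [interaction_table()].
#' @export
read_interaction_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sec <- cumsum(grepl("^\\[", lines))
  headers <- lines[grepl("^\\[", lines)]
  out <- split(lines[!grepl("^\\[", lines)], sec[!grepl("^\\[", lines)])
  names(out) <- gsub("[][]", "", headers)
  potentials <- list()
  for (ln in out[["potentials"]]) {
    f <- strsplit(ln, " ")[[1]]
    potentials[[f[1]]] <- step_potential(
      as.numeric(strsplit(f[2], ",")[[1]]),
      as.numeric(strsplit(f[3], ",")[[1]]))
  }
  nb_f <- do.call(rbind, strsplit(out[["nonbonded"]], " "))
  nonbonded <- tibble::tibble(i = as.integer(nb_f[, 1]),
                              j = as.integer(nb_f[, 2]), pot = nb_f[, 3])
  cs <- out[["constraints"]]
  constraints <- if (length(cs)) {
    cf <- do.call(rbind, strsplit(cs, " "))
    tibble::tibble(i = as.integer(cf[, 1]), j = as.integer(cf[, 2]),
                   rmin = as.numeric(cf[, 3]), rmax = as.numeric(cf[, 4]),
                   type = cf[, 5])
  } else NULL
  interaction_table(potentials, nonbonded, constraints)
}
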