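# torsion angle (degrees) defined by four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Discrete atomic interaction table for static repacking energies
#'
#' Builds the same kind of step-potential force field the engine runs
#' on, for an all-atom system: every nonbonded pair (outside 1-2, 1-3,
#' 1-4 paths) receives a multi-step discretization of a Lennard-Jones
#' term (combining element van der Waals radii, fixed well depth) plus
#' a screened Coulomb term between formal charges. Potentials are
#' cached per (element pair, charge product), so the table stays small.
#'
#' @param system A [molecular_system()].
#' @param n_steps Shells per pair potential (default 6).
#' @param r_cut Nonbonded cutoff (Angstrom, default 8).
#' @param lj_eps Lennard-Jones well depth (kcal/mol, default 0.15).
#' @param dielectric Screening dielectric for formal charges
#'   (default 20).
#' @return An [interaction_table()].
#' @export
build_atomic_table <- function(system, n_steps = 6, r_cut = 8,
                               lj_eps = 0.15, dielectric = 20) {
  at <- system$atoms
  n <- nrow(at)
  constraints <- bonded_constraints(system)
  bonded_key <- paste(constraints$i, constraints$j)
  vdw <- .element_vdw[at$element]
  vdw[is.na(vdw)] <- 1.7
  rgrid <- seq(0.6, r_cut, by = 0.02)
  potentials <- list()
  nb <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (paste(i, j) %in% bonded_key) next
      qq <- at$charge[i] * at$charge[j]
      rmin <- vdw[i] + vdw[j]
      key <- sprintf("p_%.2f_%.2f", rmin, qq)
      if (is.null(potentials[[key]])) {
        sigma <- rmin / 2^(1 / 6)
        U <- lj_samples(lj_eps, sigma, rgrid)[, 2]
        if (qq != 0) U <- U + 332 * qq / (dielectric * rgrid)
        potentials[[key]] <- discretize_potential(cbind(rgrid, U),
                                                  n_steps, r_cut)
      }
      nb[[length(nb) + 1L]] <- tibble::tibble(i = i, j = j, pot = key)
    }
  }
  interaction_table(potentials = potentials,
                    nonbonded = dplyr::bind_rows(nb),
                    constraints = constraints)
}

# Candidate side-chain placements for a repackable site: one coordinate
# block per rotamer of the site's residue type at the nearest backbone
# bin of the library.
.site_candidates <- function(system, chain, resno, rotlib, template = NULL) {
  at <- system$atoms
  sel <- which(at$chain == chain & at$resno == resno)
  if (length(sel) == 0) stop("residue not found: ", chain, resno)
  resname <- at$resname[sel[1]]
  if (is.null(template)) template <- residue_template(resname)
  bb_names <- c("N", "CA", "C", "O")
  bb_idx <- sel[match(bb_names, at$name[sel])]
  if (any(is.na(bb_idx))) stop("incomplete backbone at ", chain, resno)
  backbone <- stats::setNames(lapply(bb_idx, function(i)
    c(at$x[i], at$y[i], at$z[i])), bb_names)
  side_idx <- setdiff(sel, bb_idx)
  # measure (phi, psi) if the neighbours exist, else use a generic bin
  phi <- -120; psi <- 140
  prevC <- which(at$chain == chain & at$resno == resno - 1 & at$name == "C")
  nextN <- which(at$chain == chain & at$resno == resno + 1 & at$name == "N")
  crd <- function(i) c(at$x[i], at$y[i], at$z[i])
  if (length(prevC) == 1) {
    phi <- .dihedral(crd(prevC), backbone$N, backbone$CA, backbone$C)
  }
  if (length(nextN) == 1) {
    psi <- .dihedral(backbone$N, backbone$CA, backbone$C, crd(nextN))
  }
  n_chi <- template$n_chi
  if (n_chi == 0 || nrow(rotlib) == 0) {
    cand <- list(.build_sidechain(template, backbone, numeric(0)))
  } else {
    dphi <- .ang_diff(rotlib$phi, phi)^2 + .ang_diff(rotlib$psi, psi)^2
    bin <- rotlib[dphi == min(dphi), , drop = FALSE]
    mean_cols <- paste0("chi", seq_len(n_chi), "_mean")
    cand <- lapply(seq_len(nrow(bin)), function(r) {
      chi <- as.numeric(bin[r, mean_cols])
      .build_sidechain(template, backbone, chi)
    })
  }
  list(site_atoms = side_idx, candidates = cand, template = template,
       backbone_idx = bb_idx, phi = phi, psi = psi, resname = resname)
}

# Apply candidate placement k of a prepared site to a coordinate matrix.
.apply_candidate <- function(coords, site, k) {
  cand <- site$candidates[[k]]
  idx <- site$site_atoms
  nms <- names(cand)
  for (a in seq_along(idx)) {
    coords[idx[a], ] <- cand[[a]]$pos
  }
  coords
}

#' Repacking Monte Carlo over rotamer placements
#'
#' Metropolis Monte Carlo over rotamer substitutions at the given
#' sites, scored by the static step-potential energy of the system.
#' In flexible mode each accepted-or-rejected move also perturbs the
#' site's side-chain orientation through small Gaussian phi/psi-style
#' rotations about the N-CA and CA-C axes (sigma 3 degrees, capped at
#' +/- 10), applied to the side chain only. Returns the best (lowest)
#' energy visited, including the initial placement.
#'
#' @param system A [molecular_system()].
#' @param sites Tibble or data frame with columns `chain`, `resno`.
#' @param rotlib Named list mapping residue names to
#'   `rotamer_library` objects (a single library is recycled).
#' @param table Optional precomputed [build_atomic_table()]; built on
#'   the fly when `NULL`.
#' @param n_mc Monte Carlo steps (>= 0).
#' @param temperature Metropolis temperature k_B*T (kcal/mol).
#' @param seed Integer seed.
#' @param mode `"fixed"` or `"flexible"` backbone.
#' @return Best energy visited (kcal/mol), with attribute
#'   `"assignment"` (rotamer index per site at the optimum).
#' @export
repack_energy <- function(system, sites, rotlib, table = NULL, n_mc = 20,
                          temperature = 0.6, seed = 1,
                          mode = c("fixed", "flexible")) {
  mode <- match.arg(mode)
  if (n_mc < 0) stop("`n_mc` must be >= 0")
  set.seed(seed)
  if (is.null(table)) table <- build_atomic_table(system)
  # score nonbonded terms only: bond/angle geometry is preserved by
  # construction when side chains are rebuilt from templates, and 1-4
  # distances legitimately change with chi, so the engine's bonded
  # wells must not act as (infinite) penalties here
  nb_only <- table
  nb_only$constraints <- table$constraints[0, , drop = FALSE]
  pairs <- .compile_pairs(nb_only)
  sites <- as.data.frame(sites)
  prepared <- lapply(seq_len(nrow(sites)), function(s) {
    resname <- system$atoms$resname[
      which(system$atoms$chain == sites$chain[s] &
              system$atoms$resno == sites$resno[s])[1]]
    lib <- if (inherits(rotlib, "rotamer_library")) rotlib
           else rotlib[[resname]]
    if (is.null(lib)) stop("no rotamer coverage for residue type ", resname)
    .site_candidates(system, sites$chain[s], sites$resno[s], lib)
  })
  coords <- system_coords(system)
  energy_of <- function(crd) .step_energy_cpp(crd, pairs)
  # start from the first (most probable) rotamer of every site
  assign <- rep(1L, length(prepared))
  for (s in seq_along(prepared)) coords <- .apply_candidate(coords, prepared[[s]], 1L)
  e_cur <- energy_of(coords)
  best <- e_cur
  best_assign <- assign
  if (n_mc == 0) {
    attr(best, "assignment") <- best_assign
    return(best)
  }
  for (step in seq_len(n_mc)) {
    s <- sample.int(length(prepared), 1)
    k <- sample.int(length(prepared[[s]]$candidates), 1)
    prop <- .apply_candidate(coords, prepared[[s]], k)
    if (mode == "flexible") {
      prop <- .perturb_sidechain(prop, prepared[[s]])
    }
    e_prop <- .step_energy_cpp(prop, pairs)
    accept <- is.finite(e_prop) &&
      (e_prop <= e_cur || stats::runif(1) < exp(-(e_prop - e_cur) / temperature))
    if (accept) {
      coords <- prop
      e_cur <- e_prop
      assign[s] <- k
      if (e_cur < best) { best <- e_cur; best_assign <- assign }
    }
  }
  attr(best, "assignment") <- best_assign
  best
}

# Flexible-backbone move: rotate the site's side-chain atoms rigidly
# about the N-CA (phi-like) and CA-C (psi-like) axes by small Gaussian
# angles. A local approximation to backbone flexing that leaves the
# rest of the chain in place.
.perturb_sidechain <- function(coords, site) {
  idx <- site$site_atoms
  if (length(idx) == 0) return(coords)
  bb <- site$backbone_idx
  for (axpair in list(c(1L, 2L), c(2L, 3L))) {  # N-CA, CA-C
    ang <- max(-10, min(10, stats::rnorm(1, 0, 3))) * pi / 180
    p0 <- coords[bb[axpair[1]], ]
    ax <- coords[bb[axpair[2]], ] - p0
    ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    coords[idx, ] <- sweep(sweep(coords[idx, , drop = FALSE], 2, p0) %*% t(R),
                           2, p0, `+`)
  }
  coords
}

#' Estimate the folding free-energy change of a point substitution
#'
#' Repacking-protocol estimate: per independent round, both the wild-type and
#' the mutant residue are repacked `n_sims` times (each `n_mc`
#' Metropolis steps) over the local shell of residues within
#' `shell_radius` of the site, keeping the minimum energy of each arm;
#' the same repack is run on an extracted tripeptide (site plus its
#' sequence neighbours) as the unfolded-state reference, and
#' \deqn{\Delta\Delta G = (E^{fold}_{mut} - E^{ref}_{mut}) -
#'       (E^{fold}_{wt} - E^{ref}_{wt}).}
#' The result is the mean and standard deviation over `n_rounds`
#' paired rounds; positive values mean destabilization.
#'
#' @param system A [molecular_system()].
#' @param chain,resno Site address.
#' @param target A `residue_template` (or name) to substitute in.
#' @param rotlib Named list of `rotamer_library` objects covering the
#'   wild-type and target residue types.
#' @param mode `"fixed"` or `"flexible"` backbone.
#' @param n_rounds Independent rounds (default 20).
#' @param n_sims Repack repeats per arm per round (default 20).
#' @param n_mc Monte Carlo steps per repack (default 20).
#' @param shell_radius Local shell radius (Angstrom, default 8).
#' @param temperature Metropolis temperature (default 0.6).
#' @param seed Master seed.
#' @return Object of class `ddg_result`.
#' @export
estimate_ddg <- function(system, chain, resno, target, rotlib,
                         mode = c("fixed", "flexible"),
                         n_rounds = 20, n_sims = 20, n_mc = 20,
                         shell_radius = 8, temperature = 0.6, seed = 1) {
  mode <- match.arg(mode)
  if (is.character(target)) target <- residue_template(target)
  at <- system$atoms
  sel <- which(at$chain == chain & at$resno == resno)
  if (length(sel) == 0) stop("residue not found: chain ", chain, " ", resno)
  wt_name <- at$resname[sel[1]]
  mutant <- substitute_residue(system, chain, resno, target)

  wt_shell <- .extract_shell(system, chain, resno, shell_radius)
  mut_shell <- .extract_shell(mutant, chain, resno, shell_radius)
  wt_ref <- .extract_tripeptide(system, chain, resno)
  mut_ref <- .extract_tripeptide(mutant, chain, resno)
  tabs <- lapply(list(wt_shell, mut_shell, wt_ref, mut_ref),
                 build_atomic_table)

  set.seed(seed)
  round_seeds <- matrix(sample.int(2^31 - 2, n_rounds * n_sims * 4),
                        n_rounds, n_sims * 4)
  site <- tibble::tibble(chain = chain, resno = resno)
  arm_min <- function(sys, tab, seeds) {
    min(vapply(seeds, function(sd)
      as.numeric(repack_energy(sys, site, rotlib, table = tab, n_mc = n_mc,
                               temperature = temperature, seed = sd,
                               mode = mode)),
      numeric(1)))
  }
  per_round <- vapply(seq_len(n_rounds), function(r) {
    sds <- round_seeds[r, ]
    blocks <- split(sds, rep(1:4, each = n_sims))
    e_wt <- arm_min(wt_shell, tabs[[1]], blocks[[1]])
    e_mut <- arm_min(mut_shell, tabs[[2]], blocks[[2]])
    e_wt_ref <- arm_min(wt_ref, tabs[[3]], blocks[[3]])
    e_mut_ref <- arm_min(mut_ref, tabs[[4]], blocks[[4]])
    (e_mut - e_mut_ref) - (e_wt - e_wt_ref)
  }, numeric(1))
  structure(list(chain = chain, resno = resno, wt = wt_name,
                 target = target$name, mode = mode,
                 per_round = per_round,
                 mean = mean(per_round),
                 sd = stats::sd(per_round),
                 n_rounds = n_rounds,
                 params = list(n_sims = n_sims, n_mc = n_mc,
                               shell_radius = shell_radius, seed = seed)),
            class = "ddg_result")
}

# Residues with any atom within `radius` of any atom of the site.
.extract_shell <- function(system, chain, resno, radius) {
  at <- system$atoms
  coords <- system_coords(system)
  sel <- which(at$chain == chain & at$resno == resno)
  keep_res <- unique(paste(at$chain, at$resno)[
    apply(coords, 1, function(p)
      min(colSums((t(coords[sel, , drop = FALSE]) - p)^2)) <= radius^2)])
  .subset_system(system, paste(at$chain, at$resno) %in% keep_res)
}

.extract_tripeptide <- function(system, chain, resno) {
  at <- system$atoms
  keep <- at$chain == chain & abs(at$resno - resno) <= 1
  .subset_system(system, keep)
}

.subset_system <- function(system, keep) {
  idx <- which(keep)
  remap <- match(seq_len(nrow(system$atoms)), idx)
  b <- system$bonds
  b <- b[b[, 1] %in% idx & b[, 2] %in% idx, , drop = FALSE]
  b <- cbind(remap[b[, 1]], remap[b[, 2]])
  sc <- system$special_constraints
  sc <- sc[sc$i %in% idx & sc$j %in% idx, , drop = FALSE]
  if (nrow(sc)) { sc$i <- remap[sc$i]; sc$j <- remap[sc$j] }
  molecular_system(system$atoms[idx, , drop = FALSE], b, sc)
}

#' @export
print.ddg_result <- function(x, ...) {
  cat("<ddg_result> ", x$wt, x$resno, x$chain, " -> ", x$target, " (", x$mode,
      " backbone): ddG = ", sprintf("%.2f +/- %.2f", x$mean, x$sd),
      " kcal/mol over ", x$n_rounds, " rounds\n", sep = "")
  invisible(x)
}

#' Scan every serine in a chain against target residues
#'
#' Runs [estimate_ddg()] for each serine in the designated chain and
#' each target template, reporting one row per (site, target), ordered
#' by sequence number.
#'
#' @param system A [molecular_system()].
#' @param chain Chain to scan.
#' @param targets Character vector of target template names
#'   (default `c("BMAA", "LYS")`).
#' @param rotlib Named list of rotamer libraries covering serine and
#'   the targets.
#' @param ... Passed to [estimate_ddg()].
#' @return Tibble with columns `site`, `resno`, `wt`, `target`, `mode`,
#'   `ddg_mean`, `ddg_sd`, `n_rounds`.
#' @export
serine_scan <- function(system, chain, targets = c("BMAA", "LYS"),
                        rotlib, ...) {
  at <- system$atoms
  ser <- sort(unique(at$resno[at$chain == chain & at$resname == "SER"]))
  if (length(ser) == 0) {
    warning("chain ", chain, " contains no serines; empty scan")
    return(tibble::tibble(site = character(), resno = integer(),
                          wt = character(), target = character(),
                          mode = character(), ddg_mean = numeric(),
                          ddg_sd = numeric(), n_rounds = integer()))
  }
  rows <- list()
  for (rn in ser) {
    for (tg in targets) {
      res <- estimate_ddg(system, chain, rn, tg, rotlib, ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site = paste0("S", rn), resno = rn, wt = res$wt, target = res$target,
        mode = res$mode, ddg_mean = res$mean, ddg_sd = res$sd,
        n_rounds = res$n_rounds)
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), resno, target)
}
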