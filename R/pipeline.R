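#' Default run configuration
#'
#' All workflow parameters with their defaults, as a validated nested
#' list. Every source of randomness flows from the single `seed`
#' entry. Desk-scale defaults: a 20-bead helical fold with native well
#' depth 1.2 kcal/mol, the 16-rung melting ladder, and a destabilized
#' variant whose modified bead is slightly bulkier with native wells
#' shallowed to 40% of their depth.
#'
#' @param seed Master seed.
#' @param ... Named overrides for any top-level entry.
#' @return Object of class `stepfold_config`.
#' @export
stepfold_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    peptide = list(n_residues = 20, fold = "helix", eps = 1.2),
    variant = list(site = NULL, delta_radius = 0.1, delta_eps = 0.6),
    ladder = list(temperatures = melting_ladder(), exchange_interval = 25),
    remd = list(length = 40000, frame_interval = 1, equilibration = 0.2),
    low_t = list(temperature = 0.40, length = 8000, frame_interval = 1),
    analysis = list(bins = 30, min_prominence = 0.1,
                    t_grid = seq(0.40, 0.85, by = 0.002)),
    ddg = list(n_rounds = 5, n_sims = 5, n_mc = 40, mode = "fixed"),
    output_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config entry: ", nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config key ", nm, "$", bad[1])
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  if (!is.numeric(cfg$seed)) stop("`seed` must be numeric")
  structure(cfg, class = "stepfold_config")
}

#' Read / write a run configuration (YAML)
#' @param path File path.
#' @return A `stepfold_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1
  raw$seed <- NULL
  do.call(stepfold_config, c(list(seed = seed), raw))
}

#' @rdname read_config
#' @param config A `stepfold_config`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# build the WT/variant pair of a config
.config_systems <- function(config) {
  wt <- make_go_peptide(n_residues = config$peptide$n_residues,
                        fold = config$peptide$fold,
                        eps = config$peptide$eps,
                        seed = config$seed)
  var <- make_modified_variant(wt, site = config$variant$site,
                               delta_radius = config$variant$delta_radius,
                               delta_eps = config$variant$delta_eps)
  list(wt = wt, variant = var)
}

#' Melting-comparison workflow
#'
#' Runs replica-exchange DMD for the wild-type peptide and its
#' destabilized variant, combines each ladder's energy histograms with
#' WHAM, evaluates specific-heat curves, detects melting events, and
#' histograms low-temperature potential energies. The headline numbers
#' are the major melting temperatures and their shift
#' \eqn{\Delta T_m = T_m(WT) - T_m(variant)} and the low-temperature
#' modal potential energies of the two systems.
#'
#' @param config A [stepfold_config()].
#' @param progress Print progress lines?
#' @return List of class `melting_report`.
#' @export
run_melting_workflow <- function(config = stepfold_config(),
                                 progress = FALSE) {
  systems <- .config_systems(config)
  ladder <- replica_ladder(config$ladder$temperatures,
                           config$ladder$exchange_interval)
  arms <- lapply(systems, function(pep) {
    remd <- run_remd(pep$system, pep$table, ladder,
                     length = config$remd$length, seed = config$seed,
                     frame_interval = config$remd$frame_interval,
                     equilibration = config$remd$equilibration,
                     progress = progress)
    hist <- energy_histograms(remd)
    profile <- wham(hist)
    cv <- specific_heat(profile, config$analysis$t_grid)
    peaks <- find_melting_events(cv, config$analysis$min_prominence)
    low_t <- run_dmd(pep$system, pep$table,
                     temperature = config$low_t$temperature,
                     length = config$low_t$length, seed = config$seed + 17,
                     frame_interval = config$low_t$frame_interval)
    list(remd = remd, profile = profile, cv = cv, peaks = peaks,
         pe_hist = pe_histogram(low_t, config$analysis$bins),
         low_t = low_t)
  })
  tm <- vapply(arms, function(a)
    if (nrow(a$peaks)) a$peaks$temperature[a$peaks$major][1] else NA_real_,
    numeric(1))
  out <- list(wt = arms$wt, variant = arms$variant,
              t_melt = tm,
              delta_tm = tm[["wt"]] - tm[["variant"]],
              modal_pe = c(wt = arms$wt$pe_hist$mode,
                           variant = arms$variant$pe_hist$mode),
              config = config)
  class(out) <- "melting_report"
  if (!is.null(config$output_dir)) .write_melting_report(out)
  out
}

.write_melting_report <- function(report) {
  dir.create(report$config$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- report$config$output_dir
  utils::write.table(report$wt$cv, file.path(od, "cv_wt.txt"),
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$variant$cv, file.path(od, "cv_variant.txt"),
                     row.names = FALSE, quote = FALSE)
  summary_lines <- c(
    sprintf("T_m(WT)      = %.4f reduced (%.0f K)", report$t_melt[["wt"]],
            reduced_to_kelvin(report$t_melt[["wt"]])),
    sprintf("T_m(variant) = %.4f reduced (%.0f K)", report$t_melt[["variant"]],
            reduced_to_kelvin(report$t_melt[["variant"]])),
    sprintf("delta T_m    = %.4f reduced", report$delta_tm),
    sprintf("modal PE: WT %.3f, variant %.3f kcal/mol",
            report$modal_pe[["wt"]], report$modal_pe[["variant"]]))
  writeLines(summary_lines, file.path(od, "melting_summary.txt"))
}

#' @export
print.melting_report <- function(x, ...) {
  cat("<melting_report>\n",
      sprintf("  T_m(WT)      = %.4f (%.0f K)\n", x$t_melt[["wt"]],
              reduced_to_kelvin(x$t_melt[["wt"]])),
      sprintf("  T_m(variant) = %.4f (%.0f K)\n", x$t_melt[["variant"]],
              reduced_to_kelvin(x$t_melt[["variant"]])),
      sprintf("  delta T_m    = %+.4f\n", x$delta_tm),
      sprintf("  modal PE     : WT %.2f, variant %.2f kcal/mol\n",
              x$modal_pe[["wt"]], x$modal_pe[["variant"]]), sep = "")
  invisible(x)
}

#' Stability-scan workflow
#'
#' Builds a small all-atom peptide fixture carrying serines, a rotamer
#' library for each residue type involved, and runs [serine_scan()]
#' for each target template (default BMAA and the lysine control).
#'
#' @param system A [molecular_system()] with serines (default: the
#'   packaged serine-bearing fixture peptide).
#' @param chain Chain to scan.
#' @param config A [stepfold_config()] (`ddg` entries are used).
#' @param targets Target templates.
#' @return Tibble as from [serine_scan()].
#' @export
run_ddg_workflow <- function(system = NULL, chain = "A",
                             config = stepfold_config(),
                             targets = c("BMAA", "LYS")) {
  if (is.null(system)) system <- make_ser_peptide()
  rotlib <- standard_rotamer_set()
  serine_scan(system, chain, targets = targets, rotlib = rotlib,
              mode = config$ddg$mode, n_rounds = config$ddg$n_rounds,
              n_sims = config$ddg$n_sims, n_mc = config$ddg$n_mc,
              seed = config$seed)
}

#' Dynamics-comparison workflow
#'
#' Paired low-temperature runs of the wild-type and variant peptides at
#' matched seeds, followed by RMSF profiles, correlated-motion maps and
#' their difference.
#'
#' @param config A [stepfold_config()].
#' @return List of class `dynamics_report`: `rmsf` (long tibble),
#'   `map_wt`, `map_variant`, `difference`, `site`, temperatures in
#'   reduced and Kelvin units.
#' @export
run_dynamics_workflow <- function(config = stepfold_config()) {
  systems <- .config_systems(config)
  trajs <- lapply(systems, function(pep)
    run_dmd(pep$system, pep$table, temperature = config$low_t$temperature,
            length = config$low_t$length, seed = config$seed,
            frame_interval = config$low_t$frame_interval))
  eq <- config$remd$equilibration
  rm_wt <- dplyr::mutate(rmsf(trajs$wt, systems$wt$system,
                              equilibration = eq), system = "wt")
  rm_var <- dplyr::mutate(rmsf(trajs$variant, systems$variant$system,
                               equilibration = eq), system = "variant")
  map_wt <- correlation_map(trajs$wt, systems$wt$system, equilibration = eq)
  map_var <- correlation_map(trajs$variant, systems$variant$system,
                             equilibration = eq)
  out <- list(rmsf = dplyr::bind_rows(rm_wt, rm_var),
              map_wt = map_wt, map_variant = map_var,
              difference = difference_map(map_var, map_wt),
              site = systems$variant$modified_site,
              temperature = config$low_t$temperature,
              temperature_kelvin = reduced_to_kelvin(config$low_t$temperature),
              trajectories = trajs,
              config = config)
  class(out) <- "dynamics_report"
  out
}

#' @export
print.dynamics_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$rmsf, names_from = "system",
                             values_from = "rmsf")
  near <- abs(wide$atom - x$site) <= 2
  cat("<dynamics_report> T = ", x$temperature, " (",
      round(x$temperature_kelvin), " K), modified site ", x$site, "\n",
      "  mean RMSF near site: WT ",
      sprintf("%.3f", mean(wide$wt[near])), " A, variant ",
      sprintf("%.3f", mean(wide$variant[near])), " A\n", sep = "")
  invisible(x)
}

#' A small all-atom serine-bearing fixture peptide
#'
#' Deterministic five-residue peptide (default ALA-SER-ALA-SER-GLY)
#' built entirely from internal coordinates: an ideal backbone (bond
#' lengths 1.458 / 1.525 / 1.329 Angstrom, trans peptide bonds) at the
#' given backbone dihedrals, with side chains from the packaged
#' templates. Used by the stability-scan workflow and the test-suite
#' as an all-atom input that needs no external structure file.
#'
#' @param resnames Residue names (templates must exist for each).
#' @param phi,psi Backbone dihedrals (degrees) applied to every
#'   residue (default extended: -120, 140).
#' @return A [molecular_system()].
#' @export
make_ser_peptide <- function(resnames = c("ALA", "SER", "ALA", "SER", "GLY"),
                             phi = -120, psi = 140) {
  n <- length(resnames)
  # ideal backbone via sequential internal-coordinate placement
  bb <- vector("list", n)
  N1 <- c(0, 0, 0)
  CA1 <- c(1.458, 0, 0)
  ang <- 111 * pi / 180
  C1 <- CA1 + 1.525 * c(-cos(ang), sin(ang), 0)
  for (r in seq_len(n)) {
    if (r == 1) {
      bb[[1]] <- list(N = N1, CA = CA1, C = C1)
    } else {
      p <- bb[[r - 1]]
      Nn <- .place_atom(p$N, p$CA, p$C, 1.329, 116.6, psi)
      CAn <- .place_atom(p$CA, p$C, Nn, 1.458, 121.7, 180)
      Cn <- .place_atom(p$C, Nn, CAn, 1.525, 111.0, phi)
      bb[[r]] <- list(N = Nn, CA = CAn, C = Cn)
    }
    prev <- bb[[r]]
    bb[[r]]$O <- .place_atom(prev$N, prev$CA, prev$C, 1.231, 120.5, psi + 180)
  }
  atoms <- list()
  bonds <- list()
  idx <- 0
  prevC <- NULL
  for (r in seq_len(n)) {
    tmpl <- residue_template(resnames[r])
    chi <- rep(180, tmpl$n_chi)
    side <- .build_sidechain(tmpl, bb[[r]], chi)
    local_names <- c(names(bb[[r]]), names(side))
    local_idx <- stats::setNames(idx + seq_along(local_names), local_names)
    for (nm in names(bb[[r]])) {
      atoms[[length(atoms) + 1L]] <- tibble::tibble(
        name = nm, element = substr(nm, 1, 1), charge = 0,
        mass = .mass_of(substr(nm, 1, 1)), resname = resnames[r],
        chain = "A", resno = r,
        x = bb[[r]][[nm]][1], y = bb[[r]][[nm]][2], z = bb[[r]][[nm]][3])
    }
    for (nm in names(side)) {
      s <- side[[nm]]
      atoms[[length(atoms) + 1L]] <- tibble::tibble(
        name = nm, element = s$element, charge = s$charge, mass = s$mass,
        resname = resnames[r], chain = "A", resno = r,
        x = s$pos[1], y = s$pos[2], z = s$pos[3])
    }
    for (k in seq_len(nrow(tmpl$bonds))) {
      bonds[[length(bonds) + 1L]] <- c(local_idx[[tmpl$bonds[k, 1]]],
                                       local_idx[[tmpl$bonds[k, 2]]])
    }
    if (!is.null(prevC)) {
      bonds[[length(bonds) + 1L]] <- c(prevC, local_idx[["N"]])
    }
    prevC <- local_idx[["C"]]
    idx <- idx + length(local_names)
  }
  molecular_system(dplyr::bind_rows(atoms), do.call(rbind, bonds))
}

#' Rotamer libraries for the packaged residue types
#'
#' Builds coarse backbone-dependent libraries (90 degree backbone
#' bins, 30 degree chi scans) for SER, BMAA, LYS, ALA and GLY from
#' simple threefold torsional energy functions. Coarse bins keep the
#' build fast; the BMAA library can be rebuilt at full 10 degree
#' resolution with [build_rotamer_library()].
#'
#' @param phi_increment Backbone bin width (degrees, default 90).
#' @return Named list of `rotamer_library` objects.
#' @export
standard_rotamer_set <- function(phi_increment = 90) {
  threefold <- function(n_chi) {
    function(phi, psi, chi) {
      sum(1.2 * (1 + cos(3 * chi * pi / 180)))
    }
  }
  libs <- list(
    SER = build_rotamer_library(threefold(1), n_chi = 1, residue = "SER",
                                phi_increment = phi_increment),
    BMAA = build_rotamer_library(bmaa_torsion_energy, n_chi = 2,
                                 residue = "BMAA",
                                 phi_increment = phi_increment),
    # 60 degree chi scan keeps the 4-torsion lysine build tractable
    LYS = build_rotamer_library(threefold(4), n_chi = 4, residue = "LYS",
                                phi_increment = phi_increment,
                                chi_increment = 60),
    DAP = build_rotamer_library(threefold(1), n_chi = 1, residue = "DAP",
                                phi_increment = phi_increment),
    ALA = build_rotamer_library(function(phi, psi, chi) 0, n_chi = 0,
                                residue = "ALA",
                                phi_increment = phi_increment),
    GLY = build_rotamer_library(function(phi, psi, chi) 0, n_chi = 0,
                                residue = "GLY",
                                phi_increment = phi_increment))
  libs
}
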