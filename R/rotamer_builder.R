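#' Backbone dihedral grid for a rotamer library
#'
#' Regular (phi, psi) bin centers covering (-180, 180] at a given
#' increment: a 10 degree increment yields the standard 36 x 36 = 1296
#' bins of a backbone-dependent library.
#'
#' @param increment Bin width in degrees; must divide 360.
#' @return Tibble with columns `phi`, `psi` (bin centers, degrees).
#' @export
phi_psi_grid <- function(increment = 10) {
  if (360 %% increment != 0) stop("`increment` must divide 360")
  centers <- seq(-180 + increment, 180, by = increment)
  tidyr::expand_grid(phi = centers, psi = centers)
}

#' Staggered seed conformations for the chi torsions
#'
#' The Cartesian product of the three staggered rotamer states
#' (+60, 180, -60 degrees) over `n_chi` side-chain torsions:
#' 3^n_chi seed conformations per backbone bin.
#'
#' @param n_chi Number of chi torsions (>= 0).
#' @return Matrix with one row per seed and `n_chi` columns (a single
#'   empty row when `n_chi = 0`).
#' @export
chi_seed_conformations <- function(n_chi) {
  if (n_chi < 0) stop("`n_chi` must be >= 0")
  if (n_chi == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  stag <- c(60, 180, -60)
  grid <- do.call(tidyr::expand_grid,
                  stats::setNames(rep(list(stag), n_chi),
                                  paste0("chi", seq_len(n_chi))))
  as.matrix(grid)
}

# smallest angular difference in degrees, in [-180, 180)
.ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d >= 180] <- d[d >= 180] - 360
  d
}

# wrap angles into (-180, 180]
.wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

# Boltzmann-weighted circular mean and standard deviation (degrees)
.circ_stats <- function(angles, weights) {
  w <- weights / sum(weights)
  rad <- angles * pi / 180
  s <- sum(w * sin(rad))
  c <- sum(w * cos(rad))
  mean_deg <- .wrap_angle(atan2(s, c) * 180 / pi)
  Rbar <- min(sqrt(s^2 + c^2), 1)
  sd_deg <- if (Rbar <= 0) 180 else sqrt(-2 * log(Rbar)) * 180 / pi
  c(mean = mean_deg, sd = max(sd_deg, 1e-6))
}

#' Fit the rotamers of one backbone bin
#'
#' Scans the chi torsion space of a residue on a regular grid (default
#' 30 degree increments), assigns every grid point to its nearest
#' staggered seed (per-chi angular distance), and reduces each seed's
#' Boltzmann mass at the given temperature to a rotamer record: the
#' Boltzmann-weighted circular mean and standard deviation of each chi
#' and the seed's probability (its share of the bin's total Boltzmann
#' mass).
#'
#' @param energy_fn Function `(phi, psi, chi)` returning energy in
#'   kcal/mol, where `chi` is a numeric vector of length `n_chi`.
#' @param bin Length-2 numeric: the (phi, psi) bin center (degrees).
#' @param n_chi Number of chi torsions.
#' @param chi_increment Chi scan increment in degrees; must divide 360.
#' @param temperature Boltzmann temperature k_B*T in kcal/mol
#'   (default 0.5917, i.e. 298 K).
#' @return Tibble of rotamer records: `phi`, `psi`, `rotamer` (seed
#'   label), `chi_mean_*`, `chi_sd_*`, `probability`, sorted by
#'   descending probability.
#' @export
fit_bin_rotamers <- function(energy_fn, bin, n_chi, chi_increment = 30,
                             temperature = 0.5917) {
  if (360 %% chi_increment != 0) stop("`chi_increment` must divide 360")
  if (temperature <= 0) stop("`temperature` must be positive")
  seeds <- chi_seed_conformations(n_chi)
  if (n_chi == 0) {
    return(tibble::tibble(phi = bin[1], psi = bin[2], rotamer = "none",
                          probability = 1))
  }
  centers <- seq(-180 + chi_increment, 180, by = chi_increment)
  grid <- as.matrix(do.call(tidyr::expand_grid,
                            stats::setNames(rep(list(centers), n_chi),
                                            paste0("chi", seq_len(n_chi)))))
  U <- apply(grid, 1, function(chi) energy_fn(bin[1], bin[2], chi))
  if (all(!is.finite(U))) stop("energy function non-finite on the whole grid")
  # nearest staggered seed per grid point (per-chi angular distance);
  # grid points equidistant between two seeds are assigned by a
  # consistent half-open convention so cells tile the circle evenly
  seed_idx <- apply(grid, 1, function(chi) {
    d <- .ang_diff(matrix(chi, nrow(seeds), n_chi, byrow = TRUE), seeds)
    which.min(rowSums(abs(d - 1e-6)^2))
  })
  w <- exp(-(U - min(U, na.rm = TRUE)) / temperature)
  w[!is.finite(w)] <- 0
  total <- sum(w)
  rows <- lapply(seq_len(nrow(seeds)), function(s) {
    inb <- seed_idx == s
    mass <- sum(w[inb])
    rec <- tibble::tibble(phi = bin[1], psi = bin[2],
                          rotamer = paste(seeds[s, ], collapse = ","),
                          probability = mass / total)
    for (k in seq_len(n_chi)) {
      if (mass > 0) {
        st <- .circ_stats(grid[inb, k], w[inb])
      } else {
        st <- c(mean = unname(seeds[s, k]), sd = 1e-6)
      }
      rec[[paste0("chi", k, "_mean")]] <- .wrap_angle(st[["mean"]])
      rec[[paste0("chi", k, "_sd")]] <- st[["sd"]]
    }
    rec
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$probability), ]
}

#' Build a full backbone-dependent rotamer library
#'
#' Runs [fit_bin_rotamers()] over every (phi, psi) bin of
#' [phi_psi_grid()].
#'
#' @inheritParams fit_bin_rotamers
#' @param phi_increment Backbone grid increment (degrees).
#' @param residue Residue name stored with the library.
#' @return A tibble of class `rotamer_library` (attribute `residue`,
#'   `n_chi`).
#' @export
build_rotamer_library <- function(energy_fn, n_chi, residue = "BMAA",
                                  phi_increment = 10, chi_increment = 30,
                                  temperature = 0.5917) {
  grid <- phi_psi_grid(phi_increment)
  recs <- purrr::pmap(grid, function(phi, psi) {
    fit_bin_rotamers(energy_fn, c(phi, psi), n_chi, chi_increment,
                     temperature)
  })
  out <- dplyr::bind_rows(recs)
  attr(out, "residue") <- residue
  attr(out, "n_chi") <- n_chi
  class(out) <- c("rotamer_library", class(out))
  out
}

#' Default side-chain torsional energy for BMAA
#'
#' A molecular-mechanics-style stand-in for a quantum-chemical torsion
#' surface: threefold torsional barriers on both chi angles, a gauche
#' preference on chi1, and a backbone-coupling term that mildly favours
#' extended backbones, mimicking the sterics of the beta-branched
#' methylamino group.
#'
#' @param phi,psi Backbone dihedrals (degrees).
#' @param chi Numeric vector (chi1, chi2), degrees.
#' @return Energy (kcal/mol).
#' @export
bmaa_torsion_energy <- function(phi, psi, chi) {
  d2r <- pi / 180
  u <- 1.4 * (1 + cos(3 * chi[1] * d2r)) +
       0.9 * (1 + cos(3 * chi[2] * d2r)) +
       0.35 * cos((chi[1] - 60) * d2r) +
       0.2 * cos(phi * d2r) * cos(chi[1] * d2r)
  u + 0.1 * (1 - cos((psi - 140) * d2r))
}

#' Write a rotamer library to a plain-text file
#'
#' One line per (phi bin, psi bin, rotamer): phi, psi, probability,
#' chi means, chi standard deviations; rotamers sorted by descending
#' probability within each bin. The format round-trips losslessly via
#' [read_rotlib()].
#'
#' @param records A `rotamer_library` (or compatible tibble).
#' @param path Output path.
#' @param phi_increment Backbone increment used to check grid
#'   completeness (default inferred from the data).
#' @return `path`, invisibly.
#' @export
write_rotlib <- function(records, path, phi_increment = NULL) {
  n_chi <- attr(records, "n_chi") %||%
    sum(grepl("^chi[0-9]+_mean$", names(records)))
  if (is.null(phi_increment)) {
    ph <- sort(unique(records$phi))
    phi_increment <- if (length(ph) > 1) min(diff(ph)) else 360
  }
  want <- phi_psi_grid(phi_increment)
  have <- unique(paste(records$phi, records$psi))
  missing_bins <- setdiff(paste(want$phi, want$psi), have)
  if (length(missing_bins)) {
    stop("incomplete grid: missing bins ",
         paste(utils::head(missing_bins, 5), collapse = "; "),
         if (length(missing_bins) > 5) " ...")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# rotamer library:", attr(records, "residue") %||% "?",
                   "n_chi", n_chi), con)
  mean_cols <- paste0("chi", seq_len(n_chi), "_mean")
  sd_cols <- paste0("chi", seq_len(n_chi), "_sd")
  ord <- order(records$phi, records$psi, -records$probability)
  records <- records[ord, ]
  fields <- cbind(records$phi, records$psi,
                  sprintf("%.8g", records$probability),
                  do.call(cbind, lapply(c(mean_cols, sd_cols), function(cc)
                    sprintf("%.6f", records[[cc]]))))
  writeLines(apply(fields, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a rotamer library written by [write_rotlib()]
#'
#' @param path File path.
#' @return A `rotamer_library` tibble.
#' @export
read_rotlib <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  n_chi <- as.integer(hdr[length(hdr)])
  residue <- hdr[4]
  body <- do.call(rbind, strsplit(lines[-1], " "))
  out <- tibble::tibble(phi = as.numeric(body[, 1]),
                        psi = as.numeric(body[, 2]),
                        probability = as.numeric(body[, 3]))
  for (k in seq_len(n_chi)) {
    out[[paste0("chi", k, "_mean")]] <- as.numeric(body[, 3 + k])
    out[[paste0("chi", k, "_sd")]] <- as.numeric(body[, 3 + n_chi + k])
  }
  out$rotamer <- apply(as.matrix(out[, paste0("chi", seq_len(n_chi), "_mean"),
                                     drop = FALSE]), 1,
                       function(m) paste(.nearest_stagger(m), collapse = ","))
  attr(out, "residue") <- residue
  attr(out, "n_chi") <- n_chi
  class(out) <- c("rotamer_library", class(out))
  out
}

.nearest_stagger <- function(chis) {
  stag <- c(60, 180, -60)
  vapply(chis, function(a) stag[which.min(abs(.ang_diff(a, stag)))], numeric(1))
}

#' Overwrite library spreads with a surrogate residue's values
#'
#' Unbranched positively charged residues behave alike, so a library
#' for a non-canonical residue can borrow the chi-angle standard
#' deviations and reference energy of lysine. The packaged table is a
#' synthetic stand-in with representative magnitudes (it is not an
#' extract of any published library); it supplies per-chi standard
#' deviations, and the reference energy is attached as an attribute.
#'
#' @param library A `rotamer_library`.
#' @param surrogate Name of the packaged surrogate table
#'   (default `"LYS"`).
#' @return The library with replaced `chi*_sd` columns and a
#'   `reference_energy` attribute.
#' @export
apply_surrogate_spreads <- function(library, surrogate = "LYS") {
  path <- system.file("extdata",
                      paste0(tolower(surrogate), "_spreads_synthetic.txt"),
                      package = "stepfold")
  if (!nzchar(path)) stop("no packaged surrogate table for ", surrogate)
  tab <- utils::read.table(path, header = TRUE)
  n_chi <- attr(library, "n_chi")
  for (k in seq_len(n_chi)) {
    col <- paste0("chi", k, "_sd")
    library[[col]] <- tab$sd[pmin(k, nrow(tab))]
  }
  attr(library, "reference_energy") <- tab$reference_energy[1]
  attr(library, "surrogate") <- surrogate
  library
}
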