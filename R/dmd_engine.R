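#' Time to the next wall crossing of a ballistic pair
#'
#' Particles in discrete molecular dynamics move ballistically between
#' events, so the next interaction of a pair is the smallest positive
#' root of \eqn{|r + w t| = R} consistent with the crossing direction.
#'
#' @param rel_pos Relative position vector (Angstrom).
#' @param rel_vel Relative velocity vector.
#' @param wall_radius Wall radius R (Angstrom, positive).
#' @param direction `"inward"` (pair approaching a wall inside its
#'   current shell) or `"outward"`.
#' @return The event time, or `NA` if the pair never reaches the wall.
#' @export
next_event_time <- function(rel_pos, rel_vel, wall_radius,
                            direction = c("inward", "outward")) {
  direction <- match.arg(direction)
  if (!is.numeric(wall_radius) || wall_radius <= 0) {
    stop("`wall_radius` must be positive")
  }
  r2 <- sum(rel_pos^2)
  w2 <- sum(rel_vel^2)
  b <- sum(rel_pos * rel_vel)
  if (w2 == 0) return(NA_real_)
  disc <- b^2 - w2 * (r2 - wall_radius^2)
  if (direction == "inward") {
    if (b >= 0 || disc <= 0) return(NA_real_)
    t <- (-b - sqrt(disc)) / w2
  } else {
    if (disc < 0) return(NA_real_)
    t <- (-b + sqrt(disc)) / w2
  }
  if (t <= 0) NA_real_ else t
}

#' Resolve a pair event at a potential step
#'
#' At a wall the relative velocity component along the line of centers
#' either carries the pair across the step (if the radial kinetic
#' energy in the pair frame exceeds the step height `dU`, with total
#' energy conserved exactly) or reflects it elastically. Momentum is
#' exchanged along the line of centers only, so total momentum is
#' conserved exactly in both cases.
#'
#' @param masses Length-2 vector of masses (amu).
#' @param rel_pos Relative position at contact (on the wall).
#' @param velocities 2 x 3 matrix of the two particles' velocities.
#' @param dU Potential step height crossed in the direction of motion
#'   (kcal/mol); `Inf` for a hard wall.
#' @return List with `velocities` (2 x 3) and `crossed` (logical).
#' @export
resolve_step_crossing <- function(masses, rel_pos, velocities, dU) {
  stopifnot(length(masses) == 2, nrow(velocities) == 2)
  R <- sqrt(sum(rel_pos^2))
  nvec <- rel_pos / R
  w <- velocities[1, ] - velocities[2, ]
  vr <- sum(w * nvec)
  mu <- masses[1] * masses[2] / sum(masses)
  ek_rad <- 0.5 * mu * vr^2
  if (is.finite(dU) && ek_rad > dU) {
    crossed <- TRUE
    vr_new <- sign(vr) * sqrt(vr^2 - 2 * dU / mu)
  } else {
    crossed <- FALSE
    vr_new <- -vr
  }
  imp <- mu * (vr_new - vr)
  velocities[1, ] <- velocities[1, ] + imp * nvec / masses[1]
  velocities[2, ] <- velocities[2, ] - imp * nvec / masses[2]
  list(velocities = velocities, crossed = crossed)
}

#' Maxwell-Boltzmann velocities
#'
#' Draws velocities at reduced temperature `temperature` (k_B = 1, so
#' temperature carries energy units, kcal/mol) and removes the
#' center-of-mass drift.
#'
#' @param masses Atom masses (amu).
#' @param temperature Reduced temperature (kcal/mol).
#' @return n x 3 velocity matrix.
#' @export
maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(temperature / masses)
  mom <- colSums(v * masses) / sum(masses)
  sweep(v, 2, mom)
}

#' Run an event-driven DMD simulation
#'
#' Event-ordered dynamics over the step potentials and square-well
#' constraints of `table`. With the thermostat off, total energy is
#' conserved to floating-point accuracy; with the Andersen-style
#' thermostat on, ghost collisions redraw single-atom velocities from
#' the Maxwell-Boltzmann distribution at Poisson-distributed times, so
#' the velocity distribution relaxes to the set temperature.
#'
#' Reduced units throughout: energy kcal/mol, length Angstrom, mass
#' amu, k_B = 1; one reduced time unit is about 48.9 fs.
#'
#' @param system A [molecular_system()] (or n x 3 coordinate matrix
#'   with `masses` supplied via `state`).
#' @param table An [interaction_table()] covering the system.
#' @param temperature Reduced temperature (kcal/mol).
#' @param length Simulation length (reduced time units).
#' @param seed Integer seed; runs are bitwise reproducible.
#' @param thermostat `"on"` or `"off"`.
#' @param frame_interval Frame recording interval (reduced time units).
#' @param thermo_rate Total ghost-collision rate (events per reduced
#'   time unit) when the thermostat is on.
#' @param state Optional list with `positions` and `velocities` to
#'   continue a previous run (used by replica exchange); when given,
#'   `seed` is not re-applied unless non-NULL.
#' @param max_events Safety cap on the number of events.
#' @return A `dmd_trajectory`: frame times, coordinates, potential and
#'   kinetic energies, plus the final state.
#' @export
run_dmd <- function(system, table, temperature, length, seed = NULL,
                    thermostat = c("on", "off"), frame_interval = 1,
                    thermo_rate = NULL, state = NULL, max_events = 5e7) {
  thermostat <- match.arg(thermostat)
  if (length <= 0) stop("`length` must be positive")
  coords <- system_coords(system)
  masses <- system$atoms$mass
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) {
    state <- list(positions = coords,
                  velocities = maxwell_velocities(masses, temperature))
  }
  if (is.null(thermo_rate)) thermo_rate <- 0.5 * nrow(coords)
  pairs <- .compile_pairs(table)
  res <- .dmd_run_cpp(state$positions, state$velocities, masses, pairs,
                      length, frame_interval,
                      if (thermostat == "on") temperature else -1,
                      thermo_rate, max_events)
  structure(list(
    time = res$time, coords = res$coords, pe = res$pe, ke = res$ke,
    temperature = temperature,
    state = list(positions = res$final_positions,
                 velocities = res$final_velocities),
    n_events = res$n_events,
    final_pe = res$final_pe, recomputed_pe = res$recomputed_pe,
    metadata = list(seed = seed, thermostat = thermostat,
                    frame_interval = frame_interval, length = length)),
    class = "dmd_trajectory")
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat("<dmd_trajectory> ", length(x$time), " frames, ",
      dim(x$coords)[2], " atoms, T = ", format(x$temperature, digits = 4),
      ", ", format(x$n_events, big.mark = ","), " events\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `dmd_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$time)

#' Extract one frame's coordinates
#' @param traj A `dmd_trajectory`.
#' @param frame Frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, frame) {
  traj$coords[frame, , , drop = TRUE]
}

#' Per-frame energy table of a trajectory
#'
#' @param traj A `dmd_trajectory`.
#' @return Tibble with columns `time`, `pe`, `ke`, `temperature`.
#' @export
trajectory_energies <- function(traj) {
  tibble::tibble(time = traj$time, pe = traj$pe, ke = traj$ke,
                 temperature = traj$temperature)
}

#' Write a trajectory as a multi-model PDB plus an energy table
#'
#' @param traj A `dmd_trajectory`.
#' @param system The [molecular_system()] the trajectory was run on
#'   (provides atom names and residue numbering).
#' @param path Output PDB path; the energy table is written next to it
#'   with extension `.energies.txt`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, system, path) {
  a <- system$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     seq_len(nrow(a)), a$name, substr(a$resname, 1, 3),
                     a$chain, a$resno, xyz[, 1], xyz[, 2], xyz[, 3],
                     a$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  etab <- trajectory_energies(traj)
  utils::write.table(etab, sub("\\.pdb$", "", path) |> paste0(".energies.txt"),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
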