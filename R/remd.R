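#' Convert a reduced DMD temperature to Kelvin
#'
#' Simulation temperatures are expressed in kcal/(mol k_B); dividing by
#' the Boltzmann constant k_B = 0.0019872 kcal/(mol K) gives an
#' approximate physical temperature. Reduced temperatures in simplified
#' force fields do not equate exactly to physical temperatures, so the
#' conversion is for reporting only.
#'
#' @param t_red Reduced temperature(s), kcal/(mol k_B), positive.
#' @return Temperature(s) in Kelvin.
#' @examples
#' reduced_to_kelvin(0.60)  # ~302 K
#' @export
reduced_to_kelvin <- function(t_red) {
  if (any(t_red <= 0)) stop("reduced temperature must be positive")
  t_red / 0.0019872
}

#' The standard 16-rung melting ladder
#'
#' The package's default replica ladder for melting runs: sixteen
#' reduced temperatures from 0.48 (~242 K) to 0.71 (~357 K).
#'
#' @return Numeric vector of 16 reduced temperatures.
#' @export
melting_ladder <- function() {
  c(0.48, 0.495, 0.51, 0.525, 0.54, 0.555, 0.57, 0.585,
    0.60, 0.615, 0.63, 0.645, 0.65, 0.67, 0.69, 0.71)
}

#' Replica ladder for temperature replica exchange
#'
#' @param temperatures Strictly ascending reduced temperatures (>= 2).
#' @param exchange_interval Simulation time between neighbour exchange
#'   attempts (reduced time units). The conventional 50 ps exchange
#'   interval corresponds to roughly 1000 reduced time units (one
#'   reduced time unit is about 48.9 fs); melting runs at desk scale
#'   use much shorter segments.
#' @return An object of class `replica_ladder`.
#' @export
replica_ladder <- function(temperatures = melting_ladder(),
                           exchange_interval = 50) {
  if (length(temperatures) < 2) stop("a ladder needs at least 2 temperatures")
  if (any(diff(temperatures) <= 0)) {
    stop("ladder temperatures must be strictly ascending")
  }
  if (exchange_interval <= 0) stop("`exchange_interval` must be positive")
  structure(list(temperatures = as.numeric(temperatures),
                 exchange_interval = exchange_interval),
            class = "replica_ladder")
}

#' @export
print.replica_ladder <- function(x, ...) {
  cat("<replica_ladder> ", length(x$temperatures), " rungs, T = ",
      format(min(x$temperatures), digits = 3), " .. ",
      format(max(x$temperatures), digits = 3), ", exchange every ",
      x$exchange_interval, " time units\n", sep = "")
  invisible(x)
}

#' Metropolis acceptance for a replica temperature swap
#'
#' Neighbouring replicas exchange temperatures with probability
#' \eqn{\min(1, e^{\Delta})}, \eqn{\Delta = (1/T_i - 1/T_j)(E_i - E_j)}
#' with the pair ordered so that \eqn{T_i < T_j}. This preserves the
#' product of the two canonical distributions (detailed balance).
#'
#' @param E_i,E_j Replica potential energies (kcal/mol).
#' @param T_i,T_j Reduced temperatures (positive, distinct).
#' @param u Uniform(0,1) draw.
#' @return Logical: accept the swap?
#' @export
metropolis_swap <- function(E_i, E_j, T_i, T_j, u) {
  if (T_i <= 0 || T_j <= 0) stop("temperatures must be positive")
  if (T_i == T_j) stop("degenerate pair: equal temperatures")
  if (T_i > T_j) {  # order so that T_i is the colder rung
    tmp <- T_i; T_i <- T_j; T_j <- tmp
    tmp <- E_i; E_i <- E_j; E_j <- tmp
  }
  delta <- (1 / T_i - 1 / T_j) * (E_i - E_j)
  u < min(1, exp(delta))
}

#' Run temperature replica-exchange DMD
#'
#' Runs one replica per ladder rung, attempting Metropolis swaps
#' between temperature-neighbouring replicas every
#' `exchange_interval` time units with alternating even/odd pairing.
#' On an accepted swap the replicas exchange temperatures and their
#' velocities are rescaled by \eqn{\sqrt{T_{new}/T_{old}}}. Output
#' trajectories are labelled by temperature rung (not by replica), as
#' WHAM consumes them. Each replica draws from its own seeded RNG
#' stream; swap draws use a separate stream, so runs are fully
#' reproducible.
#'
#' @param system A [molecular_system()].
#' @param table An [interaction_table()].
#' @param ladder A [replica_ladder()].
#' @param length Total simulation time per replica (reduced units).
#' @param seed Master integer seed.
#' @param frame_interval Frame recording interval.
#' @param equilibration Fraction of each rung's frames discarded from
#'   the front when analysed downstream (stored in metadata).
#' @param progress Print a line per segment?
#' @return List of class `remd_result`: `trajectories` (one
#'   `dmd_trajectory` per rung, temperature-labelled), `exchange_log`
#'   (tibble of attempts), `occupancy` (tibble of replica-to-rung
#'   assignment over time), `acceptance_rate`.
#' @export
run_remd <- function(system, table, ladder, length, seed = 1,
                     frame_interval = 1, equilibration = 0.2,
                     progress = FALSE) {
  stopifnot(inherits(ladder, "replica_ladder"))
  temps <- ladder$temperatures
  n_rep <- base::length(temps)
  n_seg <- max(1L, floor(length / ladder$exchange_interval))
  pairs <- .compile_pairs(table)
  masses <- system$atoms$mass
  coords <- system_coords(system)

  # pre-drawn sub-seeds: one stream per replica, one for swaps
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2^31 - 2, n_rep * n_seg), n_rep, n_seg)
  swap_seeds <- sample.int(2^31 - 2, n_seg)

  rung_of <- seq_len(n_rep)          # replica -> rung
  states <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(rep_seeds[r, 1])
    states[[r]] <- list(positions = coords,
                        velocities = maxwell_velocities(masses, temps[r]))
  }
  rung_frames <- lapply(seq_len(n_rep), function(k)
    list(time = NULL, pe = NULL, ke = NULL, coords = NULL))
  log_rows <- list()
  occ_rows <- list()
  seg_energy <- numeric(n_rep)

  for (s in seq_len(n_seg)) {
    t0 <- (s - 1) * ladder$exchange_interval
    for (r in seq_len(n_rep)) {
      k <- rung_of[r]
      set.seed(rep_seeds[r, s])
      res <- .dmd_run_cpp(states[[r]]$positions, states[[r]]$velocities,
                          masses, pairs, ladder$exchange_interval,
                          frame_interval, temps[k], 0.5 * nrow(coords), 5e7)
      states[[r]] <- list(positions = res$final_positions,
                          velocities = res$final_velocities)
      seg_energy[r] <- res$final_pe
      keep <- if (s == 1) seq_along(res$time) else -1L  # drop duplicate t0 frame
      rung_frames[[k]]$time <- c(rung_frames[[k]]$time, t0 + res$time[keep])
      rung_frames[[k]]$pe <- c(rung_frames[[k]]$pe, res$pe[keep])
      rung_frames[[k]]$ke <- c(rung_frames[[k]]$ke, res$ke[keep])
      rung_frames[[k]]$coords <- c(rung_frames[[k]]$coords,
                                   list(res$coords[keep, , , drop = FALSE]))
    }
    occ_rows[[s]] <- tibble::tibble(time = t0 + ladder$exchange_interval,
                                    replica = seq_len(n_rep),
                                    rung = rung_of)
    # alternating-parity neighbour swaps
    set.seed(swap_seeds[s])
    start <- if (s %% 2 == 1) 1L else 2L
    ks <- if (start > n_rep - 1L) integer(0) else seq(start, n_rep - 1L, by = 2L)
    for (k in ks) {
      ri <- which(rung_of == k)
      rj <- which(rung_of == k + 1L)
      u <- stats::runif(1)
      acc <- metropolis_swap(seg_energy[ri], seg_energy[rj],
                             temps[k], temps[k + 1L], u)
      log_rows[[base::length(log_rows) + 1L]] <- tibble::tibble(
        time = t0 + ladder$exchange_interval, rung_lo = k,
        replica_lo = ri, replica_hi = rj,
        E_lo = seg_energy[ri], E_hi = seg_energy[rj], accepted = acc)
      if (acc) {
        sc_i <- sqrt(temps[k + 1L] / temps[k])
        states[[ri]]$velocities <- states[[ri]]$velocities * sc_i
        states[[rj]]$velocities <- states[[rj]]$velocities / sc_i
        rung_of[ri] <- k + 1L
        rung_of[rj] <- k
      }
    }
    if (progress) message("segment ", s, "/", n_seg)
  }

  trajectories <- lapply(seq_len(n_rep), function(k) {
    f <- rung_frames[[k]]
    co <- do.call(function(...) abind_frames(list(...)), f$coords)
    structure(list(time = f$time, coords = co, pe = f$pe, ke = f$ke,
                   temperature = temps[k], state = NULL,
                   n_events = NA_real_,
                   metadata = list(seed = seed, rung = k,
                                   equilibration = equilibration,
                                   frame_interval = frame_interval)),
              class = "dmd_trajectory")
  })
  xlog <- dplyr::bind_rows(log_rows)
  structure(list(trajectories = trajectories,
                 exchange_log = xlog,
                 occupancy = dplyr::bind_rows(occ_rows),
                 acceptance_rate = if (nrow(xlog)) mean(xlog$accepted) else NA_real_,
                 ladder = ladder),
            class = "remd_result")
}

# Bind frame blocks (n_f x n_atoms x 3 arrays) along the first axis.
abind_frames <- function(blocks) {
  blocks <- blocks[vapply(blocks, function(b) length(dim(b)) == 3 && dim(b)[1] > 0,
                          logical(1))]
  n_at <- dim(blocks[[1]])[2]
  total <- sum(vapply(blocks, function(b) dim(b)[1], numeric(1)))
  out <- array(NA_real_, c(total, n_at, 3))
  at <- 0
  for (b in blocks) {
    nf <- dim(b)[1]
    out[at + seq_len(nf), , ] <- b
    at <- at + nf
  }
  out
}

#' @export
print.remd_result <- function(x, ...) {
  cat("<remd_result> ", base::length(x$trajectories), " rungs, ",
      nrow(x$exchange_log), " swap attempts, acceptance ",
      format(x$acceptance_rate, digits = 3), "\n", sep = "")
  invisible(x)
}
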