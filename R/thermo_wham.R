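logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Build a shared-bin energy histogram set from multi-temperature runs
#'
#' @param energies List of numeric energy samples, one per temperature
#'   (e.g. the equilibrated potential energies of each REMD rung), or a
#'   `remd_result` (equilibration fraction is then discarded from the
#'   front of each rung).
#' @param temperatures Reduced temperatures, one per element.
#' @param bin_width Histogram bin width (kcal/mol); default uses the
#'   Freedman-Diaconis rule on the pooled sample.
#' @return Object of class `energy_histogram_set`: shared `edges`,
#'   per-temperature `counts` matrix, `n_samples`, `temperatures`.
#'   Warns when neighbouring temperatures' occupied bins do not
#'   overlap (WHAM then cannot connect them).
#' @export
energy_histograms <- function(energies, temperatures = NULL, bin_width = NULL) {
  if (inherits(energies, "remd_result")) {
    eq <- energies$trajectories[[1]]$metadata$equilibration %||% 0.2
    temperatures <- vapply(energies$trajectories, `[[`, numeric(1), "temperature")
    energies <- lapply(energies$trajectories, function(tr) {
      drop <- floor(eq * length(tr$pe))
      tr$pe[(drop + 1):length(tr$pe)]
    })
  }
  stopifnot(length(energies) == length(temperatures))
  pooled <- unlist(energies)
  if (is.null(bin_width)) {
    iqr <- stats::IQR(pooled)
    bin_width <- if (iqr > 0) 2 * iqr / length(pooled)^(1 / 3) else 1
  }
  lo <- min(pooled) - bin_width / 2
  hi <- max(pooled) + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (utils::tail(edges, 1) < hi) edges <- c(edges, utils::tail(edges, 1) + bin_width)
  counts <- vapply(energies, function(e)
    graphics::hist(e, breaks = edges, plot = FALSE)$counts,
    numeric(length(edges) - 1))
  counts <- t(counts)  # temperature x bin
  ord <- order(temperatures)
  counts <- counts[ord, , drop = FALSE]
  temperatures <- temperatures[ord]
  for (k in seq_len(length(temperatures) - 1)) {
    if (!any(counts[k, ] > 0 & counts[k + 1, ] > 0)) {
      warning("occupied bins of temperatures ", temperatures[k], " and ",
              temperatures[k + 1], " do not overlap; WHAM may be unreliable")
    }
  }
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 n_samples = rowSums(counts),
                 temperatures = temperatures),
            class = "energy_histogram_set")
}

#' @export
print.energy_histogram_set <- function(x, ...) {
  cat("<energy_histogram_set> ", length(x$temperatures), " temperatures, ",
      ncol(x$counts), " bins, ", sum(x$counts), " samples\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted histogram analysis: density of states from energy histograms
#'
#' Self-consistent estimation of the density of states g(E) from
#' overlapping energy histograms collected at multiple temperatures:
#' \deqn{g(E_m) = \frac{\sum_k n_k(E_m)}{\sum_k N_k e^{f_k - E_m/T_k}},
#'       \qquad e^{-f_k} = \sum_m g(E_m) e^{-E_m/T_k},}
#' iterated in log space until the largest change in any dimensionless
#' free energy f_k falls below `tol`. The recovered ln g is normalized
#' to a maximum of 0 (g is defined up to a constant).
#'
#' @param histset An [energy_histograms()] set.
#' @param tol Convergence threshold on max |delta f_k|.
#' @param max_iter Iteration cap; reaching it raises a warning with the
#'   residual.
#' @return Object of class `thermo_profile`: `energy` (occupied bin
#'   centers), `ln_g`, `f` (per-temperature dimensionless free
#'   energies), `temperatures`, plus convergence diagnostics.
#' @export
wham <- function(histset, tol = 1e-7, max_iter = 1e5) {
  stopifnot(inherits(histset, "energy_histogram_set"))
  occupied <- colSums(histset$counts) > 0
  if (!any(occupied)) stop("no occupied bins")
  # connectivity of the occupied support across temperatures
  E <- histset$centers[occupied]
  n_km <- histset$counts[, occupied, drop = FALSE]
  Tk <- histset$temperatures
  Nk <- histset$n_samples
  if (length(Tk) > 1 && !.support_connected(n_km)) {
    stop("disconnected support: histograms do not overlap into one component")
  }
  ln_total <- log(colSums(n_km))
  f <- rep(0, length(Tk))
  for (it in seq_len(max_iter)) {
    # ln denominator_m = logsumexp_k [ ln N_k + f_k - E_m / T_k ]
    mat <- outer(log(Nk) + f, rep(1, length(E))) -
      outer(1 / Tk, E)
    ln_den <- apply(mat, 2, logsumexp)
    ln_g <- ln_total - ln_den
    f_new <- -vapply(seq_along(Tk),
                     function(k) logsumexp(ln_g - E / Tk[k]), numeric(1))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
  }
  if (resid >= tol) {
    warning("WHAM did not converge in ", max_iter,
            " iterations (residual ", format(resid, digits = 3), ")")
  }
  ln_g <- ln_g - max(ln_g)
  structure(list(energy = E, ln_g = ln_g, f = f, temperatures = Tk,
                 iterations = it, residual = resid,
                 bin_width = diff(histset$edges[1:2])),
            class = "thermo_profile")
}

# occupied-bin overlap graph over temperatures must form one component
.support_connected <- function(n_km) {
  K <- nrow(n_km)
  adj <- matrix(FALSE, K, K)
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) {
      adj[a, b] <- adj[b, a] <- any(n_km[a, ] > 0 & n_km[b, ] > 0)
    }
  }
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(apply(adj[frontier, , drop = FALSE], 2, any)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == K
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat("<thermo_profile> ", length(x$energy), " energy levels, ",
      length(x$temperatures), " temperatures, converged in ",
      x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Specific heat from a density of states
#'
#' Canonical averages over the recovered density of states give
#' \eqn{C_V(T) = (\langle E^2\rangle_T - \langle E\rangle_T^2)/(k_B T^2)}
#' in units of k_B (k_B = 1 in reduced units). Computed with
#' log-sum-exp stabilization so deep low-temperature weights do not
#' underflow.
#'
#' @param profile A `thermo_profile` from [wham()].
#' @param T_grid Reduced temperatures at which to evaluate.
#' @return Tibble with columns `temperature`, `cv`, `mean_energy`.
#' @export
specific_heat <- function(profile, T_grid) {
  stopifnot(inherits(profile, "thermo_profile"))
  if (any(T_grid <= 0)) stop("temperatures must be positive")
  E <- profile$energy
  ln_g <- profile$ln_g
  out <- vapply(T_grid, function(T) {
    lw <- ln_g - E / T
    A <- logsumexp(lw)
    w <- exp(lw - A)
    m1 <- sum(w * E)
    m2 <- sum(w * E^2)
    c(max(m2 - m1^2, 0) / T^2, m1)
  }, numeric(2))
  tibble::tibble(temperature = T_grid, cv = out[1, ], mean_energy = out[2, ])
}

#' Detect melting events as peaks in a specific-heat curve
#'
#' Local maxima of C_V(T) with topographic prominence at least
#' `min_prominence` times the global maximum mark cooperative melting
#' events; the global maximum is the major melting transition.
#'
#' @param cv_curve Tibble with columns `temperature` and `cv` (as from
#'   [specific_heat()]), on an ascending temperature grid of >= 3
#'   points.
#' @param min_prominence Prominence threshold as a fraction of the
#'   global maximum (default 0.1).
#' @return Tibble of peaks (`temperature`, `cv`, `prominence`,
#'   `major`), sorted by temperature; zero rows for a flat curve.
#' @export
find_melting_events <- function(cv_curve, min_prominence = 0.1) {
  stopifnot(all(c("temperature", "cv") %in% names(cv_curve)))
  y <- cv_curve$cv
  x <- cv_curve$temperature
  n <- length(y)
  if (n < 3) stop("need at least 3 grid points")
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1)) {
    return(tibble::tibble(temperature = numeric(), cv = numeric(),
                          prominence = numeric(), major = logical()))
  }
  is_peak <- which(diff(sign(diff(y))) == -2) + 1L
  # plateau-tolerant ends
  if (length(is_peak) == 0) is_peak <- which.max(y)
  prom <- vapply(is_peak, function(p) {
    left <- if (p > 1) seq_len(p - 1) else integer(0)
    right <- if (p < n) (p + 1):n else integer(0)
    higher_l <- left[y[left] > y[p]]
    higher_r <- right[y[right] > y[p]]
    left_min <- if (length(left) == 0) y[p]
                else if (length(higher_l)) min(y[(max(higher_l)):(p - 1)])
                else min(y[left])
    right_min <- if (length(right) == 0) y[p]
                 else if (length(higher_r)) min(y[(p + 1):(min(higher_r))])
                 else min(y[right])
    y[p] - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence * max(y)
  # the global maximum always survives
  keep[which.max(y[is_peak])] <- TRUE
  peaks <- tibble::tibble(temperature = x[is_peak][keep],
                          cv = y[is_peak][keep],
                          prominence = prom[keep])
  peaks <- peaks[order(peaks$temperature), ]
  peaks$major <- peaks$cv == max(peaks$cv)
  peaks
}

#' Potential-energy histogram of a single-temperature trajectory
#'
#' Discards an initial equilibration fraction, then bins the remaining
#' per-frame potential energies into a normalized histogram and
#' reports the modal bin center (the peak of the energy distribution).
#'
#' @param traj A `dmd_trajectory` (or numeric vector of energies).
#' @param bins Number of bins (default 30) or a vector of bin edges.
#' @param equilibration Fraction of frames discarded from the front
#'   (default 0.2).
#' @return List of class `pe_histogram`: tibble `histogram` (columns
#'   `energy`, `density`), `mode` (modal bin center), `n`.
#' @export
pe_histogram <- function(traj, bins = 30, equilibration = 0.2) {
  pe <- if (inherits(traj, "dmd_trajectory")) traj$pe else as.numeric(traj)
  if (length(pe) < 1) stop("empty trajectory")
  drop <- floor(equilibration * length(pe))
  pe <- pe[(drop + 1):length(pe)]
  if (length(unique(pe)) == 1) {
    hist_tbl <- tibble::tibble(energy = pe[1], density = 1)
    return(structure(list(histogram = hist_tbl, mode = pe[1], n = length(pe)),
                     class = "pe_histogram"))
  }
  h <- graphics::hist(pe, breaks = bins, plot = FALSE)
  dens <- h$counts / sum(h$counts)
  structure(list(histogram = tibble::tibble(energy = h$mids, density = dens),
                 mode = h$mids[which.max(h$counts)],
                 n = length(pe)),
            class = "pe_histogram")
}

#' @export
print.pe_histogram <- function(x, ...) {
  cat("<pe_histogram> n = ", x$n, ", modal energy = ",
      format(x$mode, digits = 5), " kcal/mol\n", sep = "")
  invisible(x)
}
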