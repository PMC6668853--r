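test_that("reduced temperatures convert to the standard Kelvin values", {
  expect_equal(round(reduced_to_kelvin(0.48)), 242)
  expect_equal(round(reduced_to_kelvin(0.60)), 302)
  expect_equal(round(reduced_to_kelvin(0.71)), 357)
  expect_equal(reduced_to_kelvin(0.0019872), 1)
  expect_error(reduced_to_kelvin(-1), "positive")
})

test_that("the standard melting ladder has 16 ascending rungs", {
  tt <- melting_ladder()
  expect_length(tt, 16)
  expect_true(all(diff(tt) > 0))
  expect_equal(range(tt), c(0.48, 0.71))
  expect_error(replica_ladder(c(0.5, 0.5)), "ascending")
  expect_error(replica_ladder(0.5), "at least 2")
})

test_that("Metropolis swap rule matches its closed form", {
  # equal energies always accepted
  expect_true(metropolis_swap(-10, -10, 0.5, 0.6, u = 0.999999))
  # hot replica at lower energy: delta >= 0, always accepted
  expect_true(metropolis_swap(-5, -8, 0.5, 0.6, u = 0.999999))
  # argument order must not matter (pair is sorted internally)
  expect_true(metropolis_swap(-8, -5, 0.6, 0.5, u = 0.999999))
  expect_error(metropolis_swap(0, 0, 0.5, 0.5, 0.5), "degenerate")
  # fixed delta = -1: acceptance estimates exp(-1)
  dT <- 1 / 0.5 - 1 / 0.6   # delta = dT * dE = -1 => dE = -1 / dT
  dE <- -1 / dT
  set.seed(1)
  u <- runif(1e5)
  acc <- mean(vapply(u, function(uu)
    metropolis_swap(0, -dE, 0.5, 0.6, uu), logical(1)))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("swap rule satisfies detailed balance on a two-state system", {
  T1 <- 0.5; T2 <- 0.7
  for (pair in list(c(-3, -1), c(-1, -3), c(2, 5))) {
    E1 <- pair[1]; E2 <- pair[2]
    d <- (1 / T1 - 1 / T2) * (E1 - E2)
    p_fwd <- min(1, exp(d))
    p_bwd <- min(1, exp(-d))
    # pi(E1,T1) pi(E2,T2) p_fwd == pi(E2,T1) pi(E1,T2) p_bwd
    lhs <- exp(-E1 / T1 - E2 / T2) * p_fwd
    rhs <- exp(-E2 / T1 - E1 / T2) * p_bwd
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("REMD keeps a replica-temperature bijection and neighbour moves", {
  pep <- make_go_peptide(n_residues = 8, seed = 1)
  ladder <- replica_ladder(c(0.5, 0.6, 0.7, 0.8), exchange_interval = 10)
  res <- run_remd(pep$system, pep$table, ladder, length = 200, seed = 2)
  occ <- res$occupancy
  for (tp in unique(occ$time)) {
    expect_setequal(occ$rung[occ$time == tp], 1:4)
  }
  # replica paths move at most one rung per attempt
  for (r in 1:4) {
    path <- occ$rung[occ$replica == r]
    expect_true(all(abs(diff(path)) <= 1))
  }
  expect_s3_class(res$exchange_log, "tbl_df")
})

test_that("zero-interaction replicas always exchange", {
  # free beads: potential energy identically zero at every attempt
  sys <- free_bead_system(3)
  tab <- interaction_table(
    potentials = list(hard = step_potential(2, 0)),
    nonbonded = tibble::tibble(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                               pot = "hard"),
    constraints = NULL)
  ladder <- replica_ladder(c(0.5, 0.7), exchange_interval = 5)
  res <- run_remd(sys, tab, ladder, length = 100, seed = 3)
  expect_equal(res$acceptance_rate, 1.0)
})

test_that("REMD per-temperature distributions match single-T sampling", {
  # barrier-free toy (one square well on the 1-4 pair of a 4-bead
  # chain) so both samplers reach equilibrium quickly; detailed
  # balance then demands identical per-temperature distributions
  sys <- free_bead_system(4, spacing = 3.8)
  cons <- bonded_constraints(sys)
  cons <- cons[cons$type == "bond", ]
  tab <- interaction_table(
    potentials = list(hard = step_potential(3.0, 0),
                      well = step_potential(c(3.0, 5.0, 8.0), c(0, -1, 0))),
    nonbonded = tibble::tibble(i = c(1L, 2L, 1L), j = c(3L, 4L, 4L),
                               pot = c("hard", "hard", "well")),
    constraints = cons)
  ladder <- replica_ladder(c(0.5, 0.7), exchange_interval = 20)
  res <- run_remd(sys, tab, ladder, length = 20000, seed = 4)
  keep <- seq(2001, 20000, by = 2)
  for (k in 1:2) {
    single <- run_dmd(sys, tab, ladder$temperatures[k], 20000, seed = 40 + k)
    # PE here is two-valued (well occupied or not): compare occupancies
    p_remd <- mean(res$trajectories[[k]]$pe[keep] < -0.5)
    p_single <- mean(single$pe[keep] < -0.5)
    se <- sqrt(p_single * (1 - p_single) / (length(keep) / 10))
    expect_lt(abs(p_remd - p_single), 4 * se + 0.01)
  }
})
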