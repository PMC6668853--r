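test_that("head-on hard-core contact happens at the closed-form time", {
  t <- next_event_time(c(2, 0, 0), c(-1, 0, 0), 1, "inward")
  expect_equal(t, 1)
  expect_true(is.na(next_event_time(c(2, 0, 0), c(1, 0, 0), 1, "inward")))
  expect_error(next_event_time(c(1, 0, 0), c(1, 0, 0), -1), "positive")
})

test_that("3-D event times agree with a dense trajectory scan", {
  set.seed(11)
  for (k in 1:20) {
    r0 <- rnorm(3, sd = 3)
    v <- rnorm(3)
    R <- runif(1, 0.5, 4)
    tg <- seq(1e-6, 20, by = 1e-6)
    d <- sqrt((r0[1] + v[1] * tg)^2 + (r0[2] + v[2] * tg)^2 +
                (r0[3] + v[3] * tg)^2)
    for (dir in c("inward", "outward")) {
      t_pred <- next_event_time(r0, v, R, dir)
      crossing <- if (dir == "inward") {
        which(d < R & sqrt(sum(r0^2)) > R)
      } else {
        which(d > R & sqrt(sum(r0^2)) < R)
      }
      t_scan <- if (length(crossing)) tg[crossing[1]] else NA_real_
      if (is.na(t_scan)) {
        # scan found no crossing within its horizon; prediction must
        # agree or lie beyond the horizon
        expect_true(is.na(t_pred) || t_pred > 20 - 1e-3)
      } else {
        expect_false(is.na(t_pred))
        expect_lt(abs(t_pred - t_scan), 1e-5)
      }
    }
  }
})

test_that("step crossing follows the two-body closed form", {
  # dU = 0: crossing with velocities unchanged
  res <- resolve_step_crossing(c(1, 1), c(1, 0, 0),
                               rbind(c(-1, 0, 0), c(1, 0, 0)), 0)
  expect_true(res$crossed)
  expect_equal(res$velocities, rbind(c(-1, 0, 0), c(1, 0, 0)))
  # equal masses, head-on closing speed 2, entering a well of depth 1:
  # v_rel' = sqrt(v_rel^2 - 2 dU / mu), mu = 0.5
  res <- resolve_step_crossing(c(1, 1), c(1, 0, 0),
                               rbind(c(-1, 0, 0), c(1, 0, 0)), -1)
  v_rel <- res$velocities[1, 1] - res$velocities[2, 1]
  expect_equal(abs(v_rel), sqrt(4 + 2 * 1 / 0.5))
  # momentum conserved exactly
  expect_equal(colSums(res$velocities), c(0, 0, 0))
  # insufficient radial energy: elastic reflection, KE unchanged
  res <- resolve_step_crossing(c(1, 1), c(1, 0, 0),
                               rbind(c(-0.1, 0, 0), c(0.1, 0, 0)), 5)
  expect_false(res$crossed)
  expect_equal(sum(res$velocities^2), 2 * 0.1^2)
})

test_that("thermostat-free dynamics conserves energy to 1e-7", {
  sys <- two_bead_system()
  tab <- two_bead_table(sys)
  tr <- run_dmd(sys, tab, temperature = 0.5, length = 80000, seed = 1,
                thermostat = "off", frame_interval = 20)
  expect_gt(tr$n_events, 1e4)
  etot <- tr$pe + tr$ke
  expect_lt(max(abs(etot - etot[1])), 1e-7)
  # a larger interacting system conserves too
  pep <- make_go_peptide(seed = 1)
  tr2 <- run_dmd(pep$system, pep$table, temperature = 0.6, length = 500,
                 seed = 2, thermostat = "off")
  etot2 <- tr2$pe + tr2$ke
  expect_lt(max(abs(etot2 - etot2[1])), 1e-7)
  # running PE agrees with a from-scratch recompute
  expect_lt(abs(tr2$final_pe - tr2$recomputed_pe), 1e-6)
})

test_that("equal seeds give bitwise-identical trajectories", {
  pep <- make_go_peptide(seed = 4)
  a <- run_dmd(pep$system, pep$table, 0.5, 300, seed = 9)
  b <- run_dmd(pep$system, pep$table, 0.5, 300, seed = 9)
  expect_identical(a$coords, b$coords)
  expect_identical(a$pe, b$pe)
})

test_that("thermostat drives kinetic energy to equipartition", {
  pep <- make_go_peptide(seed = 1)
  T0 <- 0.6
  tr <- run_dmd(pep$system, pep$table, T0, 4000, seed = 3, thermostat = "on")
  n_dof <- 3 * nrow(pep$system$atoms)
  keep <- 500:length(tr$ke)
  ke_per_dof <- tr$ke[keep] / n_dof
  se <- sd(ke_per_dof) / sqrt(length(keep) / 20)  # ~20-frame correlation
  expect_lt(abs(mean(ke_per_dof) - T0 / 2), 3 * se + 0.01)
})

test_that("no recorded frame penetrates a hard core", {
  pep <- make_go_peptide(seed = 5)
  tr <- run_dmd(pep$system, pep$table, 0.7, 1000, seed = 6)
  hard <- vapply(pep$table$potentials, function(p) p$radii[1], numeric(1))
  min_r <- Inf
  nb <- pep$table$nonbonded
  for (f in seq(1, n_frames(tr), by = 7)) {
    xyz <- frame_coords(tr, f)
    d <- sqrt(rowSums((xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE])^2))
    min_r <- min(min_r, min(d - hard[nb$pot]))
  }
  expect_gte(min_r, -1e-9)
})

test_that("two-body motion is time reversible", {
  sys <- two_bead_system()
  tab <- two_bead_table(sys)
  fwd <- run_dmd(sys, tab, 0.5, 50, seed = 7, thermostat = "off",
                 frame_interval = 50)
  back_state <- list(positions = fwd$state$positions,
                     velocities = -fwd$state$velocities)
  bwd <- run_dmd(sys, tab, 0.5, 50, thermostat = "off", frame_interval = 50,
                 state = back_state)
  start <- system_coords(sys)
  # returned positions match the start (velocities were drawn at seed 7
  # from the start positions)
  expect_equal(bwd$state$positions, fwd$coords[1, , ], tolerance = 1e-6)
})

test_that("overlapping hard cores abort initialization with the pair named", {
  atoms <- tibble::tibble(name = "CA", element = "C", charge = 0, mass = 10,
                          resname = "GLY", chain = "A", resno = 1:2,
                          x = c(0, 1.0), y = 0, z = 0)
  sys <- molecular_system(atoms, matrix(integer(0), ncol = 2))
  tab <- interaction_table(
    potentials = list(hard = step_potential(3.6, 0)),
    nonbonded = tibble::tibble(i = 1L, j = 2L, pot = "hard"))
  expect_error(run_dmd(sys, tab, 0.5, 10, seed = 1),
               "initialization error.*1.*2")
})

test_that("trajectories serialize to multi-model PDB plus energies", {
  pep <- make_go_peptide(seed = 1)
  tr <- run_dmd(pep$system, pep$table, 0.5, 10, seed = 1, frame_interval = 5)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(tr, pep$system, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), n_frames(tr))
  etab <- read.table(sub("\\.pdb$", ".energies.txt", path), header = TRUE)
  expect_equal(nrow(etab), n_frames(tr))
})
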