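test_that("the two-level sampler follows its exact Boltzmann weights", {
  ts <- make_two_state(E0 = 0, E1 = 2, g0 = 1, g1 = 50)
  set.seed(1)
  e <- ts$sample(1, 1e5)
  p1 <- 50 * exp(-2) / (1 + 50 * exp(-2))
  phat <- mean(e == 2)
  expect_lt(abs(phat - p1), 3 * sqrt(p1 * (1 - p1) / 1e5))
  # T -> 0 limit emits only the ground level
  expect_true(all(ts$sample(1e-3, 1000) == 0))
  expect_error(make_two_state(E1 = -1), "E1 > E0")
  expect_error(make_two_state(g0 = 0), ">= 1")
})

test_that("closed-form C_V peak equals brute-force grid maximization", {
  ts <- make_two_state(E0 = 0, E1 = 2, g0 = 1, g1 = 50)
  grid <- seq(0.05, 3, by = 1e-4)
  t_grid <- grid[which.max(ts$cv(grid))]
  t_opt <- optimize(ts$cv, c(0.05, 3), maximum = TRUE)$maximum
  expect_lt(abs(t_grid - t_opt), 1e-3)
  # closed forms match direct summation
  Tset <- c(0.3, 0.7, 1.5)
  for (T in Tset) {
    Z <- 1 * exp(0) + 50 * exp(-2 / T)
    expect_equal(ts$Z(T), Z, tolerance = 1e-12)
    p <- 50 * exp(-2 / T) / Z
    expect_equal(ts$mean_energy(T), 2 * p, tolerance = 1e-12)
    expect_equal(ts$cv(T), 4 * p * (1 - p) / T^2, tolerance = 1e-12)
  }
})

test_that("peptide generation is deterministic and self-avoiding", {
  a <- make_go_peptide(seed = 3)
  b <- make_go_peptide(seed = 3)
  expect_identical(system_coords(a$system), system_coords(b$system))
  expect_identical(a$contacts, b$contacts)
  d <- as.matrix(dist(system_coords(a$system)))
  diag(d) <- Inf
  bonded <- abs(row(d) - col(d)) == 1
  expect_gt(min(d[!bonded]), 3.6)
  expect_error(make_go_peptide(n_residues = 5), "at least 8")
})

test_that("native-contact counts equal the brute-force recount", {
  for (fold in c("helix", "hairpin")) {
    pep <- make_go_peptide(seed = 2, fold = fold)
    expect_equal(nrow(pep$contacts),
                 count_contacts_brute(pep$system, pep$cutoff))
  }
})

test_that("generators emit usable PDB and table fixtures", {
  dir <- tempfile()
  pep <- make_go_peptide(seed = 1, out_dir = dir)
  sys <- read_pdb(file.path(dir, "native.pdb"))
  expect_equal(nrow(sys$atoms), 20)
  tab <- read_interaction_table(file.path(dir, "table.txt"))
  expect_equal(nrow(tab$nonbonded), nrow(pep$table$nonbonded))
})

test_that("a null modification leaves the variant identical", {
  pep <- make_go_peptide(seed = 1)
  var <- make_modified_variant(pep, delta_radius = 0, delta_eps = 0)
  for (nm in names(pep$table$potentials)) {
    expect_equal(var$table$potentials[[sub("_mod$", "", nm)]] %||%
                   var$table$potentials[[nm]],
                 pep$table$potentials[[nm]])
  }
  e_wt <- configuration_energy(system_coords(pep$system), pep$table)
  e_var <- configuration_energy(system_coords(var$system), var$table)
  expect_equal(e_wt, e_var, tolerance = 1e-12)
})

test_that("only wells touching the site change, one per contact", {
  pep <- make_go_peptide(seed = 2)
  site <- 7
  var <- make_modified_variant(pep, site = site, delta_radius = 0.1,
                               delta_eps = 0.5)
  wt_depth <- native_contacts(pep$table)
  var_depth <- native_contacts(var$table)
  changed <- which(abs(wt_depth$depth - var_depth$depth) > 1e-12)
  touches <- which(wt_depth$i == site | wt_depth$j == site)
  expect_equal(sort(changed), sort(touches))
  expect_equal(length(changed), contact_degree(pep)[site])
  expect_equal(var_depth$depth[touches], wt_depth$depth[touches] * 0.5)
  expect_error(make_modified_variant(pep, site = 99), "invalid site")
  expect_error(make_modified_variant(pep, delta_eps = 1), "delta_eps")
})

test_that("core-site well shallowing raises low-temperature energy", {
  pep <- make_go_peptide(seed = 1)
  var <- make_modified_variant(pep, delta_radius = 0, delta_eps = 0.5)
  tw <- run_dmd(pep$system, pep$table, 0.4, 3000, seed = 5)
  tv <- run_dmd(var$system, var$table, 0.4, 3000, seed = 5)
  keep <- 600:3001
  expect_gt(mean(tv$pe[keep]), mean(tw$pe[keep]))
})

test_that("deeper native wells melt at higher temperature", {
  # eps doubled: REMD-measured major C_V peak strictly higher
  ladder <- replica_ladder(seq(0.35, 0.95, length.out = 8),
                           exchange_interval = 25)
  tm <- vapply(c(0.8, 1.6), function(eps) {
    pep <- make_go_peptide(n_residues = 14, eps = eps, seed = 3)
    rr <- run_remd(pep$system, pep$table, ladder, length = 8000, seed = 5)
    prof <- wham(energy_histograms(rr))
    cv <- specific_heat(prof, seq(0.3, 1.1, by = 0.005))
    pk <- find_melting_events(cv)
    pk$temperature[pk$major]
  }, numeric(1))
  expect_gt(tm[2], tm[1])
})
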