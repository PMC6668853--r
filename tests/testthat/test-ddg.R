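# a single shared coarse rotamer set keeps these tests fast
rotlibs <- standard_rotamer_set(phi_increment = 180)

test_that("zero Monte Carlo steps return the initial placement energy", {
  sys <- make_ser_peptide()
  tab <- build_atomic_table(sys)
  site <- tibble::tibble(chain = "A", resno = 2)
  e0 <- repack_energy(sys, site, rotlibs, table = tab, n_mc = 0, seed = 1)
  cand <- stepfold:::.site_candidates(sys, "A", 2, rotlibs$SER)
  coords <- stepfold:::.apply_candidate(system_coords(sys), cand, 1L)
  nb_only <- tab
  nb_only$constraints <- tab$constraints[0, ]
  expect_equal(as.numeric(e0),
               configuration_energy(coords, nb_only), tolerance = 1e-9)
})

test_that("best-visited energy is non-increasing in the step budget", {
  pk <- make_packed_pocket()
  mut <- substitute_residue(pk$system, pk$chain, pk$resno, "BMAA")
  tab <- build_atomic_table(mut)
  site <- tibble::tibble(chain = pk$chain, resno = pk$resno)
  es <- vapply(c(0, 5, 20, 80), function(n)
    as.numeric(repack_energy(mut, site, rotlibs, table = tab, n_mc = n,
                             seed = 3)), numeric(1))
  expect_true(all(diff(es) <= 1e-9))
})

test_that("Monte Carlo repacking reaches the exhaustive single-site minimum", {
  pk <- make_packed_pocket()
  mut <- substitute_residue(pk$system, pk$chain, pk$resno, "BMAA")
  tab <- build_atomic_table(mut)
  site <- tibble::tibble(chain = pk$chain, resno = pk$resno)
  # exhaustive oracle over the site's 9 rotamers
  cand <- stepfold:::.site_candidates(mut, pk$chain, pk$resno, rotlibs$BMAA)
  nb_only <- tab
  nb_only$constraints <- tab$constraints[0, ]
  exhaustive <- min(vapply(seq_along(cand$candidates), function(k) {
    configuration_energy(
      stepfold:::.apply_candidate(system_coords(mut), cand, k), nb_only)
  }, numeric(1)))
  got <- repack_energy(mut, site, rotlibs, table = tab, n_mc = 200, seed = 8)
  expect_lt(abs(as.numeric(got) - exhaustive), 0.01)
})

test_that("identity mutations score zero within 0.1 kcal/mol", {
  sys <- make_ser_peptide()
  r <- estimate_ddg(sys, "A", 2, "SER", rotlibs, n_rounds = 3, n_sims = 3,
                    n_mc = 30, seed = 11)
  expect_lt(abs(r$mean), 0.1)
  expect_equal(length(r$per_round), 3)
  expect_equal(r$mean, mean(r$per_round))
  expect_equal(r$sd, sd(r$per_round))
})

test_that("bulky charged substitution outranks the conservative control", {
  pk <- make_packed_pocket()
  r_bulky <- estimate_ddg(pk$system, pk$chain, pk$resno, "BMAA", rotlibs,
                          n_rounds = 3, n_sims = 4, n_mc = 40, seed = 21)
  r_cons <- estimate_ddg(pk$system, pk$chain, pk$resno, "DAP", rotlibs,
                         n_rounds = 3, n_sims = 4, n_mc = 40, seed = 21)
  expect_gt(r_bulky$mean, 0)
  expect_gt(r_bulky$mean, r_cons$mean + 1)
  expect_lt(abs(r_cons$mean), 2)
})

test_that("flexible backbone relieves strain relative to fixed", {
  pk <- make_packed_pocket()
  r_fix <- estimate_ddg(pk$system, pk$chain, pk$resno, "BMAA", rotlibs,
                        mode = "fixed", n_rounds = 2, n_sims = 3, n_mc = 30,
                        seed = 31)
  r_flex <- estimate_ddg(pk$system, pk$chain, pk$resno, "BMAA", rotlibs,
                         mode = "flexible", n_rounds = 2, n_sims = 3,
                         n_mc = 30, seed = 31)
  expect_equal(r_flex$mode, "flexible")
  expect_true(is.finite(r_flex$mean))
  # extra degrees of freedom can only lower the attainable minimum
  expect_lte(r_flex$mean, r_fix$mean + 0.5)
})

test_that("serine scans cover sites x targets in sequence order", {
  sys <- make_ser_peptide()          # serines at 2 and 4
  tab <- serine_scan(sys, "A", targets = c("BMAA", "DAP"), rotlib = rotlibs,
                     n_rounds = 2, n_sims = 2, n_mc = 15, seed = 41)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$resno, c(2, 2, 4, 4))
  expect_setequal(unique(tab$target), c("BMAA", "DAP"))
  expect_true(all(c("ddg_mean", "ddg_sd") %in% names(tab)))
  no_ser <- make_ser_peptide(c("ALA", "GLY", "ALA"))
  expect_warning(empty <- serine_scan(no_ser, "A", targets = "BMAA",
                                      rotlib = rotlibs), "no serines")
  expect_equal(nrow(empty), 0)
})

test_that("ddg results expose tidy and glance views", {
  sys <- make_ser_peptide()
  r <- estimate_ddg(sys, "A", 2, "SER", rotlibs, n_rounds = 2, n_sims = 2,
                    n_mc = 10, seed = 51)
  expect_equal(nrow(tidy(r)), 2)
  g <- glance(r)
  expect_equal(g$target, "SER")
  expect_equal(g$n_rounds, 2)
})
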