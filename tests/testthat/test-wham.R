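test_that("single-temperature WHAM inverts the Boltzmann factor exactly", {
  set.seed(1)
  ts <- make_two_state(E0 = 0, E1 = 2, g0 = 1, g1 = 50)
  T0 <- 1.0
  e <- ts$sample(T0, 2e4)
  hs <- energy_histograms(list(e), T0, bin_width = 1)
  prof <- wham(hs)
  counts <- hs$counts[1, hs$counts[1, ] > 0]
  expected <- log(counts) + hs$centers[hs$counts[1, ] > 0] / T0
  expected <- expected - max(expected)
  expect_equal(prof$ln_g, expected, tolerance = 1e-9)
})

test_that("WHAM recovers the two-level degeneracy ratio within 3 sigma", {
  ts <- make_two_state(E0 = 0, E1 = 2, g0 = 1, g1 = 50)
  temps <- c(0.35, 0.5, 0.7, 1.0)
  n <- 1e5
  set.seed(7)
  energies <- lapply(temps, function(T) ts$sample(T, n))
  hs <- energy_histograms(energies, temps, bin_width = 1)
  prof <- wham(hs)
  est <- prof$ln_g[which.max(prof$energy)] - prof$ln_g[which.min(prof$energy)]
  # bootstrap the sampling error of the estimate
  boots <- vapply(1:20, function(b) {
    eb <- lapply(energies, function(e) sample(e, n, replace = TRUE))
    pb <- wham(energy_histograms(eb, temps, bin_width = 1))
    pb$ln_g[which.max(pb$energy)] - pb$ln_g[which.min(pb$energy)]
  }, numeric(1))
  expect_lt(abs(est - log(50)), 3 * max(sd(boots), 1e-3))
})

test_that("energy offsets shift free energies but not the specific heat", {
  set.seed(2)
  ts <- make_two_state()
  temps <- c(0.4, 0.6, 0.9)
  energies <- lapply(temps, function(T) ts$sample(T, 2e4))
  hs1 <- energy_histograms(energies, temps, bin_width = 1)
  hs2 <- energy_histograms(lapply(energies, `+`, 5), temps, bin_width = 1)
  p1 <- wham(hs1); p2 <- wham(hs2)
  grid <- seq(0.3, 1.2, by = 0.01)
  expect_equal(specific_heat(p1, grid)$cv, specific_heat(p2, grid)$cv,
               tolerance = 1e-6)
})

test_that("non-overlapping histograms raise a disconnected-support error", {
  hs <- structure(list(
    edges = seq(-0.5, 10.5, by = 1), centers = 0:10,
    counts = rbind(c(100, 50, rep(0, 9)), c(rep(0, 9), 50, 100)),
    n_samples = c(150, 150), temperatures = c(0.5, 1.0)),
    class = "energy_histogram_set")
  expect_error(wham(hs), "disconnected")
})

test_that("specific heat of a single level is zero; C_V is never negative", {
  prof <- structure(list(energy = 3, ln_g = 0, f = 0, temperatures = 1,
                         iterations = 1, residual = 0, bin_width = 1),
                    class = "thermo_profile")
  grid <- seq(0.2, 2, by = 0.1)
  cv <- specific_heat(prof, grid)
  expect_true(all(cv$cv == 0))
  expect_error(specific_heat(prof, c(-1, 1)), "positive")
  ts <- make_two_state()
  prof2 <- structure(list(energy = c(0, 2), ln_g = c(0, log(50)), f = 0,
                          temperatures = 1, iterations = 1, residual = 0,
                          bin_width = 1), class = "thermo_profile")
  expect_true(all(specific_heat(prof2, grid)$cv >= 0))
})

test_that("Schottky peak location matches brute-force maximization to 1%", {
  ts <- make_two_state(E0 = 0, E1 = 2, g0 = 1, g1 = 50)
  # exact density of states: the analytic two-level system
  prof <- structure(list(energy = c(0, 2), ln_g = c(0, log(50)), f = 0,
                         temperatures = 1, iterations = 1, residual = 0,
                         bin_width = 1), class = "thermo_profile")
  grid <- seq(0.1, 2, by = 0.0005)
  cv <- specific_heat(prof, grid)
  t_num <- cv$temperature[which.max(cv$cv)]
  t_exact <- optimize(ts$cv, c(0.1, 2), maximum = TRUE)$maximum
  expect_lt(abs(t_num - t_exact) / t_exact, 0.01)
})

test_that("melting-event detection handles the canonical shapes", {
  x <- seq(0, 1, by = 0.01)
  unimodal <- tibble::tibble(temperature = x, cv = exp(-(x - 0.4)^2 / 0.01))
  pk <- find_melting_events(unimodal)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$temperature, 0.4, tolerance = 0.011)
  two <- tibble::tibble(temperature = x,
                        cv = exp(-(x - 0.3)^2 / 0.002) +
                             0.7 * exp(-(x - 0.7)^2 / 0.002))
  pk2 <- find_melting_events(two)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$temperature, c(0.3, 0.7), tolerance = 0.011)
  expect_equal(pk2$major, c(TRUE, FALSE))
  flat <- tibble::tibble(temperature = x, cv = rep(1, length(x)))
  expect_equal(nrow(find_melting_events(flat)), 0)
  expect_error(find_melting_events(unimodal[1:2, ]), "at least 3")
})

test_that("potential-energy histograms normalize and locate the mode", {
  h <- pe_histogram(rep(-5, 100))
  expect_equal(h$mode, -5)
  expect_equal(sum(h$histogram$density), 1)
  set.seed(3)
  h2 <- pe_histogram(rnorm(1e4, mean = -20, sd = 2), bins = 40,
                     equilibration = 0)
  bw <- diff(h2$histogram$energy[1:2])
  expect_lt(abs(h2$mode - (-20)), 2 * bw)
  expect_equal(sum(h2$histogram$density), 1)
  expect_error(pe_histogram(numeric(0)), "empty")
})

test_that("profile summaries expose the melting temperature", {
  set.seed(4)
  ts <- make_two_state()
  temps <- c(0.4, 0.6, 0.9)
  hs <- energy_histograms(lapply(temps, function(T) ts$sample(T, 2e4)),
                          temps, bin_width = 1)
  prof <- wham(hs)
  g <- glance(prof)
  expect_true(all(c("t_melt", "t_melt_kelvin", "n_peaks") %in% names(g)))
  td <- tidy(prof)
  expect_equal(nrow(td), length(prof$energy))
})
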