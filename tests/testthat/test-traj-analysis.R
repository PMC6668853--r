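make_traj <- function(frames) {
  nf <- length(frames)
  na <- nrow(frames[[1]])
  co <- array(0, c(nf, na, 3))
  for (f in seq_len(nf)) co[f, , ] <- frames[[f]]
  structure(list(time = seq_len(nf), coords = co, pe = rep(0, nf),
                 ke = rep(0, nf), temperature = 0.5, metadata = list()),
            class = "dmd_trajectory")
}

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)

test_that("superposition is exact for congruent sets and symmetric", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  Y <- X %*% t(rot_z(0.7)) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  expect_lt(superpose(X, Y)$rmsd, 1e-9)
  expect_equal(det(superpose(X, Y)$rotation), 1, tolerance = 1e-9)
  # symmetry of the metric surrogate
  Z <- X + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(rmsd(X, Z), rmsd(Z, X), tolerance = 1e-9)
  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
  expect_error(superpose(X, X[1:5, ]), "differ in size")
})

test_that("4-point RMSD matches a dense rotation-grid brute force", {
  X <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2.5, 0), c(0.5, 0.5, 1.8))
  Y <- rbind(c(0.2, 0, 0.2), c(2.2, 0.4, -0.1), c(-0.3, 2.3, 0.4),
             c(0.8, 0.3, 1.5))
  got <- superpose(X, Y)$rmsd
  # brute force: centred sets over a dense Euler-angle grid
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  ang <- seq(0, 2 * pi, length.out = 60)
  ang_b <- seq(0, pi, length.out = 30)
  best <- Inf
  for (a in ang) for (b in ang_b) for (g in ang) {
    Rz1 <- rot_z(a)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    R <- rot_z(g) %*% Ry %*% Rz1
    best <- min(best, sqrt(mean(rowSums((Yc %*% t(R) - Xc)^2))))
  }
  expect_lt(got, best + 1e-9)          # optimal beats every grid point
  expect_lt(best - got, 0.02)          # and the grid approaches it
  # independent cross-check against the bio3d implementation
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(X)), mobile = as.numeric(t(Y))))
  Yfit <- matrix(fit, ncol = 3, byrow = TRUE)
  expect_equal(got, sqrt(mean(rowSums((Yfit - X)^2))), tolerance = 1e-6)
})

test_that("RMSF is zero for static or rigidly translated trajectories", {
  base <- matrix(rnorm(24), 8, 3)
  tr <- make_traj(list(base, base, base))
  expect_true(all(rmsf(tr)$rmsf == 0))
  shifted <- lapply(1:6, function(k) base + matrix(k, 8, 3))
  tr2 <- make_traj(shifted)
  expect_lt(max(rmsf(tr2, fit = TRUE)$rmsf), 1e-9)
  expect_warning(r1 <- rmsf(make_traj(list(base))), "single frame")
  expect_true(all(r1$rmsf == 0))
})

test_that("isotropic jitter gives RMSF sigma*sqrt(3) within 5%", {
  set.seed(5)
  base <- matrix(rnorm(15, sd = 10), 5, 3)
  sigma <- 0.2
  frames <- lapply(1:10000, function(k)
    base + matrix(rnorm(15, sd = sigma), 5, 3))
  tr <- make_traj(frames)
  r <- rmsf(tr, fit = FALSE)
  expect_true(all(abs(r$rmsf - sigma * sqrt(3)) / (sigma * sqrt(3)) < 0.05))
})

test_that("correlation maps recover perfect (anti)correlation", {
  set.seed(6)
  base <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0, 5, 5, 0), 4, 3, byrow = TRUE)
  disp <- rnorm(200)
  frames <- lapply(seq_along(disp), function(k) {
    out <- base
    out[1, 1] <- out[1, 1] + disp[k]   # residue 1 moves +x
    out[2, 1] <- out[2, 1] + disp[k]   # residue 2 moves identically
    out[3, 1] <- out[3, 1] - disp[k]   # residue 3 exactly opposite
    out
  })
  cm <- correlation_map(make_traj(frames), fit = FALSE)
  expect_equal(diag(cm$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$matrix[1, 2], 1, tolerance = 1e-9)
  expect_equal(cm$matrix[1, 3], -1, tolerance = 1e-9)
  expect_true(4 %in% cm$flagged)       # static residue zeroed but diag 1
  expect_equal(cm$matrix[4, 4], 1)
  expect_true(all(cm$matrix >= -1 - 1e-9 & cm$matrix <= 1 + 1e-9))
})

test_that("correlation maps are invariant to global rigid motion", {
  set.seed(7)
  base <- matrix(rnorm(18, sd = 4), 6, 3)
  frames <- lapply(1:150, function(k)
    base + matrix(rnorm(18, sd = 0.3), 6, 3))
  tr1 <- make_traj(frames)
  moved <- lapply(seq_along(frames), function(k)
    frames[[k]] %*% t(rot_z(0.01 * k)) +
      matrix(c(k * 0.05, 0, 1), 6, 3, byrow = TRUE))
  tr2 <- make_traj(moved)
  m1 <- correlation_map(tr1, fit = TRUE)$matrix
  m2 <- correlation_map(tr2, fit = TRUE)$matrix
  expect_equal(m1, m2, tolerance = 1e-4)
})

test_that("difference maps subtract elementwise with zero diagonal", {
  set.seed(8)
  base <- matrix(rnorm(15, sd = 4), 5, 3)
  mk <- function(seed) {
    set.seed(seed)
    make_traj(lapply(1:100, function(k)
      base + matrix(rnorm(15, sd = 0.2), 5, 3)))
  }
  A <- correlation_map(mk(1))
  B <- correlation_map(mk(2))
  D <- difference_map(A, B)
  expect_true(all(diag(D) == 0))
  expect_equal(D, -difference_map(B, A))
  expect_true(all(D >= -2 & D <= 2))
  expect_true(all(difference_map(A, A) == 0))
  B2 <- B
  B2$labels <- paste0("X", seq_along(B$labels))
  expect_error(difference_map(A, B2), "labels do not match")
})

test_that("decoupling a block shows as a negative difference block", {
  set.seed(9)
  base <- matrix(c(0, 0, 0, 4, 0, 0, 8, 0, 0, 0, 6, 0, 4, 6, 0), 5, 3,
                 byrow = TRUE)
  common <- rnorm(300)
  coupled <- lapply(seq_along(common), function(k) {
    out <- base + matrix(rnorm(15, sd = 0.05), 5, 3)
    out[1:2, 2] <- out[1:2, 2] + common[k]   # block 1-2 coupled
    out
  })
  uncoupled <- lapply(seq_along(common), function(k) {
    out <- base + matrix(rnorm(15, sd = 0.05), 5, 3)
    out[1, 2] <- out[1, 2] + rnorm(1)
    out[2, 2] <- out[2, 2] + rnorm(1)
    out
  })
  A <- correlation_map(make_traj(coupled), fit = FALSE)
  B <- correlation_map(make_traj(uncoupled), fit = FALSE)
  D <- difference_map(B, A)
  expect_lt(D[1, 2], -0.5)
})
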