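test_that("TI integrates constants exactly and reproduces the harmonic switch", {
  lam <- seq(0, 1, length.out = 11)
  est <- ti_estimate(lam, rep(2.5, 11))
  expect_equal(est$value, 2.5, tolerance = 1e-12)
  expect_equal(est$se, 0)
  expect_equal(sum(est$segments$value), est$value, tolerance = 1e-12)
  expect_error(ti_estimate(c(0.5, 0, 1), rep(1, 3)), "sorted")

  # 1-dof switch k0 = 4000 -> k1 = 40: integrate along the reversed path with
  # restraint constant k1 + (k0 - k1) t^4 (states packed at the weak end,
  # where the integrand varies fastest) on a dense linear t grid;
  # exact dA = (1/2) ln(k1/k0) = -2.3026
  set.seed(21)
  k0 <- 4000; k1 <- 40
  tgrid <- seq(0, 1, length.out = 101)
  n <- 2000
  means <- ses <- numeric(101)
  for (i in seq_along(tgrid)) {
    t <- tgrid[i]
    kt <- k1 + (k0 - k1) * t^4
    x2 <- rnorm(n, 0, 1 / sqrt(kt))^2
    dhdl <- (k0 - k1) * 4 * t^3 * x2 / 2
    means[i] <- mean(dhdl)
    ses[i] <- sd(dhdl) / sqrt(n)
  }
  ti <- ti_estimate(tgrid, means, ses) # k1 -> k0 direction
  exact <- 0.5 * log(k1 / k0)
  expect_lt(abs(-ti$value - exact), 3 * ti$se + 0.02)

  # quadrature sensitivity: K = 2 on the same curved integrand is far off
  # from the dense-grid result
  ti2 <- ti_estimate(tgrid[c(1, 101)], means[c(1, 101)], ses[c(1, 101)])
  expect_gt(abs(ti2$value - ti$value), 0.5)
})

test_that("EXP is exact for constant shifts and matches the Gaussian cumulant identity", {
  for (c0 in c(-3, 0, 2.7))
    expect_equal(exp_estimate(rep(c0, 50))$value, c0, tolerance = 1e-12)
  set.seed(13)
  dU <- rnorm(1e5, 2, 1)
  est <- exp_estimate(dU, seed = 2)
  expect_lt(abs(est$value - 1.5), 3 * est$se + 0.02) # m - s^2/2
  expect_error(exp_estimate(numeric(0)), "sample")
})

test_that("forward and backward EXP disagree beyond joint error without overlap", {
  # unit harmonic states with means 5 sigma apart: exact dA = 0, work
  # distribution N(12.5, 25); one-sided averages are badly biased
  set.seed(17)
  n <- 500; delta <- 5
  x0 <- rnorm(n, 0, 1); x1 <- rnorm(n, delta, 1)
  dU_f <- ((x0 - delta)^2 - x0^2) / 2
  dU_b <- (x1^2 - (x1 - delta)^2) / 2
  ef <- exp_estimate(dU_f, seed = 3)
  eb <- exp_estimate(dU_b, seed = 4)
  # chained consistency would require ef$value == -eb$value
  expect_gt(abs(ef$value + eb$value), 3 * sqrt(ef$se^2 + eb$se^2))
})

test_that("BAR is exact for identical states, antisymmetric, and matches Gaussians", {
  z <- rep(0, 200)
  expect_equal(bar_estimate(z, z)$value, 0, tolerance = 1e-10)

  set.seed(31)
  rpm <- gaussian_ladder_rpm(c(4, 8), 1e4, seed = 31)
  fw <- rpm$u[rpm$origin == 1, 2] - rpm$u[rpm$origin == 1, 1]
  bw <- rpm$u[rpm$origin == 2, 1] - rpm$u[rpm$origin == 2, 2]
  b <- bar_estimate(fw, bw)
  expect_lt(abs(b$value - 0.5 * log(2)), 3 * b$se)
  expect_gt(b$se, 0)
  b_swapped <- bar_estimate(bw, fw)
  expect_equal(b_swapped$value, -b$value, tolerance = 1e-8)
})

test_that("MBAR reduces to BAR at K = 2 and is exact for identical states", {
  rpm <- gaussian_ladder_rpm(c(4, 8), 4000, seed = 2)
  mb <- mbar_solve(rpm)
  fw <- rpm$u[rpm$origin == 1, 2] - rpm$u[rpm$origin == 1, 1]
  bw <- rpm$u[rpm$origin == 2, 1] - rpm$u[rpm$origin == 2, 2]
  b <- bar_estimate(fw, bw)
  expect_lt(abs(mb$value - b$value), 1e-8)

  K <- 4
  rpm_id <- gaussian_ladder_rpm(rep(4, K), 400, seed = 3)
  mb_id <- mbar_solve(rpm_id)
  expect_lt(max(abs(mb_id$f)), 1e-10)
  O <- overlap_matrix(mb_id)
  expect_lt(max(abs(O - matrix(rep(rpm_id$N_k / sum(rpm_id$N_k), each = K), K))),
            1e-10)
})

test_that("MBAR recovers the harmonic-ladder closed form with tight self-consistency", {
  K <- 24
  k_vec <- 4000 * (seq(0, K - 1) / (K - 1))^4 + 0.04
  rpm <- gaussian_ladder_rpm(k_vec, 2000, seed = 11)
  mb <- mbar_solve(rpm)
  expect_true(mb$converged)
  expect_lt(mb$residual, 1e-10)
  exact <- gaussian_ladder_exact(k_vec)
  expect_lt(abs(mb$value - exact), 3 * mb$se)
  # overlap rows sum to one
  expect_lt(max(abs(rowSums(overlap_matrix(mb)) - 1)), 1e-10)
})

test_that("MBAR free energies are invariant under state reordering", {
  K <- 6
  k_vec <- c(5, 9, 18, 40, 80, 160)
  rpm <- gaussian_ladder_rpm(k_vec, 800, seed = 4)
  mb <- mbar_solve(rpm)
  perm <- c(3, 1, 6, 2, 5, 4)
  # rebuild by stacking samples in permuted state order
  rows <- unlist(lapply(perm, function(k) which(rpm$origin == k)))
  rpm_p <- rpm_from_parts(rpm$u[rows, perm], rpm$N_k[perm])
  mb_p <- mbar_solve(rpm_p)
  f_back <- mb_p$f[match(seq_len(K), perm)]
  expect_lt(max(abs((f_back - f_back[1]) - (mb$f - mb$f[1]))), 1e-9)
})

test_that("reversing a path negates every segment free energy", {
  K <- 5
  k_vec <- c(4, 10, 25, 60, 150)
  rpm <- gaussian_ladder_rpm(k_vec, 600, seed = 8)
  mb <- mbar_solve(rpm)
  rows <- unlist(lapply(K:1, function(k) which(rpm$origin == k)))
  rpm_r <- rpm_from_parts(rpm$u[rows, K:1], rpm$N_k[K:1])
  mb_r <- mbar_solve(rpm_r)
  seg_f <- diff(mb$f)
  seg_r <- diff(mb_r$f)
  expect_equal(seg_r, -rev(seg_f), tolerance = 1e-9)
})

test_that("distant states give an identity-like overlap matrix", {
  rpm <- shifted_gaussian_rpm(c(0, 100), 500, seed = 6)
  mb <- suppressWarnings(mbar_solve(rpm))
  O <- overlap_matrix(mb)
  expect_lt(max(O[1, 2], O[2, 1]), 1e-6)
  expect_gt(min(diag(O)), 1 - 1e-6)
  d <- diagnose_path(O)
  expect_equal(d$status, "warn")
  expect_equal(nrow(d$broken_links), 1L)
})

test_that("segment chaining sums values, adds variances, and respects splits", {
  a <- free_energy_estimate(1.0, 0.1, "BAR")
  b <- free_energy_estimate(-1.0, 0.2, "BAR")
  ch <- chain_segments(list(a, b))
  expect_equal(ch$value, 0)
  expect_equal(ch$se, sqrt(0.1^2 + 0.2^2))
  expect_equal(chain_segments(list(a))$value, a$value)

  # splitting a long path into chunks sharing endpoint states chains to the
  # same total as the unsplit path (same samples)
  K <- 21
  k_vec <- exp(seq(log(4), log(400), length.out = K))
  rpm <- gaussian_ladder_rpm(k_vec, 300, seed = 12)
  whole <- bar_chain(rpm)
  chunks <- list(1:6, 6:11, 11:16, 16:21)
  split_total <- chain_segments(lapply(chunks, function(ix)
    bar_chain(rpm_subset(rpm, ix))))
  expect_lt(abs(split_total$value - whole$value), 1e-9)
})

test_that("estimator concordance: TI, chained BAR and MBAR agree on an overlapping path", {
  K <- 12
  tgrid <- seq(0, 1, length.out = K)
  k0 <- 4; k1 <- 400 # weak -> strong, states packed at the weak end
  k_vec <- k0 + (k1 - k0) * tgrid^4
  n <- 1500
  rpm <- gaussian_ladder_rpm(k_vec, n, seed = 14)
  mb <- mbar_solve(rpm)
  expect_gt(min(diagnose_path(overlap_matrix(mb))$min_neighbor_overlap), 0.03)
  bc <- bar_chain(rpm)
  set.seed(15)
  means <- ses <- numeric(K)
  for (i in seq_len(K)) {
    x2 <- rnorm(n, 0, 1 / sqrt(k_vec[i]))^2
    dhdl <- (k1 - k0) * 4 * tgrid[i]^3 * x2 / 2
    means[i] <- mean(dhdl); ses[i] <- sd(dhdl) / sqrt(n)
  }
  ti <- ti_estimate(tgrid, means, ses)
  exact <- gaussian_ladder_exact(k_vec)
  for (est in list(mb, bc, ti))
    expect_lt(abs(est$value - exact), 3 * est$se + 0.02)
  expect_lt(abs(mb$value - bc$value), 3 * sqrt(mb$se^2 + bc$se^2) + 0.02)
  expect_lt(abs(mb$value - ti$value), 3 * sqrt(mb$se^2 + ti$se^2) + 0.05)
})
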