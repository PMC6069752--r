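test_that("lambda schedules have the stated spacing", {
  expect_equal(make_schedule("linear", 3), c(0, 0.5, 1))
  expect_equal(make_schedule("power", 5, 4), c(0, 1, 16, 81, 256) / 256)
  expect_error(make_schedule("linear", 1), "at least 2")
  lam <- make_schedule("power", 600, 4)
  expect_true(all(diff(lam) > 0))
  expect_identical(range(lam), c(0, 1))
})

test_that("lambda paths validate monotonicity, endpoints and default mixing", {
  p <- lambda_path(c(0, 0.3, 1))
  expect_equal(p$f(0), 1); expect_equal(p$g(0), 0)
  expect_equal(p$f(1), 0); expect_equal(p$g(1), 1)
  expect_error(lambda_path(c(0, 0.5, 0.5, 1)), "strictly increasing")
  expect_error(lambda_path(c(0.1, 0.5, 1)), "endpoints")
})

test_that("mixed Hamiltonians hit the end states exactly and degenerate paths are flat", {
  box <- rep(12, 3)
  set.seed(7)
  coords <- matrix(runif(15, 3, 9), 5, 3)
  ref <- coords + 0.1
  mi <- energy_model(site_restraint(50, ref), box = box)
  mf <- energy_model(lj_pair(1, 3, 5.5, atoms = 1:5), box = box)
  ei <- evaluate_energy(mi, coords)$total
  ef <- evaluate_energy(mf, coords)$total
  expect_equal(mixed_energy(mi, mf, 0, coords)$energy, ei)
  expect_equal(mixed_energy(mi, mf, 1, coords)$energy, ef)
  expect_error(mixed_energy(mi, mf, 1.2, coords), "\\[0, 1\\]")
  # identical end states: dH/dlambda = 0 everywhere
  for (l in c(0, 0.25, 0.8, 1))
    expect_equal(mixed_energy(mi, mi, l, coords)$dhdl, 0, tolerance = 1e-12)
  # the mixed model evaluates to the mixed energy
  mm <- mixed_model(mi, mf, 0.3)
  expect_equal(evaluate_energy(mm, coords)$total, 0.7 * ei + 0.3 * ef,
               tolerance = 1e-12)
})

test_that("soft-core pair energy has the stated limits", {
  eps <- 1.3; sigma <- 3.1
  r <- seq(0.5, 8, by = 0.25)
  lj <- 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  expect_equal(softcore_pair_energy(eps, sigma, r, lambda = 1), lj,
               tolerance = 1e-12)
  expect_equal(softcore_pair_energy(eps, sigma, r, lambda = 0), rep(0, length(r)))
  # finite at r -> 0 for lambda = 0.5: D = 0.5 * 0.25 = 1/8
  expect_equal(softcore_pair_energy(eps, sigma, 0, 0.5),
               4 * eps * 0.5 * (64 - 8))
  expect_error(softcore_pair_energy(eps, sigma, 1, 1.5), "\\[0, 1\\]")
})

test_that("Metropolis sampling of a harmonic well matches equipartition", {
  cr <- build_fcc_crystal(1, 5.0)
  k <- 4.0
  m <- energy_model(site_restraint(k, cr$coords, exclude = cr$fixed_atom),
                    box = cr$box)
  s <- sample_state(m, cr$coords, 8000, seed = 101,
                    fixed_atom = cr$fixed_atom, step = 0.6)
  expect_gt(s$acceptance, 0.2); expect_lt(s$acceptance, 0.65)
  # fixed atom never displaced
  expect_equal(max(abs(s$frames[cr$fixed_atom, , ] - cr$coords[cr$fixed_atom, ])), 0)
  # variance per coordinate -> 1/(beta k) within 3 standard errors
  d <- s$frames[2, 1, ] - cr$coords[2, 1]
  sub <- subsample_decorrelated(d)
  di <- d[sub$indices]
  v <- var(di)
  se_v <- v * sqrt(2 / (length(di) - 1))
  expect_lt(abs(v - 1 / k), 3 * se_v)
  # and the sampled marginal is Gaussian (KS at alpha = 0.01); rejected moves
  # leave occasional tied values, harmless for the test
  expect_gt(suppressWarnings(ks.test(di, "pnorm", 0, sqrt(1 / k)))$p.value, 0.01)
})

test_that("sampling is deterministic given the seed", {
  cr <- build_fcc_crystal(1, 5.0)
  m <- energy_model(site_restraint(10, cr$coords, exclude = 1), box = cr$box)
  s1 <- sample_state(m, cr$coords, 500, seed = 7, fixed_atom = 1)
  s2 <- sample_state(m, cr$coords, 500, seed = 7, fixed_atom = 1)
  expect_identical(s1$frames, s2$frames)
  s3 <- sample_state(m, cr$coords, 500, seed = 8, fixed_atom = 1)
  expect_false(identical(s1$frames, s3$frames))
})

test_that("Langevin (BAOAB) sampling reproduces the harmonic variance", {
  cr <- build_fcc_crystal(1, 5.0)
  k <- 4.0
  m <- energy_model(site_restraint(k, cr$coords, exclude = 1), box = cr$box)
  s <- sample_state(m, cr$coords, 20000, seed = 33, fixed_atom = 1,
                    mode = "langevin", dt = 0.02, gamma = 2)
  d <- s$frames[3, 2, ] - cr$coords[3, 2]
  sub <- subsample_decorrelated(d)
  v <- var(d[sub$indices])
  se_v <- v * sqrt(2 / (length(sub$indices) - 1))
  expect_lt(abs(v - 1 / k), 4 * se_v + 0.01) # allows small O(dt^2) bias
})

test_that("statistical inefficiency matches i.i.d. and AR(1) closed forms", {
  set.seed(5)
  expect_lt(abs(statistical_inefficiency(rnorm(1e4))$g - 1), 0.2)
  # AR(1), rho = 0.8: g = (1 + rho) / (1 - rho) = 9
  rho <- 0.8
  x <- as.vector(arima.sim(list(ar = rho), 1e5))
  g <- statistical_inefficiency(x)$g
  expect_lt(abs(g - 9) / 9, 0.25)
  expect_warning(s <- subsample_decorrelated(rep(1, 100)), "constant")
  expect_equal(length(s$indices), 1L)
})

test_that("cross-evaluation is consistent with sampling energies and state identity", {
  cr <- build_fcc_crystal(1, 5.0)
  k_values <- c(40, 400, 4000)
  states <- restraint_switch_states(cr, 4000, k_values)
  sp <- sample_path(states, cr$coords, 600, seed = 3,
                    fixed_atom = cr$fixed_atom, step = 1 / sqrt(k_values))
  rpm <- cross_evaluate(sp, states)
  expect_lt(rpm$diag_dev, 1e-10)
  expect_equal(ncol(rpm$u), 3L)
  expect_equal(as.integer(table(rpm$origin)), rpm$N_k)
  # identical Hamiltonians at all states: u independent of the target state
  same <- replicate(3, states[[2]], simplify = FALSE)
  sp2 <- sample_path(same, cr$coords, 300, seed = 4, fixed_atom = cr$fixed_atom,
                     step = 0.05)
  rpm2 <- cross_evaluate(sp2, same)
  expect_lt(max(abs(rpm2$u - rpm2$u[, 1])), 1e-12)
  # padded array view has the contracted shape
  arr <- rpm_array(rpm)
  expect_equal(dim(arr), c(3L, 3L, max(rpm$N_k)))
  expect_equal(sum(!is.na(arr[1, 1, ])), rpm$N_k[1])
  # serialization round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_rpm(rpm, f)
  rpm3 <- read_rpm(f)
  expect_equal(rpm3$u, unname(rpm$u), tolerance = 1e-12)
  expect_equal(rpm3$N_k, rpm$N_k)
})

test_that("two-state cross-evaluation provides the forward/backward lists EXP and BAR use", {
  rpm <- gaussian_ladder_rpm(c(4, 8), 500, seed = 9)
  fw <- rpm$u[rpm$origin == 1, 2] - rpm$u[rpm$origin == 1, 1]
  bw <- rpm$u[rpm$origin == 2, 1] - rpm$u[rpm$origin == 2, 2]
  expect_length(fw, 500); expect_length(bw, 500)
  b <- bar_estimate(fw, bw)
  expect_lt(abs(b$value - gaussian_ladder_exact(c(4, 8))), 3 * b$se + 0.05)
})
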