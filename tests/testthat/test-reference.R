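lam_ar <- de_broglie_wavelength(39.948, 298.15)

test_that("analytic Einstein molecule free energy has the stated limits", {
  V <- 125
  # N = 1: only the fixed particle remains
  expect_equal(em_free_energy_analytic(1, 4000, lam_ar, V)$A,
               log(lam_ar^3 / V))
  # k = 2 pi / (beta Lambda^2): the mobile-particle term vanishes
  kc <- 2 * pi / lam_ar^2
  for (N in c(2, 10))
    expect_equal(em_free_energy_analytic(N, kc, lam_ar, V)$A,
                 log(N * lam_ar^3 / V), tolerance = 1e-12)
  expect_error(em_free_energy_analytic(4, -1, lam_ar, V), "positive")
  # decomposition sums to the total
  r <- em_free_energy_analytic(4, 4000, lam_ar, V)
  expect_equal(sum(r$decomposition), r$A)
})

test_that("analytic result matches direct quadrature of the restraint integral", {
  N <- 4; k <- 4000; V <- 125
  # 1-D Gaussian integral oracle, cubed for the isotropic 3-D restraint
  I1 <- integrate(function(x) exp(-k * x^2 / 2), -Inf, Inf, rel.tol = 1e-12)$value
  A_oracle <- log(N * lam_ar^3 / V) - (N - 1) * log(I1^3 / lam_ar^3)
  expect_equal(em_free_energy_analytic(N, k, lam_ar, V)$A, A_oracle,
               tolerance = 1e-9)
})

test_that("MC reference agrees with the analytic route for atomic systems", {
  cr <- build_fcc_crystal(1, 5.0)
  an <- em_free_energy_analytic(4, 4000, lam_ar, 125)
  mc <- em_free_energy_mc(atomic_topology(), cr, 4000, lam_ar, 5e4, seed = 2)
  expect_lt(abs(mc$A - an$A), 3 * mc$se + 1e-8)
  expect_lt(abs(mc$A - an$A), 0.05)
  expect_true(mc$converged)
})

test_that("orientation-independent restraints recover the full angular measure", {
  # all sites of the anchored molecule coincide with the fixed site, so
  # rotations cost nothing and the orientational integral is 8 pi^2
  top <- molecule_topology(c("X", "X", "X"), c(1, 1, 1), matrix(0, 3, 3),
                           sigma_rot = 1L, linear = FALSE)
  coords <- rbind(matrix(2, 3, 3, byrow = TRUE),
                  matrix(6, 3, 3, byrow = TRUE))
  cr <- crystal_spec(coords, rep(10, 3), top, n_molecules = 2, fixed_atom = 1L)
  mc <- em_free_energy_mc(top, cr, 100, 0.1, 2000, seed = 5)
  expect_equal(unname(mc$decomposition["orientational"]), -log(8 * pi^2),
               tolerance = 1e-10)
})

test_that("rigid diatomic reference matches a deterministic grid oracle", {
  d <- 0.8; k <- 20
  top <- diatomic_topology(d = d)
  cr <- build_toy_molecular_crystal(top, c(2, 1, 1), 8)
  lam <- 0.2
  mc <- em_free_energy_mc(top, cr, k, lam, 4e4, seed = 9)

  # oracle: direct quadrature over orientations (sphere grid) and, for the
  # mobile molecule, a displacement grid around the lattice site
  sphere_grid <- function(nth, nph) {
    th <- seq(0, pi, length.out = nth + 2)[-c(1, nth + 2)]
    ph <- seq(0, 2 * pi, length.out = nph + 1)[-(nph + 1)]
    dth <- th[2] - th[1]; dph <- ph[2] - ph[1]
    list(dirs = cbind(rep(sin(th), each = nph) * cos(ph),
                      rep(sin(th), each = nph) * sin(ph),
                      rep(cos(th), each = nph)),
         wts = rep(sin(th), each = nph) * dth * dph)
  }
  ref1 <- cr$coords[1:2, ]
  piv <- ref1[1, ]
  arm <- sqrt(sum((ref1[2, ] - piv)^2))
  sg1 <- sphere_grid(120, 240)
  e1 <- exp(-k / 2 * rowSums((matrix(piv, nrow(sg1$dirs), 3, byrow = TRUE) +
                                arm * sg1$dirs -
                                matrix(ref1[2, ], nrow(sg1$dirs), 3, byrow = TRUE))^2))
  I1 <- sum(e1 * sg1$wts)

  sg2 <- sphere_grid(40, 80)
  dirs <- sg2$dirs; wts <- sg2$wts
  ref2 <- cr$coords[3:4, ]
  cen <- colMeans(ref2)
  half <- d / 2
  gs <- seq(-0.6, 0.6, length.out = 25)
  hg <- gs[2] - gs[1]
  grid <- as.matrix(expand.grid(gs, gs, gs))
  I2 <- 0
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    s1 <- matrix(cen - half * u, nrow(grid), 3, byrow = TRUE) + grid
    s2 <- matrix(cen + half * u, nrow(grid), 3, byrow = TRUE) + grid
    U <- k / 2 * (rowSums((s1 - matrix(ref2[1, ], nrow(grid), 3, byrow = TRUE))^2) +
                  rowSums((s2 - matrix(ref2[2, ], nrow(grid), 3, byrow = TRUE))^2))
    I2 <- I2 + sum(exp(-U)) * hg^3 * wts[i]
  }
  A_oracle <- log(2 * lam^3 / prod(cr$box)) - log(I1) - log(I2 / lam^3)
  expect_lt(abs(mc$A - A_oracle), 0.05)
  expect_lt(abs(mc$A - A_oracle), 3 * mc$se + 0.02)
})

test_that("MC reference is unbiased across seeds for a rigid diatomic", {
  top <- diatomic_topology(d = 0.8)
  cr <- build_toy_molecular_crystal(top, c(2, 1, 1), 8)
  k <- 20; lam <- 0.2
  runs <- vapply(1:20, function(s)
    em_free_energy_mc(top, cr, k, lam, 2000, seed = 100 + s)$A, 0)
  one <- em_free_energy_mc(top, cr, k, lam, 5e4, seed = 999)
  se_mean <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - one$A), 3 * sqrt(se_mean^2 + one$se^2))
})

test_that("the mobile-particle term is extensive in N - 1", {
  k <- 4000; V1 <- 125; lam <- lam_ar
  t3 <- function(N, V) em_free_energy_analytic(N, k, lam, V)$decomposition[["translational_orientational"]]
  expect_equal(t3(9, V1), 2 * t3(5, V1), tolerance = 1e-12)
})

test_that("symmetry correction follows -N log(sigma) and is additive", {
  expect_equal(symmetry_correction(100, 1), 0)
  expect_equal(symmetry_correction(64, 2), -64 * log(2))
  expect_equal(symmetry_correction(64, 2), -64 * log(2), tolerance = 1e-12)
  expect_equal(symmetry_correction(40, 3) + symmetry_correction(24, 3),
               symmetry_correction(64, 3), tolerance = 1e-12)
  expect_error(symmetry_correction(10, 0), "integer")
  expect_error(symmetry_correction(10, 1.5), "integer")
})
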