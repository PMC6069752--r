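test_that("solid chemical potential assembly reproduces the bundled crystal cycle", {
  comp <- asa_reference_data("solid_components")
  mbar <- comp[comp$estimator %in% c("MC", "MBAR"), ]
  v <- setNames(mbar$value, mbar$component)
  s <- setNames(mbar$sigma, mbar$component)
  solid <- assemble_solid_mu(v["A_EM"], v["dA_em_iem"], v["dA_iem_solid"],
                             N = 64, sigma_rot = 1L, per_molecule = TRUE,
                             se_A_EM = s["A_EM"], se_em_iem = s["dA_em_iem"],
                             se_iem_solid = s["dA_iem_solid"])
  expect_equal(unname(solid$mu), 48 - 167.07 - 101.644, tolerance = 1e-10)
  expect_equal(round(unname(solid$mu)), -221)
  expect_equal(unname(solid$se), sqrt(3^2 + 0.03^2 + 0.002^2), tolerance = 1e-10)

  # all-zero components with sigma_rot = 1 give zero
  expect_equal(assemble_solid_mu(0, 0, 0, N = 10)$mu, 0)
  # extensive inputs at N x the per-molecule values give the same mu
  a <- assemble_solid_mu(48, -167.07, -101.644, N = 64, per_molecule = TRUE)
  b <- assemble_solid_mu(64 * 48, 64 * -167.07, 64 * -101.644, N = 64)
  expect_equal(a$mu, b$mu, tolerance = 1e-10)
})

test_that("the symmetry number shifts mu by exactly -log(sigma) per molecule", {
  base <- assemble_solid_mu(10, -20, -5, N = 8)
  for (sr in c(2L, 3L, 6L)) {
    shifted <- assemble_solid_mu(10, -20, -5, N = 8, sigma_rot = sr)
    expect_equal(shifted$mu - base$mu, -log(sr), tolerance = 1e-12)
  }
})

test_that("PdV correction is tiny at crystal-relaxation scales and bilinear", {
  expect_equal(pdv_correction(101.325, 0, 298.15), 0)
  v <- pdv_correction(101.325, 0.14, 298.15)
  expect_equal(v, 3.45e-3, tolerance = 0.01)
  expect_lt(v, 0.01) # far below the k_BT-scale statistical error of the legs
  expect_equal(pdv_correction(2 * 101.325, 0.14, 298.15), 2 * v, tolerance = 1e-12)
  expect_equal(pdv_correction(101.325, 3 * 0.14, 298.15), 3 * v, tolerance = 1e-12)
})

test_that("a constructed logarithmic series crosses at the known concentration", {
  mu_solid <- -40
  x0 <- 0.013
  x <- exp(seq(log(1e-3), log(0.3), length.out = 12))
  series <- data.frame(x = x, mu = mu_solid + log(x / x0), sigma = 0.05)
  rep <- find_solubility(series, mu_solid, se_solid = 0.05)
  expect_equal(rep$verdict, "crossing")
  expect_equal(rep$x_star, x0, tolerance = 1e-6)
  # tie-break at exact equality returns the smaller concentration
  series2 <- data.frame(x = c(0.01, x0, 0.1, 0.2),
                        mu = mu_solid + log(c(0.01, x0, 0.1, 0.2) / x0))
  expect_equal(find_solubility(series2, mu_solid)$x_star, x0)
})

test_that("parallel curves yield range-relative verdicts, not extrapolation", {
  x <- c(0.001, 0.01, 0.1)
  above <- data.frame(x = x, mu = -10 + log(x) * 0, sigma = 0.1)
  rep1 <- find_solubility(above, -20, se_solid = 0.1)
  expect_equal(rep1$verdict, "insoluble-in-range")
  expect_true(rep1$confident)
  expect_true(is.na(rep1$x_star))
  rep2 <- find_solubility(above, 5, se_solid = 0.1)
  expect_equal(rep2$verdict, "supersaturated-in-range")
  expect_error(find_solubility(above[1, , drop = FALSE], -20), "two")
  expect_error(find_solubility(data.frame(x = c(1e-3, 1e-3), mu = c(0, 1)), -20),
               "duplicate")
})

test_that("bundled solid and solution tables reconstruct the insolubility verdict", {
  comp <- asa_reference_data("solid_components")
  mbar <- comp[comp$estimator %in% c("MC", "MBAR"), ]
  solid <- assemble_solid_mu(mbar$value[1], mbar$value[2], mbar$value[3],
                             N = 64, per_molecule = TRUE,
                             se_A_EM = mbar$sigma[1], se_em_iem = mbar$sigma[2],
                             se_iem_solid = mbar$sigma[3])
  legs <- asa_reference_data("standard_mu")
  mu0 <- mu_standard(legs$value[1], legs$value[2], legs$value[3],
                     legs$sigma[1], legs$sigma[2], legs$sigma[3])
  tab <- asa_reference_data("solution_series")
  series <- reconstruct_solution_series(tab, mu0$value, mu0$se,
                                        mass = 180.158, temperature = 298.15)
  rep <- find_solubility(setNames(series, c("x", "mu", "sigma")),
                         solid$mu, solid$se)
  expect_equal(rep$verdict, "insoluble-in-range")
  # the solution branch sits tens of k_BT above the solid everywhere sampled
  expect_gt(min(series$mu - solid$mu), 20)
})

test_that("interior concentrations never flip a confident verdict", {
  mu_solid <- -30
  x <- exp(seq(log(1e-4), log(0.2), length.out = 6))
  mu <- mu_solid + 8 + 0.5 * log(x / x[1]) # stays well above the solid
  series <- data.frame(x = x, mu = mu, sigma = 0.1)
  rep0 <- find_solubility(series, mu_solid, se_solid = 0.1)
  expect_true(rep0$confident)
  expect_equal(rep0$verdict, "insoluble-in-range")
  # refine with interior points interpolated from the same curve
  xi <- sort(c(x, sqrt(x[-1] * x[-length(x)])))
  seri <- data.frame(x = xi, mu = mu_solid + 8 + 0.5 * log(xi / x[1]),
                     sigma = 0.1)
  repi <- find_solubility(seri, mu_solid, se_solid = 0.1)
  expect_equal(repi$verdict, rep0$verdict)
})

test_that("solubility report prints and plots without error", {
  x <- c(0.001, 0.01, 0.1)
  series <- data.frame(x = x, mu = -5 + log(x / 0.01), sigma = 0.1)
  rep <- find_solubility(series, -5)
  expect_output(print(rep), "crossing")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(rep))
})
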