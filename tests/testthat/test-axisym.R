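# Oracle tests use deliberately short ducts and coarse-but-validated grids to
# keep runtimes low; the acceptance suite exercises the default resolution.

test_that("uniform duct recovers Poiseuille within 0.5%", {
  duct <- make_sinusoidal_duct(amp = 0, length = 40, dz = 1)
  prof <- axisym_resistance_profile(duct, mu = 1, n_eta = 33L, dzeta = 0.5)
  Rex <- 8 / (pi * 50^4)
  expect_lt(max(abs(prof$R_local[prof$included] / Rex - 1)), 0.005)
  expect_lt(attr(prof, "flux_error"), 0.005)
  expect_equal(prof$method, "ORACLE")
})

test_that("resistance is independent of the imposed flow rate", {
  duct <- make_sinusoidal_duct(length = 40, dz = 1)
  p1 <- axisym_resistance_profile(duct, mu = 1, Q = 2.19e4,
                                  n_eta = 17L, dzeta = 1)
  p2 <- axisym_resistance_profile(duct, mu = 1, Q = 2 * 2.19e4,
                                  n_eta = 17L, dzeta = 1)
  expect_equal(p1$R_local, p2$R_local, tolerance = 1e-9)
})

test_that("grid refinement changes the average resistance by < 1%", {
  duct <- make_sinusoidal_duct(length = 50, dz = 1)
  p1 <- axisym_resistance_profile(duct, mu = 1, n_eta = 17L, dzeta = 1)
  p2 <- axisym_resistance_profile(duct, mu = 1, n_eta = 33L, dzeta = 0.5)
  expect_lt(abs(p1$R_avg / p2$R_avg - 1), 0.01)
})

test_that("oracle refuses non-circular ducts", {
  duct <- make_bilobed_duct(seed = 1, length = 4, dz = 0.7)
  expect_error(axisym_resistance_profile(duct), "circular")
})

test_that("the second-order correction captures most of the oracle deviation", {
  # long-wavelength sinusoids: adding R2 to R0 shrinks the residual
  for (amp in c(1.5, 0.75)) {
    wl <- 200
    duct <- make_sinusoidal_duct(r0 = 50, amp = amp, wavelength = wl,
                                 length = wl, dz = 2)
    prof <- axisym_resistance_profile(duct, mu = 1, n_eta = 33L, dzeta = 1)
    z <- prof$z[prof$included]; Ror <- prof$R_local[prof$included]
    k <- 2 * pi / wl
    r <- 50 + amp * sin(k * z); dr <- amp * k * cos(k * z)
    d2r <- -amp * k^2 * sin(k * z)
    R0 <- 8 / (pi * r^4)
    R2 <- ellipse_R2(r, r, dr, dr, d2r, d2r, mu = 1)
    expect_lt(rms((Ror - R0 - R2) / R0), 0.8 * rms((Ror - R0) / R0))
  }
})

test_that("radial pressure fluctuations are antisymmetric about extrema", {
  duct <- make_sinusoidal_duct(length = 50, dz = 1)
  prof <- axisym_resistance_profile(duct, mu = 1, n_eta = 25L, dzeta = 0.5)
  f <- attr(prof, "field")
  # radial fluctuation P - Pmean(z) at the wall-adjacent ring
  pm <- 2 * ductresist:::colSums_trapz(f$p * matrix(f$eta, length(f$zeta),
                                                    length(f$eta),
                                                    byrow = TRUE),
                                       f$eta[2])
  fluct <- f$p[, length(f$eta) - 1L] - pm
  # nonzero, and of opposite sign on the two sides of the bulge at z = 12.5
  i_up <- which.min(abs(f$zeta - 7)); i_dn <- which.min(abs(f$zeta - 18))
  expect_gt(max(abs(fluct)), 0)
  expect_lt(fluct[i_up] * fluct[i_dn], 0)
})
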