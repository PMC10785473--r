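test_that("SUN matches closed forms for circles and ellipses within 0.5%", {
  R <- sun_resistance(circle_polygon(r = 5, n = 256L), mu = 1)
  expect_lt(abs(as.numeric(R) / (8 / (pi * 625)) - 1), 0.005)
  for (beta in c(1.5, 2, 3)) {
    c0 <- 3; b0 <- beta * c0
    Rex <- 4 * (b0^2 + c0^2) / (pi * b0^3 * c0^3)
    Rn <- as.numeric(sun_resistance(ellipse_polygon(b0, c0, n = 256L),
                                    mu = 1))
    expect_lt(abs(Rn / Rex - 1), 0.005)
  }
})

test_that("SUN scales as k^-4 and is invariant under rigid motion", {
  set.seed(21)
  v <- make_bilobed_duct(seed = 3)$sections[[10]]$vertices
  R1 <- as.numeric(sun_resistance(v, mu = 1))
  R2 <- as.numeric(sun_resistance(v * 2, mu = 1))
  expect_equal(R2, R1 / 16, tolerance = 1e-6)
  for (k in 1:3) {
    vr <- rotate_translate(v, runif(1, 0, 2 * pi), rnorm(2, sd = 5))
    expect_lt(abs(as.numeric(sun_resistance(vr, mu = 1)) / R1 - 1), 1e-3)
  }
})

test_that("SUN converges monotonically to the circle solution", {
  Rex <- 8 / (pi * 5^4)
  errs <- vapply(c(0.5, 0.25, 0.125), function(h)
    abs(as.numeric(sun_resistance(circle_polygon(r = 5, n = 256L), mu = 1,
                                  mesh_size = h)) / Rex - 1), numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("SUA is Hagen-Poiseuille and agrees with the ellipse formula", {
  expect_equal(sua_circle(1, mu = 1), 8 / pi)
  expect_equal(sua_circle(2, mu = 1), sua_circle(1, mu = 1) / 16)
  expect_equal(sua_circle(1.7, mu = 1), ellipse_R0(1.7, 1.7, mu = 1))
  expect_error(sua_circle(-1), "r_eq")
})

test_that("the circle minimizes resistance at fixed area", {
  secs <- c(lapply(1:4, function(s) make_bilobed_duct(seed = s)$sections[[8]]),
            list(cross_section(ellipse_polygon(4, 2, n = 128L), z = 0,
                               check = FALSE)))
  set.seed(5)
  secs <- c(secs, list(cross_section(random_star_polygon(r0 = 4), z = 0,
                                     check = FALSE)))
  for (s in secs) {
    m <- polygon_metrics(s)
    expect_gte(as.numeric(sun_resistance(s, mu = 1)),
               sua_circle(m$r_eq, mu = 1))
  }
})

test_that("series profiles are flat on uniform circular ducts", {
  duct <- make_sinusoidal_duct(r0 = 5, amp = 0, length = 5, dz = 1,
                               n_vertices = 128L)
  Rex <- 8 / (pi * 5^4)
  for (method in c("SUN", "SUA", "II", "III", "IV")) {
    prof <- series_profile(duct, mu = 1, method = method)
    expect_lt(max(abs(prof$R_local / Rex - 1)), 0.005)
    expect_lt(diff(range(prof$R_local)) / Rex, 0.005)
  }
})

test_that("SUA profile of the sinusoidal duct peaks at constrictions", {
  duct <- make_sinusoidal_duct(length = 50, dz = 2.5)
  an <- attr(duct, "analytic")
  prof <- series_profile(duct, mu = 1, method = "SUA")
  expect_equal(prof$R_local, 8 / (pi * an$r(prof$z)^4), tolerance = 1e-9)
  expect_equal(prof$z[which.max(prof$R_local)],
               prof$z[which.min(an$r(prof$z))])
})

test_that("profile summaries integrate and dispatch correctly", {
  p <- resistance_profile(z = c(0, 1), R_local = c(1, 3), method = "SUA")
  expect_equal(p$R_total, 2)   # trapezoid
  expect_equal(p$R_avg, 2)
  duct <- make_bilobed_duct(seed = 1, length = 4, dz = 0.7)
  expect_error(series_profile(duct, method = "SUA"), "non-circular")
})
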