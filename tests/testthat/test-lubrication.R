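test_that("zeroth-order ellipse resistance matches its two closed forms", {
  expect_equal(ellipse_R0(1, 1, mu = 1), 8 / pi)
  expect_equal(ellipse_R0(2, 1, mu = 1), 20 / (8 * pi))
  set.seed(13)
  for (k in 1:20) {
    b <- runif(1, 0.5, 5); c0 <- runif(1, 0.5, b)
    expect_equal(ellipse_R0(b, c0, mu = 1),
                 R0_from_area_beta(pi * b * c0, b / c0, mu = 1),
                 tolerance = 1e-12)
  }
})

test_that("second-order resistance: taper value, symmetry, uniform limit", {
  expect_equal(ellipse_R2(1, 1, 0, 0, 0, 0, mu = 1), 0)
  # linear taper b = c = r, slope s: R2 = -16 mu s^2 / (3 pi r^4)
  expect_equal(ellipse_R2(1, 1, 0.1, 0.1, 0, 0, mu = 1),
               -16 * 0.01 / (3 * pi), tolerance = 1e-12)
  # swapping the two axes (with their derivatives) leaves R2 unchanged
  set.seed(29)
  for (k in 1:10) {
    p <- runif(6, -0.5, 0.5); p[1:2] <- abs(p[1:2]) + 0.5
    expect_equal(ellipse_R2(p[1], p[2], p[3], p[4], p[5], p[6], mu = 1),
                 ellipse_R2(p[2], p[1], p[4], p[3], p[6], p[5], mu = 1),
                 tolerance = 1e-12)
  }
})

test_that("general and fixed-aspect-ratio second-order forms agree when self-similar", {
  set.seed(31)
  for (k in 1:20) {
    beta <- runif(1, 1, 4)
    c0 <- runif(1, 0.5, 3); dc <- runif(1, -0.3, 0.3); d2c <- runif(1, -0.2, 0.2)
    b <- beta * c0; db <- beta * dc; d2b <- beta * d2c
    A <- pi * b * c0
    dA <- 2 * pi * beta * c0 * dc
    d2A <- 2 * pi * beta * (dc^2 + c0 * d2c)
    r40 <- ellipse_R2(b, c0, db, dc, d2b, d2c, mu = 1)
    r41 <- fixed_beta_R2(A, dA, d2A, beta = beta, mu = 1)
    expect_equal(r40, r41, tolerance = 1e-10)
  }
  expect_equal(fixed_beta_R2(100, 0, 0, beta = 2, mu = 1), 0)
})

test_that("circular sinusoid: fixed-beta form tracks the general form", {
  k <- 2 * pi / 50
  z <- seq(0, 50, by = 2.5)
  r <- 50 + 1.5 * sin(k * z); dr <- 1.5 * k * cos(k * z)
  d2r <- -1.5 * k^2 * sin(k * z)
  r40 <- ellipse_R2(r, r, dr, dr, d2r, d2r, mu = 1)
  r41 <- fixed_beta_R2(pi * r^2, 2 * pi * r * dr,
                       2 * pi * (dr^2 + r * d2r), beta = 1, mu = 1)
  expect_equal(r40, r41, tolerance = 1e-10)
})

test_that("error prefactor: circular value, reciprocity, 13.3% bound", {
  expect_equal(beta_prefactor(1), 1 / (6 * pi))
  for (beta in c(2, 3, 5))
    expect_equal(beta_prefactor(beta), beta_prefactor(1 / beta),
                 tolerance = 1e-12)
  dev <- beta_prefactor_deviation(7)
  expect_equal(dev$grid, 13.33, tolerance = 1e-2)
  expect_equal(dev$continuous, 13.3, tolerance = 1e-2)
})

test_that("series-unidirectional error has the predicted sign structure", {
  # uniform duct: zero error
  expect_equal(elt_error(100, 0, 0)$full, 0)
  k <- 2 * pi / 50
  z <- seq(0, 50, by = 1)
  r <- 50 + 1.5 * sin(k * z); dr <- 1.5 * k * cos(k * z)
  d2A <- 2 * pi * (dr^2 + r * (-1.5 * k^2 * sin(k * z)))
  er <- elt_error(pi * r^2, 2 * pi * r * dr, d2A)
  # positive (underestimate) at constrictions where A'' > 0, negative at bulges
  expect_true(all(er$full[d2A > 2] > 0))
  expect_true(all(er$full[d2A < -2] < 0))
  expect_equal(er$leading, d2A / (6 * pi), tolerance = 1e-12)
})

test_that("lambda correction inverts the error line", {
  expect_equal(lambda_factor(correction_model("circular"), 0), 100 / 100.22)
  expect_equal(lambda_factor(correction_model("analytic"), 0), 1)
  expect_equal(correction_model("realistic")$slope, -1.8)
  expect_equal(correction_model("realistic")$intercept, -3.2)
  expect_equal(correction_model("analytic")$slope, -100 / (6 * pi))
  expect_error(lambda_factor(correction_model("circular"), 30), "validity")

  prof <- resistance_profile(z = 0:3, R_local = rep(2, 4), method = "SUA",
                             d2A = c(-1, 0, 1, 2))
  corr <- lambda_correct(prof, correction_model("analytic"))
  expect_equal(corr$method, "SUA.lambda")
  expect_equal(corr$R_local,
               2 * 100 / (100 - 100 / (6 * pi) * c(-1, 0, 1, 2)))
})
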