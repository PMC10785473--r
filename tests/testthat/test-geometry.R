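test_that("polygon metrics recover circle and ellipse limits", {
  m <- polygon_metrics(circle_polygon(r = 5, n = 1000L))
  expect_equal(m$A, pi * 25, tolerance = 1e-6)
  expect_equal(m$beta, 1, tolerance = 1e-6)
  expect_equal(m$I_p, pi * 5^4 / 2, tolerance = 1e-4)
  expect_equal(m$D_h, 2 * m$r_eq, tolerance = 1e-4)

  me <- polygon_metrics(ellipse_polygon(2, 1, n = 1000L))
  expect_equal(me$beta, 2, tolerance = 1e-6)
  expect_equal(me$A, 2 * pi, tolerance = 1e-9)
  expect_equal(me$I_p, pi * 2 * 1 * (4 + 1) / 4, tolerance = 1e-4)
})

test_that("polygon second moments match Monte-Carlo integration", {
  # square, side 2: closed form I_p = 8/3, checked against dense MC
  sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  m <- polygon_metrics(sq)
  expect_equal(m$A, 4)
  expect_equal(m$I_p, 8 / 3, tolerance = 1e-12)
  set.seed(11)
  px <- runif(1e6, -1, 1); py <- runif(1e6, -1, 1)
  expect_equal(m$I_p, 4 * mean(px^2 + py^2), tolerance = 5e-3)

  # random convex and star-shaped polygons against rejection-sampling MC
  set.seed(42)
  for (k in 1:5) {
    for (v in list(random_convex_polygon(), random_star_polygon())) {
      m <- polygon_metrics(v)
      mc <- mc_polygon_moments(v)
      expect_equal(m$A, mc$A, tolerance = 5e-3)
      expect_equal(m$I_p, mc$I_p, tolerance = 5e-3)
    }
  }
})

test_that("hydraulic diameter never exceeds the equivalent-circle diameter", {
  set.seed(7)
  for (k in 1:10) {
    v <- if (k %% 2) random_convex_polygon() else random_star_polygon()
    m <- polygon_metrics(v)
    expect_lte(m$D_h, 2 * m$r_eq * (1 + 1e-12))
  }
})

test_that("matched-ellipse beta is invariant under rigid motion", {
  set.seed(3)
  v <- random_star_polygon()
  m0 <- polygon_metrics(v)
  for (k in 1:5) {
    v2 <- rotate_translate(v, runif(1, 0, 2 * pi), rnorm(2, sd = 10))
    expect_equal(polygon_metrics(v2)$beta, m0$beta, tolerance = 1e-10)
  }
})

test_that("cross_section validates and orients its polygon", {
  expect_error(cross_section(rbind(c(0, 0), c(1, 0)), z = 0), "3 vertices")
  # polygon with crossing edges
  expect_error(cross_section(rbind(c(0, 0), c(3, 0), c(3, 2), c(1.5, -1),
                                   c(0, 2)), z = 0),
               "self-intersecting")
  # clockwise input is reversed to counter-clockwise
  cw <- circle_polygon(r = 1, n = 32L)[32:1, ]
  s <- cross_section(cw, z = 0)
  expect_gt(ductresist:::signed_area(s$vertices), 0)
})

test_that("area-profile differentiation is exact for quadratics", {
  mk <- function(afun, zmax = 20, dz = 0.7)
    build_duct(lapply(seq(0, zmax, by = dz), function(z)
      cross_section(circle_polygon(area = afun(z), n = 64L), z = z,
                    check = FALSE)), resample_dz = dz)
  d1 <- mk(function(z) 100)
  expect_equal(max(abs(d1$grid$dA)), 0, tolerance = 1e-9)
  expect_equal(max(abs(d1$grid$d2A)), 0, tolerance = 1e-9)

  d2 <- mk(function(z) (z + 5)^2, zmax = 100)
  expect_equal(d2$grid$d2A, rep(2, length(d2$grid$z)), tolerance = 1e-7)

  # sinusoidal duct: A''(12.5) = 2 pi (r r'' + r'^2) ~ -7.665
  duct <- make_sinusoidal_duct()
  expect_equal(area_profile_at(duct, 12.5, "d2A"), -7.664752,
               tolerance = 3e-3)
})

test_that("build_duct rejects non-monotone stations", {
  secs <- lapply(c(0, 1, 2, 1.5, 3), function(z)
    cross_section(circle_polygon(r = 2, n = 32L), z = z, check = FALSE))
  expect_error(build_duct(secs), "strictly increasing")
})

test_that("circularization preserves the area profile on a straight axis", {
  duct <- make_bilobed_duct(seed = 2)
  circ <- circularize(duct)
  expect_equal(circ$grid$A, duct$grid$A, tolerance = 1e-9)
  expect_true(all(vapply(circ$sections, ductresist:::is_circular_section,
                         logical(1))))
  # constant elliptical duct circularizes to r_eq = sqrt(b c)
  ed <- make_elliptical_duct(function(z) 2, function(z) 1, length = 5, dz = 1)
  ec <- circularize(ed)
  expect_equal(polygon_metrics(ec$sections[[3]])$r_eq, sqrt(2),
               tolerance = 1e-9)
})

test_that("Dean number and centerline curvature behave as expected", {
  expect_equal(dean_number(1e-3, 6, 100), 1e-3 * sqrt(6 / 100))
  expect_equal(dean_number(0, 6, 100), 0)
  expect_error(dean_number(1e-3, 6, 0), "r_c")
  # straight centerline: infinite curvature radius, De -> 0
  duct <- make_sinusoidal_duct(length = 10, dz = 1)
  rc <- centerline_curvature_radius(duct)
  expect_true(all(is.infinite(rc)))
  expect_equal(dean_number(1e-3, 6, rc[1]), 0)
  # three points on a known circle
  expect_equal(ductresist:::circumradius3(c(10, 0, 0), c(0, 10, 0),
                                          c(-10, 0, 0)), 10)
})
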