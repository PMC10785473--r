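#' Area-exact circle polygon
#'
#' Regular n-gon whose polygon (shoelace) area equals the requested circle
#' area exactly: the vertex radius is inflated by the inscribed-polygon area
#' deficit, so downstream area-based quantities are free of discretization
#' bias.
#'
#' @param r circle radius (um); ignored if `area` is given.
#' @param area target polygon area (um^2); default `pi * r^2`.
#' @param n number of vertices.
#' @return an `n` x 2 vertex matrix.
#' @export
circle_polygon <- function(r = NULL, area = NULL, n = 128L) {
  if (is.null(area)) area <- pi * r^2
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rv <- sqrt(2 * area / (n * sin(2 * pi / n)))
  cbind(rv * cos(th), rv * sin(th))
}

#' Area-exact ellipse polygon
#'
#' Ellipse with semi-axes `b` (x) and `c` (y), discretized at `n` parameter
#' angles and uniformly inflated so the polygon area is exactly `pi*b*c`
#' (the aspect ratio is preserved).
#'
#' @param b,c semi-axes (um).
#' @param n number of vertices.
#' @return an `n` x 2 vertex matrix.
#' @export
ellipse_polygon <- function(b, c, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  s <- sqrt(2 * pi / (n * sin(2 * pi / n)))
  cbind(s * b * cos(th), s * c * sin(th))
}

#' Circular duct with sinusoidally varying radius
#'
#' The benchmark duct `r(z) = r0 + amp * sin(2*pi*z/wavelength)` with circular
#' cross sections on a straight axis. The default parameters give
#' `r = 50 + 1.5 sin(2*pi*z/50)` micrometres. Analytic callbacks for r(z),
#' A(z) and its derivatives are attached as attribute `"analytic"` for
#' cross-checking finite-difference profiles.
#'
#' @param r0 mean radius (um).
#' @param amp amplitude (um); must satisfy `amp < r0`.
#' @param wavelength axial wavelength (um).
#' @param length duct length (um); default 100 (two wavelengths at defaults).
#' @param dz station spacing (um).
#' @param n_vertices vertices per circle polygon.
#' @return a `duct_geometry`.
#' @export
make_sinusoidal_duct <- function(r0 = 50, amp = 1.5, wavelength = 50,
                                 length = 100, dz = 0.7, n_vertices = 128L) {
  if (amp >= r0) stop("invalid spec: amp must be < r0")
  if (dz <= 0) stop("invalid spec: dz must be > 0")
  k <- 2 * pi / wavelength
  rfun  <- function(z) r0 + amp * sin(k * z)
  drfun <- function(z) amp * k * cos(k * z)
  d2rfun <- function(z) -amp * k^2 * sin(k * z)
  z <- seq(0, length, by = dz)
  secs <- lapply(z, function(zi) {
    cross_section(circle_polygon(area = pi * rfun(zi)^2, n = n_vertices),
                  z = zi, check = FALSE)
  })
  duct <- build_duct(secs, resample_dz = dz)
  attr(duct, "analytic") <- list(
    r = rfun, A = function(z) pi * rfun(z)^2,
    dA = function(z) 2 * pi * rfun(z) * drfun(z),
    d2A = function(z) 2 * pi * (rfun(z) * d2rfun(z) + drfun(z)^2))
  duct
}

#' Elliptical duct with axially varying semi-axes
#'
#' Cross sections are ellipses `(x/b(z))^2 + (y/c(z))^2 = 1`. The semi-axis
#' callbacks (and, optionally, their analytic derivatives) are attached as
#' attribute `"analytic"` so extended-lubrication evaluations can use exact
#' derivatives; when derivative callbacks are not supplied they are formed by
#' central differencing of `b` and `c` with a small step.
#'
#' @param b_of_z,c_of_z functions of z returning the semi-axes (um, > 0).
#' @param length duct length (um).
#' @param dz station spacing (um).
#' @param n_vertices vertices per ellipse polygon.
#' @param derivs optional list with functions `db`, `dc`, `d2b`, `d2c`.
#' @return a `duct_geometry`.
#' @export
make_elliptical_duct <- function(b_of_z, c_of_z, length, dz = 0.7,
                                 n_vertices = 128L, derivs = NULL) {
  z <- seq(0, length, by = dz)
  bv <- vapply(z, b_of_z, numeric(1))
  cv <- vapply(z, c_of_z, numeric(1))
  if (any(bv <= 0) || any(cv <= 0))
    stop("invalid spec: semi-axes must be > 0 over the duct")
  secs <- lapply(seq_along(z), function(i) {
    cross_section(ellipse_polygon(bv[i], cv[i], n = n_vertices),
                  z = z[i], check = FALSE)
  })
  duct <- build_duct(secs, resample_dz = dz)
  h <- dz / 10
  num_d1 <- function(f) function(z) (f(z + h) - f(z - h)) / (2 * h)
  num_d2 <- function(f) function(z) (f(z + h) - 2 * f(z) + f(z - h)) / h^2
  if (is.null(derivs))
    derivs <- list(db = num_d1(b_of_z), dc = num_d1(c_of_z),
                   d2b = num_d2(b_of_z), d2c = num_d2(c_of_z))
  attr(duct, "analytic") <- c(list(b = b_of_z, c = c_of_z), derivs)
  duct
}

#' Synthetic bi-lobed (perivascular-space-like) duct
#'
#' Generates a single-lobe, partly concave duct emulating the shape
#' statistics of segmented murine pial perivascular spaces: each section is an
#' incomplete-annulus lobe hugging a circular blood vessel, built as the
#' region between the vessel wall and an outer bulge over a limited angular
#' span. Sections are uniformly rescaled so the mean cross-sectional area
#' equals `target_area`; the matched-ellipse aspect ratio beta then falls in
#' the observed range (roughly 1.1 to 2) for the default construction
#' parameters. The axial area modulation is a smooth sinusoid.
#'
#' The generator is deterministic for a fixed `seed`: the seed draws the
#' angular span, lobe thickness and modulation phase once per duct.
#'
#' @param vessel_radius blood-vessel radius (um). The defaults place the
#'   matched-ellipse aspect ratio of generated sections in the middle of the
#'   range observed for murine pial lobes (about 1.1 to 2).
#' @param lobe_scale nominal lobe thickness (um) before area rescaling.
#' @param eccentricity stretch factor applied along the arc (chord) direction;
#'   1 leaves the shape untouched.
#' @param axial_modulation list with `amp` (relative area amplitude, e.g. 0.15)
#'   and `wavelength` (um).
#' @param target_area mean cross-sectional area (um^2).
#' @param length duct length (um).
#' @param dz station spacing (um).
#' @param n_vertices boundary points per section.
#' @param seed integer seed; identical seeds give identical ducts.
#' @return a `duct_geometry`; attribute `"stats"` holds the achieved mean
#'   area and the per-section beta range.
#' @export
make_bilobed_duct <- function(vessel_radius = 8, lobe_scale = 8,
                              eccentricity = 1,
                              axial_modulation = list(amp = 0.15,
                                                      wavelength = 25),
                              target_area = 100, length = 35, dz = 0.7,
                              n_vertices = 100L, seed = 1L) {
  stopifnot(vessel_radius > 0, lobe_scale > 0, target_area > 0)
  rng <- local({ set.seed(as.integer(seed)); list(
    span  = stats::runif(1, 0.8, 1.1),         # angular half-span (rad)
    thick = lobe_scale * stats::runif(1, 0.85, 1.15),
    phase = stats::runif(1, 0, 2 * pi),
    jitter = stats::runif(10, -0.05, 0.05)) })
  z <- seq(0, length, by = dz)
  m <- axial_modulation
  scale_z <- sqrt(1 + m$amp * sin(2 * pi * z / m$wavelength + rng$phase))

  base_section <- function(jit) {
    th <- seq(-rng$span * (1 + jit), rng$span * (1 + jit),
              length.out = ceiling(n_vertices / 2))
    f <- 0.15 + 0.85 * cos(th / max(abs(th)) * pi / 2)^1.5
    r_out <- vessel_radius + rng$thick * f
    outer <- cbind(r_out * sin(th), r_out * cos(th) - vessel_radius)
    thi <- rev(th)
    inner <- cbind(vessel_radius * 0.999 * sin(thi),
                   vessel_radius * 0.999 * cos(thi) - vessel_radius)
    v <- rbind(outer, inner)
    v[, 1L] <- v[, 1L] * eccentricity
    if (signed_area(v) < 0) v <- v[nrow(v):1L, , drop = FALSE]
    v
  }

  for (attempt in 1:10) {
    v0 <- base_section(if (attempt == 1) 0 else rng$jitter[attempt])
    if (is_simple_polygon(v0)) break
    if (attempt == 10) stop("bi-lobe generation failed: self-intersecting polygon")
  }
  A0 <- polygon_metrics(v0)$A
  s0 <- sqrt(target_area / A0)     # rescale so mean area hits the target
  secs <- lapply(seq_along(z), function(i) {
    cross_section(v0 * (s0 * scale_z[i]), z = z[i], check = FALSE)
  })
  duct <- build_duct(secs, resample_dz = dz)
  betas <- vapply(secs, function(s) polygon_metrics(s)$beta, numeric(1))
  areas <- vapply(secs, function(s) polygon_metrics(s)$A, numeric(1))
  attr(duct, "stats") <- list(mean_area = mean(areas),
                              beta_range = range(betas),
                              mean_beta = mean(betas))
  duct
}
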