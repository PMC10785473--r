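#' Planar cross section of a duct
#'
#' Constructs a validated cross section: a simple, counter-clockwise polygon
#' in its local (in-plane) frame, together with its axial station along the
#' centerline, the 3D centerline point it is attached to, and the unit axial
#' vector normal to the section plane. All lengths are in micrometres.
#'
#' @param vertices two-column numeric matrix of boundary points (um), ordered
#'   along the boundary. Clockwise input is silently reversed to
#'   counter-clockwise; a closing duplicate of the first vertex is dropped.
#' @param z axial station (um).
#' @param centerline_point length-3 numeric, 3D location of the section centre
#'   on the centerline (um). Defaults to `(0, 0, z)` (straight axis).
#' @param axial_vector length-3 unit vector normal to the section plane.
#'   Defaults to `(0, 0, 1)`.
#' @param check if `TRUE` (default) verify the polygon is simple. The check is
#'   O(n^2) in the vertex count; generators that construct polygons known to
#'   be simple may skip it.
#' @return an object of class `cross_section`.
#' @export
cross_section <- function(vertices, z,
                          centerline_point = c(0, 0, z),
                          axial_vector = c(0, 0, 1),
                          check = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L)
    stop("`vertices` must be a two-column matrix of (x, y) points")
  storage.mode(vertices) <- "double"
  n <- nrow(vertices)
  if (n >= 2L && all(abs(vertices[n, ] - vertices[1L, ]) < 1e-12)) {
    vertices <- vertices[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop("invalid geometry: polygon needs at least 3 vertices")
  if (!all(is.finite(vertices))) stop("invalid geometry: non-finite vertex")
  a <- signed_area(vertices)
  if (abs(a) < 1e-12)
    stop("invalid geometry: polygon area is zero (degenerate)")
  if (a < 0) {                       # enforce counter-clockwise orientation
    vertices <- vertices[n:1L, , drop = FALSE]
    a <- -a
  }
  if (check && !is_simple_polygon(vertices))
    stop("invalid geometry: polygon is self-intersecting")
  axial_vector <- axial_vector / sqrt(sum(axial_vector^2))
  structure(
    list(z = as.numeric(z), vertices = vertices,
         centerline_point = as.numeric(centerline_point),
         axial_vector = as.numeric(axial_vector)),
    class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  m <- polygon_metrics(x)
  cat(sprintf(
    "<cross_section> z = %.3f um, %d vertices, A = %.3f um^2, beta = %.3f\n",
    x$z, nrow(x$vertices), m$A, m$beta))
  invisible(x)
}

signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]) / 2
}

# Simplicity test: no two non-adjacent edges intersect.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  x1 <- v[, 1L]; y1 <- v[, 2L]; x2 <- v[j, 1L]; y2 <- v[j, 2L]
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  a <- idx[, 1L]; b <- idx[, 2L]
  adj <- (b - a == 1L) | (a == 1L & b == n)      # shared endpoint
  a <- a[!adj]; b <- b[!adj]
  if (!length(a)) return(TRUE)
  !any(segments_cross(x1[a], y1[a], x2[a], y2[a],
                      x1[b], y1[b], x2[b], y2[b]))
}

segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Exact polygon metrics of a cross section
#'
#' Area, wetted perimeter, hydraulic diameter, equivalent radius, centroid,
#' central second moments, polar moment, and the matched-ellipse aspect ratio
#' beta, all from closed-form polygon (shoelace-type) formulas.
#'
#' `beta = sqrt(lambda1/lambda2)` where `lambda1 >= lambda2` are the
#' eigenvalues of the central second-moment tensor
#' `[[Int x^2 dA, Int xy dA], [Int xy dA, Int y^2 dA]]` (coordinates relative
#' to the centroid). For an ellipse with semi-axes `b >= c` this recovers
#' `b/c`, so beta is the aspect ratio of the ellipse with the same second
#' moments as the section. `I_xx = Int y^2 dA` and `I_yy = Int x^2 dA` follow
#' the engineering (bending-axis) convention; `I_p = I_xx + I_yy`.
#'
#' @param section a `cross_section`, or a two-column vertex matrix.
#' @return a list with elements `A`, `P`, `D_h`, `r_eq`, `centroid`,
#'   `I_xx`, `I_yy`, `I_xy`, `I_p`, `beta`.
#' @export
polygon_metrics <- function(section) {
  v <- if (inherits(section, "cross_section")) section$vertices
       else as.matrix(section)
  n <- nrow(v)
  if (n < 3L) stop("invalid geometry: polygon needs at least 3 vertices")
  j <- c(2:n, 1L)
  x <- v[, 1L]; y <- v[, 2L]; xj <- x[j]; yj <- y[j]
  cr <- x * yj - xj * y
  A <- sum(cr) / 2
  if (A <= 0) stop("invalid geometry: area <= 0")
  P <- sum(sqrt((xj - x)^2 + (yj - y)^2))
  cx <- sum((x + xj) * cr) / (6 * A)
  cy <- sum((y + yj) * cr) / (6 * A)
  # second moments about the origin, then shift to the centroid
  Jx  <- sum((x^2 + x * xj + xj^2) * cr) / 12
  Jy  <- sum((y^2 + y * yj + yj^2) * cr) / 12
  Jxy <- sum((x * yj + 2 * x * y + 2 * xj * yj + xj * y) * cr) / 24
  Jx  <- Jx  - A * cx^2
  Jy  <- Jy  - A * cy^2
  Jxy <- Jxy - A * cx * cy
  ev <- eigen(matrix(c(Jx, Jxy, Jxy, Jy), 2L, 2L), symmetric = TRUE,
              only.values = TRUE)$values
  beta <- sqrt(max(ev[1L], 0) / max(ev[2L], .Machine$double.xmin))
  list(A = A, P = P, D_h = 4 * A / P, r_eq = sqrt(A / pi),
       centroid = c(cx, cy),
       I_xx = Jy, I_yy = Jx, I_xy = Jxy, I_p = Jx + Jy,
       beta = max(beta, 1))
}

#' Resample a polygon boundary at equal arc-length spacing
#'
#' @param vertices two-column vertex matrix (closed implicitly).
#' @param n number of output boundary points.
#' @return an `n` x 2 matrix of points on the boundary, equally spaced in arc
#'   length, starting at the first vertex.
#' @export
resample_boundary <- function(vertices, n) {
  v <- rbind(as.matrix(vertices), vertices[1L, ])
  seg <- sqrt(diff(v[, 1L])^2 + diff(v[, 2L])^2)
  s <- c(0, cumsum(seg))
  st <- seq(0, s[length(s)], length.out = n + 1L)[-(n + 1L)]
  cbind(stats::approx(s, v[, 1L], xout = st)$y,
        stats::approx(s, v[, 2L], xout = st)$y)
}

point_in_polygon <- function(px, py, vertices) {
  pracma::inpolygon(px, py, vertices[, 1L], vertices[, 2L],
                    boundary = FALSE)
}

#' Assemble a duct geometry from ordered cross sections
#'
#' Collects the sections, samples the area profile A(z) at the stations,
#' interpolates it onto a uniform grid (cubic spline), optionally smooths it
#' with a centred boxcar, and differentiates it by central finite differences
#' (second-order one-sided stencils at the two ends). The derivative scheme on
#' the uniform grid is exact for area profiles that are polynomials of degree
#' <= 2.
#'
#' @param sections list of `cross_section` objects with strictly increasing z.
#' @param resample_dz uniform grid spacing for the area profile (um).
#' @param smooth_window optional odd integer width of a boxcar smoother
#'   applied to A(z) before differentiation; `NULL` (default) disables
#'   smoothing. The window used is recorded in the result.
#' @return an object of class `duct_geometry` with elements `sections`, `z`
#'   (stations), `spacing` (median station spacing), and `grid`, a list with
#'   the uniform-grid samples `z`, `A`, `dA`, `d2A`.
#' @export
build_duct <- function(sections, resample_dz = 0.7, smooth_window = NULL) {
  if (length(sections) < 5L) stop("need at least 5 cross sections")
  z <- vapply(sections, function(s) s$z, numeric(1))
  if (any(diff(z) <= 0)) {
    i <- which(diff(z) <= 0)[1L]
    stop(sprintf("sections must have strictly increasing z (section %d, z = %g, follows z = %g)",
                 i + 1L, z[i + 1L], z[i]))
  }
  A <- vapply(sections, function(s) polygon_metrics(s)$A, numeric(1))
  zg <- seq(z[1L], z[length(z)], by = resample_dz)
  Ag <- stats::spline(z, A, xout = zg, method = "fmm")$y
  if (!is.null(smooth_window)) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L) stop("smooth_window must be odd")
    if (w > 1L) {
      k <- rep(1 / w, w)
      sm <- stats::filter(Ag, k, sides = 2)
      Ag[!is.na(sm)] <- sm[!is.na(sm)]   # ends left unsmoothed
    }
  }
  d <- fd_derivatives(zg, Ag)
  structure(
    list(sections = sections, z = z, spacing = stats::median(diff(z)),
         grid = list(z = zg, A = Ag, dA = d$d1, d2A = d$d2),
         smooth_window = smooth_window),
    class = "duct_geometry")
}

# central differences with second-order one-sided stencils at the ends;
# exact for polynomials of degree <= 2 on a uniform grid
fd_derivatives <- function(z, f) {
  n <- length(z)
  h <- z[2L] - z[1L]
  d1 <- d2 <- numeric(n)
  i <- 2:(n - 1L)
  d1[i] <- (f[i + 1L] - f[i - 1L]) / (2 * h)
  d2[i] <- (f[i + 1L] - 2 * f[i] + f[i - 1L]) / h^2
  d1[1L] <- (-3 * f[1L] + 4 * f[2L] - f[3L]) / (2 * h)
  d1[n]  <- (3 * f[n] - 4 * f[n - 1L] + f[n - 2L]) / (2 * h)
  d2[1L] <- (f[1L] - 2 * f[2L] + f[3L]) / h^2
  d2[n]  <- (f[n] - 2 * f[n - 1L] + f[n - 2L]) / h^2
  list(d1 = d1, d2 = d2)
}

#' @export
print.duct_geometry <- function(x, ...) {
  cat(sprintf(
    "<duct_geometry> %d sections, z in [%.2f, %.2f] um (spacing %.3f), mean A = %.2f um^2\n",
    length(x$sections), x$z[1L], x$z[length(x$z)], x$spacing,
    mean(x$grid$A)))
  invisible(x)
}

#' Interpolate the area profile and its derivatives at arbitrary stations
#'
#' @param duct a `duct_geometry`.
#' @param z stations (um) at which to evaluate.
#' @param what one of `"A"`, `"dA"`, `"d2A"`.
#' @return numeric vector of interpolated values.
#' @export
area_profile_at <- function(duct, z, what = c("A", "dA", "d2A")) {
  what <- match.arg(what)
  stats::approx(duct$grid$z, duct$grid[[what]], xout = z, rule = 2)$y
}

#' Replace every section by a circle of equal area on a straight axis
#'
#' Builds the circularized companion duct: same area profile A(z), straight
#' centerline, circular cross sections. Isolates the effect of area variation
#' from the effect of shape. The circle polygons are area-exact: the inscribed
#' polygon radius is inflated so the polygon area equals the target area.
#'
#' @param duct a `duct_geometry`.
#' @param n_vertices vertices per circle polygon (default 128).
#' @return a new `duct_geometry` with circular sections.
#' @export
circularize <- function(duct, n_vertices = 128L) {
  secs <- lapply(duct$sections, function(s) {
    A <- polygon_metrics(s)$A
    cross_section(circle_polygon(area = A, n = n_vertices), z = s$z,
                  centerline_point = c(0, 0, s$z), check = FALSE)
  })
  build_duct(secs, resample_dz = duct$grid$z[2L] - duct$grid$z[1L],
             smooth_window = duct$smooth_window)
}

#' Dean number of a curved duct
#'
#' `De = Re * sqrt(r_e / r_c)` where `Re` is the Reynolds number, `r_e` the
#' equivalent (same-area circle) radius and `r_c` the radius of curvature of
#' the centerline. Measures the strength of curvature-induced secondary flow;
#' values around 1e-4, as in pial perivascular spaces, make centerline
#' curvature negligible for resistance.
#'
#' @param Re Reynolds number (dimensionless, >= 0).
#' @param r_e equivalent radius (um, > 0).
#' @param r_c centerline radius of curvature (um, > 0; `Inf` for a straight
#'   centerline gives `De = 0`).
#' @return the Dean number (dimensionless).
#' @export
dean_number <- function(Re, r_e, r_c) {
  if (any(r_e <= 0)) stop("r_e must be > 0")
  if (any(r_c <= 0)) stop("r_c must be > 0")
  Re * sqrt(r_e / r_c)
}

#' Centerline radius of curvature from consecutive centre points
#'
#' Three-point circumradius of each interior triple of centerline points;
#' collinear triples give `Inf` (straight centerline).
#'
#' @param duct a `duct_geometry`.
#' @return numeric vector, one value per interior station (stations 2..n-1).
#' @export
centerline_curvature_radius <- function(duct) {
  pts <- t(vapply(duct$sections, function(s) s$centerline_point, numeric(3)))
  n <- nrow(pts)
  vapply(2:(n - 1L), function(i) {
    circumradius3(pts[i - 1L, ], pts[i, ], pts[i + 1L, ])
  }, numeric(1))
}

circumradius3 <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  c <- sqrt(sum((p1 - p2)^2))
  v1 <- p2 - p1; v2 <- p3 - p1
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  K <- sqrt(sum(cr^2)) / 2
  if (K < 1e-12 * a * b * c) return(Inf)
  a * b * c / (4 * K)
}
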