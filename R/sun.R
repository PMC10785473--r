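#' Series-unidirectional resistance of one cross section (SUN)
#'
#' Solves the unidirectional (Poisson) flow problem
#' `mu * Laplacian(w) = dp/dz` with no-slip `w = 0` on the section boundary,
#' for a unit pressure gradient, and returns the hydraulic resistance per
#' unit length `R = |dp/dz| / Int(w dA)`. In Stokes flow `R` is independent of
#' the imposed gradient, so the unit-gradient formulation needs no iteration.
#'
#' The discretization is a boundary-corrected (Shortley-Weller) finite
#' difference scheme on a Cartesian grid: interior nodes carry the standard
#' five-point stencil, and nodes next to the boundary use the exact distances
#' to the wall along the grid lines. The scheme is second order and is exact
#' at the nodes for the quadratic velocity fields of circular and elliptical
#' sections, so the residual error there is pure quadrature. The default grid
#' spacing (64 nodes across the equivalent diameter, refined for thin
#' sections) keeps the circular benchmark error well below 0.5%, the
#' calibration criterion used for all solver settings; see
#' [sun_circle_benchmark()].
#'
#' @param section a `cross_section` or a two-column vertex matrix.
#' @param mu dynamic viscosity (Pa s).
#' @param mesh_size grid spacing h (um); default
#'   `min(2 r_eq / 64, D_h / 10)`.
#' @return resistance per unit length (Pa s / um^4), with attributes
#'   `n_nodes` (interior unknowns) and `h` (spacing used).
#' @export
sun_resistance <- function(section, mu = 6.9e-4, mesh_size = NULL) {
  v <- if (inherits(section, "cross_section")) section$vertices
       else as.matrix(section)
  if (mu <= 0) stop("mu must be > 0")
  met <- polygon_metrics(v)
  h <- if (is.null(mesh_size)) min(2 * met$r_eq / 64, met$D_h / 10)
       else mesh_size
  sol <- poisson_section_solve(v, h)
  R <- mu / sol$flux               # R = |dp/dz| / Q_2d with |dp/dz| = mu here
  attr(R, "n_nodes") <- sol$n
  attr(R, "h") <- h
  R
}

# Solve Laplacian(w) = -1, w = 0 on the polygon boundary; return the flux
# integral Int(w dA). Resistance for viscosity mu follows as mu / flux.
poisson_section_solve <- function(v, h) {
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  # grid strictly covering the polygon, offset so nodes avoid the boundary
  gx <- seq(xr[1L] - 0.51 * h, xr[2L] + 0.51 * h, by = h)
  gy <- seq(yr[1L] - 0.51 * h, yr[2L] + 0.51 * h, by = h)
  nx <- length(gx); ny <- length(gy)
  px <- rep(gx, times = ny); py <- rep(gy, each = nx)
  inside <- point_in_polygon(px, py, v)
  idx <- integer(nx * ny); idx[inside] <- seq_len(sum(inside))
  n <- sum(inside)
  if (n < 20L) stop("solver error: fewer than 20 interior nodes; reduce mesh_size")
  which_in <- which(inside)
  ix <- (which_in - 1L) %% nx + 1L
  iy <- (which_in - 1L) %/% nx + 1L

  # neighbour offsets in flattened index: W, E, S, N
  offs <- c(-1L, 1L, -nx, nx)
  dirx <- c(-1, 1, 0, 0); diry <- c(0, 0, -1, 1)
  th <- matrix(1, n, 4L)       # distance to wall / h, per direction
  nb <- matrix(0L, n, 4L)      # interior-neighbour unknown index or 0
  for (d in 1:4) {
    nbr <- which_in + offs[d]
    edge_ok <- if (d == 1L) ix > 1L else if (d == 2L) ix < nx
               else if (d == 3L) iy > 1L else iy < ny
    nbr_in <- edge_ok & inside[pmin(pmax(nbr, 1L), nx * ny)]
    nb[nbr_in, d] <- idx[nbr[nbr_in]]
    cut <- which(!nbr_in)
    if (length(cut)) {
      th[cut, d] <- boundary_fraction(px[which_in[cut]], py[which_in[cut]],
                                      dirx[d] * h, diry[d] * h, v)
    }
  }
  th <- pmax(th, 1e-6)

  # Shortley-Weller: f_xx ~ 2 [ fW/(h1(h1+h2)) - fP/(h1 h2) + fE/(h2(h1+h2)) ]
  h1x <- th[, 1L] * h; h2x <- th[, 2L] * h
  h1y <- th[, 3L] * h; h2y <- th[, 4L] * h
  diag_c <- -2 / (h1x * h2x) - 2 / (h1y * h2y)
  coefs <- cbind(2 / (h1x * (h1x + h2x)), 2 / (h2x * (h1x + h2x)),
                 2 / (h1y * (h1y + h2y)), 2 / (h2y * (h1y + h2y)))
  keep <- nb > 0L
  ii <- c(seq_len(n), row(nb)[keep])
  jj <- c(seq_len(n), nb[keep])
  xx <- c(diag_c, coefs[keep])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  w <- as.numeric(Matrix::solve(A, rep(-1, n)))
  list(flux = sum(w) * h^2, n = n, w = w,
       x = px[which_in], y = py[which_in], h = h)
}

# first intersection of the segment p -> p + (dx, dy) with the polygon
# boundary, as a fraction of the step; vectorized over points
boundary_fraction <- function(px, py, dx, dy, v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  x1 <- v[, 1L]; y1 <- v[, 2L]
  ex <- v[j, 1L] - x1; ey <- v[j, 2L] - y1
  vapply(seq_along(px), function(k) {
    denom <- dx * ey - dy * ex
    ok <- abs(denom) > 1e-14
    t <- (ex * (py[k] - y1) - ey * (px[k] - x1)) / denom
    s <- (dx * (py[k] - y1) - dy * (px[k] - x1)) / denom
    hit <- ok & t > 0 & t <= 1 + 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
    if (!any(hit)) 1 else min(t[hit])
  }, numeric(1))
}

#' Hagen-Poiseuille resistance of a circular duct (SUA)
#'
#' `R = 8 mu / (pi r^4)`, the exact series-unidirectional resistance for a
#' circular cross section of radius `r`.
#'
#' @param r_eq radius (um, > 0).
#' @param mu dynamic viscosity (Pa s).
#' @return resistance per unit length (Pa s / um^4).
#' @export
sua_circle <- function(r_eq, mu = 6.9e-4) {
  if (any(r_eq <= 0)) stop("r_eq must be > 0")
  8 * mu / (pi * r_eq^4)
}

is_circular_section <- function(section, tol = 1e-3) {
  v <- section$vertices
  ctr <- colMeans(v)
  r <- sqrt((v[, 1L] - ctr[1L])^2 + (v[, 2L] - ctr[2L])^2)
  (max(r) - min(r)) / mean(r) < tol
}

#' Per-station resistance profile of a duct
#'
#' Applies the chosen per-section estimator at every station of the duct and
#' assembles a `resistance_profile`: local values, their mean, and the total
#' resistance (trapezoidal integral over z). Methods:
#' \describe{
#'   \item{SUN}{numerical Poisson solve per section ([sun_resistance()]).}
#'   \item{SUA}{analytic circular solution ([sua_circle()]); requires circular
#'     sections (errors otherwise).}
#'   \item{I}{area scaling from a reference section ([method_I()]); the
#'     reference is selected by `ref`.}
#'   \item{II}{shape-factor correction of the circular resistance
#'     ([method_II()]).}
#'   \item{III}{matched-ellipse lubrication formula ([method_III()]).}
#'   \item{IV}{polar-moment formula ([method_IV()]).}
#' }
#'
#' @param duct a `duct_geometry`.
#' @param mu dynamic viscosity (Pa s).
#' @param method one of `"SUN"`, `"SUA"`, `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param ref reference selector for method I: `"max"` (largest area),
#'   `"min"` (smallest area), or a station index.
#' @param N boundary points for method II's shape factor.
#' @param mesh_size grid spacing forwarded to [sun_resistance()].
#' @return a `resistance_profile`.
#' @export
series_profile <- function(duct, mu = 6.9e-4,
                           method = c("SUN", "SUA", "I", "II", "III", "IV"),
                           ref = "max", N = 100L, mesh_size = NULL) {
  method <- match.arg(method)
  secs <- duct$sections
  z <- duct$z
  mets <- lapply(secs, polygon_metrics)
  A <- vapply(mets, `[[`, numeric(1), "A")
  R <- switch(method,
    SUN = vapply(secs, function(s)
      as.numeric(sun_resistance(s, mu, mesh_size)), numeric(1)),
    SUA = {
      circ <- vapply(secs, is_circular_section, logical(1))
      if (!all(circ))
        stop("SUA requested on a non-circular duct (section ",
             which(!circ)[1L], "); use SUN")
      vapply(mets, function(m) sua_circle(m$r_eq, mu), numeric(1))
    },
    I = {
      iref <- if (identical(ref, "max")) which.max(A)
              else if (identical(ref, "min")) which.min(A)
              else as.integer(ref)
      sref <- secs[[iref]]
      R_ref <- if (is_circular_section(sref))
        sua_circle(mets[[iref]]$r_eq, mu)
      else as.numeric(sun_resistance(sref, mu, mesh_size))
      method_I(A, R_ref, A[iref])
    },
    II = vapply(secs, function(s) method_II(s, mu, N)$R, numeric(1)),
    III = vapply(mets, function(m) method_III(m, mu), numeric(1)),
    IV = vapply(secs, function(s) method_IV(s, mu), numeric(1)))
  resistance_profile(z = z, R_local = R, method = method,
                     A = A, d2A = area_profile_at(duct, z, "d2A"))
}
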