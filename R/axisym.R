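#' Axisymmetric Stokes resistance profile for a circular duct
#'
#' Ground-truth resistance for ducts with circular cross sections and slowly
#' varying radius: solves the steady axisymmetric Stokes equations exactly
#' (no lubrication truncation) with a Stokes stream function on a
#' boundary-fitted grid, then applies the standard slice-averaged-pressure
#' post-processing.
#'
#' The stream function satisfies `E^2(E^2 psi) = 0` where
#' `E^2 = d2/dz2 + d2/dr2 - (1/r) d/dr`. The solver maps the duct onto the
#' rectangle `(zeta, eta) = (z, r/R(z))` and solves the coupled second-order
#' system `E^2 psi = phi`, `E^2 phi = 0` with central differences (mixed
#' derivatives from the corner stencil). Boundary conditions: Poiseuille
#' inflow with flow rate `Q` at the upstream end of a prepended uniform
#' entrance duct of length `entrance_length` (which satisfies the
#' entrance-length rule `z_L ~ 0.5 D_h` with a wide margin at these Reynolds
#' numbers), `psi = 0` and `phi = 0` on the axis, `psi = Q/(2 pi)` and
#' `d psi/d eta = 0` (no slip) at the wall, and fully developed outflow.
#'
#' Pressure is recovered from the momentum balance written with the azimuthal
#' vorticity (`phi = -r w_theta`): the axial gradient
#' `dp/dz = mu (1/r) dphi/dr` is integrated along the axis from the outlet
#' (where p = 0) and the radial gradient `dp/dr = -mu d(phi/r)/dz` outward
#' along each column, so only first derivatives of the solved fields enter. The per-station resistance divides differences
#' of volume-weighted slice-averaged pressures (slices of thickness
#' `slice_thickness`) by `Q`. Stations upstream of the duct proper are
#' dropped and the last `exclude_outlet` stations are excluded from the
#' profile average (exit effects).
#'
#' Results are independent of `Q` (Stokes linearity); `Q` only scales the
#' fields.
#'
#' @param duct a `duct_geometry` with circular sections (checked; use the
#'   extended-lubrication or SUN estimators for non-circular ducts).
#' @param mu dynamic viscosity (Pa s).
#' @param Q volume flow rate (um^3/s).
#' @param slice_thickness axial averaging slice (um).
#' @param entrance_length uniform entrance extension (um).
#' @param exclude_outlet number of trailing stations excluded from `R_avg`.
#' @param n_eta radial grid nodes (including axis and wall).
#' @param dzeta axial grid spacing (um).
#' @return a `resistance_profile` (method `"ORACLE"`). Attribute `"field"`
#'   holds the solution grid and the `w`, `u`, `p` fields; attribute
#'   `"flux_error"` the worst relative mass-conservation defect across
#'   stations.
#' @export
axisym_resistance_profile <- function(duct, mu = 6.9e-4, Q = 2.19e4,
                                      slice_thickness = 2,
                                      entrance_length = 40,
                                      exclude_outlet = 5L,
                                      n_eta = 33L, dzeta = 0.5) {
  circ <- vapply(duct$sections, is_circular_section, logical(1))
  if (!all(circ))
    stop("oracle requires circular sections (section ", which(!circ)[1L],
         " is not); use SUN or the lubrication estimators instead")
  z0 <- duct$z[1L]; z1 <- duct$z[length(duct$z)]
  rad <- vapply(duct$sections, function(s) polygon_metrics(s)$r_eq, numeric(1))
  rfun <- stats::splinefun(duct$z, rad, method = "natural")

  zeta <- seq(z0 - entrance_length, z1, by = dzeta)
  nz <- length(zeta); nr <- as.integer(n_eta)
  eta <- seq(0, 1, length.out = nr)
  deta <- eta[2L] - eta[1L]
  in_entrance <- zeta < z0
  Rz <- ifelse(in_entrance, rad[1L], rfun(zeta))
  Rp <- ifelse(in_entrance, 0, rfun(zeta, deriv = 1L))
  Rpp <- ifelse(in_entrance, 0, rfun(zeta, deriv = 2L))

  sol <- axisym_solve(zeta, eta, Rz, Rp, Rpp, Q)
  psi <- sol$psi; phi <- sol$phi

  EM <- matrix(eta, nz, nr, byrow = TRUE)
  RM <- matrix(Rz, nz, nr)
  aM <- -EM * matrix(Rp / Rz, nz, nr)

  # velocities; near the axis psi ~ a eta^2 + b eta^4 gives w on the axis
  psi_eta <- fd_dim(psi, deta, 2L)
  w <- psi_eta / (EM * RM^2)
  e2 <- eta[2L]; e3 <- eta[3L]
  a_ax <- (psi[, 2L] * e3^4 - psi[, 3L] * e2^4) /
    (e2^2 * e3^4 - e3^2 * e2^4)
  w[, 1L] <- 2 * a_ax / Rz^2
  w[, nr] <- 0
  psi_zeta <- fd_dim(psi, dzeta, 1L)
  u <- -(psi_zeta + aM * psi_eta) / (EM * RM)
  u[, 1L] <- 0
  u[, nr] <- 0

  # mass conservation check: 2 pi R^2 Int(w eta d eta) == Q
  Qnum <- 2 * pi * Rz^2 * colSums_trapz(w * EM, deta)
  flux_error <- max(abs(Qnum - Q) / Q)

  # pressure from the momentum balance written with the azimuthal vorticity
  # (phi = -r w_theta): dp/dz = mu (1/r) dphi/dr, dp/dr = -mu d(phi/r)/dz.
  # Only first derivatives of the solved phi field enter.
  phi_eta <- fd_dim(phi, deta, 2L)
  gz <- mu * phi_eta / (EM * RM^2)
  gz[, 1L] <- 2 * mu * phi[, 2L] / (eta[2L]^2 * Rz^2)   # phi ~ eta^2 on axis
  p_axis <- as.numeric(pracma::cumtrapz(zeta, gz[, 1L]))
  p_axis <- p_axis - p_axis[nz]                     # p = 0 at outlet
  phi_over_r <- phi / (EM * RM)
  phi_over_r[, 1L] <- 0                             # phi ~ eta^2 on axis
  gr <- -mu * (fd_dim(phi_over_r, dzeta, 1L) +
                 aM * fd_dim(phi_over_r, deta, 2L))
  gr[, 1L] <- 0                                     # symmetry: dp/dr = 0
  p <- matrix(0, nz, nr)
  for (i in seq_len(nz))
    p[i, ] <- p_axis[i] + pracma::cumtrapz(eta, gr[i, ] * Rz[i])

  # volume-weighted slice averages; column average first (R constant per
  # column): p_col = 2 Int p eta d eta, column weight ~ R^2
  p_col <- 2 * colSums_trapz(p * EM, deta)
  edges <- seq(zeta[1L], zeta[nz] + 1e-9, by = slice_thickness)
  if (edges[length(edges)] < zeta[nz] - 1e-9)
    edges <- c(edges, zeta[nz])
  bin <- findInterval(zeta, edges, rightmost.closed = TRUE)
  wcol <- Rz^2
  p_bar <- tapply(p_col * wcol, bin, sum) / tapply(wcol, bin, sum)
  z_bar <- tapply(zeta * wcol, bin, sum) / tapply(wcol, bin, sum)
  p_bar <- as.numeric(p_bar); z_bar <- as.numeric(z_bar)
  k <- seq_len(length(p_bar) - 1L)
  R_loc <- (p_bar[k] - p_bar[k + 1L]) / (diff(z_bar) * Q)
  z_st <- (z_bar[k] + z_bar[k + 1L]) / 2

  keep <- z_st >= z0 - 1e-9
  z_st <- z_st[keep]; R_loc <- R_loc[keep]
  included <- rep(TRUE, length(z_st))
  if (exclude_outlet > 0L && length(z_st) > exclude_outlet)
    included[(length(z_st) - exclude_outlet + 1L):length(z_st)] <- FALSE

  prof <- resistance_profile(
    z = z_st, R_local = R_loc, method = "ORACLE",
    A = pi * ifelse(z_st < z0, rad[1L], rfun(z_st))^2,
    d2A = area_profile_at(duct, z_st, "d2A"),
    included = included)
  attr(prof, "field") <- list(zeta = zeta, eta = eta, R = Rz,
                              psi = psi, w = w, u = u, p = p)
  attr(prof, "flux_error") <- flux_error
  prof
}

# Coupled solve of E^2 psi = phi, E^2 phi = 0 on the mapped grid.
axisym_solve <- function(zeta, eta, Rz, Rp, Rpp, Q) {
  nz <- length(zeta); nr <- length(eta)
  dz <- zeta[2L] - zeta[1L]; de <- eta[2L] - eta[1L]
  N <- nz * nr
  id <- function(i, j) (j - 1L) * nz + i

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(2L * N)
  add <- function(r, c, v) {
    ii <<- c(ii, r); jj <<- c(jj, c); xx <<- c(xx, v)
  }

  # interior nodes, vectorized
  ig <- 2:(nz - 1L); jg <- 2:(nr - 1L)
  I <- rep(ig, times = length(jg)); J <- rep(jg, each = length(ig))
  et <- eta[J]; R <- Rz[I]; rp <- Rp[I]; rpp <- Rpp[I]
  a <- -et * rp / R
  czz <- 1
  cze <- 2 * a
  cee <- a^2 + 1 / R^2
  ce_common <- -et * rpp / R + 2 * et * rp^2 / R^2
  ce <- ce_common - 1 / (et * R^2)      # E^2 operator's first-derivative term

  P <- id(I, J)
  stencil <- function(row_off, col_base) {
    # assemble E^2 rows at unknown-block offset col_base for equation rows
    # row_off + P; returns nothing, appends triplets
    add(row_off + P, col_base + P, -2 * czz / dz^2 - 2 * cee / de^2)
    add(row_off + P, col_base + id(I + 1L, J), rep(czz / dz^2, length(P)))
    add(row_off + P, col_base + id(I - 1L, J), rep(czz / dz^2, length(P)))
    add(row_off + P, col_base + id(I, J + 1L), cee / de^2 + ce / (2 * de))
    add(row_off + P, col_base + id(I, J - 1L), cee / de^2 - ce / (2 * de))
    m <- cze / (4 * dz * de)
    add(row_off + P, col_base + id(I + 1L, J + 1L), m)
    add(row_off + P, col_base + id(I - 1L, J - 1L), m)
    add(row_off + P, col_base + id(I + 1L, J - 1L), -m)
    add(row_off + P, col_base + id(I - 1L, J + 1L), -m)
  }
  stencil(0L, 0L)                    # E^2 psi ...
  add(P, N + P, rep(-1, length(P)))  # ... - phi = 0
  stencil(N, N)                      # E^2 phi = 0

  psi_pois <- function(e) (Q / pi) * (e^2 - e^4 / 2)
  # axis rows (j = 1), all i except inlet
  i_ax <- 2:nz
  add(id(i_ax, 1L), id(i_ax, 1L), rep(1, length(i_ax)))           # psi = 0
  add(N + id(i_ax, 1L), N + id(i_ax, 1L), rep(1, length(i_ax)))   # phi = 0
  # wall rows (j = nr), all i except inlet; at the outlet corner the
  # no-slip row is replaced by outflow extrapolation of phi (no-slip there
  # is already enforced by the neighbouring wall rows)
  i_w <- 2:nz
  add(id(i_w, nr), id(i_w, nr), rep(1, length(i_w)))
  rhs[id(i_w, nr)] <- Q / (2 * pi)
  i_ns <- 2:(nz - 1L)
  add(N + id(i_ns, nr), id(i_ns, nr), rep(3, length(i_ns)))       # dpsi/deta = 0
  add(N + id(i_ns, nr), id(i_ns, nr - 1L), rep(-4, length(i_ns)))
  add(N + id(i_ns, nr), id(i_ns, nr - 2L), rep(1, length(i_ns)))
  add(N + id(nz, nr), N + id(nz, nr), 3)
  add(N + id(nz, nr), N + id(nz - 1L, nr), -4)
  add(N + id(nz, nr), N + id(nz - 2L, nr), 1)
  # inlet column (i = 1): Poiseuille
  j_in <- 1:nr
  add(id(1L, j_in), id(1L, j_in), rep(1, nr))
  rhs[id(1L, j_in)] <- psi_pois(eta)
  add(N + id(1L, j_in), N + id(1L, j_in), rep(1, nr))
  rhs[N + id(1L, j_in)] <- -4 * Q * eta^2 / (pi * Rz[1L]^2)
  # outlet column (i = nz), interior j: fully developed
  j_out <- 2:(nr - 1L)
  for (off in c(0L, N)) {
    add(off + id(nz, j_out), off + id(nz, j_out), rep(3, length(j_out)))
    add(off + id(nz, j_out), off + id(nz - 1L, j_out), rep(-4, length(j_out)))
    add(off + id(nz, j_out), off + id(nz - 2L, j_out), rep(1, length(j_out)))
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(2L * N, 2L * N))
  sol <- as.numeric(Matrix::solve(A, rhs))
  list(psi = matrix(sol[1:N], nz, nr), phi = matrix(sol[(N + 1):(2 * N)], nz, nr))
}

# first (or second) derivative of a matrix along dimension `dim`, central in
# the interior, second-order one-sided at the ends
fd_dim <- function(F, h, dim, second = FALSE) {
  if (dim == 2L) return(t(fd_dim(t(F), h, 1L, second)))
  n <- nrow(F)
  D <- F * 0
  i <- 2:(n - 1L)
  if (!second) {
    D[i, ] <- (F[i + 1L, , drop = FALSE] - F[i - 1L, , drop = FALSE]) / (2 * h)
    D[1L, ] <- (-3 * F[1L, ] + 4 * F[2L, ] - F[3L, ]) / (2 * h)
    D[n, ]  <- (3 * F[n, ] - 4 * F[n - 1L, ] + F[n - 2L, ]) / (2 * h)
  } else {
    D[i, ] <- (F[i + 1L, , drop = FALSE] - 2 * F[i, , drop = FALSE] +
                 F[i - 1L, , drop = FALSE]) / h^2
    D[1L, ] <- (2 * F[1L, ] - 5 * F[2L, ] + 4 * F[3L, ] - F[4L, ]) / h^2
    D[n, ]  <- (2 * F[n, ] - 5 * F[n - 1L, ] + 4 * F[n - 2L, ] - F[n - 3L, ]) / h^2
  }
  D
}


# trapezoid integral of each row of F over the second dimension
colSums_trapz <- function(F, h) {
  n <- ncol(F)
  h * (rowSums(F) - 0.5 * (F[, 1L] + F[, n]))
}
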