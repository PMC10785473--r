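#' Method I: area scaling from a reference section
#'
#' `R_I = R_ref * (A_ref / A_i)^2` -- assumes the section shape stays roughly
#' uniform along the duct, so the resistance varies as the inverse square of
#' the area (as in the matched-ellipse formula at fixed aspect ratio).
#'
#' @param A_i local areas (um^2), vectorized.
#' @param R_ref resistance of the reference section (Pa s / um^4).
#' @param A_ref area of the reference section (um^2).
#' @return resistance values, same length as `A_i`.
#' @export
method_I <- function(A_i, R_ref, A_ref) {
  if (any(A_i <= 0) || A_ref <= 0) stop("areas must be > 0")
  R_ref * (A_ref / A_i)^2
}

#' Shape factor gamma of a cross section
#'
#' The boundary is resampled to `N` points at equal arc-length spacing; for a
#' candidate centre the factor is `gamma = mean((r_eq / d_j)^4)` where `d_j`
#' are the distances from the centre to the boundary points. The centre is the
#' interior location minimizing gamma (close to the peak-velocity point); a
#' derivative-free simplex search starts from the centroid, restarting from a
#' coarse interior grid if the optimum escapes the polygon. Using the
#' minimizing centre rather than the centroid avoids the large overestimates
#' that occur when a section narrows at its centroid.
#'
#' @param section a `cross_section` or vertex matrix.
#' @param N number of equally spaced boundary points (>= 16).
#' @return list with `gamma`, `center`, `d` (distances), `N`.
#' @export
shape_factor <- function(section, N = 100L) {
  v <- if (inherits(section, "cross_section")) section$vertices
       else as.matrix(section)
  if (N < 16L) stop("N must be >= 16")
  met <- polygon_metrics(v)
  bp <- resample_boundary(v, N)
  r_eq <- met$r_eq
  gamma_at <- function(ctr) {
    d4 <- ((bp[, 1L] - ctr[1L])^2 + (bp[, 2L] - ctr[2L])^2)^2
    mean(r_eq^4 / d4)
  }
  obj <- function(ctr) {
    if (!point_in_polygon(ctr[1L], ctr[2L], v)) return(1e8)
    gamma_at(ctr)
  }
  run <- function(start) stats::optim(start, obj, method = "Nelder-Mead",
                                      control = list(reltol = 1e-10,
                                                     maxit = 500L))
  fit <- run(met$centroid)
  inside <- point_in_polygon(fit$par[1L], fit$par[2L], v)
  if (!inside || fit$value >= 1e8) {
    # coarse interior grid restart for multimodal (e.g. bi-lobed) sections
    g <- seq(0.05, 0.95, length.out = 12L)
    xr <- range(v[, 1L]); yr <- range(v[, 2L])
    cand <- expand.grid(x = xr[1L] + g * diff(xr), y = yr[1L] + g * diff(yr))
    keep <- point_in_polygon(cand$x, cand$y, v)
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) stop("shape factor: no interior starting point found")
    vals <- apply(cand, 1L, gamma_at)
    fit <- run(as.numeric(cand[which.min(vals), ]))
    if (!point_in_polygon(fit$par[1L], fit$par[2L], v))
      stop("shape factor: optimizer failed to stay inside the section")
  }
  d <- sqrt((bp[, 1L] - fit$par[1L])^2 + (bp[, 2L] - fit$par[2L])^2)
  list(gamma = fit$value, center = as.numeric(fit$par), d = d, N = N)
}

#' Method II: shape-factor correction of the circular resistance
#'
#' `R_II = 8 mu gamma / (pi r_eq^4)` with gamma from [shape_factor()]. Assumes
#' the near-wall velocity variation resembles that of a circle whose radius is
#' the local wall distance; accurate (errors under about 10%) as long as the
#' section is not too oblong (minor-to-major axis ratio above about 0.7).
#'
#' @param section a `cross_section` or vertex matrix.
#' @param mu dynamic viscosity (Pa s).
#' @param N boundary points for the shape factor.
#' @return list with `R` (Pa s / um^4) and the [shape_factor()] fields.
#' @export
method_II <- function(section, mu = 6.9e-4, N = 100L) {
  v <- if (inherits(section, "cross_section")) section$vertices
       else as.matrix(section)
  met <- polygon_metrics(v)
  sf <- shape_factor(v, N)
  c(list(R = 8 * mu * sf$gamma / (pi * met$r_eq^4)), sf)
}

#' Method III: matched-ellipse lubrication formula
#'
#' `R_III = 4 mu (beta^2 + 1) / (pi r_eq^4 beta)` -- the exact resistance of
#' the ellipse sharing the section's area and central second moments. Exact
#' for true ellipses; a lower bound in practice for rougher or concave
#' sections, which resist more than the matched ellipse.
#'
#' @param metrics a metrics list from [polygon_metrics()] (needs `r_eq` and
#'   `beta`), or a `cross_section`/vertex matrix from which metrics are
#'   computed.
#' @param mu dynamic viscosity (Pa s).
#' @return resistance per unit length (Pa s / um^4).
#' @export
method_III <- function(metrics, mu = 6.9e-4) {
  if (!is.list(metrics) || is.null(metrics$r_eq))
    metrics <- polygon_metrics(metrics)
  if (metrics$beta < 1) stop("beta must be >= 1")
  4 * mu * (metrics$beta^2 + 1) / (pi * metrics$r_eq^4 * metrics$beta)
}

#' Method IV: polar-moment formula
#'
#' `R_IV = 16 pi^2 mu I_p / A^4` with the exact polygon polar moment `I_p`
#' about the centroid. Exact for ellipses (and circles); typically a few to
#' ~13% low for realistic perivascular sections.
#'
#' @param section a `cross_section`/vertex matrix, or a [polygon_metrics()]
#'   list.
#' @param mu dynamic viscosity (Pa s).
#' @return resistance per unit length (Pa s / um^4).
#' @export
method_IV <- function(section, mu = 6.9e-4) {
  m <- if (is.list(section) && !is.null(section$I_p) &&
           !inherits(section, "cross_section")) section
       else polygon_metrics(section)
  16 * pi^2 * mu * m$I_p / m$A^4
}
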