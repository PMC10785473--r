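#' Classical lubrication resistance of an elliptical section
#'
#' Zeroth-order (uniform-duct) resistance per unit length of an ellipse with
#' semi-axes `b`, `c`:
#' `R0 = 4 mu (b^2 + c^2) / (pi b^3 c^3)`,
#' equivalently `4 pi mu (beta^2 + 1) / (beta A^2)` with `beta = b/c` and
#' `A = pi b c`. Reduces to Hagen-Poiseuille for `b = c`.
#'
#' @param b,c semi-axes (um, > 0), vectorized.
#' @param mu dynamic viscosity (Pa s).
#' @return resistance per unit length (Pa s / um^4).
#' @export
ellipse_R0 <- function(b, c, mu = 6.9e-4) {
  if (any(b <= 0) || any(c <= 0)) stop("semi-axes must be > 0")
  4 * mu * (b^2 + c^2) / (pi * b^3 * c^3)
}

#' Classical lubrication resistance from area and aspect ratio
#'
#' `R0 = 4 pi mu (beta^2 + 1) / (beta A^2)`, the area/aspect-ratio form of
#' [ellipse_R0()].
#'
#' @param A section area (um^2).
#' @param beta aspect ratio (>= 1).
#' @param mu dynamic viscosity (Pa s).
#' @return resistance per unit length (Pa s / um^4).
#' @export
R0_from_area_beta <- function(A, beta, mu = 6.9e-4) {
  4 * pi * mu * (beta^2 + 1) / (beta * A^2)
}

#' Second-order (extended) lubrication resistance of a nonuniform ellipse
#'
#' The second-order correction to the resistance per unit length of an
#' elliptical duct whose semi-axes vary along z (primes denote d/dz):
#' \deqn{R_2 = -\frac{\mu}{6\pi b^4 c^4}\big[3 c^4 b'c'
#'   + b^3 c (2 b'^2 - 7 c c'' + 8 c'^2)
#'   + b c^3 (8 b'^2 - c c'' + 2 c'^2)
#'   + b^4 (3 b'c' - c b'')
#'   + b^2 c^2 (6 b'c' - 7 c b'')\big].}
#' It derives from averaging the second-order axial pressure gradient over
#' the cross section, and adds linearly to the classical term: the total is
#' `R0 + R2` (all quantities dimensional, so the formal aspect-ratio factor
#' is absorbed). `R2` vanishes for a uniform duct and is symmetric under
#' swapping the two axes together with their derivatives.
#'
#' @param b,c semi-axes (um), vectorized.
#' @param db,dc first derivatives of the semi-axes (dimensionless).
#' @param d2b,d2c second derivatives (1/um).
#' @param mu dynamic viscosity (Pa s).
#' @return second-order resistance per unit length (Pa s / um^4, signed).
#' @export
ellipse_R2 <- function(b, c, db, dc, d2b, d2c, mu = 6.9e-4) {
  if (any(b <= 0) || any(c <= 0)) stop("semi-axes must be > 0")
  br <- 3 * c^4 * db * dc +
    b^3 * c * (2 * db^2 - 7 * c * d2c + 8 * dc^2) +
    b * c^3 * (8 * db^2 - c * d2c + 2 * dc^2) +
    b^4 * (3 * db * dc - c * d2b) +
    b^2 * c^2 * (6 * db * dc - 7 * c * d2b)
  -mu / (6 * pi * b^4 * c^4) * br
}

#' Second-order lubrication resistance for self-similar sections
#'
#' Fixed-aspect-ratio form of [ellipse_R2()], valid when the cross sections
#' are self-similar along the duct (`d beta / dz = 0`), written in terms of
#' the area profile:
#' \deqn{R_{2} = -\frac{\mu}{12 \beta^2 A^2}\Big[\frac{3 A'^2}{A}
#'   (1 + 6\beta^2 + \beta^4) - A'' (1 + 14\beta^2 + \beta^4)\Big].}
#'
#' @param A area (um^2), vectorized.
#' @param dA_dz first derivative of area (um).
#' @param d2A_dz2 second derivative of area (dimensionless).
#' @param beta aspect ratio (>= 1).
#' @param mu dynamic viscosity (Pa s).
#' @return second-order resistance per unit length (Pa s / um^4, signed).
#' @export
fixed_beta_R2 <- function(A, dA_dz, d2A_dz2, beta = 1, mu = 6.9e-4) {
  if (any(A <= 0)) stop("A must be > 0")
  if (any(beta < 1)) stop("beta must be >= 1")
  br <- 3 * dA_dz^2 / A * (1 + 6 * beta^2 + beta^4) -
    d2A_dz2 * (1 + 14 * beta^2 + beta^4)
  -mu / (12 * beta^2 * A^2) * br
}

#' Aspect-ratio prefactor of the leading-order error
#'
#' `P(beta) = (beta^4 + 14 beta^2 + 1) / (48 pi beta (beta^2 + 1))`, the
#' coefficient multiplying `A''` in the leading-order fractional error of the
#' series-unidirectional (uniform-duct) approximation. `P(1) = 1/(6 pi)` and
#' `P(beta) = P(1/beta)`; the function varies weakly, staying within about
#' 13.3% of `P(1)` for beta below 7.
#'
#' @param beta aspect ratio(s).
#' @return prefactor value(s), dimensionless.
#' @export
beta_prefactor <- function(beta) {
  (beta^4 + 14 * beta^2 + 1) / (48 * pi * beta * (beta^2 + 1))
}

#' Maximum deviation of the error prefactor from the circular case
#'
#' Largest value of `100 |P(beta) - P(1)| / P(1)` over aspect ratios from 1
#' up to `beta_max`, evaluated both on a 0.5-step grid and by continuous
#' optimization (the two differ slightly; both are of interest because the
#' extremum sits near beta = 3.1 between grid points).
#'
#' @param beta_max upper end of the scan (default 7, exclusive for the grid).
#' @return list with `grid` and `continuous` maximum percent deviations, and
#'   `argmax` of the continuous scan.
#' @export
beta_prefactor_deviation <- function(beta_max = 7) {
  dev <- function(b) 100 * abs(beta_prefactor(b) / beta_prefactor(1) - 1)
  bg <- seq(1, beta_max - 0.5, by = 0.5)
  op <- stats::optimize(dev, c(1, beta_max), maximum = TRUE)
  list(grid = max(dev(bg)), continuous = op$objective, argmax = op$maximum)
}

#' Fractional error of the series-unidirectional approximation
#'
#' Predicted fractional error of the uniform-duct (zeroth-order) resistance
#' relative to the extended-lubrication total, for self-similar sections:
#' \deqn{E = \frac{\alpha^2}{48 \pi \beta (\beta^2+1)}
#'   \Big(-\frac{3 A'^2}{A}(\beta^4 + 6\beta^2 + 1)
#'   + A'' (\beta^4 + 14\beta^2 + 1)\Big),}
#' and its leading-order form `E ~ alpha^2 P(beta) A''` in which the second
#' derivative of the area dominates. For `beta = 1` the leading form is
#' `alpha^2 A''/(6 pi)`. With dimensional inputs the formal aspect-ratio
#' factor `alpha` is absorbed and should be left at 1. Positive error means
#' the uniform-duct value underestimates the resistance (constrictions,
#' `A'' > 0`); negative means it overestimates (bulges).
#'
#' @param A area (um^2), vectorized.
#' @param dA_dz,d2A_dz2 area derivatives.
#' @param beta aspect ratio (>= 1).
#' @param alpha formal duct aspect ratio; 1 for dimensional inputs.
#' @return list with `full` and `leading` fractional errors.
#' @export
elt_error <- function(A, dA_dz, d2A_dz2, beta = 1, alpha = 1) {
  if (any(beta < 1)) stop("beta must be >= 1")
  full <- alpha^2 / (48 * pi * beta * (beta^2 + 1)) *
    (-3 * dA_dz^2 / A * (beta^4 + 6 * beta^2 + 1) +
       d2A_dz2 * (beta^4 + 14 * beta^2 + 1))
  leading <- alpha^2 * beta_prefactor(beta) * d2A_dz2
  list(full = full, leading = leading)
}

#' Correction-factor models for the series-unidirectional resistance
#'
#' The error of the series-unidirectional approximation, in percent of the
#' reference (three-dimensional) resistance, is modelled as a line in the
#' second derivative of the area, `err% = slope * A'' + intercept`. Three
#' calibrations are provided: `"realistic"` (slope -1.8, intercept -3.2, fit
#' to segmented perivascular geometries), `"circular"` (slope -4.4, intercept
#' 0.22, fit to circularized ducts), and `"analytic"` (slope -100/(6 pi) ~
#' -5.3, intercept 0, the extended-lubrication prediction for circular
#' ducts).
#'
#' @param kind `"realistic"`, `"circular"`, `"analytic"`, or `"custom"`.
#' @param slope,intercept coefficients for `kind = "custom"` (percent per
#'   unit `A''`, and percent).
#' @return an object of class `correction_model` with `slope`, `intercept`,
#'   `kind`.
#' @export
correction_model <- function(kind = c("realistic", "circular", "analytic",
                                      "custom"),
                             slope = NULL, intercept = NULL) {
  kind <- match.arg(kind)
  co <- switch(kind,
    realistic = c(-1.8, -3.2),
    circular  = c(-4.4, 0.22),
    analytic  = c(-100 / (6 * pi), 0),
    custom    = c(slope, intercept))
  if (length(co) != 2L || anyNA(co))
    stop("custom model needs both slope and intercept")
  structure(list(slope = co[1L], intercept = co[2L], kind = kind),
            class = "correction_model")
}

#' Multiplicative correction factor lambda
#'
#' Inverts the error line of a [correction_model()] into the multiplicative
#' factor that maps a series-unidirectional resistance onto the reference
#' value: since `err% = (R_SU - R_ref)/R_ref * 100`, the factor is
#' `lambda = 100 / (100 + slope * A'' + intercept)`.
#'
#' @param model a `correction_model`.
#' @param d2A_dz2 second derivative of area (vectorized).
#' @return lambda values (> 0; an error is raised naming the offending `A''`
#'   if the fit is used outside its validity range and lambda would be
#'   non-positive).
#' @export
lambda_factor <- function(model, d2A_dz2) {
  lam <- 100 / (100 + model$slope * d2A_dz2 + model$intercept)
  if (any(lam <= 0)) {
    bad <- d2A_dz2[which(lam <= 0)[1L]]
    stop(sprintf(
      "lambda <= 0 at d2A/dz2 = %.4g: correction model '%s' used outside its validity range",
      bad, model$kind))
  }
  lam
}

#' Apply the lambda correction to a resistance profile
#'
#' `R_corrected(z) = R(z) * lambda(A''(z))`. The profile's stored `d2A` is
#' used unless `d2A_dz2` is supplied; the method tag gains a `".lambda"`
#' suffix.
#'
#' @param profile a `resistance_profile` from a series-unidirectional method.
#' @param model a [correction_model()].
#' @param d2A_dz2 optional per-station second derivative of area overriding
#'   the profile's own.
#' @return a corrected `resistance_profile`.
#' @export
lambda_correct <- function(profile, model, d2A_dz2 = NULL) {
  d2A <- if (is.null(d2A_dz2)) profile$d2A else d2A_dz2
  if (is.null(d2A))
    stop("profile carries no d2A samples; supply d2A_dz2")
  lam <- lambda_factor(model, d2A)
  resistance_profile(z = profile$z, R_local = profile$R_local * lam,
                     method = paste0(profile$method, ".lambda"),
                     A = profile$A, d2A = d2A, included = profile$included)
}
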