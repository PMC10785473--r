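# Shape constructors and small utilities shared across tests.

rms <- function(x) sqrt(mean(x^2))

rotate_translate <- function(v, angle, shift) {
  Rm <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  t(t(v %*% t(Rm)) + shift)
}

# random convex polygon: convex hull of gaussian cloud, rescaled
random_convex_polygon <- function(n = 40L, scale = 3) {
  pts <- matrix(stats::rnorm(2L * n, sd = scale), ncol = 2L)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  hull[rev(seq_len(nrow(hull))), , drop = FALSE]   # chull is clockwise
}

# random star-shaped polygon: smooth random radius about the origin
random_star_polygon <- function(n = 96L, r0 = 3) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  amp <- stats::runif(3L, 0.05, 0.25)
  ph <- stats::runif(3L, 0, 2 * pi)
  r <- r0 * (1 + amp[1L] * sin(2 * th + ph[1L]) +
               amp[2L] * sin(3 * th + ph[2L]) +
               amp[3L] * sin(5 * th + ph[3L]))
  cbind(r * cos(th), r * sin(th))
}

# dumbbell with unequal lobes: narrows near its centroid
asymmetric_dumbbell <- function(n = 160L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- 1 + 0.6 * cos(2 * th) + 0.3 * cos(th)
  cbind(r * cos(th), r * sin(th))
}

# Monte-Carlo polygon moments (independent oracle for the closed forms):
# uniform samples in the bounding box, rejection by point-in-polygon
mc_polygon_moments <- function(v, n = 2e5) {
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  px <- stats::runif(n, xr[1L], xr[2L])
  py <- stats::runif(n, yr[1L], yr[2L])
  inside <- pracma::inpolygon(px, py, v[, 1L], v[, 2L])
  px <- px[inside]; py <- py[inside]
  A <- diff(xr) * diff(yr) * mean(inside)
  cx <- mean(px); cy <- mean(py)
  list(A = A, centroid = c(cx, cy),
       I_p = A * mean((px - cx)^2 + (py - cy)^2))
}
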