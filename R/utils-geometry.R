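# Geometry primitives shared across modules. All coordinates in Angstrom,
# all angles in degrees unless noted; z is the pore axis (extracellular at
# larger z).

vec_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product for n x 3 matrices.
mat_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed dihedral angle of four points
#'
#' Standard IUPAC convention: looking down the p2->p3 bond, the angle is
#' positive for a clockwise rotation of p4 relative to p1. Result in
#' degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

# Vectorised dihedral over frames: each argument an n x 3 matrix.
dihedral_series <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- mat_cross(b1, b2)
  n2 <- mat_cross(b2, b3)
  b2u <- b2 / sqrt(rowSums(b2^2))
  m1 <- mat_cross(n1, b2u)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

# Map degrees into (-180, 180]; exact -180 becomes +180.
wrap_angle <- function(x) {
  x <- ((x + 180) %% 360) - 180
  x[x <= -180 + 1e-12 & abs(x + 180) < 1e-9] <- 180
  ifelse(x == -180, 180, x)
}

# Place atom D given A, B, C with bond |CD|, angle B-C-D and dihedral
# A-B-C-D (NeRF construction). `dihedral` may be a vector; returns a
# length(dihedral) x 3 matrix. Sign convention matches dihedral_angle().
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle)
  ph <- deg2rad(dihedral)
  u2 <- unit(c - b)
  n <- unit(vec_cross(b - a, c - b))
  m <- vec_cross(n, u2)
  d2x <- -bond * cos(th)
  d2y <- bond * sin(th) * cos(ph)
  d2z <- -bond * sin(th) * sin(ph)  # sign such that dihedral_angle(a,b,c,D) == dihedral
  out <- cbind(c[1L] + d2x * u2[1L] + d2y * m[1L] + d2z * n[1L],
               c[2L] + d2x * u2[2L] + d2y * m[2L] + d2z * n[2L],
               c[3L] + d2x * u2[3L] + d2y * m[3L] + d2z * n[3L])
  out
}

#' Circular mean of angles in degrees
#'
#' @param x angles in degrees.
#' @return mean angle in (-180, 180].
#' @export
circular_mean <- function(x) {
  r <- deg2rad(x)
  wrap_angle(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

#' Circular standard deviation of angles in degrees
#'
#' Computed from the resultant length Rbar as sqrt(-2 log Rbar),
#' converted to degrees. Zero for a constant series.
#'
#' @param x angles in degrees.
#' @return circular SD in degrees.
#' @export
circular_sd <- function(x) {
  r <- deg2rad(x)
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(max(rbar, 1e-12), 1)
  rad2deg(sqrt(-2 * log(rbar)))
}

# Deterministic 31-bit sub-seed derived from a master seed and a purpose
# tag, so independent random streams never reuse each other's draws.
derive_seed <- function(seed, tag) {
  h <- 5381
  for (ch in utf8ToInt(tag)) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}
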