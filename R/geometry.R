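#' Minimum-image displacement under an orthorhombic periodic box
#'
#' Displacement from `a` to `b` wrapped so that each component lies in
#' `[-L/2, L/2)`, the convention used throughout for periodic distances.
#'
#' @param a,b Numeric vectors of length 3 (positions, Angstrom), or matrices
#'   with 3 columns for many pairs at once.
#' @param box Numeric vector of length 3: box lengths `(Lx, Ly, Lz)` in
#'   Angstrom, all strictly positive.
#' @return Displacement `b - a` under the minimum-image convention, same
#'   shape as the inputs.
#' @examples
#' minimum_image_displacement(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10))
#' @export
minimum_image_displacement <- function(a, b, box) {
  check_box(box)
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  d <- b - a
  for (k in 1:3) {
    d[, k] <- d[, k] - box[k] * floor(d[, k] / box[k] + 0.5)
  }
  if (nrow(d) == 1L) drop(d) else d
}

check_box <- function(box) {
  if (length(box) != 3L || !is.numeric(box) || any(!is.finite(box)) ||
      any(box <= 0)) {
    stop("box lengths must be three strictly positive finite numbers",
         call. = FALSE)
  }
  invisible(box)
}

#' Signed torsion angle of four points
#'
#' Standard atan2 torsion of the dihedral p1-p2-p3-p4, in degrees on
#' `(-180, 180]`; an all-trans alkane fragment gives 180 degrees.
#'
#' @param p1,p2,p3,p4 Length-3 numeric vectors, or matrices with 3 columns
#'   to evaluate many quadruples row-wise.
#' @return Angle(s) in degrees in `(-180, 180]`.
#' @examples
#' compute_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.null(dim(p))) matrix(p, ncol = 3L) else p
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  if (any(row_norm(b1) < 1e-10) || any(row_norm(b2) < 1e-10) ||
      any(row_norm(b3) < 1e-10)) {
    stop("consecutive points coincide; torsion undefined", call. = FALSE)
  }
  if (any(row_norm(n1) < 1e-8) || any(row_norm(n2) < 1e-8)) {
    stop("collinear triple; torsion undefined", call. = FALSE)
  }
  b2h <- b2 / row_norm(b2)
  m1 <- row_cross(n1, b2h)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  # map -180 -> +180 so the range is (-180, 180]
  ang[ang <= -180 + 1e-12] <- 180
  if (length(ang) == 1L) ang[[1L]] else ang
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(a) sqrt(rowSums(a * a))

row_unit <- function(a) {
  n <- row_norm(a)
  if (any(n < 1e-12)) stop("zero-length vector cannot be normalized",
                           call. = FALSE)
  a / n
}

# Rotation matrix taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any axis perpendicular to u
    ax <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    k <- ax - sum(ax * u) * u
    k <- k / sqrt(sum(k^2))
    return(rotation_axis_angle(k, pi))
  }
  k <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(k^2))
  k <- k / s
  rotation_axis_angle(k, atan2(s, c_))
}

# Rodrigues rotation matrix about unit axis k by angle theta (radians).
rotation_axis_angle <- function(k, theta) {
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
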