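# Low-level 3D geometry shared by the helix builder, torsion analysis and
# superposition code. All angles are degrees unless noted.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Signed torsion a-b-c-d in degrees, in (-180, 180], using the standard
#' atan2 construction (IUPAC sign convention: looking b->c, clockwise
#' rotation of d relative to a is positive).
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) / DEG
}

angle3 <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

# Place an atom at given bond length / angle / torsion from three reference
# positions (NeRF construction): the new atom x satisfies |x-c| = bond,
# angle(b,c,x) = ang and dihedral(a,b,c,x) = tors.
place_atom <- function(a, b, c, bond, ang, tors) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  th <- ang * DEG
  ph <- tors * DEG
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

rot_x <- function(deg) {
  t <- deg * DEG
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

rot_y <- function(deg) {
  t <- deg * DEG
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}

rot_z <- function(deg) {
  t <- deg * DEG
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# Rotation about an arbitrary unit axis through the origin.
rot_axis <- function(axis, deg) {
  u <- unit(axis)
  t <- deg * DEG
  ct <- cos(t); st <- sin(t)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Compose a rotation matrix from inter-helical Euler angles
#'
#' Inverse of [matrix_to_euler()]: rebuilds the relative rotation from the
#' reported (alpha_h, beta_h, gamma_h). The reported alpha/gamma carry an
#' inverted sign relative to the raw ZYZ decomposition, chosen so that a
#' positive twist (alpha_h + gamma_h) corresponds to over-twisting of the
#' two-helix junction.
#'
#' @param alpha_h,beta_h,gamma_h Euler angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(alpha_h, beta_h, gamma_h) {
  rot_z(-alpha_h) %*% rot_y(beta_h) %*% rot_z(-gamma_h)
}

#' Decompose a rotation matrix into inter-helical Euler angles
#'
#' ZYZ decomposition R = Rz(a) Ry(b) Rz(g) with b in `[0, 180]`, reported with
#' the signs of a and g inverted (see [euler_to_matrix()]). Near the gimbal
#' lock at b = 0 or 180 only the twist a + g is determined; gamma_h is then
#' set to 0 and the whole twist is carried by alpha_h.
#'
#' @param R 3x3 rotation matrix.
#' @return list with `alpha_h`, `beta_h`, `gamma_h`, `bend` (= `|beta_h|`)
#'   and `twist` (= `alpha_h + gamma_h`), all degrees.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  cb <- max(-1, min(1, R[3, 3]))
  b <- acos(cb)
  if (sin(b) > 1e-9) {
    a <- atan2(R[2, 3], R[1, 3])
    g <- atan2(R[3, 2], -R[3, 1])
  } else {
    # gimbal: only a + g (b = 0) or a - g (b = 180) is determined;
    # attribute everything to alpha
    a <- if (cb > 0) atan2(R[2, 1], R[1, 1]) else atan2(-R[2, 1], -R[1, 1])
    g <- 0
  }
  alpha_h <- -a / DEG
  beta_h <- b / DEG
  gamma_h <- -g / DEG
  list(alpha_h = alpha_h, beta_h = beta_h, gamma_h = gamma_h,
       bend = abs(beta_h), twist = alpha_h + gamma_h)
}

# Kabsch: optimal rotation R and translation t mapping x (n x 3) onto y,
# i.e. minimising ||x R^T + t - y||. Returns list(R, t, rmsd).
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  if (nrow(x) < 3) stop("need at least 3 points for superposition")
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  h <- crossprod(x0, y0)  # 3x3
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- x0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - y0)^2)))
  t <- cy - as.vector(R %*% cx)
  list(R = R, t = t, rmsd = rmsd)
}

apply_rt <- function(x, R, t) sweep(x %*% t(R), 2, t, `+`)

# Deterministic near-uniform unit vectors on the sphere (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Random rotation matrix (uniform via quaternion), uses R's RNG.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}
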