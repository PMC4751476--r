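# Core 3-D geometry: dihedrals, internal-coordinate placement, rotations,
# optimal (Kabsch) superposition and rigid transforms. All lengths in
# angstrom, all angles in degrees at the interface (radians internally).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  a / n
}

#' Dihedral angle of four points
#'
#' Signed torsion angle about the p2-p3 bond under the standard IUPAC
#' convention (trans = 180 degrees, cis = 0).
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (angstrom).
#' @return Angle in degrees in the interval (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  bc <- vunit(p3 - p2)
  b2 <- p4 - p3
  v <- b0 - sum(b0 * bc) * bc
  w <- b2 - sum(b2 * bc) * bc
  ang <- rad2deg(atan2(sum(vcross(bc, v) * w), sum(v * w)))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place atom D bonded to C with bond length `len` (C-D), bond angle `ang`
# (B-C-D, degrees) and torsion `tor` (A-B-C-D, degrees): the NeRF step used
# by the backbone builder.
place_atom <- function(A, B, C, len, ang, tor) {
  ang <- deg2rad(ang)
  tor <- deg2rad(tor)
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  m <- vcross(n, bc)
  d <- c(-len * cos(ang),
         len * sin(ang) * cos(tor),
         len * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle` degrees about the (not necessarily unit)
#' direction `axis`, right-handed.
#'
#' @param axis Numeric length-3 direction.
#' @param angle Rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- vunit(axis)
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid transform
#'
#' A proper rigid motion x -> R x + t acting on column coordinate vectors
#' (rows of an n x 3 matrix).
#'
#' @param R 3x3 proper rotation matrix (orthonormal, det +1).
#' @param t Numeric length-3 translation (angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R is not a proper rotation matrix")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation angle:",
      format(rotation_angle(x$R), digits = 6), "deg\n  translation:",
      paste(format(x$t, digits = 6), collapse = " "), "A\n")
  invisible(x)
}

rotation_angle <- function(R) {
  rad2deg(acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))))
}

#' Apply a rigid transform to coordinates
#'
#' @param tr A `rigid_transform`.
#' @param xyz n x 3 coordinate matrix (or length-3 vector), angstrom.
#' @return Transformed coordinates, same shape as input.
#' @export
apply_transform <- function(tr, xyz) {
  vec <- is.null(dim(xyz))
  if (vec) xyz <- matrix(xyz, 1, 3)
  out <- xyz %*% t(tr$R) + matrix(tr$t, nrow(xyz), 3, byrow = TRUE)
  if (vec) out <- drop(out)
  out
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tr A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$R), as.numeric(-t(tr$R) %*% tr$t))
}

# Repeated composition t^n (n >= 0).
transform_power <- function(tr, n) {
  out <- rigid_transform()
  for (i in seq_len(n)) out <- compose_transform(tr, out)
  out
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid transform mapping the rows of `from` onto the rows of
#' `to`, via SVD of the cross-covariance with the usual determinant
#' correction so the rotation is proper.
#'
#' @param from,to n x 3 coordinate matrices with matched rows (angstrom).
#' @return List with the optimal `transform` (a [rigid_transform]) and the
#'   residual `rmsd` in angstrom.
#' @export
kabsch <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  stopifnot(ncol(from) == 3, all(dim(from) == dim(to)))
  if (nrow(from) < 3) stop("need at least 3 points for superposition")
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  # collinearity guard: rank of centered cloud must be >= 2
  if (sum(svd(A, nu = 0, nv = 0)$d > 1e-8 * max(1, max(abs(A)))) < 2)
    stop("points are collinear; superposition is degenerate")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- ct - as.numeric(R %*% cf)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(transform = rigid_transform(R, tvec), rmsd = rmsd)
}
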