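#' Rigid-body transforms
#'
#' A rigid transform maps a coordinate `x` (row 3-vector, Angstrom) to
#' `R x + t`, where `R` is a proper rotation (orthogonal, det +1) and `t` a
#' translation.  These transforms underlie every superposition and screw-axis
#' decomposition in the package.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric translation (Angstrom).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(1, 2, 3))
#' apply_transform(tr, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthogonal (tolerance 1e-8)")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation matrix is not proper (det != +1)")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (x -> R x + t)\n")
  cat("rotation:\n")
  print(round(x$R, 6))
  cat("translation:", paste(sprintf("%.4f", x$t), collapse = " "), "\n")
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` leaving coordinates unchanged.
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Rotation matrix about an arbitrary axis
#'
#' Right-hand-rule rotation by `angle_deg` degrees about the direction
#' `axis` (need not be normalised), via the Rodrigues formula.
#'
#' @param axis length-3 direction vector.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as.numeric(axis)
  n <- sqrt(sum(u^2))
  if (n < 1e-12) stop("axis direction has zero length")
  u <- u / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform`.
#' @param x an n x 3 coordinate matrix or a single 3-vector.
#' @return Transformed coordinates with the same shape as `x`.
#' @export
apply_transform <- function(transform, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x), 1, 3) else as.matrix(x)
  stopifnot(ncol(X) == 3L)
  out <- X %*% t(transform$R) + matrix(transform$t, nrow(X), 3, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform "b then a":
#' `x -> a(b(x))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, drop(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Ri <- t(transform$R)
  rigid_transform(Ri, drop(-Ri %*% transform$t))
}

#' Root-mean-square deviation of paired coordinates
#'
#' RMSD over already-corresponded coordinate pairs; no fitting is performed.
#'
#' @param p,q n x 3 coordinate matrices of equal size (n >= 1).
#' @return RMSD in Angstrom.
#' @examples
#' rmsd_coords(diag(3), diag(3))  # 0
#' @export
rmsd_coords <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q)))
    stop("coordinate sets differ in shape (", nrow(p), " vs ", nrow(q), " rows)")
  if (nrow(p) < 1L) stop("need at least one coordinate pair")
  stopifnot(ncol(p) == 3L)
  sqrt(mean(rowSums((p - q)^2)))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of `p`
#' transformed onto `q`, by singular value decomposition of the covariance
#' of the centred coordinate sets, with the determinant sign corrected so a
#' reflection is never returned.
#'
#' @param p,q n x 3 coordinate matrices (n >= 3), corresponded row-by-row.
#' @return A list with `transform` (the `rigid_transform` carrying `p` onto
#'   `q`), `rmsd` (post-fit, Angstrom) and `n` (number of pairs).
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' q <- apply_transform(rigid_transform(rotation_about_axis(c(1, 1, 0), 40), c(3, 0, -1)), p)
#' kabsch_fit(p, q)$rmsd  # ~0
#' @export
kabsch_fit <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q))) stop("coordinate sets differ in shape")
  n <- nrow(p)
  if (n < 3L) stop("need at least 3 coordinate pairs for a rigid fit (got ", n, ")")
  cp <- colMeans(p); cq <- colMeans(q)
  P <- sweep(p, 2, cp); Q <- sweep(q, 2, cq)
  # collinear point sets leave the rotation under-determined
  if (svd(P, nu = 0, nv = 0)$d[2] < 1e-8 || svd(Q, nu = 0, nv = 0)$d[2] < 1e-8)
    stop("degenerate (collinear) coordinates: rigid fit is under-determined")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, drop(cq - R %*% cp))
  list(transform = tr, rmsd = rmsd_coords(apply_transform(tr, p), q), n = n)
}

#' Screw-axis decomposition of a rigid transform
#'
#' Every rigid transform is a rotation by some angle about a unique axis in
#' space combined with a translation along that axis (Chasles' theorem).
#' The angle comes from the rotation-matrix trace, the direction from the
#' rotation's invariant (eigenvalue +1) eigenvector with its sign set by the
#' right-hand rule, and the axis location from solving
#' `(I - R) c = t_perp` on the plane normal to the axis.
#'
#' Rotations below `min_angle` degrees have no numerically meaningful axis;
#' the angle is still returned but `axis_defined` is `FALSE` and the axial
#' translation is the full translation norm.
#'
#' @param transform a `rigid_transform`.
#' @param min_angle smallest angle (degrees) at which an axis is resolved.
#' @return An object of class `screw_axis`: `angle_deg` in \[0, 180\],
#'   unit `axis_direction`, `axis_point` (the point on the axis closest to
#'   the origin), `translation_along_axis` (Angstrom) and `axis_defined`.
#' @examples
#' screw_decompose(rigid_transform(rotation_about_axis(c(0, 0, 1), 30)))
#' @export
screw_decompose <- function(transform, min_angle = 0.1) {
  R <- transform$R; tt <- transform$t
  cth <- (sum(diag(R)) - 1) / 2
  angle <- acos(min(1, max(-1, cth))) * 180 / pi
  if (angle < min_angle) {
    return(structure(list(
      angle_deg = angle,
      axis_direction = rep(NA_real_, 3),
      axis_point = rep(NA_real_, 3),
      translation_along_axis = sqrt(sum(tt^2)),
      axis_defined = FALSE
    ), class = "screw_axis"))
  }
  ev <- eigen(R)
  i <- which.min(abs(ev$values - 1))
  u <- Re(ev$vectors[, i])
  u <- u / sqrt(sum(u^2))
  # orient by the right-hand rule (skew part has sign 2 sin(theta) u)
  s <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sum(s * u) < 0) u <- -u
  d_axis <- sum(u * tt)
  t_perp <- tt - d_axis * u
  # axis point: least-squares solve of the rank-2 system (I - R) c = t_perp,
  # then projected onto the plane through the origin normal to u
  A <- diag(3) - R
  sv <- svd(A)
  pos <- sv$d > 1e-9
  cpt <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% t_perp) / sv$d[pos])
  cpt <- drop(cpt)
  cpt <- cpt - sum(cpt * u) * u
  structure(list(
    angle_deg = angle,
    axis_direction = u,
    axis_point = cpt,
    translation_along_axis = d_axis,
    axis_defined = TRUE
  ), class = "screw_axis")
}

#' Reconstruct the rigid transform described by a screw axis
#'
#' @param screw a `screw_axis` (must have `axis_defined = TRUE` unless the
#'   angle is zero, in which case the identity is returned).
#' @return The equivalent `rigid_transform`.
#' @export
screw_transform <- function(screw) {
  if (!isTRUE(screw$axis_defined)) {
    if (screw$angle_deg > 0.5)
      stop("screw axis undefined for a non-trivial rotation")
    return(identity_transform())
  }
  R <- rotation_about_axis(screw$axis_direction, screw$angle_deg)
  c0 <- screw$axis_point
  tt <- drop(c0 - R %*% c0) + screw$translation_along_axis * screw$axis_direction
  rigid_transform(R, tt)
}

#' @export
print.screw_axis <- function(x, ...) {
  cat(sprintf("Screw axis: rotation %.3f deg", x$angle_deg))
  if (isTRUE(x$axis_defined)) {
    cat(sprintf(", axial translation %.3f A\n", x$translation_along_axis))
    cat("  direction:", paste(sprintf("%.4f", x$axis_direction), collapse = " "), "\n")
    cat("  point    :", paste(sprintf("%.3f", x$axis_point), collapse = " "), "\n")
  } else {
    cat(" (axis undefined at this angle)\n")
  }
  invisible(x)
}
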