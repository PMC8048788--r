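#' Specification of a synthetic clam-shell structure pair
#'
#' Defines a two-lobe C-alpha model built from idealised pseudo-helices
#' (rise 1.5 A, radius 2.3 A, 100 degrees of turn per residue) joined by a
#' short hinge loop lying on the opening axis.  The "open" partner is the
#' closed model with every lobe-1 residue (and the interface metal when it
#' sits in lobe 1's half-space) rotated by `theta` degrees about the axis,
#' after which i.i.d. Gaussian coordinate noise of `noise_sigma` is added
#' independently to both models.  Residues are numbered contiguously:
#' lobe 1 first, then the hinge loop, then lobe 2.
#'
#' @param n_lobe1,n_lobe2 residue counts of the two rigid lobes (>= 10).
#' @param n_hinge residues in the connecting hinge loop.
#' @param theta opening angle, degrees, in \[0, 90\].
#' @param axis_direction,axis_point opening axis (direction is normalised).
#' @param noise_sigma coordinate noise s.d., Angstrom.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param place_metal place a zinc-like heteroatom near the lobe interface.
#' @param metal_offset offset (A) of the metal from the hinge centroid, in
#'   the canonical frame (x towards lobe 1, z along the axis).
#' @return An object of class `clamshell_spec`.
#' @export
clamshell_spec <- function(n_lobe1 = 80, n_lobe2 = 80, n_hinge = 4,
                           theta = 25, axis_direction = c(0, 0, 1),
                           axis_point = c(0, 0, 0), noise_sigma = 0,
                           seed = 1, place_metal = TRUE,
                           metal_offset = c(4, 0, 2)) {
  stopifnot(n_lobe1 >= 10, n_lobe2 >= 10, n_hinge >= 1,
            theta >= 0, theta <= 90, noise_sigma >= 0)
  structure(list(n_lobe1 = as.integer(n_lobe1), n_lobe2 = as.integer(n_lobe2),
                 n_hinge = as.integer(n_hinge), theta = theta,
                 axis_direction = axis_direction / sqrt(sum(axis_direction^2)),
                 axis_point = as.numeric(axis_point),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 place_metal = isTRUE(place_metal),
                 metal_offset = as.numeric(metal_offset)),
            class = "clamshell_spec")
}

# rotation taking the canonical frame (z axis) onto the requested axis
frame_rotation <- function(axis_direction) {
  z <- c(0, 0, 1)
  u <- axis_direction
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * u)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(rotation_about_axis(c(1, 0, 0), 180))
  }
  rotation_about_axis(v, atan2(s, cth) * 180 / pi)
}

# pseudo-helical lobe: k = 0 at the hinge-proximal end
helix_lobe <- function(n, start, dir, rise = 1.5, radius = 2.3,
                       turn_deg = 100) {
  dir <- dir / sqrt(sum(dir^2))
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * dir) * dir; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2], dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  k <- seq_len(n) - 1L
  ang <- k * turn_deg * pi / 180
  t(vapply(seq_len(n), function(i) {
    start + rise * k[i] * dir + radius * (cos(ang[i]) * e1 + sin(ang[i]) * e2)
  }, numeric(3)))
}

ca_model <- function(xyz, resno, id, metal_xyz = NULL) {
  n <- nrow(xyz)
  atom <- data.frame(record = rep("ATOM", n), eleno = seq_len(n),
                     elety = "CA", alt = "", resid = "ALA", chain = "A",
                     resno = resno, insert = "",
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
  if (!is.null(metal_xyz)) {
    atom <- rbind(atom, data.frame(
      record = "HETATM", eleno = n + 1L, elety = "ZN", alt = "",
      resid = "ZN", chain = "A", resno = max(resno) + 100L, insert = "",
      x = metal_xyz[1], y = metal_xyz[2], z = metal_xyz[3],
      o = 1, b = 0, elesy = "ZN", stringsAsFactors = FALSE))
  }
  new_structure_model(atom, id = id)
}

#' Generate a closed/open synthetic clam-shell pair with ground truth
#'
#' @param spec a [clamshell_spec].
#' @return A list with `closed` and `open` [structure_model]s, `truth`
#'   (class `clamshell_truth`: the lobe-1 `rigid_transform`, the analytic
#'   per-residue displacement table `2 r sin(theta/2)`, the hinge residue
#'   range, the metal displacement and the generating parameters) and
#'   `scheme`, a [subdomain_scheme] mapping lobe 1 / lobe 2 onto
#'   subdomains 1 / 2.
#' @examples
#' pair <- generate_clamshell(clamshell_spec(theta = 25, seed = 7))
#' pair$truth$metal_displacement
#' @export
generate_clamshell <- function(spec) {
  stopifnot(inherits(spec, "clamshell_spec"))
  n1 <- spec$n_lobe1; n2 <- spec$n_lobe2; nh <- spec$n_hinge
  # canonical frame: axis = z through origin, lobe 1 in x > 0
  hinge_xyz <- cbind(0, 0, 1.5 * (seq_len(nh) - 1L))
  lobe1_xyz <- helix_lobe(n1, start = c(3.5, 0, -1.0),
                          dir = c(1, 0.15, -0.1))[rev(seq_len(n1)), , drop = FALSE]
  lobe2_xyz <- helix_lobe(n2, start = c(-3.5, 0, 1.5 * nh + 0.5),
                          dir = c(-1, 0.15, 0.1))
  metal_can <- if (spec$place_metal) spec$metal_offset + colMeans(hinge_xyz)
  # map canonical frame onto the requested axis
  Rf <- frame_rotation(spec$axis_direction)
  world <- function(x) {
    if (is.null(x)) return(NULL)
    X <- if (is.null(dim(x))) matrix(x, 1, 3) else x
    out <- X %*% t(Rf) + matrix(spec$axis_point, nrow(X), 3, byrow = TRUE)
    if (is.null(dim(x))) drop(out) else out
  }
  xyz_closed <- world(rbind(lobe1_xyz, hinge_xyz, lobe2_xyz))
  metal_closed <- world(metal_can)
  resno <- seq_len(n1 + nh + n2)
  hinge_range <- (n1 + 1L):(n1 + nh)

  # opening transform: rotation by theta about the axis (right-hand rule)
  R <- rotation_about_axis(spec$axis_direction, spec$theta)
  tr <- rigid_transform(R, drop(spec$axis_point - R %*% spec$axis_point))
  xyz_open <- xyz_closed
  xyz_open[seq_len(n1), ] <- apply_transform(tr, xyz_closed[seq_len(n1), , drop = FALSE])
  metal_open <- metal_closed
  metal_in_lobe1 <- FALSE
  if (spec$place_metal) {
    metal_in_lobe1 <- metal_can[1] > 0      # lobe-1 half-space (canonical x > 0)
    if (metal_in_lobe1) metal_open <- apply_transform(tr, metal_closed)
  }

  # analytic displacements: 2 r sin(theta/2), r = perpendicular distance to axis
  perp_dist <- function(X) {
    d <- sweep(X, 2, spec$axis_point)
    along <- drop(d %*% spec$axis_direction)
    unname(sqrt(pmax(0, unname(rowSums(d^2)) - along^2)))
  }
  disp <- rep(0, length(resno))
  disp[seq_len(n1)] <- 2 * perp_dist(xyz_closed[seq_len(n1), , drop = FALSE]) *
    sin(spec$theta * pi / 360)
  metal_disp <- if (spec$place_metal && metal_in_lobe1)
    2 * perp_dist(matrix(metal_closed, 1, 3)) * sin(spec$theta * pi / 360)
  else if (spec$place_metal) 0 else NA_real_

  # deterministic noise, independent for the two models
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  noisy <- function(X) X + matrix(stats::rnorm(length(X), 0, spec$noise_sigma),
                                  nrow(X), 3)
  if (spec$noise_sigma > 0) {
    xyz_closed <- noisy(xyz_closed)
    xyz_open <- noisy(xyz_open)
  }

  closed <- ca_model(xyz_closed, resno, id = "clamshell_closed",
                     metal_xyz = metal_closed)
  open <- ca_model(xyz_open, resno, id = "clamshell_open",
                   metal_xyz = metal_open)
  scheme <- subdomain_scheme(
    name = "clamshell",
    subdomain1 = seq_len(n1),
    subdomain2 = (n1 + nh + 1L):(n1 + nh + n2),
    regions = list(lobe1 = seq_len(n1)),
    hinges = list(h1 = hinge_range))
  truth <- structure(list(
    transform = tr,
    displacement = data.frame(resno = resno, displacement = disp),
    hinge_range = hinge_range,
    metal_displacement = as.numeric(metal_disp),
    theta = spec$theta,
    axis_direction = spec$axis_direction,
    axis_point = spec$axis_point,
    noise_sigma = spec$noise_sigma), class = "clamshell_truth")
  list(closed = closed, open = open, truth = truth, scheme = scheme)
}

#' Score recovery of the generator's ground truth
#'
#' Compares an estimated opening screw (and optional hinge calls) against a
#' [generate_clamshell()] ground truth.
#'
#' @param truth a `clamshell_truth`.
#' @param screw a `screw_axis` estimate (e.g. from [opening_transform()]).
#' @param hinges optional hinge-call data frame from [detect_hinges()].
#' @return A list with `angle_error_deg`, `axis_dot` (estimated direction
#'   dotted with truth), `axis_angle_error_deg` and
#'   `hinge_error_residues` (0 when the best-scoring call overlaps the true
#'   hinge range, otherwise the residue gap; `NA` without calls).
#' @export
evaluate_recovery <- function(truth, screw, hinges = NULL) {
  stopifnot(inherits(truth, "clamshell_truth"), inherits(screw, "screw_axis"))
  angle_error <- abs(screw$angle_deg - truth$theta)
  axis_dot <- if (isTRUE(screw$axis_defined))
    sum(screw$axis_direction * truth$axis_direction) else NA_real_
  axis_angle_error <- if (is.na(axis_dot)) NA_real_ else
    acos(min(1, max(-1, axis_dot))) * 180 / pi
  hinge_error <- NA_real_
  if (!is.null(hinges) && nrow(hinges)) {
    best <- hinges[which.max(hinges$score), ]
    lo <- truth$hinge_range[1]; hi <- truth$hinge_range[length(truth$hinge_range)]
    hinge_error <- max(0, lo - best$end_resno, best$start_resno - hi)
  }
  list(angle_error_deg = angle_error, axis_dot = axis_dot,
       axis_angle_error_deg = axis_angle_error,
       hinge_error_residues = hinge_error)
}
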