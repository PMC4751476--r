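# Screw-transformation geometry: extract the rigid protomer1 -> protomer2
# transform from a dimer, decompose it into screw parameters (Chasles),
# derive helical descriptors, extend to N-mers and filter ring candidates.

#' Screw parameters
#'
#' A screw motion: rotation by `theta` about the axis through `axis_point`
#' with direction `axis_dir`, plus a `rise` translation along the axis.
#' Repeated application generates a helix. The axis direction is chosen so
#' that `theta` is positive; a left-handed helix then shows a negative
#' rise.
#'
#' @param axis_point Point on the screw axis (angstrom).
#' @param axis_dir Axis direction (normalized internally).
#' @param theta Rotation per step in degrees.
#' @param rise Translation per step along the axis (angstrom, signed).
#' @param degenerate Flag for a near-pure translation (no defined axis).
#' @return Object of class `screw_params`.
#' @export
screw_params <- function(axis_point, axis_dir, theta, rise, degenerate = FALSE) {
  if (!degenerate) {
    axis_dir <- vunit(axis_dir)
    if (theta <= -180 || theta > 180) theta <- ((theta + 180) %% 360) - 180
  }
  structure(list(axis_point = as.numeric(axis_point),
                 axis_dir = as.numeric(axis_dir),
                 theta = theta, rise = rise, degenerate = degenerate),
            class = "screw_params")
}

#' @export
print.screw_params <- function(x, ...) {
  if (x$degenerate) {
    cat("Screw parameters: degenerate (pure translation)\n")
  } else {
    d <- helical_descriptors(x)
    cat(sprintf(paste0("Screw parameters: theta = %.4f deg, rise = %.4f A\n",
                       "  %.3f protomers/turn, pitch %.3f nm, %s-handed\n"),
                x$theta, x$rise, d$n, d$pitch, d$handedness))
  }
  invisible(x)
}

#' Rigid transform from a dimer
#'
#' Least-squares optimal rigid transform mapping protomer1 onto protomer2
#' over a matched atom selection (default CA). Repeating this interface
#' transform generates the helical polymer.
#'
#' @param protomer1,protomer2 [conformer] objects with matching selections.
#' @param selection Atom selection (see [kabsch_rmsd]).
#' @return A [rigid_transform]; the superposition residual (angstrom) is
#'   attached as attribute `"rmsd"`.
#' @export
transform_from_dimer <- function(protomer1, protomer2, selection = "calpha") {
  s1 <- atom_selection(protomer1$atom, selection)
  s2 <- atom_selection(protomer2$atom, selection)
  if (sum(s1) != sum(s2)) stop("matched selections differ in size")
  fit <- kabsch(protomer1$xyz[s1, , drop = FALSE],
                protomer2$xyz[s2, , drop = FALSE])
  structure(fit$transform, rmsd = fit$rmsd)
}

#' Screw decomposition of a rigid transform (Chasles)
#'
#' Decomposes a proper rigid motion into rotation angle and axis, rise
#' along the axis and a point on the axis. The rotation angle comes from
#' the trace, the axis from the skew-symmetric part (eigen decomposition
#' near 180 degrees), the rise is the translation's projection on the axis
#' and the axis point solves the in-plane fixed-point equation by
#' pseudoinverse. Rotations below `tol_deg` are flagged degenerate (pure
#' translation): no axis, rise or descriptors are defined.
#'
#' @param tr A [rigid_transform].
#' @param tol_deg Angular degeneracy tolerance in degrees.
#' @return A [screw_params] object.
#' @export
screw_from_transform <- function(tr, tol_deg = 0.1) {
  R <- tr$R; tv <- tr$t
  theta <- rotation_angle(R)
  if (theta < tol_deg)
    return(screw_params(c(NA, NA, NA), c(NA, NA, NA), NA, NA, degenerate = TRUE))
  if (theta < 179.9) {
    u <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    u <- u / (2 * sin(deg2rad(theta)))
  } else {
    # near 180 deg the skew part vanishes; use the +1 eigenvector of R
    e <- eigen(R)
    k <- which.min(abs(Re(e$values) - 1))
    u <- Re(e$vectors[, k])
    # tie-break: orient the axis so the rise is non-negative
    if (sum(u * tv) < 0) u <- -u
  }
  u <- vunit(u)
  d <- sum(u * tv)
  t_perp <- tv - d * u
  p <- as.numeric(MASS::ginv(diag(3) - R) %*% t_perp)
  p <- p - sum(p * u) * u   # minimal-norm point, perpendicular to the axis
  screw_params(p, u, theta, d)
}

#' Recompose a screw into its rigid transform
#' @param s A non-degenerate [screw_params].
#' @return The equivalent [rigid_transform].
#' @export
screw_to_transform <- function(s) {
  if (s$degenerate) stop("degenerate screw has no rotation")
  R <- rotation_matrix(s$axis_dir, s$theta)
  tv <- as.numeric((diag(3) - R) %*% s$axis_point) + s$rise * s$axis_dir
  rigid_transform(R, tv)
}

#' Helical descriptors of a screw
#'
#' Protomers per turn n = 360/|theta|, pitch P = n * |rise| (reported in
#' nm) and handedness (sign of theta * rise; "flat" when the rise is
#' negligible, i.e. a closed ring).
#'
#' @param s A non-degenerate [screw_params].
#' @param flat_tol Rise below which the assembly counts as flat (angstrom).
#' @return List with `n`, `pitch` (nm) and `handedness`.
#' @export
helical_descriptors <- function(s, flat_tol = 1e-6) {
  if (s$degenerate) stop("degenerate screw: protomers per turn undefined")
  n <- 360 / abs(s$theta)
  pitch <- n * abs(s$rise) / 10
  hand <- if (abs(s$rise) < flat_tol) "flat" else
    if (sign(s$theta * s$rise) > 0) "right" else "left"
  list(n = n, pitch = pitch, handedness = hand)
}

#' Extend a protomer into an N-mer by repeating the interface transform
#'
#' Protomer k is t^(k-1) applied to protomer 1, so every consecutive
#' interface is congruent. Chains are relabelled A, B, C, ...
#'
#' @param protomer A single-chain [conformer].
#' @param tr The interface [rigid_transform].
#' @param N Number of protomers (>= 2).
#' @return Object of class `assembly`: list with the combined `conformer`,
#'   the generating `transform`, `N` and the original `protomer`.
#' @export
extend_helix <- function(protomer, tr, N) {
  stopifnot(N >= 2)
  xyz_list <- vector("list", N)
  cur <- rigid_transform()
  for (k in seq_len(N)) {
    xyz_list[[k]] <- apply_transform(cur, protomer$xyz)
    cur <- compose_transform(tr, cur)
  }
  atoms <- do.call(rbind, lapply(seq_len(N), function(k) {
    a <- protomer$atom
    a$chain <- chain_label(k)
    a
  }))
  combined <- conformer(do.call(rbind, xyz_list), atoms)
  # steric sanity: inter-protomer CA pairs below 1 A indicate a collapse
  ca <- lapply(xyz_list, function(X) X[protomer$atom$elety == "CA", , drop = FALSE])
  for (k in seq_len(N - 1)) for (l in (k + 1):N) {
    d2 <- outer(rowSums(ca[[k]]^2), rowSums(ca[[l]]^2), "+") -
      2 * ca[[k]] %*% t(ca[[l]])
    if (min(d2) < 1) {
      warning("steric clash: inter-protomer CA pair below 1 A (protomers ",
              k, ",", l, ")")
      break
    }
  }
  structure(list(conformer = combined, transform = tr, N = N,
                 protomer = protomer), class = "assembly")
}

chain_label <- function(k) {
  if (k <= 26) LETTERS[k] else paste0(LETTERS[(k - 1) %/% 26], LETTERS[(k - 1) %% 26 + 1])
}

#' Selection criteria for ring candidates
#'
#' The geometric gate for nearly circular assemblies: protomers per turn
#' within an inclusive range and pitch strictly below a maximum.
#'
#' @param n_min,n_max Inclusive bounds on protomers per turn (default 5-6).
#' @param pitch_max Strict upper bound on pitch in nm (default 2).
#' @param marker_residue Residue whose inward orientation is screened by
#'   [orientation_filter] (default: last residue, the C-terminus).
#' @return Object of class `selection_criteria`.
#' @export
selection_criteria <- function(n_min = 5, n_max = 6, pitch_max = 2,
                               marker_residue = NULL) {
  stopifnot(n_min <= n_max, pitch_max > 0)
  structure(list(n_min = n_min, n_max = n_max, pitch_max = pitch_max,
                 marker_residue = marker_residue), class = "selection_criteria")
}

#' Filter screw candidates by the ring criteria
#'
#' Keeps screws with n_min <= n <= n_max (inclusive) and pitch strictly
#' below the maximum, reporting a per-screw reason for every failure.
#'
#' @param screws List of [screw_params].
#' @param criteria A [selection_criteria].
#' @return Data frame with columns `n`, `pitch`, `pass`, `reason`.
#' @export
filter_candidates <- function(screws, criteria = selection_criteria()) {
  if (inherits(screws, "screw_params")) screws <- list(screws)
  rows <- lapply(screws, function(s) {
    if (s$degenerate)
      return(data.frame(n = NA, pitch = NA, pass = FALSE, reason = "degenerate"))
    d <- helical_descriptors(s)
    reasons <- character(0)
    if (d$n < criteria$n_min) reasons <- c(reasons, "n below range")
    if (d$n > criteria$n_max) reasons <- c(reasons, "n above range")
    if (!(d$pitch < criteria$pitch_max)) reasons <- c(reasons, "pitch too large")
    data.frame(n = d$n, pitch = d$pitch, pass = length(reasons) == 0,
               reason = if (length(reasons)) paste(reasons, collapse = "; ") else "")
  })
  do.call(rbind, rows)
}

#' Is a marker residue oriented towards the ring center?
#'
#' TRUE iff, averaged over protomers, the marker residue's CA lies at a
#' strictly smaller radial distance from the assembly axis than the mean
#' CA radial distance of the protomer. An explicit, testable rule for
#' "oriented towards the ring center".
#'
#' @param assembly An `assembly` (from [extend_helix]) or `ring_assembly`.
#' @param marker_residue Residue index (default: last residue).
#' @return Logical.
#' @export
orientation_filter <- function(assembly, marker_residue = NULL) {
  s <- if (inherits(assembly, "ring_assembly")) assembly$screw
       else screw_from_transform(assembly$transform)
  if (s$degenerate) stop("degenerate axis: orientation undefined")
  cf <- assembly$conformer
  if (is.null(marker_residue)) marker_residue <- max(cf$atom$resno)
  ca <- cf$atom$elety == "CA"
  radial <- function(X) {
    v <- sweep(X, 2, s$axis_point)
    ax <- v %*% s$axis_dir
    sqrt(pmax(0, rowSums(v^2) - ax^2))
  }
  r_all <- radial(cf$xyz[ca, , drop = FALSE])
  mk <- ca & cf$atom$resno == marker_residue
  if (!any(mk)) stop("marker residue ", marker_residue, " not found")
  r_marker <- radial(cf$xyz[mk, , drop = FALSE])
  mean(r_marker) < mean(r_all)
}
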