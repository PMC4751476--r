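# Coarse-grained rigid-body docking: two-bead-per-residue mapping, a soft
# Lennard-Jones + screened-Coulomb bead potential, systematic start-pose
# generation on a sphere, 6-DOF minimization and pose clustering/ranking.
# The whole run is deterministic: no hidden randomness anywhere.

#' Coarse-grained bead parameters
#'
#' Loads the packaged per-residue bead table: side-chain bead radius
#' (angstrom), LJ well depth (kcal/mol) and formal charge (e), plus the
#' backbone bead row. The table is editable data so the parameterization
#' is drop-in replaceable.
#'
#' @param path Optional alternative parameter file.
#' @return Data frame with columns `resid`, `radius`, `eps`, `charge`.
#' @export
cg_parameters <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cg_beads.tsv", package = "oligoring")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Map a conformer to a coarse-grained bead model
#'
#' Default two-bead scheme: one backbone bead at CA plus one side-chain
#' bead at the side-chain heavy-atom centroid (none for Gly). Side-chain
#' beads of Asp/Glu carry -1 e and Lys/Arg +1 e; the first and last
#' backbone beads of each chain carry the +1/-1 terminal charges.
#'
#' @param c A [conformer].
#' @param params Bead parameter table (see [cg_parameters]).
#' @return Object of class `cg_model`: data frame of beads with columns
#'   `x`, `y`, `z`, `radius`, `eps`, `charge`, `type`, `resno`, `chain`.
#' @export
coarse_grain <- function(c, params = cg_parameters()) {
  bb_row <- params[params$resid == "BB", ]
  rows <- list()
  for (ch in unique(c$atom$chain)) {
    in_ch <- c$atom$chain == ch
    res <- sort(unique(c$atom$resno[in_ch]))
    unknown <- setdiff(unique(c$atom$resid[in_ch]), c(params$resid, "BB"))
    if (length(unknown))
      stop("unknown residue name(s): ", paste(unknown, collapse = ", "))
    for (r in res) {
      inres <- in_ch & c$atom$resno == r
      rname <- c$atom$resid[inres][1]
      prow <- params[params$resid == rname, ]
      ica <- which(inres & c$atom$elety == "CA")
      if (length(ica) != 1) stop("residue ", r, " chain ", ch, " lacks a CA atom")
      qbb <- if (r == res[1]) 1 else if (r == res[length(res)]) -1 else 0
      rows[[length(rows) + 1]] <- data.frame(
        x = c$xyz[ica, 1], y = c$xyz[ica, 2], z = c$xyz[ica, 3],
        radius = bb_row$radius, eps = bb_row$eps, charge = qbb,
        type = "BB", resno = r, chain = ch, stringsAsFactors = FALSE)
      sc <- inres & !(c$atom$elety %in% BACKBONE_NAMES) & c$atom$elesy != "H"
      if (any(sc)) {
        ctr <- colMeans(c$xyz[sc, , drop = FALSE])
        rows[[length(rows) + 1]] <- data.frame(
          x = ctr[1], y = ctr[2], z = ctr[3],
          radius = prow$radius, eps = prow$eps, charge = prow$charge,
          type = "SC", resno = r, chain = ch, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cg_model", "data.frame")
  out
}

cg_xyz <- function(cg) as.matrix(cg[, c("x", "y", "z")])

# largest dimension of a bead model = max pairwise bead distance
cg_max_dimension <- function(cg) {
  X <- cg_xyz(cg)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  sqrt(max(0, max(d2)))
}

#' Energy model configuration
#'
#' Soft-core Lennard-Jones (4 eps ((s/r)^12 - (s/r)^6), sigma from the
#' bead-radius sum so the pair minimum sits at r_i + r_j) plus Coulomb
#' with a distance-dependent dielectric eps_r = `diel_coeff` * r. The
#' soft core replaces r by (r^6 + (soft*sigma)^6)^(1/6), keeping the
#' energy finite (never NaN) at r -> 0. Pairs beyond `cutoff` contribute
#' exactly zero; between `switch_on` and `cutoff` the pair energy is
#' tapered by the standard cubic switching function so the total energy
#' is continuously differentiable (a hard truncation would leave jumps
#' that stall the minimizer).
#'
#' @param cutoff Pair cutoff (angstrom).
#' @param switch_on Distance where the switching taper begins (angstrom).
#' @param diel_coeff Distance-dependent dielectric coefficient.
#' @param soft Soft-core fraction of sigma.
#' @param coulomb_k Coulomb constant (kcal A / mol / e^2).
#' @return List of energy parameters.
#' @export
energy_config <- function(cutoff = 12, switch_on = 10, diel_coeff = 4,
                          soft = 0.3, coulomb_k = 332.0637) {
  stopifnot(switch_on < cutoff)
  list(cutoff = cutoff, switch_on = switch_on, diel_coeff = diel_coeff,
       soft = soft, coulomb_k = coulomb_k)
}

#' Interaction energy between two bead models
#'
#' Sum over inter-body bead pairs of the soft LJ plus screened Coulomb
#' terms, with the pose applied to the ligand copy. Symmetric under
#' swapping receptor/ligand with the inverse pose and invariant under a
#' global rigid motion of both bodies.
#'
#' @param receptor,ligand `cg_model` objects.
#' @param pose Optional [rigid_transform] applied to the ligand beads.
#' @param config Energy parameters (see [energy_config]).
#' @return Energy in kcal/mol (finite for any geometry).
#' @export
interaction_energy <- function(receptor, ligand, pose = NULL,
                               config = energy_config()) {
  X <- cg_xyz(receptor)
  Y <- cg_xyz(ligand)
  if (!is.null(pose)) Y <- apply_transform(pose, Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  r <- sqrt(pmax(d2, 0))
  sig <- outer(receptor$radius, ligand$radius, "+") / 2^(1 / 6)
  eps <- sqrt(outer(receptor$eps, ligand$eps))
  qq <- outer(receptor$charge, ligand$charge)
  within <- r <= config$cutoff
  if (!any(within)) return(0)
  reff <- (r^6 + (config$soft * sig)^6)^(1 / 6)
  sr6 <- (sig / reff)^6
  elj <- 4 * eps * (sr6^2 - sr6)
  ecoul <- config$coulomb_k * qq / (config$diel_coeff * reff^2)
  # cubic switching taper between switch_on and cutoff (C1 continuous)
  c2 <- config$cutoff^2; on2 <- config$switch_on^2
  sw <- matrix(1, nrow(r), ncol(r))
  tail <- within & r > config$switch_on
  sw[tail] <- (c2 - r[tail]^2)^2 * (c2 + 2 * r[tail]^2 - 3 * on2) /
    (c2 - on2)^3
  sum((sw * (elj + ecoul))[within])
}

#' Systematic start poses on a sphere around the receptor
#'
#' Ligand centroid positions on a deterministic Fibonacci-spiral sphere of
#' radius = receptor largest dimension x `margin` ("slightly larger than
#' its largest dimension"), with `n_orientations` deterministic ligand
#' orientations at each point. Fully reproducible; no randomness.
#'
#' @param receptor,ligand `cg_model` objects.
#' @param angular_spacing Approximate angular spacing between sphere
#'   points, degrees (the point count is about 4 pi / spacing^2).
#' @param n_orientations Orientations per sphere point.
#' @param margin Sphere radius margin factor.
#' @return List of [rigid_transform] poses, with the sphere `radius`
#'   attached as an attribute.
#' @export
generate_start_poses <- function(receptor, ligand, angular_spacing = 45,
                                 n_orientations = 3, margin = 1.2) {
  stopifnot(angular_spacing > 0, n_orientations >= 1)
  radius <- cg_max_dimension(receptor) * margin
  npts <- max(1, round(4 * pi / deg2rad(angular_spacing)^2))
  golden <- pi * (3 - sqrt(5))
  rc <- colMeans(cg_xyz(receptor))
  lc <- colMeans(cg_xyz(ligand))
  # deterministic orientation set: rotation k about the k-th spiral axis
  orient <- lapply(seq_len(n_orientations) - 1L, function(k) {
    if (k == 0) diag(3) else {
      z <- 1 - 2 * (k - 0.5) / n_orientations
      rr <- sqrt(max(0, 1 - z^2))
      rotation_matrix(c(rr * cos(golden * k), rr * sin(golden * k), z),
                      360 * k / n_orientations)
    }
  })
  poses <- vector("list", npts * n_orientations)
  idx <- 1
  for (i in seq_len(npts) - 1L) {
    z <- 1 - 2 * (i + 0.5) / npts
    rr <- sqrt(max(0, 1 - z^2))
    pt <- c(rr * cos(golden * i), rr * sin(golden * i), z)
    target <- rc + radius * pt
    for (R in orient) {
      poses[[idx]] <- rigid_transform(R, target - as.numeric(R %*% lc))
      idx <- idx + 1
    }
  }
  attr(poses, "radius") <- radius
  poses
}

# rotation from a rotation vector (radians); identity at zero
rotvec_matrix <- function(rv) {
  ang <- sqrt(sum(rv^2))
  if (ang < 1e-12) diag(3) else rotation_matrix(rv, rad2deg(ang))
}

#' Minimize a docking pose over six rigid degrees of freedom
#'
#' Local minimization over three translations plus three axis-angle
#' rotation increments composed onto the current orientation (no Euler
#' singularities), Nelder-Mead with the start pose in the initial simplex
#' so the final energy never exceeds the starting energy. Because start
#' poses sit outside the interaction cutoff where the energy surface is
#' exactly flat, an optional deterministic approach phase first slides
#' the ligand along the line of bead-model centers until its closest
#' bead pair enters the interaction shell; the minimizer then has a
#' gradient to follow.
#'
#' @param receptor,ligand `cg_model` objects.
#' @param pose Starting [rigid_transform].
#' @param config Energy parameters.
#' @param maxit Iteration budget.
#' @param reltol Relative convergence tolerance.
#' @param approach Slide into the interaction shell before minimizing.
#' @return Object of class `dock_pose`: list with `transform`, `energy`
#'   (kcal/mol), `start_energy` and `converged`.
#' @export
minimize_pose <- function(receptor, ligand, pose, config = energy_config(),
                          maxit = 2000, reltol = 1e-6, approach = TRUE) {
  if (approach) pose <- approach_pose(receptor, ligand, pose, config)
  Y0 <- apply_transform(pose, cg_xyz(ligand))
  c0 <- colMeans(Y0)
  build <- function(par) {
    Rinc <- rotvec_matrix(par[4:6])
    Rn <- Rinc %*% pose$R
    tn <- as.numeric(Rinc %*% (pose$t - c0)) + c0 + par[1:3]
    rigid_transform(Rn, tn)
  }
  fn <- function(par) interaction_energy(receptor, ligand, build(par), config)
  e0 <- fn(rep(0, 6))
  if (!is.finite(e0)) stop("energy not evaluable at the start pose")
  res <- stats::optim(rep(0, 6), fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  final <- build(res$par)
  structure(list(transform = final, energy = res$value, start_energy = e0,
                 converged = res$convergence == 0), class = "dock_pose")
}

# deterministic pre-positioning: translate the posed ligand towards the
# receptor center in 1 A steps until the closest inter-body bead gap is
# inside the interaction shell (cutoff minus a 2 A margin), never past
# bead contact
approach_pose <- function(receptor, ligand, pose, config) {
  X <- cg_xyz(receptor)
  Y <- apply_transform(pose, cg_xyz(ligand))
  dir <- colMeans(X) - colMeans(Y)
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-9) return(pose)
  dir <- dir / nd
  target <- config$cutoff - 2
  contact <- outer(receptor$radius, ligand$radius, "+")
  for (i in seq_len(200)) {
    d <- sqrt(pmax(outer(rowSums(X^2), rowSums(Y^2), "+") -
                     2 * tcrossprod(X, Y), 0))
    # stop once the closest pair is inside the interaction shell, or at
    # bead contact, whichever comes first
    if (min(d) <= target || min(d - contact) <= 0) break
    Y <- Y + matrix(dir, nrow(Y), 3, byrow = TRUE)
    pose <- rigid_transform(pose$R, pose$t + dir)
  }
  pose
}

#' Cluster minimized poses and rank by energy
#'
#' Single-linkage grouping on ligand-bead RMSD between posed copies (the
#' receptor frame stays fixed, no re-superposition); the representative of
#' each cluster is its lowest-energy member and clusters are ranked by
#' representative energy, ascending.
#'
#' @param poses List of `dock_pose` objects.
#' @param ligand The `cg_model` the poses act on.
#' @param rmsd_cutoff Single-linkage merge cutoff, nm.
#' @return Data frame of cluster representatives: `cluster`, `size`,
#'   `energy`, `pose_id`, plus the full membership as attribute
#'   `"members"` and the pose list as `"poses"`.
#' @export
cluster_and_rank <- function(poses, ligand, rmsd_cutoff = 0.5) {
  conv <- vapply(poses, function(p) isTRUE(p$converged), logical(1))
  if (!any(conv)) {
    warning("no converged pose to cluster")
    return(data.frame(cluster = integer(0), size = integer(0),
                      energy = numeric(0), pose_id = integer(0)))
  }
  ids <- which(conv)
  Y <- cg_xyz(ligand)
  m <- nrow(Y)
  flat <- t(vapply(ids, function(i)
    as.numeric(apply_transform(poses[[i]]$transform, Y)), numeric(3 * m)))
  if (length(ids) == 1) {
    grp <- 1L
  } else {
    d <- stats::dist(flat) / sqrt(m) / 10   # ligand-bead RMSD, nm
    grp <- stats::cutree(stats::hclust(d, method = "single"), h = rmsd_cutoff)
  }
  energies <- vapply(ids, function(i) poses[[i]]$energy, numeric(1))
  reps <- vapply(split(seq_along(ids), grp), function(members)
    members[which.min(energies[members])], integer(1))
  ord <- order(energies[reps])
  out <- data.frame(cluster = seq_along(ord),
                    size = as.integer(table(grp)[names(reps)])[ord],
                    energy = energies[reps][ord],
                    pose_id = ids[reps][ord])
  attr(out, "members") <- lapply(names(reps)[ord], function(g) ids[grp == as.integer(g)])
  attr(out, "poses") <- poses
  out
}

#' Systematic self-docking run
#'
#' Convenience driver: coarse-grain both partners, generate the start
#' sphere, minimize every pose and cluster/rank the results.
#'
#' @param receptor,ligand [conformer] objects (ligand defaults to the
#'   receptor: self-docking).
#' @param angular_spacing,n_orientations,margin Start-pose lattice (see
#'   [generate_start_poses]).
#' @param rmsd_cutoff Pose clustering cutoff, nm.
#' @param config Energy parameters.
#' @param maxit Minimization budget per pose.
#' @return List with `ranked` (from [cluster_and_rank]), `poses`, and the
#'   `receptor_cg`/`ligand_cg` bead models.
#' @export
dock_run <- function(receptor, ligand = receptor, angular_spacing = 45,
                     n_orientations = 3, margin = 1.2, rmsd_cutoff = 0.5,
                     config = energy_config(), maxit = 2000) {
  rcg <- coarse_grain(receptor)
  lcg <- coarse_grain(ligand)
  starts <- generate_start_poses(rcg, lcg, angular_spacing, n_orientations, margin)
  poses <- lapply(starts, function(p) minimize_pose(rcg, lcg, p, config, maxit))
  ranked <- cluster_and_rank(poses, lcg, rmsd_cutoff)
  list(ranked = ranked, poses = poses, receptor_cg = rcg, ligand_cg = lcg)
}
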