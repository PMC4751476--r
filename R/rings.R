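# Ring assembly: Monte-Carlo cyclization with exact N-fold closure, ring
# metrics, inter-protomer contact maps and ring-on-ring stacking.

#' Monte-Carlo configuration for cyclization
#'
#' @param steps Total number of Monte-Carlo steps.
#' @param max_rot Maximum protomer rotation per move, degrees.
#' @param max_trans Maximum protomer translation per move, angstrom.
#' @param kT Metropolis temperature, kcal/mol.
#' @param cycles Annealing cycles: move amplitudes and temperature shrink
#'   by `shrink` after each cycle, so late steps refine locally.
#' @param shrink Per-cycle scale factor for amplitudes and kT.
#' @param seed RNG seed (the accepted-state trajectory is reproducible).
#' @return List of MC parameters.
#' @export
mc_config <- function(steps = 200, max_rot = 2, max_trans = 0.5,
                      kT = 0.5, cycles = 4, shrink = 0.4, seed = 1) {
  list(steps = steps, max_rot = max_rot, max_trans = max_trans,
       kT = kT, cycles = cycles, shrink = shrink, seed = seed)
}

# interface energy of a protomer bead model against its own screw image
ring_interface_energy <- function(cg, tr, config = energy_config()) {
  interaction_energy(cg, cg, tr, config)
}

#' Cyclize a protomer interface into an exact N-fold ring
#'
#' Projects the interface screw onto the cyclic manifold (rotation exactly
#' 360/N degrees, zero rise, same axis) so closure is exact by
#' construction, then Metropolis Monte-Carlo refines the protomer's rigid
#' placement (small rotations about its centroid plus small translations)
#' against the coarse-grained interface energy. The best state visited is
#' returned, so the final energy never exceeds the projected starting
#' energy.
#'
#' @param protomer A single-chain [conformer].
#' @param tr The candidate interface [rigid_transform] (its screw should
#'   pass [filter_candidates] for some N in range).
#' @param N Ring order (3 to 24).
#' @param mc Monte-Carlo parameters (see [mc_config]).
#' @param config Energy parameters (see [energy_config]).
#' @return Object of class `ring_assembly`: list with the N-chain
#'   `conformer`, `N`, `screw` (the enforced cyclic interface),
#'   `transform`, `closure_error` (angstrom), `energy` (kcal/mol per
#'   interface), `start_energy` and the accepted-energy `trace`.
#' @export
cyclize <- function(protomer, tr, N, mc = mc_config(),
                    config = energy_config()) {
  if (N < 3 || N > 24) stop("ring order N must be in [3, 24]")
  s <- screw_from_transform(tr)
  if (s$degenerate) stop("degenerate interface transform: no screw axis")
  s_c <- screw_params(s$axis_point, s$axis_dir, 360 / N, 0)
  tr_c <- screw_to_transform(s_c)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(mc$seed)
  cur <- protomer
  cg <- coarse_grain(cur)
  e_cur <- ring_interface_energy(cg, tr_c, config)
  e_start <- e_cur
  best <- cur; e_best <- e_cur
  trace <- numeric(mc$steps)
  improved <- FALSE
  cycle_of <- ceiling(seq_len(max(1, mc$steps)) / max(1, mc$steps / mc$cycles))
  for (step in seq_len(mc$steps)) {
    scale <- mc$shrink^(cycle_of[step] - 1)
    cand <- cur
    ctr <- colMeans(cand$xyz)
    ax <- stats::rnorm(3)
    ang <- stats::runif(1, -mc$max_rot, mc$max_rot) * scale
    shift <- stats::runif(3, -mc$max_trans, mc$max_trans) * scale
    cand$xyz <- sweep(sweep(cand$xyz, 2, ctr) %*% t(rotation_matrix(ax, ang)),
                      2, -(ctr + shift))
    cg_cand <- coarse_grain(cand)
    e_cand <- ring_interface_energy(cg_cand, tr_c, config)
    if (e_cand <= e_cur ||
        stats::runif(1) < exp(-(e_cand - e_cur) / (mc$kT * scale))) {
      cur <- cand; e_cur <- e_cand
      if (e_cur < e_best) { best <- cur; e_best <- e_cur; improved <- TRUE }
    }
    trace[step] <- e_cur
  }
  if (!improved)
    message("cyclize: no energy improvement over ", mc$steps,
            " steps; returning the projected start")
  asm <- extend_helix(best, tr_c, N)
  # closure: displacement of test points under N applications of the screw
  full <- transform_power(tr_c, N)
  ca <- best$xyz[best$atom$elety == "CA", , drop = FALSE]
  closure <- max(sqrt(rowSums((apply_transform(full, ca) - ca)^2)))
  structure(list(conformer = asm$conformer, N = N, screw = s_c,
                 transform = tr_c, closure_error = closure,
                 energy = e_best, start_energy = e_start, trace = trace,
                 protomer = best),
            class = c("ring_assembly", "assembly"))
}

#' @export
print.ring_assembly <- function(x, ...) {
  m <- ring_metrics(x)
  cat(sprintf(paste0("Ring assembly: N = %d, closure error %.2e A,\n",
                     "  interface energy %.3f kcal/mol; outer diameter ",
                     "%.2f nm, height %.2f nm, pore %.2f nm\n"),
              x$N, x$closure_error, x$energy,
              m$outer_diameter, m$height, m$pore_diameter))
  invisible(x)
}

#' Geometric metrics of a ring assembly
#'
#' Operational definitions: outer diameter = twice the maximum heavy-atom
#' radial distance from the symmetry axis; height = heavy-atom extent
#' along the axis; pore diameter = twice the minimum heavy-atom radial
#' distance. All in nm.
#'
#' @param ring A `ring_assembly` (or an `assembly` with a non-degenerate
#'   screw).
#' @return List with `outer_diameter`, `height`, `pore_diameter` (nm).
#' @export
ring_metrics <- function(ring) {
  s <- if (inherits(ring, "ring_assembly")) ring$screw
       else screw_from_transform(ring$transform)
  if (s$degenerate) stop("no symmetry axis defined")
  cf <- ring$conformer
  heavy <- cf$atom$elesy != "H"
  v <- sweep(cf$xyz[heavy, , drop = FALSE], 2, s$axis_point)
  ax <- as.numeric(v %*% s$axis_dir)
  rad <- sqrt(pmax(0, rowSums(v^2) - ax^2))
  list(outer_diameter = 2 * max(rad) / 10,
       height = (max(ax) - min(ax)) / 10,
       pore_diameter = 2 * min(rad) / 10)
}

#' Inter-protomer residue contact map
#'
#' Entry (i, j) is TRUE iff the minimum heavy-atom distance between
#' residue i of protomer A and residue j of protomer B is below the
#' cutoff.
#'
#' @param protomerA,protomerB [conformer] objects.
#' @param cutoff Contact cutoff in nm (default 0.45, the common
#'   heavy-atom contact convention).
#' @return Logical matrix with residue numbers as dimnames.
#' @export
contact_map <- function(protomerA, protomerB, cutoff = 0.45) {
  stopifnot(cutoff > 0)
  resA <- sort(unique(protomerA$atom$resno))
  resB <- sort(unique(protomerB$atom$resno))
  hA <- protomerA$atom$elesy != "H"
  hB <- protomerB$atom$elesy != "H"
  XA <- protomerA$xyz[hA, , drop = FALSE]; aA <- protomerA$atom$resno[hA]
  XB <- protomerB$xyz[hB, , drop = FALSE]; aB <- protomerB$atom$resno[hB]
  d <- sqrt(pmax(outer(rowSums(XA^2), rowSums(XB^2), "+") -
                   2 * tcrossprod(XA, XB), 0)) / 10
  out <- matrix(FALSE, length(resA), length(resB),
                dimnames = list(resA, resB))
  for (i in seq_along(resA)) {
    di <- d[aA == resA[i], , drop = FALSE]
    for (j in seq_along(resB))
      out[i, j] <- min(di[, aB == resB[j]]) < cutoff
  }
  out
}

#' Extract one protomer of an assembly as a conformer
#' @param ring An `assembly` or `ring_assembly`.
#' @param k Protomer index (chain order).
#' @return A [conformer].
#' @export
get_protomer <- function(ring, k) {
  cf <- ring$conformer
  ch <- unique(cf$atom$chain)[k]
  sel <- cf$atom$chain == ch
  conformer(cf$xyz[sel, , drop = FALSE], cf$atom[sel, ])
}

#' Dock one ring onto another and label the contacting faces
#'
#' Reuses the systematic coarse-grained docking with ring 1 fixed. Each
#' ring's "N-face" is the side of the ring plane where the N-terminal
#' residue range sits (mean axial position of residues `nterm_range`);
#' every ranked pose is labelled by which face of ring 1 meets which face
#' of ring 2 (e.g. "N-N" for stacking through both N-terminal faces).
#'
#' @param ring1,ring2 `ring_assembly` objects.
#' @param nterm_range Residue range defining the N-terminal face.
#' @param angular_spacing,n_orientations,margin Start-pose lattice.
#' @param rmsd_cutoff Pose clustering cutoff, nm.
#' @param config Energy parameters.
#' @param maxit Minimization budget per pose.
#' @return The ranked representative table (see [cluster_and_rank]) with
#'   an extra `faces` column.
#' @export
stack_rings <- function(ring1, ring2, nterm_range = 1:9,
                        angular_spacing = 60, n_orientations = 2,
                        margin = 1.2, rmsd_cutoff = 0.5,
                        config = energy_config(), maxit = 300) {
  cg1 <- coarse_grain(ring1$conformer)
  cg2 <- coarse_grain(ring2$conformer)
  starts <- generate_start_poses(cg1, cg2, angular_spacing, n_orientations,
                                 margin)
  poses <- lapply(starts, function(p) minimize_pose(cg1, cg2, p, config, maxit))
  ranked <- cluster_and_rank(poses, cg2, rmsd_cutoff)
  if (nrow(ranked) == 0) return(ranked)
  ranked$faces <- vapply(ranked$pose_id, function(i)
    pose_faces(ring1, ring2, poses[[i]]$transform, nterm_range), character(1))
  attr(ranked, "poses") <- poses
  ranked
}

# which axial side of a ring holds the N-terminal residue range
nterm_face_sign <- function(ring, nterm_range) {
  cf <- ring$conformer
  s <- ring$screw
  ca <- cf$atom$elety == "CA"
  ax <- as.numeric(sweep(cf$xyz, 2, s$axis_point) %*% s$axis_dir)
  nt <- ca & cf$atom$resno %in% nterm_range
  sign(mean(ax[nt]) - mean(ax[ca]))
}

pose_faces <- function(ring1, ring2, pose, nterm_range) {
  s1 <- ring1$screw; s2 <- ring2$screw
  f1 <- nterm_face_sign(ring1, nterm_range)
  f2 <- nterm_face_sign(ring2, nterm_range)
  c1 <- colMeans(ring1$conformer$xyz)
  c2 <- colMeans(apply_transform(pose, ring2$conformer$xyz))
  dir <- vunit(c2 - c1)
  u2 <- as.numeric(pose$R %*% s2$axis_dir)
  face1 <- if (sum(s1$axis_dir * dir) * f1 > 0) "N" else "C"
  face2 <- if (sum(u2 * (-dir)) * f2 > 0) "N" else "C"
  paste(face1, face2, sep = "-")
}
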