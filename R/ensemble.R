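# Ensemble observables and conformational analysis: backbone dihedrals,
# Karplus J-couplings, secondary chemical shifts, secondary-structure
# propensities, RMSD/Rg free-energy surfaces and gromos clustering.

# Boltzmann/gas constant in kcal/mol/K
KB_KCAL <- 0.0019872

#' Backbone phi/psi dihedrals of every frame
#'
#' phi(i) is C(i-1)-N(i)-CA(i)-C(i); psi(i) is N(i)-CA(i)-C(i)-N(i+1). The
#' first residue has no phi and the last no psi (NA). Residues with missing
#' backbone atoms are marked NA with a warning.
#'
#' @param ens An [ensemble] (or single [conformer]).
#' @return Object of class `dihedral_series`: list with `phi` and `psi`
#'   (frames x residues matrices, degrees in (-180, 180]) and `resno`.
#' @export
backbone_dihedrals <- function(ens) {
  if (inherits(ens, "conformer")) ens <- ensemble(list(ens))
  atom <- ens$atom
  ch <- atom$chain[1]
  sel <- atom$chain == ch
  resno <- sort(unique(atom$resno[sel]))
  nres <- length(resno)
  idx_of <- function(r, name) {
    i <- which(sel & atom$resno == r & atom$elety == name)
    if (length(i) == 1) i else NA_integer_
  }
  iN <- vapply(resno, idx_of, integer(1), name = "N")
  iCA <- vapply(resno, idx_of, integer(1), name = "CA")
  iC <- vapply(resno, idx_of, integer(1), name = "C")
  incomplete <- is.na(iN) | is.na(iCA) | is.na(iC)
  if (any(incomplete))
    warning("residue(s) ", paste(resno[incomplete], collapse = ","),
            " missing backbone atoms; dihedrals set to NA")
  nf <- n_frames(ens)
  phi <- matrix(NA_real_, nf, nres)
  psi <- matrix(NA_real_, nf, nres)
  for (f in seq_len(nf)) {
    X <- frame_xyz(ens, f)
    for (r in seq_len(nres)) {
      if (incomplete[r]) next
      if (r > 1 && !incomplete[r - 1])
        phi[f, r] <- dihedral_angle(X[iC[r - 1], ], X[iN[r], ], X[iCA[r], ], X[iC[r], ])
      if (r < nres && !incomplete[r + 1])
        psi[f, r] <- dihedral_angle(X[iN[r], ], X[iCA[r], ], X[iC[r], ], X[iN[r + 1], ])
    }
  }
  structure(list(phi = phi, psi = psi, resno = resno), class = "dihedral_series")
}

#' Karplus parameters for 3J(HN-Ha)
#'
#' Loads the packaged empirical three-bond J-coupling parameterization
#' (coefficients in Hz, phase offset in degrees; the usual 60-degree offset
#' of the HN-Ha convention). The constants live in a data file so alternate
#' parameterizations are drop-in replacements.
#'
#' @param path Optional path to an alternative parameter file (TSV with
#'   columns A, B, C, offset).
#' @return List with elements `A`, `B`, `C` (Hz) and `offset` (degrees).
#' @export
karplus_parameters <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "karplus_vuister_bax.tsv", package = "oligoring")
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  p <- list(A = tab$A[1], B = tab$B[1], C = tab$C[1], offset = tab$offset[1])
  if (!is.finite(p$A) || p$A <= 0) stop("Karplus A coefficient must be positive")
  p
}

karplus_j <- function(phi, params) {
  x <- cos(deg2rad(phi - params$offset))
  params$A * x^2 + params$B * x + params$C
}

#' Analytic range of the Karplus curve
#'
#' Minimum and maximum of A cos^2 x + B cos x + C over all dihedrals,
#' obtained in closed form from the quadratic in cos x on [-1, 1].
#'
#' @param params Karplus parameters (see [karplus_parameters]).
#' @return Numeric `c(min, max)` in Hz.
#' @export
karplus_range <- function(params) {
  ends <- params$A * c(1, 1) + params$B * c(-1, 1) + params$C
  vals <- c(params$A - params$B + params$C, params$A + params$B + params$C)
  xstar <- -params$B / (2 * params$A)
  if (abs(xstar) <= 1)
    vals <- c(vals, params$A * xstar^2 + params$B * xstar + params$C)
  range(vals)
}

#' Ensemble-averaged J-coupling profile
#'
#' Back-calculates per-residue 3J(HN-Ha) scalar couplings from the phi
#' dihedrals via the Karplus relation and averages over frames.
#'
#' @param dihedrals A `dihedral_series` from [backbone_dihedrals].
#' @param params Karplus parameters (default: packaged set).
#' @return [observable_table] of mean J in Hz; residues with no phi (the
#'   N-terminus) are omitted.
#' @export
jcoupling_profile <- function(dihedrals, params = karplus_parameters()) {
  if (nrow(dihedrals$phi) < 1) stop("empty ensemble: no frames to average")
  J <- karplus_j(dihedrals$phi, params)
  mean_j <- colMeans(J)
  keep <- !is.na(mean_j)
  observable_table(dihedrals$resno[keep], mean_j[keep], kind = "jcoupling",
                   provenance = "karplus back-calculation")
}

#' Secondary chemical shifts
#'
#' Computes the secondary shift as the deviation of the observed shift from
#' its random-coil reference, delta_coil - delta by default; `flip = TRUE`
#' gives the other common convention delta - delta_coil.
#'
#' @param observed [observable_table] of shifts (ppm).
#' @param coil_reference [observable_table] of random-coil shifts keyed by
#'   the same residue indices (see [random_coil_reference]).
#' @param flip Use the delta - delta_coil sign convention instead.
#' @return [observable_table] of secondary shifts; residues absent from the
#'   reference are missing (NA).
#' @export
secondary_shift <- function(observed, coil_reference, flip = FALSE) {
  na <- attr(observed, "nucleus"); nb <- attr(coil_reference, "nucleus")
  if (!is.null(na) && !is.null(nb) && !identical(na, nb))
    stop("nucleus mismatch: ", na, " vs ", nb)
  ref <- coil_reference$value[match(observed$residue, coil_reference$residue)]
  d <- ref - observed$value
  if (flip) d <- -d
  observable_table(observed$residue, d, kind = "shift", nucleus = na,
                   provenance = "secondary shift")
}

#' Packaged random-coil chemical-shift reference for a sequence
#'
#' Maps the packaged per-amino-acid random-coil Ca/Cb shift table onto a
#' peptide sequence, returning a residue-indexed reference table.
#'
#' @param sequence One-letter amino-acid string.
#' @param nucleus `"CA"` or `"CB"`.
#' @return [observable_table] of coil shifts (ppm); Gly has no Cb (NA).
#' @export
random_coil_reference <- function(sequence, nucleus = c("CA", "CB")) {
  nucleus <- match.arg(nucleus)
  path <- system.file("extdata", "random_coil_shifts.tsv", package = "oligoring")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, tab$aa)
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ","))
  vals <- tab[[tolower(nucleus)]][match(aa, tab$aa)]
  observable_table(seq_along(aa), vals, kind = "shift", nucleus = nucleus,
                   provenance = "random-coil reference")
}

#' Pearson correlation between two observable profiles
#'
#' Computed on the residues shared by both tables with non-missing values;
#' the comparison machinery for back-calculated vs experimental profiles.
#'
#' @param x,y [observable_table] objects.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  shared <- intersect(x$residue, y$residue)
  xv <- x$value[match(shared, x$residue)]
  yv <- y$value[match(shared, y$residue)]
  ok <- !is.na(xv) & !is.na(yv)
  if (sum(ok) < 3) stop("need at least 3 shared residues with values")
  if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0)
    stop("zero variance: Pearson correlation undefined")
  stats::cor(xv[ok], yv[ok])
}

# Secondary structure ----------------------------------------------------

# phi/psi region rule standing in for an external assigner. Boundaries
# (degrees) are deliberately coarse Ramachandran regions; checked in order
# H, E, T, else C.
SS_REGIONS <- list(
  H = c(phi_min = -100, phi_max = -30, psi_min = -80, psi_max = -5),
  E = c(phi_min = -180, phi_max = -90, psi_min = 90, psi_max = 180),
  T1 = c(phi_min = -140, phi_max = 0, psi_min = -120, psi_max = 80),
  T2 = c(phi_min = 30, phi_max = 90, psi_min = -20, psi_max = 90))

in_region <- function(phi, psi, r) {
  !is.na(phi) & !is.na(psi) &
    phi >= r["phi_min"] & phi <= r["phi_max"] &
    psi >= r["psi_min"] & psi <= r["psi_max"]
}

#' Assign secondary-structure classes from backbone dihedrals
#'
#' Deterministic phi/psi-region rule: helical (H), extended (E), turn (T),
#' otherwise coil (C). A stand-in for an external assigner whose H/G/I,
#' E/B and T classes are grouped the same way (see [map_ss_classes] for
#' parsing external output).
#'
#' @param dihedrals `dihedral_series` from [backbone_dihedrals].
#' @param frame Frame index, or `NULL` for all frames.
#' @return Character matrix (frames x residues) of classes in {H,E,T,C};
#'   terminal residues lacking phi or psi are "C".
#' @export
assign_secondary_structure <- function(dihedrals, frame = NULL) {
  phi <- dihedrals$phi; psi <- dihedrals$psi
  if (!is.null(frame)) { phi <- phi[frame, , drop = FALSE]; psi <- psi[frame, , drop = FALSE] }
  cls <- matrix("C", nrow(phi), ncol(phi))
  cls[in_region(phi, psi, SS_REGIONS$T1) | in_region(phi, psi, SS_REGIONS$T2)] <- "T"
  cls[in_region(phi, psi, SS_REGIONS$E)] <- "E"
  cls[in_region(phi, psi, SS_REGIONS$H)] <- "H"
  cls
}

#' Map external secondary-structure letters to the three grouped classes
#'
#' Groups an external assigner's alphabet: H, G, I -> helical (H); E, B, b
#' -> extended (E); T -> turn (T); everything else coil (C).
#'
#' @param letters Character vector (or matrix) of single-letter classes.
#' @return Same shape, letters in {H,E,T,C}.
#' @export
map_ss_classes <- function(letters) {
  out <- letters
  out[] <- ifelse(letters %in% c("H", "G", "I"), "H",
                  ifelse(letters %in% c("E", "B", "b"), "E",
                         ifelse(letters == "T", "T", "C")))
  out
}

#' Read an external per-frame secondary-structure assignment file
#'
#' TSV with columns `frame`, `residue`, `class`; raw letters are grouped
#' via [map_ss_classes].
#'
#' @param path Input file.
#' @return Character matrix (frames x residues) of grouped classes.
#' @export
read_ss_assignments <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "residue", "class") %in% names(tab)))
  frames <- sort(unique(tab$frame)); res <- sort(unique(tab$residue))
  m <- matrix("C", length(frames), length(res))
  m[cbind(match(tab$frame, frames), match(tab$residue, res))] <-
    map_ss_classes(tab$class)
  m
}

#' Per-residue secondary-structure propensities
#'
#' Ensemble-averaged percentage of helical, extended and turn conformations
#' at each residue.
#'
#' @param ens An [ensemble], or a precomputed class matrix from
#'   [assign_secondary_structure]/[read_ss_assignments].
#' @return Data frame with columns `residue`, `H`, `E`, `T` (percent); the
#'   three profiles sum to at most 100 per residue.
#' @export
ss_propensity <- function(ens) {
  cls <- if (is.matrix(ens)) ens else
    assign_secondary_structure(backbone_dihedrals(ens))
  pct <- function(k) 100 * colMeans(cls == k)
  data.frame(residue = seq_len(ncol(cls)),
             H = pct("H"), E = pct("E"), T = pct("T"))
}

# RMSD / Rg / free energy -------------------------------------------------

#' Minimum RMSD after optimal superposition
#'
#' Kabsch-superposed root-mean-square deviation between two conformers on a
#' named atom selection. Symmetric and invariant to rigid motion of either
#' argument.
#'
#' @param a,b [conformer] objects with equal selected atom counts.
#' @param selection `"calpha"`, `"backbone"`, `"heavy"` or `"all"`.
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(a, b, selection = "backbone") {
  sa <- atom_selection(a$atom, selection)
  sb <- atom_selection(b$atom, selection)
  if (sum(sa) != sum(sb)) stop("selections differ in atom count")
  kabsch(a$xyz[sa, , drop = FALSE], b$xyz[sb, , drop = FALSE])$rmsd / 10
}

#' Radius of gyration
#'
#' Root-mean-square distance of atoms to the center of mass (mass-weighted)
#' or to the geometric center.
#'
#' @param c A [conformer].
#' @param mass_weighted Weight by atomic mass (H=1, C=12, N=14, O=16, S=32).
#' @param selection Atom selection (default all atoms).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(c, mass_weighted = FALSE, selection = "all") {
  sel <- atom_selection(c$atom, selection)
  X <- c$xyz[sel, , drop = FALSE]
  if (nrow(X) < 1) stop("no atoms selected")
  w <- if (mass_weighted) {
    m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
    mm <- m[c$atom$elesy[sel]]
    mm[is.na(mm)] <- 12
    mm
  } else rep(1, nrow(X))
  ctr <- colSums(X * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(X, 2, ctr)^2)) / sum(w)) / 10
}

#' RMSD/Rg free-energy surface
#'
#' Bins every frame by (RMSD to a reference conformer, radius of gyration)
#' and converts counts to free energies, F = -kT ln N, shifted so the
#' global minimum is zero; empty bins are masked (NA).
#'
#' @param ens An [ensemble].
#' @param reference Reference [conformer] for the RMSD axis.
#' @param rmsd_breaks,rg_breaks Bin edges in nm (or integer bin counts).
#' @param T Temperature in K.
#' @param selection Atom selection for RMSD (Rg uses all atoms).
#' @return Object of class `free_energy_surface`: list with `rmsd_breaks`,
#'   `rg_breaks`, `counts`, `F` (kcal/mol), `T`, `k`, `rmsd`, `rg`.
#' @export
free_energy_surface <- function(ens, reference, rmsd_breaks = 30,
                                rg_breaks = 30, T = 300,
                                selection = "backbone") {
  if (n_frames(ens) < 1) stop("empty ensemble")
  rmsd <- vapply(seq_len(n_frames(ens)), function(i)
    kabsch_rmsd(get_conformer(ens, i), reference, selection), numeric(1))
  rg <- vapply(seq_len(n_frames(ens)), function(i)
    radius_of_gyration(get_conformer(ens, i)), numeric(1))
  mk_breaks <- function(x, b) {
    if (length(b) == 1) seq(min(x) - 1e-9, max(x) + 1e-9, length.out = b + 1) else b
  }
  rb <- mk_breaks(rmsd, rmsd_breaks)
  gb <- mk_breaks(rg, rg_breaks)
  ix <- cut(rmsd, rb, include.lowest = TRUE, labels = FALSE)
  iy <- cut(rg, gb, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0L, length(rb) - 1, length(gb) - 1)
  keep <- !is.na(ix) & !is.na(iy)
  for (k in which(keep)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  fes_from_counts(counts, rb, gb, T, rmsd = rmsd, rg = rg)
}

# free energies from a count matrix (shared with tests of the closed form)
fes_from_counts <- function(counts, rmsd_breaks = NULL, rg_breaks = NULL,
                            T = 300, rmsd = NULL, rg = NULL) {
  F <- matrix(NA_real_, nrow(counts), ncol(counts))
  occ <- counts > 0
  F[occ] <- -KB_CAL_T(T) * log(counts[occ])
  F <- F - min(F, na.rm = TRUE)
  structure(list(rmsd_breaks = rmsd_breaks, rg_breaks = rg_breaks,
                 counts = counts, F = F, T = T, k = KB_KCAL,
                 rmsd = rmsd, rg = rg),
            class = "free_energy_surface")
}

KB_CAL_T <- function(T) KB_KCAL * T

#' @export
print.free_energy_surface <- function(x, ...) {
  cat("Free-energy surface:", sum(x$counts), "frames in",
      sum(x$counts > 0), "occupied bins; T =", x$T, "K; max F =",
      format(max(x$F, na.rm = TRUE), digits = 4), "kcal/mol\n")
  invisible(x)
}

# Pairwise RMSD matrix (nm) on a selection; Kabsch via the singular values
# of the 3x3 cross-covariance, frames pre-centered once.
rmsd_matrix <- function(ens, selection = "backbone") {
  sel <- atom_selection(ens$atom, selection)
  nf <- n_frames(ens)
  m <- sum(sel)
  frames <- vector("list", nf)
  G <- numeric(nf)
  for (i in seq_len(nf)) {
    X <- frame_xyz(ens, i)[sel, , drop = FALSE]
    X <- sweep(X, 2, colMeans(X))
    frames[[i]] <- X
    G[i] <- sum(X^2)
  }
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    Ai <- frames[[i]]
    for (j in (i + 1):nf) {
      H <- crossprod(Ai, frames[[j]])
      sv <- svd(H, nu = 0, nv = 0)$d
      if (det(H) < 0) sv[3] <- -sv[3]
      msd <- max(0, (G[i] + G[j] - 2 * sum(sv)) / m)
      D[i, j] <- D[j, i] <- sqrt(msd)
    }
  }
  D / 10
}

#' Gromos conformational clustering
#'
#' The greedy neighbor-count algorithm: the frame with the most neighbors
#' within the RMSD cutoff becomes a cluster center, it and its neighbors
#' are removed, and the procedure repeats until no frame remains. Ties on
#' neighbor count resolve to the lowest frame index.
#'
#' @param ens An [ensemble].
#' @param cutoff RMSD cutoff in nm (the canonical choice is 0.2 nm).
#' @param selection Atom selection for the pairwise RMSD.
#' @return Object of class `cluster_set`: list of `clusters` (integer
#'   frame-index vectors, sorted by decreasing size, ties by lower center
#'   index), `centers` (representative frame per cluster) and `cutoff`.
#' @export
gromos_cluster <- function(ens, cutoff = 0.2, selection = "backbone") {
  if (cutoff <= 0) stop("cutoff must be positive")
  D <- rmsd_matrix(ens, selection)
  gromos_from_matrix(D, cutoff)
}

# clustering given a precomputed distance matrix (also used on pose RMSDs)
gromos_from_matrix <- function(D, cutoff) {
  nf <- nrow(D)
  adj <- D <= cutoff
  alive <- rep(TRUE, nf)
  clusters <- list(); centers <- integer(0)
  while (any(alive)) {
    counts <- rowSums(adj[, alive, drop = FALSE]) * alive
    center <- which.max(counts)           # which.max takes the lowest index on ties
    members <- which(alive & adj[center, ])
    clusters[[length(clusters) + 1]] <- members
    centers <- c(centers, center)
    alive[members] <- FALSE
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes, centers)
  structure(list(clusters = clusters[ord], centers = centers[ord],
                 cutoff = cutoff), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Cluster set:", length(x$clusters), "clusters at cutoff", x$cutoff,
      "nm; sizes:", paste(utils::head(lengths(x$clusters), 10), collapse = " "),
      if (length(x$clusters) > 10) "..." else "", "\n")
  invisible(x)
}

#' Minimal side-chain distance between two residues
#'
#' Minimum over heavy-atom pairs of the two side chains (backbone N, CA, C,
#' O excluded); glycine contributes its CA.
#'
#' @param c A [conformer].
#' @param resA,resB Residue indices (1-based).
#' @param chainA,chainB Chain ids (default first chain).
#' @return Distance in nm.
#' @export
min_sidechain_distance <- function(c, resA, resB, chainA = NULL, chainB = NULL) {
  pick <- function(res, chain) {
    if (is.null(chain)) chain <- c$atom$chain[1]
    inres <- c$atom$resno == res & c$atom$chain == chain
    if (!any(inres)) stop("residue ", res, " not found in chain ", chain)
    sc <- inres & !(c$atom$elety %in% BACKBONE_NAMES) & c$atom$elesy != "H"
    if (!any(sc)) sc <- inres & c$atom$elety == "CA"   # Gly fallback
    c$xyz[sc, , drop = FALSE]
  }
  A <- pick(resA, chainA); B <- pick(resB, chainB)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2))) / 10
}
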