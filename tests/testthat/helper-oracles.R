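# Independent oracles and toy builders shared across the suite. Each
# oracle is written from first principles, independent of the package
# implementation it checks.

# Dihedral by projection: angle between the components of (p1-p2) and
# (p4-p3) perpendicular to the central bond, signed by the triple product.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- (p3 - p2); b <- b / sqrt(sum(b^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * b) * b
  v2 <- (p4 - p3) - sum((p4 - p3) * b) * b
  ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  s <- sum(b * c(v1[2] * v2[3] - v1[3] * v2[2],
                 v1[3] * v2[1] - v1[1] * v2[3],
                 v1[1] * v2[2] - v1[2] * v2[1]))
  deg <- ang * 180 / pi * sign(ifelse(s == 0, 1, s))
  if (deg <= -180) deg + 360 else deg
}

# Minimum RMSD by brute-force search over a fine rotation grid (Euler
# angles), both clouds centered. Slow; use tiny point sets only.
oracle_grid_rmsd <- function(A, B, step = 3) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  rot <- function(ax, th) {
    th <- th * pi / 180; c1 <- cos(th); s1 <- sin(th)
    switch(ax,
           x = matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3),
           y = matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3),
           z = matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3))
  }
  fn <- function(ang) {
    R <- rot("z", ang[1]) %*% rot("y", ang[2]) %*% rot("z", ang[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- Inf; barg <- c(0, 0, 0)
  for (a in seq(0, 360 - step, step))
    for (b in seq(0, 180, step))
      for (g in seq(0, 360 - step, step)) {
        v <- fn(c(a, b, g))
        if (v < best) { best <- v; barg <- c(a, b, g) }
      }
  # polish the best grid cell locally (still independent of Kabsch)
  stats::optim(barg, fn, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))$value
}

# Reference gromos clustering: recompute neighbor counts from scratch
# every round with explicit loops.
oracle_gromos <- function(D, cutoff) {
  n <- nrow(D)
  alive <- seq_len(n)
  clusters <- list(); centers <- integer(0)
  while (length(alive) > 0) {
    counts <- sapply(alive, function(i) sum(D[i, alive] <= cutoff))
    center <- alive[which.max(counts)]
    members <- alive[D[center, alive] <= cutoff]
    clusters[[length(clusters) + 1]] <- members
    centers <- c(centers, center)
    alive <- setdiff(alive, members)
  }
  ord <- order(-lengths(clusters), centers)
  list(clusters = clusters[ord], centers = centers[ord])
}

# Reference single-linkage clustering at a distance threshold: repeatedly
# merge the two closest groups while their minimum inter-group distance
# is <= h.
oracle_single_linkage <- function(D, h) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  repeat {
    best <- c(NA, NA); bd <- Inf
    if (length(groups) < 2) break
    for (i in seq_along(groups)[-length(groups)])
      for (j in (i + 1):length(groups)) {
        d <- min(D[groups[[i]], groups[[j]]])
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    if (bd > h) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  membership <- integer(n)
  for (g in seq_along(groups)) membership[groups[[g]]] <- g
  membership
}

# canonical form of a partition for comparison: sorted list of sorted sets
canonical_partition <- function(clusters) {
  sets <- lapply(clusters, function(x) sort(unname(x)))
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

# single neutral test bead at a position
mk_bead <- function(x, y = 0, z = 0, radius = 2.3, eps = 0.2, charge = 0) {
  structure(data.frame(x = x, y = y, z = z, radius = radius, eps = eps,
                       charge = charge, type = "BB", resno = 1, chain = "A",
                       stringsAsFactors = FALSE),
            class = c("cg_model", "data.frame"))
}

mk_beads <- function(xyz, radius = 2.3, eps = 0.2, charge = 0) {
  structure(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       radius = radius, eps = eps, charge = charge,
                       type = "BB", resno = seq_len(nrow(xyz)), chain = "A",
                       stringsAsFactors = FALSE),
            class = c("cg_model", "data.frame"))
}

# random rigid conformer of n CA pseudo-atoms (non-degenerate cloud)
random_conformer <- function(n = 20, seed = 1, spread = 8) {
  set.seed(seed)
  xyz <- matrix(rnorm(3 * n, sd = spread), ncol = 3)
  conformer(xyz, data.frame(elety = "CA", resno = seq_len(n), resid = "ALA",
                            chain = "A", stringsAsFactors = FALSE))
}

random_rotation <- function(seed) {
  set.seed(seed)
  rotation_matrix(rnorm(3), runif(1, 10, 350))
}
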