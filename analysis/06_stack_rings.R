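#!/usr/bin/env Rscript
# Ring-on-ring stacking: dock the pentamer ring against itself with the
# coarse-grained engine and label each ranked pose by the contacting
# faces (N = the side of the ring plane holding the N-terminal residue
# range 1-9, C = the other). Face-to-face stacks through the N-terminal
# surfaces are the geometry proposed for decamer/dodecamer growth.

suppressMessages(library(oligoring))
dir.create("results", showWarnings = FALSE)

protomer <- get_conformer(read_structures("results/selected_protomer.pdb"), 1)
poses <- utils::read.table("results/dock_poses.tsv", header = TRUE, sep = "\t")
ranked <- utils::read.table("results/dock_ranked.tsv", header = TRUE, sep = "\t")
screw_tab <- utils::read.table("results/interface_screws.tsv", header = TRUE,
                               sep = "\t")
ok <- screw_tab$pass & screw_tab$energy < 0
pick <- if (any(ok)) which(ok)[which.min(screw_tab$energy[ok])] else {
  bound <- which(screw_tab$energy < 0 & !is.na(screw_tab$n))
  gd <- pmax(0, 5 - screw_tab$n[bound]) + pmax(0, screw_tab$n[bound] - 6) +
    pmax(0, screw_tab$pitch[bound] - 2)
  bound[which.min(gd)]
}
p <- poses[poses$pose_id == ranked$pose_id[pick], ]
tr <- rigid_transform(matrix(as.numeric(p[, paste0("r", 1:9)]), 3, 3),
                      as.numeric(p[, c("tx", "ty", "tz")]))
ring <- cyclize(protomer, tr, 5, mc_config(steps = 400, max_trans = 2, seed = 1))

stacks <- stack_rings(ring, ring, nterm_range = 1:9,
                      angular_spacing = 70, n_orientations = 2, maxit = 3000)
utils::write.table(stacks, "results/ring_stacks.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("stacked poses:", nrow(stacks), "\n")
if (nrow(stacks)) {
  cat(sprintf("best stack: E = %.2f kcal/mol through faces %s\n",
              stacks$energy[1], stacks$faces[1]))
  cat("face labels:", paste(unique(stacks$faces), collapse = " "), "\n")
}
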