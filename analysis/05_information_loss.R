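#!/usr/bin/env Rscript
# Information loss under coarser relocation schedules: how many visited
# patches and realized links survive 1-in-k resampling, and how many
# detected links are spurious shortcuts.
#
# Reads results/study/loss.csv, summarizes by process, fragmentation and k,
# and demonstrates the spurious-link mechanism on a scripted fixture with a
# known ground-truth network.

library(patchnet)

loss <- read.csv("results/study/loss.csv")
agg <- aggregate(loss[c("prop_patches_detected", "prop_links_detected",
                        "prop_spurious")],
                 by = loss[c("process", "frag_level", "k")], FUN = mean)
agg <- agg[order(agg$process, agg$frag_level, agg$k), ]
write.csv(agg, "results/information_loss_summary.csv", row.names = FALSE)

f_high <- agg[agg$process == "F" & agg$frag_level == "high", ]
cat("foraging-only, high fragmentation:\n")
print(f_high[c("k", "prop_patches_detected", "prop_links_detected",
               "prop_spurious")], row.names = FALSE, digits = 2)
cat("\nLink detection decays much faster than patch detection, and a",
    "growing share\nof the links that are detected never happened.\n")

## the mechanism on a scripted itinerary -------------------------------------
pm <- make_patch_mosaic(6, spacing = 4, patch_size = 3, dims = c(12, 50))
st <- make_scripted_trajectory(pm, c(1, 2, 3, 4, 5, 6, 5, 4, 3, 2, 1),
                               dwell = c(7, 3, 5, 2, 6, 4, 5, 3, 7, 2, 6),
                               transit = 4)
cat("\nscripted itinerary over a 6-patch mosaic (reference:",
    nrow(st$reference$links), "links):\n")
for (k in c(2, 5, 8, 13)) {
  net <- trajectory_network(resample_trajectory(st$traj, k), pm)
  il <- information_loss(st$reference, net)
  ls <- link_sets(st$reference, net)
  spur <- if (nrow(ls$spurious))
    paste(apply(ls$spurious, 1, paste, collapse = "-"), collapse = ", ")
  else "none"
  cat(sprintf("  k=%2d: %.0f%% links detected, spurious: %s\n",
              k, 100 * il$prop_links_detected, spur))
}
cat("Spurious links are exactly the pairs bridging a skipped stepping-stone",
    "visit.\n")
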