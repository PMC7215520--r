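#!/usr/bin/env Rscript
# Global conformational metrics of the study proteins: per-frame RMSD and
# radius of gyration, their KDE distributions, per-residue RMSF, and the
# mean / percent-difference summary table.

source("analysis/00_config.R")
ensure_dirs()

trajs <- study_trajectories()

rmsd <- lapply(trajs, rmsd_series)
rg <- lapply(trajs, rg_series)
s <- rbind(summary_table(unname(rmsd), "WT"), summary_table(unname(rg), "WT"))
write.csv(s, file.path(OUT_DIR, "summary_means.csv"), row.names = FALSE)
cat("Mean RMSD / Rg and percent difference from WT:\n")
print(structure(s, class = c("summary_table", "data.frame")))

# KDE of the RMSD distributions: peak locations summarise which
# conformations each protein samples most
modes <- do.call(rbind, lapply(names(rmsd), function(lb) {
  dens <- kde_distribution(rmsd[[lb]])
  m <- trajnet:::density_modes(dens)
  m <- m[dens$density[match(m, dens$grid)] > 0.2 * max(dens$density)]
  data.frame(label = lb, mode_rmsd_A = m, bandwidth = dens$bandwidth)
}))
write.csv(modes, file.path(OUT_DIR, "kde_rmsd_modes.csv"), row.names = FALSE)
cat("\nRMSD KDE modes (most-sampled conformations):\n")
print(modes, row.names = FALSE)

# per-residue flexibility and its WT - variant differences
rmsf <- lapply(trajs, rmsf_profile)
prof <- data.frame(residue = rmsf$WT$labels,
                   WT = rmsf$WT$values)
for (lb in setdiff(names(rmsf), "WT")) {
  prof[[lb]] <- rmsf[[lb]]$values
  prof[[paste0("delta_", lb)]] <- delta_profile(rmsf$WT, rmsf[[lb]])$values
}
write.csv(prof, file.path(OUT_DIR, "rmsf_profiles.csv"), row.names = FALSE)

for (lb in setdiff(names(rmsf), "WT")) {
  d <- prof[[paste0("delta_", lb)]]
  cat(sprintf("\n%s: mean delta-RMSF %+.3f A; most rigidified %s (%+.2f), most flexibilised %s (%+.2f)\n",
              lb, mean(d), prof$residue[which.max(d)], max(d),
              prof$residue[which.min(d)], min(d)))
}
cat("\nwrote", file.path(OUT_DIR, "summary_means.csv"), "and",
    file.path(OUT_DIR, "rmsf_profiles.csv"), "\n")
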