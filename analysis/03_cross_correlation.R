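#!/usr/bin/env Rscript
# Dynamic cross-correlation of alpha-carbon motion: full matrices (kept
# under scratch/, they are 268 x 268) and the correlated / uncorrelated /
# anti-correlated pair fractions per protein.

source("analysis/00_config.R")
ensure_dirs()

trajs <- study_trajectories()

fractions <- NULL
for (lb in names(trajs)) {
  m <- dcc_matrix(trajs[[lb]])
  write.csv(round(m$values, 4),
            file.path(SCRATCH, paste0("dcc_", lb, ".csv")))
  cl <- classify_motion(m)
  fractions <- rbind(fractions,
                     data.frame(label = lb,
                                anti = cl$fractions[["anti"]],
                                none = cl$fractions[["none"]],
                                correlated = cl$fractions[["correlated"]]))
  cat(sprintf("%-14s anti %5.1f%%  none %5.1f%%  correlated %5.1f%%\n", lb,
              100 * cl$fractions[["anti"]], 100 * cl$fractions[["none"]],
              100 * cl$fractions[["correlated"]]))
}
write.csv(fractions, file.path(OUT_DIR, "dcc_fractions.csv"),
          row.names = FALSE)
cat("wrote", file.path(OUT_DIR, "dcc_fractions.csv"), "\n")
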