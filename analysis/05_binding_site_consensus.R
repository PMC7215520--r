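#!/usr/bin/env Rscript
# Merge the packaged binding-site residue groups into the consensus set
# and annotate it with the variant positions and the network outliers
# found in 04: which predicted binding-site residues does each variant
# perturb?

source("analysis/00_config.R")
ensure_dirs()

groups <- lapply(c("green", "blue", "red"), function(g) {
  parse_residue_set(system.file("extdata", paste0("binding_site_", g, ".txt"),
                                package = "trajnet"))
})
cons <- consensus(groups, rule = "majority", k = 1)
cons <- annotate_consensus(cons, list(
  variant_positions = c(100, 109, 162, 237)
))

# overlay the network outliers from 04 when available
outlier_file <- file.path(OUT_DIR, "drn_outliers.json")
if (file.exists(outlier_file)) {
  ol <- jsonlite::read_json(outlier_file, simplifyVector = TRUE)
  anns <- list()
  for (lb in names(ol)) {
    flagged <- unique(unlist(ol[[lb]]$deltaL[c("increase", "decrease")]))
    if (length(flagged)) {
      anns[[paste0("deltaL_outliers_", lb)]] <- residue_set(flagged, lb)
    }
  }
  if (length(anns)) cons <- annotate_consensus(cons, anns)
}

print(cons)
writeLines(cons$consensus$members,
           file.path(OUT_DIR, "consensus_residues.txt"))
summary <- list(
  n_consensus = length(cons$consensus),
  union_size = cons$union_size,
  per_source = as.list(cons$per_source_counts),
  annotations = cons$annotations
)
jsonlite::write_json(summary, file.path(OUT_DIR, "consensus.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", file.path(OUT_DIR, "consensus.json"), "\n")
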