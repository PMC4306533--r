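#!/usr/bin/env Rscript

# Stage 1: generate a synthetic replicate titration study with known
# ground truth. The cells mirror the headline protein x ligand contrast
# of the real panel (eIF4E1a vs eIF4E1b binding m7GTP, plus a weak GTP
# cell), at the study's conditions: 0.1 uM protein, 1% baseline noise,
# four independent titrations per cell. Curves are written as titration
# CSVs under results/simulated_curves/ plus a truth manifest, so stage 2
# can treat them exactly like raw exported instrument data.

library(capaffinity)

out_dir <- "results/simulated_curves"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cells <- data.frame(
  protein_id = c("eIF4E1a", "eIF4E1b", "eIF4E1a"),
  ligand     = c("m7GTP",   "m7GTP",   "GTP"),
  kas        = c(68.4,      22.0,      0.027))

design <- simulation_design(noise_sd_frac = 0.01, seed = 20140101)
study <- simulate_replicate_study(cells, replicates_per_cell = 4,
                                  design = design)

for (i in seq_along(study$curves)) {
  cv <- study$curves[[i]]
  write_titration_csv(cv, file.path(
    out_dir, sprintf("curve_%02d_%s_%s.csv", i, cv$protein_id, cv$ligand)))
}
write.table(study$manifest, "results/simulation_manifest.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("Simulated %d curves (%d cells x %d replicates) into %s\n",
            length(study$curves), nrow(cells), 4, out_dir))
cat("Ground-truth association constants (uM^-1):\n")
print(study$manifest[, c("protein_id", "ligand", "kas")])
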