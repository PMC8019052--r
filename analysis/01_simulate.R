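#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study (fish, genotypes, otoliths, lakes)
# under the default study conditions, scaled to a 4,000-locus panel so the
# whole workflow runs in minutes, and write it under results/study/.

suppressMessages(library(charpop))

seed <- 2026L
cfg <- sim_config(seed = seed, n_loci = 4000)
st <- simulate_study(cfg)

dir.create("results/study", showWarnings = FALSE, recursive = TRUE)
paths <- write_study(st, "results/study")
saveRDS <- NULL  # all downstream stages re-read the plain-text artifacts

cat("Simulated", nrow(st$fish), "fish across", nrow(cfg$lakes), "lakes;",
    ncol(st$genotypes$values), "loci with",
    length(st$truth$sex_loci_xy), "planted XY loci and",
    length(st$truth$sex_loci_female_only), "female-only locus.\n")
cat("Wrote:", paste(basename(unname(paths)), collapse = ", "),
    "under results/study/\n")
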