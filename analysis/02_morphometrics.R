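#!/usr/bin/env Rscript
# Stage 2: allometric size adjustment and model-based size-class detection.
# The scientific contrast: raw traits carry the length-mixture structure,
# size-adjusted traits should not (plasticity, not distinct morphs).

suppressMessages(library(charpop))

fish <- read.delim("results/study/fish.tsv")
traits <- default_allometry()$trait

raw <- gmm_cluster(fish[, traits], K_max = 5)
allo <- fit_allometric_slope(fish[, traits], fish$total_length_mm)
adj <- size_adjust_fish(fish, allo)
adjm <- gmm_cluster(adj[, traits], K_max = 5)

fish <- assign_size_classes(raw, fish)
dir.create("results", showWarnings = FALSE)
write.table(fish[, c("id", "lake", "group", "total_length_mm", "size_class",
                     "true_size_class")],
            "results/size_classes.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(data.frame(trait = allo$coef$trait, b = allo$coef$b,
                       L_m = allo$L_m),
            "results/allometry.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat("Raw-trait clustering selects K =", raw$K,
    sprintf("(dBIC = %.1f)", raw$delta_bic), "\n")
cat("Size-adjusted clustering selects K =", adjm$K,
    sprintf("(dBIC = %.1f)", adjm$delta_bic), "\n")
cat("Reference length L_m =", round(allo$L_m, 1), "mm; slopes b in",
    sprintf("[%.2f, %.2f]", min(allo$coef$b), max(allo$coef$b)), "\n")
acc <- assignment_accuracy(fish$size_class, fish$true_size_class)$accuracy
cat("Size-class vs planted-component agreement:", round(acc, 1), "%\n")
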