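# Shared builders for small synthetic fixtures.

# single-lake design with an arbitrary length mixture
lake_design <- function(n, mean = 350, sd = 40, weight = 1,
                        lake = "L1", group = "G1") {
  d <- data.frame(lake = lake, group = group, n_fish = as.integer(n),
                  stringsAsFactors = FALSE)
  d$mixture <- list(data.frame(mean = mean, sd = sd, weight = weight))
  d
}

# two single-lake groups (a deme pair diverged at the configured F)
two_deme_design <- function(n1, n2 = n1) {
  d <- data.frame(lake = c("L1", "L2"), group = c("G1", "G2"),
                  n_fish = as.integer(c(n1, n2)), stringsAsFactors = FALSE)
  d$mixture <- list(data.frame(mean = 350, sd = 40, weight = 1),
                    data.frame(mean = 160, sd = 15, weight = 1))
  d
}

# a bimodal single lake (dwarf + normal component)
bimodal_design <- function(n, lake = "L1", group = "G1") {
  d <- data.frame(lake = lake, group = group, n_fish = as.integer(n),
                  stringsAsFactors = FALSE)
  d$mixture <- list(data.frame(mean = c(160, 350), sd = c(15, 40),
                               weight = c(0.5, 0.5)))
  d
}

# a config without any planted sex loci
neutral_config <- function(seed, lakes, n_loci, fst_between = 0.2,
                           fst_within = 0, missing_rate = 0.1) {
  sim_config(seed = seed, lakes = lakes, n_loci = n_loci,
             fst_between_groups = fst_between,
             fst_within_group = fst_within,
             missing_rate = missing_rate,
             n_sex_loci_xy = 0L, n_sex_loci_female_only = 0L,
             n_sex_assoc_loci = 0L)
}

# hand-built genotype matrix from a values matrix (one chromosome by default)
toy_genotypes <- function(values, chrom = NULL, pos = NULL) {
  values <- as.matrix(values)
  L <- ncol(values)
  if (is.null(chrom)) chrom <- rep("chr01", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  loci <- data.frame(id = paste0("snp", seq_len(L)), chrom = chrom,
                     pos = as.integer(pos), ref = "A", alt = "G",
                     counted = "alt", stringsAsFactors = FALSE)
  indiv <- data.frame(id = sprintf("ind%02d", seq_len(nrow(values))),
                      stringsAsFactors = FALSE)
  genotype_matrix(values, loci, indiv)
}
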