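test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 42, lakes = two_deme_design(10), n_loci = 120,
                    n_sex_assoc_loci = 10L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$fish, b$fish)
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(a$otoliths, b$otoliths)
})

test_that("config validation rejects bad mixtures and rates", {
  bad <- lake_design(10)
  bad$mixture <- list(data.frame(mean = c(100, 300), sd = c(10, 10),
                                 weight = c(0.5, 0.6)))
  expect_error(sim_config(lakes = bad), "sum to 1")
  expect_error(sim_config(missing_rate = 1.5))
  expect_error(sim_config(n_loci = 3, n_sex_loci_xy = 4L))
})

test_that("realized within-deme frequency variance matches Balding-Nichols", {
  cfg <- neutral_config(5, two_deme_design(30), n_loci = 2000,
                        fst_between = 0.2, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  truth <- attr(g, "truth")
  p <- truth$p_anc
  # per-locus deme variance around the ancestral frequency
  v <- (truth$p_group[, 1] - p)^2
  ratio <- mean(v) / mean(0.2 * p * (1 - p))
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("F = 0 collapses deme frequencies without division errors", {
  cfg <- neutral_config(6, two_deme_design(10), n_loci = 200,
                        fst_between = 0, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  truth <- attr(g, "truth")
  expect_identical(truth$p_group[, 1], truth$p_anc)
  expect_identical(truth$p_lake[, 1], truth$p_group[, 1])
})

test_that("planted sex loci carry their patterns by construction", {
  cfg <- sim_config(seed = 9, lakes = two_deme_design(25), n_loci = 400,
                    n_sex_loci_xy = 4L, n_sex_loci_female_only = 1L,
                    n_sex_assoc_loci = 0L, missing_rate = 0)
  fish <- simulate_phenotypes(cfg)
  g <- simulate_genotypes(cfg, fish)
  truth <- attr(g, "truth")
  expect_length(truth$sex_loci_xy, 4)
  expect_length(truth$sex_loci_female_only, 1)
  male <- fish$sex == "male"
  for (l in truth$sex_loci_xy) {
    expect_true(all(g$values[male, l] == 1L))
    expect_true(all(g$values[!male, l] == 0L))
  }
  fo <- truth$sex_loci_female_only
  expect_true(all(is.na(g$values[male, fo])))
  expect_true(all(!is.na(g$values[!male, fo])))
  # all planted loci live on the three dedicated chromosomes
  expect_true(all(g$loci$chrom[c(truth$sex_loci_xy, fo, truth$sex_loci_assoc)]
                  %in% truth$sex_chromosomes))
})

test_that("phenotypes follow the planted mixture and allometry", {
  cfg <- neutral_config(11, bimodal_design(300), n_loci = 50)
  fish <- simulate_phenotypes(cfg)
  expect_true(all(fish$total_length_mm > 0))
  expect_setequal(unique(fish$true_size_class), 1:2)
  # dwarf component fish are shorter on average
  m <- tapply(fish$total_length_mm, fish$true_size_class, mean)
  expect_lt(m[["1"]], m[["2"]])
  # noiseless allometry collapses exactly under size adjustment
  al <- default_allometry()
  al$sigma <- 0
  cfg0 <- sim_config(seed = 12, lakes = bimodal_design(50), n_loci = 50,
                     allometry = al, n_sex_loci_xy = 0L,
                     n_sex_loci_female_only = 0L, n_sex_assoc_loci = 0L)
  f0 <- simulate_phenotypes(cfg0)
  for (i in seq_len(nrow(al))) {
    y <- size_adjust(f0[[al$trait[i]]], f0$total_length_mm, al$b[i], 400)
    expect_lt(stats::sd(log10(y)), 1e-10)
  }
})

test_that("otolith records respect age and monotonicity invariants", {
  cfg <- neutral_config(13, bimodal_design(60), n_loci = 50)
  fish <- simulate_phenotypes(cfg)
  oto <- simulate_otoliths(cfg, fish)
  for (d in split(oto, oto$fish_id)) {
    d <- d[order(d$age), ]
    expect_identical(d$age, seq_len(max(d$age)))
    expect_true(all(diff(d$radius) > 0))
    expect_lte(max(d$radius), d$capture_radius[1] + 1e-12)
  }
  # dwarf (slow) fish have lower mean back-calculated length at shared ages
  tr <- attr(oto, "truth")$lengths_at_age
  slow_ids <- fish$id[fish$true_size_class == 1]
  tr$slow <- tr$fish_id %in% slow_ids
  shared <- intersect(tr$age[tr$slow], tr$age[!tr$slow])
  shared <- setdiff(shared, 0)
  for (a in shared) {
    expect_lt(mean(tr$length_mm[tr$slow & tr$age == a]),
              mean(tr$length_mm[!tr$slow & tr$age == a]))
  }
})

test_that("written study round-trips through VCF and TSV", {
  cfg <- sim_config(seed = 21, lakes = two_deme_design(8), n_loci = 60,
                    n_sex_assoc_loci = 5L)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  g2 <- read_vcf(paths[["vcf"]])
  expect_equal(dim(g2$values), dim(st$genotypes$values))
  expect_identical(is.na(g2$values), is.na(st$genotypes$values))
  # genotype codes agree up to the minor-allele recoding read_vcf applies
  expect_equal(unname(maf(g2)), unname(maf(st$genotypes)))
  fish2 <- read.delim(paths[["fish"]])
  expect_equal(nrow(fish2), nrow(st$fish))
})
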