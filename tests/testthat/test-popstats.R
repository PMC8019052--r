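test_that("Reich-Patterson estimator matches hand-worked cases", {
  # fixed difference -> F_ST = 1
  r1 <- fst_reich_patterson(10, 10, 0, 10)
  expect_equal(r1$estimate, 1)
  # a1 = 4/10 vs a2 = 1/10
  r2 <- fst_reich_patterson(4, 10, 1, 10)
  expect_equal(r2$N, 0.09 - 4 * 6 / 90 / 10 - 1 * 9 / 90 / 10,
               tolerance = 1e-12)
  expect_equal(r2$D, r2$N + 4 * 6 / 90 + 9 / 90, tolerance = 1e-12)
  expect_lt(abs(r2$estimate - 0.12698), 1e-5)
  # monomorphic everywhere -> undefined with status
  r3 <- fst_reich_patterson(c(0, 10), c(10, 10), c(0, 5), c(10, 5))
  expect_equal(r3$status, "undefined")
  expect_true(is.na(r3$estimate))
})

test_that("ratio of sums equals a brute-force locus loop and is symmetric", {
  set.seed(61)
  for (rep in 1:5) {
    n1 <- 2L * sample(3:12, 20, replace = TRUE)
    n2 <- 2L * sample(3:12, 20, replace = TRUE)
    a1 <- rbinom(20, n1, runif(20, 0.05, 0.95))
    a2 <- rbinom(20, n2, runif(20, 0.05, 0.95))
    res <- fst_reich_patterson(a1, n1, a2, n2)
    # brute force, locus by locus
    sN <- 0; sD <- 0
    for (l in 1:20) {
      h1 <- a1[l] * (n1[l] - a1[l]) / (n1[l] * (n1[l] - 1))
      h2 <- a2[l] * (n2[l] - a2[l]) / (n2[l] * (n2[l] - 1))
      N <- (a1[l] / n1[l] - a2[l] / n2[l])^2 - h1 / n1[l] - h2 / n2[l]
      sN <- sN + N
      sD <- sD + N + h1 + h2
    }
    expect_equal(res$estimate, sN / sD, tolerance = 1e-12)
    # symmetry and allele-flip invariance
    expect_equal(fst_reich_patterson(a2, n2, a1, n1)$estimate, res$estimate)
    expect_equal(fst_reich_patterson(n1 - a1, n1, n2 - a2, n2)$estimate,
                 res$estimate, tolerance = 1e-12)
  }
})

test_that("loci with fewer than two called alleles are excluded and counted", {
  r <- fst_reich_patterson(c(4, 1), c(10, 1), c(1, 0), c(10, 4))
  expect_equal(r$n_excluded, 1)
  expect_equal(r$n_loci, 1)
})

test_that("bootstrap CI degenerates sensibly and covers a panmictic zero", {
  r <- fst_reich_patterson(rep(4, 30), rep(10, 30), rep(1, 30), rep(10, 30))
  ci <- fst_bootstrap_ci(r, n_boot = 50, seed = 1)
  # identical per-locus ratios -> zero-width CI at the estimate
  expect_equal(ci$ci_low, ci$ci_high)
  expect_equal(ci$ci_low, r$estimate)
  ci1 <- fst_bootstrap_ci(r, n_boot = 1, seed = 2)
  expect_equal(ci1$flag, "single-replicate CI")
  # two samples from one panmictic population: CI covers 0
  cfg <- neutral_config(62, lake_design(60), n_loci = 1500, fst_between = 0)
  st <- simulate_study(cfg)
  res <- fst_genotypes(st$genotypes, 1:30, 31:60)
  res <- fst_bootstrap_ci(res, n_boot = 100, seed = 3)
  expect_lte(res$ci_low, 0)
  expect_gte(res$ci_high, 0)
})

test_that("folded SFS matches a brute-force tally and theta agrees with it", {
  set.seed(63)
  cfg <- neutral_config(63, lake_design(20), n_loci = 400, fst_between = 0)
  st <- simulate_study(cfg)
  g <- st$genotypes
  sfs <- folded_sfs(g)
  # brute force per-site tally
  for (b in c(0, 1, 2, 5)) {
    cnt <- 0L
    for (l in seq_len(ncol(g$values))) {
      v <- g$values[, l]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      if (min(sum(v), 2 * length(v) - sum(v)) == b) cnt <- cnt + 1L
    }
    expect_identical(unname(sfs$sfs[as.character(b)]), cnt)
  }
  # theta recomputed from the per-site spectrum equals the direct value
  th <- watterson_theta(g)
  use <- sfs$site_n >= 2
  seg <- use & sfs$site_minor_count > 0
  harm <- vapply(sfs$site_n[seg], function(n) sum(1 / seq_len(n - 1)),
                 numeric(1))
  expect_equal(th$theta_w, sum(1 / harm) / sum(use), tolerance = 1e-12)
})

test_that("Watterson theta hand cases", {
  # 5 segregating sites among n = 10 alleles, L = 1000
  vals <- matrix(0L, 5, 1000)
  vals[1, 1:5] <- 1L  # one heterozygote at 5 sites
  th <- watterson_theta(toy_genotypes(vals))
  a9 <- sum(1 / 1:9)
  expect_equal(th$theta_w, 5 / (a9 * 1000), tolerance = 1e-9)
  expect_equal(th$theta_w, 0.0017675, tolerance = 1e-4)
  # no segregating sites -> 0
  expect_equal(watterson_theta(toy_genotypes(matrix(0L, 4, 50)))$theta_w, 0)
  # n = 2 called alleles everywhere (one genotyped diploid) -> theta = S/L
  v2 <- rbind(c(1L, 0L, 1L, 0L), rep(NA_integer_, 4))
  th2 <- watterson_theta(toy_genotypes(v2))
  expect_equal(th2$L, 4)
  expect_equal(th2$S, 2)
  expect_equal(th2$theta_w, 2 / 4)
})

test_that("heterozygosity and F_IS hand cases and HWE calibration", {
  # every individual heterozygous at p = 0.5 -> Ho = 1, He = 0.5, F_IS = -1
  vals <- matrix(1L, 6, 10)
  d <- het_fis(toy_genotypes(vals))
  expect_equal(d$Ho, 1)
  expect_equal(d$He, 0.5)
  expect_equal(d$fis, -1, tolerance = 1e-9)
  # all homozygous at intermediate frequency -> F_IS = 1
  vals2 <- matrix(rep(c(0L, 2L), 5), 10, 8)
  d2 <- het_fis(toy_genotypes(vals2))
  expect_equal(d2$Ho, 0)
  expect_equal(d2$fis, 1)
  # monomorphic matrix -> He = 0, F_IS undefined with status
  d3 <- het_fis(toy_genotypes(matrix(0L, 5, 6)))
  expect_match(d3$status, "undefined")
  expect_true(is.na(d3$fis))
  # HWE simulation: F_IS near 0
  set.seed(64)
  p <- runif(2000, 0.05, 0.95)
  vals4 <- sapply(p, function(pp) rbinom(200, 2, pp))
  d4 <- het_fis(toy_genotypes(vals4))
  expect_lt(abs(d4$fis), 0.02)
})

test_that("GRM matches hand arithmetic and HWE expectations", {
  # one locus p = 0.5, genotypes (0, 2): W = (-1, 1), constant 0.5, G12 = -2
  grm <- relatedness_grm(toy_genotypes(cbind(c(0L, 2L), c(0L, 2L))))
  # two identical loci: constant = 2 * (0.25 + 0.25) = 1, G12 = -2
  expect_equal(grm$G[1, 2], -2)
  expect_true(isSymmetric(grm$G))
  expect_error(relatedness_grm(toy_genotypes(matrix(0L, 3, 4))),
               "monomorphic")
  # unrelated HWE individuals: mean off-diagonal ~ 0, mean diagonal ~ 1
  set.seed(65)
  p <- runif(1500, 0.1, 0.9)
  vals <- sapply(p, function(pp) rbinom(80, 2, pp))
  G <- relatedness_grm(toy_genotypes(vals))$G
  expect_lt(abs(mean(G[upper.tri(G)])), 0.02)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("full siblings show elevated relatedness near 0.5", {
  set.seed(66)
  p <- runif(1500, 0.1, 0.9)
  draw_gamete <- function(geno) ifelse(geno == 1L, rbinom(length(geno), 1, 0.5),
                                       geno / 2L)
  mum <- sapply(p, function(pp) rbinom(1, 2, pp))
  dad <- sapply(p, function(pp) rbinom(1, 2, pp))
  sibs <- t(replicate(6, draw_gamete(mum) + draw_gamete(dad)))
  # a large unrelated pool keeps the sample allele frequencies close to the
  # base population's, avoiding the family's own contribution shrinking G
  unrel <- sapply(p, function(pp) rbinom(150, 2, pp))
  vals <- rbind(sibs, unrel)
  storage.mode(vals) <- "integer"
  G <- relatedness_grm(toy_genotypes(vals))$G
  sib_vals <- G[1:6, 1:6][upper.tri(diag(6))]
  expect_equal(mean(sib_vals), 0.5, tolerance = 0.1)
})

test_that("relatedness modality separates unimodal from bimodal distributions", {
  set.seed(67)
  expect_equal(relatedness_modality(rnorm(200, 0, 0.05))$verdict, "unimodal")
  bim <- c(rnorm(100, 0, 0.03), rnorm(100, 0.5, 0.03))
  expect_equal(relatedness_modality(bim)$verdict, "bimodal")
  deg <- relatedness_modality(rep(0.2, 50))
  expect_equal(deg$verdict, "unimodal")
  expect_true(deg$degenerate)
})
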