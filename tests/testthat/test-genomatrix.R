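write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

test_that("read_vcf codes genotypes as minor-allele counts", {
  path <- write_test_vcf(c(
    "chr1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tsnpB\tC\tT\t.\tPASS\t.\tGT\t1/1\t1|1\t0/1",
    "chr1\t300\tsnpC\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "chr1\t400\tsnpD\tA\tG\t.\tPASS\t.\tGT\t./.\t./.\t./."))
  expect_warning(g <- read_vcf(path), "multiallelic")
  expect_equal(dim(g$values), c(3L, 3L))
  # snpA: ALT is minor at freq 0.5 boundary -> counted as alt
  expect_equal(unname(g$values[, "snpA"]), c(0L, 1L, 2L))
  # snpB: ALT frequency 5/6 -> REF is the counted (minor) allele
  expect_equal(g$loci$counted[g$loci$id == "snpB"], "ref")
  expect_equal(unname(g$values[, "snpB"]), c(0L, 0L, 1L))
  # snpD: all missing, retained with undefined MAF
  expect_true(all(is.na(g$values[, "snpD"])))
  expect_true(is.na(maf(g)["snpD"]))
})

test_that("read_vcf rejects haploid genotypes", {
  path <- write_test_vcf("chr1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0\t1\t0")
  expect_error(read_vcf(path), "haploid")
})

test_that("write_vcf/read_vcf round-trips genotype content", {
  set.seed(51)
  vals <- matrix(rbinom(8 * 20, 2, 0.3), 8, 20)
  vals[sample(length(vals), 15)] <- NA
  g <- toy_genotypes(vals)
  path <- tempfile(fileext = ".vcf")
  write_vcf(g, path)
  g2 <- read_vcf(path)
  expect_identical(is.na(g2$values), is.na(g$values))
  expect_equal(unname(maf(g2)), unname(maf(g)))
})

test_that("filter_genotypes applies the documented steps on a hand-counted fixture", {
  # 6 SNPs x 10 individuals: one at MAF 0.005-scale (1/20), one 60% missing,
  # two 50 bp apart, two clean -> 3 survive at defaults
  vals <- matrix(0L, 10, 6)
  vals[, 1] <- c(1L, rep(0L, 9))                    # MAF 0.05 > 0.01: kept
  vals[1, 2] <- 1L; vals[2:7, 2] <- NA              # 60% missing: dropped
  vals[, 3] <- rep(c(0L, 1L), 5)                    # clean
  vals[, 4] <- rep(c(1L, 0L), 5)                    # 50 bp from snp3: thinned
  vals[, 5] <- rep(c(0L, 2L), 5)                    # clean
  vals[, 6] <- 0L                                   # monomorphic: MAF 0
  g <- toy_genotypes(vals, pos = c(1000L, 2000L, 3000L, 3050L, 5000L, 6000L))
  out <- filter_genotypes(g)
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_removed_missing, 1)
  expect_equal(rep$n_removed_maf, 1)
  expect_equal(rep$n_removed_thin, 1)
  expect_equal(out$loci$id, c("snp1", "snp3", "snp5"))
})

test_that("filtering is idempotent and thinning is exhaustively spaced", {
  set.seed(52)
  vals <- matrix(rbinom(40 * 300, 2, runif(300, 0.02, 0.5)[rep(1:300, each = 40)]),
                 40, 300)
  vals[sample(length(vals), 1200)] <- NA
  pos <- sort(sample.int(20000, 300))
  pos <- pos + seq_len(300)  # force strict increase
  g <- toy_genotypes(vals, chrom = rep(c("chr01", "chr02"), each = 150),
                     pos = c(pos[1:150], pos[151:300]))
  f1 <- filter_genotypes(g)
  f2 <- filter_genotypes(f1)
  expect_identical(f1$values, f2$values)
  expect_identical(f1$loci$id, f2$loci$id)
  for (ch in unique(f1$loci$chrom)) {
    p <- f1$loci$pos[f1$loci$chrom == ch]
    if (length(p) > 1) expect_true(all(diff(p) >= 90))
  }
})

test_that("degenerate filter settings behave explicitly", {
  vals <- matrix(c(0L, 1L, NA, 1L, NA, 1L), 3, 2)  # every site has a missing call
  g <- toy_genotypes(vals)
  expect_warning(out <- filter_genotypes(
    g, snp_filter_config(max_missing_frac = 0)), "empty")
  expect_true(attr(out, "filter_report")$empty)
  # thin_bp = 0 disables thinning
  out2 <- filter_genotypes(toy_genotypes(matrix(rep(c(0L, 1L), 5), 5, 2),
                                         pos = c(10L, 11L)),
                           snp_filter_config(thin_bp = 0))
  expect_equal(ncol(out2$values), 2)
})

test_that("pairwise-complete covariance equals a brute-force oracle", {
  set.seed(53)
  vals <- matrix(rbinom(10 * 50, 2, 0.4), 10, 50)
  vals[sample(length(vals), 60)] <- NA
  g <- toy_genotypes(vals)
  cv <- genotype_covariance(g)
  center <- colMeans(vals, na.rm = TRUE)
  W <- sweep(vals, 2, center)
  oracle <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    shared <- which(!is.na(vals[i, ]) & !is.na(vals[j, ]))
    oracle[i, j] <- mean(W[i, shared] * W[j, shared])
  }
  expect_equal(unname(cv$cov), oracle, tolerance = 1e-12)
  # no missingness: equals the standard row-covariance computation
  vals2 <- matrix(rbinom(10 * 50, 2, 0.4), 10, 50)
  cv2 <- genotype_covariance(toy_genotypes(vals2))
  W2 <- sweep(vals2, 2, colMeans(vals2))
  expect_equal(unname(cv2$cov), W2 %*% t(W2) / 50, tolerance = 1e-12)
})

test_that("covariance hand cases: identical individuals and one locus", {
  # one locus, genotypes (0, 2): centered (-1, +1), off-diagonal -1
  vals <- cbind(c(0L, 2L), c(1L, 1L))  # second locus constant to meet >= 2
  cv <- genotype_covariance(toy_genotypes(vals))
  expect_equal(cv$cov[1, 2], -0.5)  # mean over 2 loci: (-1 + 0)/2
  # individuals 1 and 3 are identical: their covariance equals the diagonal
  v1 <- cbind(c(0L, 2L, 0L), c(0L, 2L, 0L))
  cv1 <- genotype_covariance(toy_genotypes(v1))
  expect_equal(cv1$cov[1, 3], cv1$cov[1, 1])
})

test_that("eigen structure of the PCA is coherent", {
  set.seed(54)
  vals <- matrix(rbinom(20 * 200, 2, 0.3), 20, 200)
  cv <- genotype_covariance(toy_genotypes(vals))
  pc <- pca_genotypes(cv)
  expect_equal(sum(pc$eigenvalues), sum(diag(cv$cov)), tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-10))
  # rank-1 covariance has exactly one nonzero eigenvalue
  u <- rnorm(6)
  pc1 <- pca_genotypes(outer(u, u))
  expect_equal(sum(abs(pc1$eigenvalues) > 1e-8), 1)
  # identity: all eigenvalues equal
  pci <- pca_genotypes(diag(5))
  expect_equal(pci$eigenvalues, rep(1, 5))
})

test_that("PC1 separates two diverged groups with zero score overlap", {
  cfg <- neutral_config(55, two_deme_design(40), n_loci = 2000,
                        fst_between = 0.2)
  st <- simulate_study(cfg)
  pc <- pca_genotypes(genotype_covariance(st$genotypes))
  s <- pc$scores[, 1]
  grp <- st$genotypes$indiv$group
  r1 <- range(s[grp == "G1"])
  r2 <- range(s[grp == "G2"])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
})

test_that("pc_length_association finds planted and null relationships", {
  cfg <- neutral_config(56, two_deme_design(40), n_loci = 800,
                        fst_between = 0.2)
  st <- simulate_study(cfg)
  pc <- pca_genotypes(genotype_covariance(st$genotypes))
  # lengths differ by deme (planted genotype-length dependence)
  lens <- st$genotypes$indiv$total_length_mm
  res <- pc_length_association(pc, lens)
  expect_lt(res$p[1], 1e-3)
  # lengths equal to PC1 scores: r = 1
  res2 <- pc_length_association(pc, pc$scores[, 1])
  expect_equal(res2$r[1], 1, tolerance = 1e-12)
  expect_error(pc_length_association(pc, rep(5, length(lens))),
               "zero variance")
})

test_that("PC-length null calibration holds at nominal level", {
  set.seed(57)
  n_sim <- 200
  rej <- 0L
  for (i in seq_len(n_sim)) {
    vals <- matrix(rbinom(30 * 80, 2, 0.3), 30, 80)
    pc <- pca_genotypes(genotype_covariance(toy_genotypes(vals)))
    p <- pc_length_association(pc, rnorm(30, 300, 50), axes = 1)$p
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_sim, 0.02)
  expect_lt(rej / n_sim, 0.09)
})
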