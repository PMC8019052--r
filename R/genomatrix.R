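#' Genotype matrix container
#'
#' Individuals x loci matrix of diploid genotypes coded 0/1/2 as the count of
#' a designated ("counted") allele, with `NA` for missing calls, plus locus
#' metadata (chromosome, 1-based position, alleles) and individual metadata
#' (lake, group, sex, length where known).
#'
#' @param values integer matrix, individuals in rows, loci in columns.
#' @param loci data.frame with at least `id`, `chrom`, `pos`; positions must
#'   be strictly increasing within each chromosome.
#' @param indiv data.frame with at least `id`, aligned to rows of `values`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, loci, indiv) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  stopifnot(nrow(values) == nrow(indiv), ncol(values) == nrow(loci),
            all(c("id", "chrom", "pos") %in% names(loci)),
            "id" %in% names(indiv),
            all(values %in% c(0L, 1L, 2L) | is.na(values)))
  for (ch in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(values) <- indiv$id
  colnames(values) <- loci$id
  structure(list(values = values, loci = loci, indiv = indiv),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "individuals x", ncol(x$values),
      "loci;", sum(is.na(x$values)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param indiv,loci index vectors (integer, logical, or ids) selecting
#'   individuals / loci; `NULL` keeps all.
#' @return a [genotype_matrix()].
#' @export
subset_genotypes <- function(g, indiv = NULL, loci = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ri <- if (is.null(indiv)) seq_len(nrow(g$values)) else {
    if (is.character(indiv)) match(indiv, g$indiv$id) else indiv
  }
  ci <- if (is.null(loci)) seq_len(ncol(g$values)) else {
    if (is.character(loci)) match(loci, g$loci$id) else loci
  }
  genotype_matrix(g$values[ri, ci, drop = FALSE],
                  g$loci[ci, , drop = FALSE],
                  g$indiv[ri, , drop = FALSE])
}

#' Minor allele frequency per locus
#'
#' Computed over nonmissing calls; `NA` where a locus has no calls.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector of length `n_loci`.
#' @export
maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- colMeans(g$values, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Read a VCF into a genotype matrix
#'
#' Loads diploid biallelic SNPs from a VCF 4.x file; multiallelic sites are
#' dropped with a warning, haploid GT entries are an error. Genotypes are
#' recoded as the count of the minor allele, judged over nonmissing calls
#' (the `counted` column of the locus table records whether REF or ALT is
#' counted; sites with no calls keep ALT and an `NA` frequency).
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) fix <- matrix(fix, nrow = 1,
                                     dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  biallelic <- !grepl(",", fix$ALT) & !is.na(fix$ALT) & fix$ALT != "." &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (!all(biallelic))
    warning(sum(!biallelic), " multiallelic/non-SNP site(s) dropped")
  if (!any(biallelic)) stop("no biallelic SNPs in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  nonmiss <- !is.na(gt) & !gt %in% c("./.", ".|.", ".")
  if (any(nonmiss & !grepl("[/|]", gt)))
    stop("haploid GT entries found; diploid genotypes required")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  alt_count <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  alt_count[ok] <- (a1 == "1")[ok] + (a2 == "1")[ok]
  values <- t(alt_count)  # individuals x loci

  alt_freq <- colMeans(values, na.rm = TRUE) / 2
  counted <- ifelse(is.nan(alt_freq), "alt",
                    ifelse(alt_freq > 0.5, "ref", "alt"))
  flip <- which(counted == "ref")
  if (length(flip)) values[, flip] <- 2L - values[, flip]

  loci <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, counted = counted,
    stringsAsFactors = FALSE)
  indiv <- data.frame(id = colnames(gt), stringsAsFactors = FALSE)
  genotype_matrix(values, loci, indiv)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a minimal VCF with a GT-only FORMAT; missing calls become `./.`.
#' Genotype values are written as counts of the ALT allele, so loci whose
#' counted allele is REF are flipped back on output.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  vals <- g$values
  counted <- if ("counted" %in% names(g$loci)) g$loci$counted else "alt"
  flip <- which(counted == "ref")
  if (length(flip)) vals[, flip] <- 2L - vals[, flip]
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(vals), ncol(vals))
  ok <- !is.na(vals)
  gt[ok] <- code[vals[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=charpop",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$indiv$id), collapse = "\t"))
  ref <- if ("ref" %in% names(g$loci)) g$loci$ref else "A"
  alt <- if ("alt" %in% names(g$loci)) g$loci$alt else "G"
  body <- paste(g$loci$chrom, g$loci$pos, g$loci$id, ref, alt, ".", "PASS",
                ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' SNP filter configuration
#'
#' The filtering regime applied to the genotype matrix: per-site missingness
#' cap (default 50%, with 30% as the stringent alternative), minor allele
#' frequency strictly greater than `min_maf`, positional thinning to one site
#' per `thin_bp` base pairs (reducing linkage disequilibrium among
#' reduced-representation loci), and removal of individuals missing more than
#' `max_ind_missing_frac` of the retained sites.
#'
#' @param max_missing_frac maximum fraction of missing calls per site.
#' @param min_maf sites kept only when MAF > `min_maf`.
#' @param thin_bp minimum distance between retained same-chromosome sites;
#'   0 disables thinning.
#' @param max_ind_missing_frac individuals above this missing fraction over
#'   retained sites are dropped.
#' @return object of class `snp_filter_config`.
#' @export
snp_filter_config <- function(max_missing_frac = 0.5, min_maf = 0.01,
                              thin_bp = 90, max_ind_missing_frac = 0.8) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
            min_maf >= 0, min_maf <= 0.5, thin_bp >= 0,
            max_ind_missing_frac >= 0, max_ind_missing_frac <= 1)
  structure(list(max_missing_frac = max_missing_frac, min_maf = min_maf,
                 thin_bp = thin_bp,
                 max_ind_missing_frac = max_ind_missing_frac),
            class = "snp_filter_config")
}

#' Apply the SNP filters
#'
#' Filters run in a fixed order: (1) per-site missingness, (2) MAF over
#' nonmissing calls (strict inequality), (3) positional thinning that scans
#' each chromosome in position order and keeps a site only when it lies at
#' least `thin_bp` from the last kept site (keep-first semantics), and
#' (4) dropping of high-missingness individuals over the retained sites.
#' Counts removed at each step are recorded in the `filter_report` attribute;
#' an empty result at any stage is flagged there and warned about rather than
#' returned silently.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [snp_filter_config()].
#' @return filtered [genotype_matrix()] with a `filter_report` attribute.
#' @export
filter_genotypes <- function(g, cfg = snp_filter_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "snp_filter_config"))
  report <- list(n_sites_in = ncol(g$values), n_indiv_in = nrow(g$values))

  miss_frac <- colMeans(is.na(g$values))
  keep <- miss_frac <= cfg$max_missing_frac
  report$n_removed_missing <- sum(!keep)
  g1 <- subset_genotypes(g, loci = which(keep))

  f <- maf(g1)
  keep <- !is.na(f) & f > cfg$min_maf
  report$n_removed_maf <- sum(!keep)
  g2 <- subset_genotypes(g1, loci = which(keep))

  if (cfg$thin_bp > 0 && ncol(g2$values) > 0) {
    keep <- logical(ncol(g2$values))
    for (ch in unique(g2$loci$chrom)) {
      idx <- which(g2$loci$chrom == ch)
      last <- -Inf
      for (i in idx) {
        if (g2$loci$pos[i] - last >= cfg$thin_bp) {
          keep[i] <- TRUE
          last <- g2$loci$pos[i]
        }
      }
    }
  } else keep <- rep(TRUE, ncol(g2$values))
  report$n_removed_thin <- sum(!keep)
  g3 <- subset_genotypes(g2, loci = which(keep))

  if (ncol(g3$values) > 0) {
    ind_miss <- rowMeans(is.na(g3$values))
    keep_ind <- ind_miss <= cfg$max_ind_missing_frac
  } else keep_ind <- rep(TRUE, nrow(g3$values))
  report$n_indiv_removed <- sum(!keep_ind)
  out <- subset_genotypes(g3, indiv = which(keep_ind))

  report$n_sites_out <- ncol(out$values)
  report$n_indiv_out <- nrow(out$values)
  report$empty <- report$n_sites_out == 0 || report$n_indiv_out == 0
  if (report$empty)
    warning("filtering produced an empty genotype matrix")
  attr(out, "filter_report") <- report
  out
}

#' Pairwise-complete genotype covariance among individuals
#'
#' Each locus is centered by its mean genotype over nonmissing calls. Entry
#' (i, j) is the mean, over loci where both individuals have a call, of the
#' product of their centered genotypes; the diagonal is computed the same
#' way over each individual's own called loci. Pairs that share no loci get
#' a 0 entry with a warning. The number of shared loci per pair is kept.
#'
#' @param g a [genotype_matrix()].
#' @return list of class `geno_cov`: `cov` (individuals x individuals),
#'   `n_shared`, `center` (per-locus means).
#' @export
genotype_covariance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"),
            nrow(g$values) >= 2, ncol(g$values) >= 2)
  X <- g$values
  center <- colMeans(X, na.rm = TRUE)
  W <- sweep(X, 2, center)
  M <- !is.na(X)
  W[!M] <- 0
  num <- W %*% t(W)
  den <- M %*% t(M)
  if (any(den == 0)) {
    warning(sum(den == 0 & upper.tri(den)),
            " individual pair(s) share no loci; covariance set to 0")
  }
  cv <- ifelse(den > 0, num / den, 0)
  dimnames(cv) <- list(g$indiv$id, g$indiv$id)
  structure(list(cov = cv, n_shared = den, center = center,
                 indiv = g$indiv), class = "geno_cov")
}

#' Principal components of a genotype covariance matrix
#'
#' Eigendecomposition of the (symmetric) covariance; axes are ordered by
#' eigenvalue, individual scores are eigenvectors scaled by the square root
#' of the (nonnegative part of the) eigenvalue, and each axis's sign is fixed
#' so its largest-magnitude loading is positive. Pairwise-complete
#' covariances can be non-positive-semidefinite; negative eigenvalues are
#' reported, not clipped (their axes get zero scores). Proportions of
#' variance are taken over the positive eigenvalues.
#'
#' @param cov a [genotype_covariance()] result or a symmetric matrix.
#' @return list of class `geno_pca`: `eigenvalues`, `scores`, `prop_var`,
#'   `vectors`, `covariance`.
#' @export
pca_genotypes <- function(cov) {
  cv <- if (inherits(cov, "geno_cov")) cov$cov else as.matrix(cov)
  if (!all(is.finite(cv))) stop("non-finite entries in covariance")
  stopifnot(isSymmetric(unname(cv), tol = 1e-8))
  e <- eigen((cv + t(cv)) / 2, symmetric = TRUE)
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- vec %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values))
  rownames(scores) <- rownames(cv)
  colnames(scores) <- paste0("PC", seq_along(e$values))
  pos <- pmax(e$values, 0)
  structure(list(eigenvalues = e$values, vectors = vec, scores = scores,
                 prop_var = pos / sum(pos), covariance = cv),
            class = "geno_pca")
}

#' Association between leading PC axes and fish length
#'
#' Pearson correlation of each requested axis's scores with total length,
#' with the two-sided t-test p-value and, optionally, a permutation p-value
#' from shuffling lengths.
#'
#' @param pca a [pca_genotypes()] result.
#' @param lengths numeric vector aligned to the PCA's individuals.
#' @param axes which axes to test (default first two).
#' @param n_perm number of permutations for an optional permutation p
#'   (0 disables).
#' @param seed seed for the permutations.
#' @return data.frame with `axis`, `r`, `p`, and `p_perm` when requested.
#' @export
pc_length_association <- function(pca, lengths, axes = 1:2, n_perm = 0,
                                  seed = NULL) {
  stopifnot(inherits(pca, "geno_pca"),
            length(lengths) == nrow(pca$scores))
  if (stats::sd(lengths) == 0) stop("zero variance in lengths")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(axes, function(a) {
    s <- pca$scores[, a]
    ct <- stats::cor.test(s, lengths)
    row <- data.frame(axis = a, r = unname(ct$estimate), p = ct$p.value)
    if (n_perm > 0) {
      r_obs <- abs(row$r)
      r_perm <- replicate(n_perm, abs(stats::cor(s, sample(lengths))))
      row$p_perm <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
    }
    row
  })
  do.call(rbind, out)
}
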