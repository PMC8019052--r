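#' Per-locus allele counts for a set of individuals
#'
#' @param g a [genotype_matrix()].
#' @param indiv individual ids or indices (default: all).
#' @return data.frame `a` (counted-allele copies) and `n` (called allele
#'   total, twice the nonmissing individuals) per locus.
#' @export
allele_counts <- function(g, indiv = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  sub <- if (is.null(indiv)) g else subset_genotypes(g, indiv = indiv)
  data.frame(a = colSums(sub$values, na.rm = TRUE),
             n = 2L * colSums(!is.na(sub$values)))
}

#' Reich-Patterson F_ST between two populations
#'
#' The small-sample-unbiased estimator. Per locus, with allele count a_k out
#' of n_k called alleles in population k and h_k = a_k(n_k - a_k) /
#' (n_k(n_k - 1)): N = (a_1/n_1 - a_2/n_2)^2 - h_1/n_1 - h_2/n_2 and
#' D = N + h_1 + h_2. The estimate is the ratio of sums sum(N)/sum(D)
#' (the "weighted" form). Loci with fewer than two called alleles in either
#' population are excluded and counted. If every locus is monomorphic in
#' both populations (sum D = 0) the estimate is undefined and flagged.
#'
#' @param a1,n1 per-locus counted-allele copies and called allele totals in
#'   population 1 (see [allele_counts()]).
#' @param a2,n2 likewise for population 2.
#' @param labels optional length-2 character vector naming the populations.
#' @return object of class `fst_result`: `estimate`, per-locus `N` and `D`
#'   (included loci only), `n_loci`, `n_excluded`, `status`, `labels`.
#' @export
fst_reich_patterson <- function(a1, n1, a2, n2, labels = c("pop1", "pop2")) {
  stopifnot(length(a1) == length(n1), length(a2) == length(n2),
            length(a1) == length(a2))
  ok <- n1 >= 2 & n2 >= 2
  n_excluded <- sum(!ok)
  a1 <- a1[ok]; n1 <- n1[ok]; a2 <- a2[ok]; n2 <- n2[ok]
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  N <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
  D <- N + h1 + h2
  sD <- sum(D)
  est <- if (sD == 0) NA_real_ else sum(N) / sD
  structure(list(estimate = est, N = N, D = D,
                 n_loci = length(N), n_excluded = n_excluded,
                 status = if (sD == 0) "undefined" else "ok",
                 labels = labels),
            class = "fst_result")
}

#' Reich-Patterson F_ST between two individual subsets of a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param indiv1,indiv2 ids or indices of the two populations.
#' @param labels population names for the result.
#' @return an `fst_result`.
#' @export
fst_genotypes <- function(g, indiv1, indiv2,
                          labels = c("pop1", "pop2")) {
  c1 <- allele_counts(g, indiv1)
  c2 <- allele_counts(g, indiv2)
  fst_reich_patterson(c1$a, c1$n, c2$a, c2$n, labels = labels)
}

#' Percentile bootstrap confidence interval for F_ST
#'
#' Resamples loci with replacement, recomputes the ratio of sums per
#' replicate, and takes the percentile interval. Degenerate replicates
#' (sum D = 0) are redrawn and counted.
#'
#' @param result an [fst_reich_patterson()] result.
#' @param n_boot bootstrap replicates (default 100).
#' @param seed optional seed.
#' @param conf confidence level.
#' @return `result` with `ci_low`, `ci_high`, `n_boot`, `boot_estimates`,
#'   `n_degenerate` added.
#' @export
fst_bootstrap_ci <- function(result, n_boot = 100, seed = NULL, conf = 0.95) {
  stopifnot(inherits(result, "fst_result"), result$n_loci >= 2)
  if (!is.null(seed)) set.seed(seed)
  L <- result$n_loci
  est <- numeric(n_boot)
  n_degen <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(L, L, replace = TRUE)
      sD <- sum(result$D[idx])
      if (sD != 0) break
      n_degen <- n_degen + 1L
      if (n_degen > 1000L) stop("bootstrap replicates persistently degenerate")
    }
    est[b] <- sum(result$N[idx]) / sD
  }
  # (B+1)*alpha order-statistic percentile interval (quantile type 6), the
  # standard percentile-bootstrap definition; the interpolation-based type 7
  # runs narrow at B = 100 and undercovers
  q <- stats::quantile(est, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE, type = 6)
  result$ci_low <- q[1]
  result$ci_high <- q[2]
  result$n_boot <- n_boot
  result$boot_estimates <- est
  result$n_degenerate <- n_degen
  if (n_boot == 1) result$flag <- "single-replicate CI"
  result
}

#' Folded site frequency spectrum from called genotypes
#'
#' Per site, the minor-allele copy count over nonmissing calls is tallied
#' into bins 0..floor(max n / 2). Because missingness makes the called
#' allele total vary by site, the per-site totals are returned alongside the
#' aggregate spectrum.
#'
#' @param g a [genotype_matrix()].
#' @param indiv subset of individuals (default all).
#' @return list: `sfs` (named counts for bins 0..), `site_minor_count`,
#'   `site_n`.
#' @export
folded_sfs <- function(g, indiv = NULL) {
  sub <- if (is.null(indiv)) g else subset_genotypes(g, indiv = indiv)
  stopifnot(nrow(sub$values) >= 2)
  a <- colSums(sub$values, na.rm = TRUE)
  n <- 2L * colSums(!is.na(sub$values))
  minor <- pmin(a, n - a)
  minor[n == 0] <- NA
  bins <- 0:(max(n) %/% 2)
  sfs <- vapply(bins, function(b) sum(minor == b, na.rm = TRUE), integer(1))
  names(sfs) <- bins
  list(sfs = sfs, site_minor_count = minor, site_n = n)
}

#' Watterson's theta per site
#'
#' theta_w = sum over sites of segregating(site)/a(n_site), divided by the
#' number of assayed sites L, where a(n) is the harmonic number
#' sum_{i=1}^{n-1} 1/i evaluated at each site's called allele total (missing
#' calls shrink n site by site). Sites with fewer than two called alleles
#' are skipped and excluded from L.
#'
#' @param g a [genotype_matrix()].
#' @param indiv subset of individuals (default all).
#' @return list: `theta_w`, `S` (segregating sites), `L` (assayed sites),
#'   `per_site` contributions.
#' @export
watterson_theta <- function(g, indiv = NULL) {
  sub <- if (is.null(indiv)) g else subset_genotypes(g, indiv = indiv)
  stopifnot(nrow(sub$values) >= 2)
  a <- colSums(sub$values, na.rm = TRUE)
  n <- 2L * colSums(!is.na(sub$values))
  use <- n >= 2
  seg <- use & a > 0 & a < n
  harm <- function(m) sum(1 / seq_len(m - 1))
  contrib <- ifelse(seg, 1 / vapply(pmax(n, 2L), harm, numeric(1)), 0)
  contrib[!use] <- 0
  L <- sum(use)
  list(theta_w = sum(contrib) / L, S = sum(seg), L = L,
       per_site = contrib)
}

#' Heterozygosity and inbreeding coefficient
#'
#' Per site: observed heterozygosity Ho is the fraction of heterozygotes
#' among called individuals; expected heterozygosity He = 2 p (1 - p) from
#' the called allele frequency, reported both uncorrected and with the
#' small-sample factor n/(n - 1) (n = called individuals). Site averages
#' give the summary; F_IS = 1 - mean(Ho)/mean(He) uses the uncorrected He
#' (so the all-heterozygote case at p = 0.5 gives exactly -1), with the
#' corrected variant reported alongside. He = 0 across all sites leaves
#' F_IS undefined with an explicit status.
#'
#' @param g a [genotype_matrix()].
#' @param indiv subset of individuals (default all).
#' @param unit label for the summary row.
#' @return object of class `diversity_summary`: `unit`, `Ho`, `He`,
#'   `He_corrected`, `fis`, `fis_corrected`, `n_individuals`, `n_sites`,
#'   `status`.
#' @export
het_fis <- function(g, indiv = NULL, unit = "all") {
  sub <- if (is.null(indiv)) g else subset_genotypes(g, indiv = indiv)
  stopifnot(nrow(sub$values) >= 2)
  X <- sub$values
  called <- colSums(!is.na(X))
  use <- called >= 2
  ho <- colMeans(X == 1L, na.rm = TRUE)[use]
  p <- (colMeans(X, na.rm = TRUE) / 2)[use]
  n <- called[use]
  he <- 2 * p * (1 - p)
  he_c <- he * n / (n - 1)
  mHo <- mean(ho); mHe <- mean(he); mHeC <- mean(he_c)
  status <- if (mHe == 0) "He zero: F_IS undefined" else "ok"
  structure(list(unit = unit, Ho = mHo, He = mHe, He_corrected = mHeC,
                 fis = if (mHe > 0) 1 - mHo / mHe else NA_real_,
                 fis_corrected = if (mHeC > 0) 1 - mHo / mHeC else NA_real_,
                 n_individuals = nrow(X), n_sites = sum(use),
                 status = status),
            class = "diversity_summary")
}

#' Additive relationship matrix (VanRaden/Endelman normalization)
#'
#' W holds genotypes centered by twice the counted-allele frequency per
#' locus (missing entries mean-imputed, i.e. zero after centering, and
#' counted); G = W W' / (2 sum p(1 - p)). Off-diagonal entries are the
#' pairwise additive relatedness estimates; under Hardy-Weinberg the
#' diagonal averages 1 + F. Loci with undefined frequency (no calls) are
#' excluded; a zero normalization constant is an error.
#'
#' @param g a [genotype_matrix()].
#' @param indiv subset of individuals (default all).
#' @return object of class `relatedness_matrix`: `G`, `constant`,
#'   `n_imputed`, `n_loci`.
#' @export
relatedness_grm <- function(g, indiv = NULL) {
  sub <- if (is.null(indiv)) g else subset_genotypes(g, indiv = indiv)
  stopifnot(nrow(sub$values) >= 2)
  X <- sub$values
  p <- colMeans(X, na.rm = TRUE) / 2
  use <- !is.na(p)
  X <- X[, use, drop = FALSE]
  p <- p[use]
  const <- 2 * sum(p * (1 - p))
  if (const == 0) stop("normalization constant is zero (all loci monomorphic)")
  W <- sweep(X, 2, 2 * p)
  n_imputed <- sum(is.na(W))
  W[is.na(W)] <- 0
  G <- W %*% t(W) / const
  dimnames(G) <- list(sub$indiv$id, sub$indiv$id)
  structure(list(G = G, constant = const, n_imputed = n_imputed,
                 n_loci = ncol(X)),
            class = "relatedness_matrix")
}

#' Modality of the pairwise relatedness distribution
#'
#' Panmixia predicts a unimodal distribution of off-diagonal relatedness
#' values; family or stock structure predicts bimodality. A one- versus
#' two-component Gaussian mixture is compared by BIC (via [gmm_cluster()]);
#' the verdict is bimodal iff the two-component BIC exceeds the
#' one-component BIC by at least `delta_threshold`.
#'
#' @param values numeric vector of off-diagonal relatedness values (>= 10),
#'   or a `relatedness_matrix` (its upper triangle is used).
#' @param delta_threshold BIC gap required to call bimodality.
#' @return list: `verdict` ("unimodal"/"bimodal"), `delta_bic`, `degenerate`.
#' @export
relatedness_modality <- function(values, delta_threshold = 3) {
  if (inherits(values, "relatedness_matrix"))
    values <- values$G[upper.tri(values$G)]
  stopifnot(length(values) >= 10)
  if (stats::var(values) < 1e-12)
    return(list(verdict = "unimodal", delta_bic = NA_real_,
                degenerate = TRUE))
  fit <- gmm_cluster(matrix(values, ncol = 1), K_max = 2,
                     delta_threshold = delta_threshold)
  bic_by_k <- apply(fit$bic_table, 1, max, na.rm = TRUE)
  delta21 <- unname(bic_by_k["2"] - bic_by_k["1"])
  list(verdict = if (is.finite(delta21) && delta21 >= delta_threshold)
    "bimodal" else "unimodal",
    delta_bic = delta21, degenerate = FALSE)
}
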