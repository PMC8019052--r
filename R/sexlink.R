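#' Infer putative sex groups from a PC axis
#'
#' Scans the leading principal component axes for one whose two-cluster
#' split (a one-dimensional two-component Gaussian mixture) perfectly
#' separates the individuals of known sex, then assigns a putative sex to
#' every individual from that split. Because only a handful of fish have
#' known sex, a candidate axis must also be genuinely bimodal (the
#' two-component BIC must exceed the one-component BIC by
#' `delta_bic_threshold`) with well-separated component means (at least
#' `min_separation` component standard deviations apart - a narrow-center/
#' wide-tail fit to a leptokurtic axis is not a sex split); otherwise noise
#' axes whose arbitrary split happens to agree with the few known-sex fish
#' would qualify. Fails explicitly when no axis separates the known-sex
#' fish.
#'
#' @param pca a [pca_genotypes()] result.
#' @param known_sex named character vector (`"male"`/`"female"`) for the
#'   individuals of known sex; at least two of each sex.
#' @param n_axes how many leading axes to scan (default 10).
#' @param delta_bic_threshold required BIC advantage of the two-component
#'   over the one-component model on the candidate axis.
#' @param min_separation required distance between the two component means,
#'   in units of the larger component standard deviation.
#' @return list: `putative_sex` (named vector over all individuals), `axis`
#'   (the separating axis index).
#' @export
infer_sex_groups <- function(pca, known_sex, n_axes = 10,
                             delta_bic_threshold = 3, min_separation = 3) {
  stopifnot(inherits(pca, "geno_pca"))
  ids <- rownames(pca$scores)
  known_sex <- known_sex[names(known_sex) %in% ids]
  if (sum(known_sex == "male") < 2 || sum(known_sex == "female") < 2)
    stop("need at least two known-sex individuals of each sex")
  kidx <- match(names(known_sex), ids)
  for (a in seq_len(min(n_axes, ncol(pca$scores)))) {
    s <- pca$scores[, a]
    if (stats::sd(s) < 1e-12) next
    bic <- tryCatch(
      suppressWarnings(mclust::mclustBIC(s, G = 1:2,
                                         modelNames = c("E", "V"),
                                         verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(bic)) next
    b <- matrix(bic, nrow = 2)
    gap <- max(b[2, ], na.rm = TRUE) - max(b[1, ], na.rm = TRUE)
    if (!is.finite(gap) || gap < delta_bic_threshold) next
    fit <- tryCatch(
      mclust::Mclust(s, G = 2, modelNames = c("E", "V"), verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    mu <- fit$parameters$mean
    sig <- sqrt(fit$parameters$variance$sigmasq)
    if (abs(diff(mu)) < min_separation * max(sig)) next
    cl <- fit$classification
    km <- cl[kidx][known_sex == "male"]
    kf <- cl[kidx][known_sex == "female"]
    if (length(unique(km)) == 1 && length(unique(kf)) == 1 &&
        unique(km) != unique(kf)) {
      male_cluster <- unique(km)
      putative <- ifelse(cl == male_cluster, "male", "female")
      names(putative) <- ids
      return(list(putative_sex = putative, axis = a))
    }
  }
  stop("no principal component axis separates the known-sex individuals")
}

#' Discriminant analysis of principal components
#'
#' Linear discriminant analysis on the top `n_pc` PC scores. When `n_pc` is
#' not given it is chosen by stratified repeated holdout (default 30
#' repetitions of a 90/10 split) minimizing the root mean squared assignment
#' error. Per-SNP loadings (available when the genotype matrix is supplied)
#' are the covariances between each locus's centered genotypes (missing
#' entries mean-imputed) and the first discriminant axis scores, which maps
#' the discriminant coefficients back through the PCA loadings.
#'
#' @param scores individuals x axes matrix of PC scores.
#' @param groups factor/character vector of group labels (>= 2 groups with
#'   >= 2 members each).
#' @param n_pc number of PC axes to retain; chosen by cross-validation when
#'   `NULL`.
#' @param genotypes optional [genotype_matrix()] for SNP loadings.
#' @param n_rep,holdout repetitions and held-out fraction for the
#'   cross-validation.
#' @param seed optional seed for the holdout draws.
#' @return object of class `dapc_fit`: `n_pc`, `cv` (per-candidate RMSE),
#'   `lda`, `ld_scores`, `posterior`, `assignment`, `accuracy`,
#'   `snp_loadings`.
#' @export
dapc <- function(scores, groups, n_pc = NULL, genotypes = NULL,
                 n_rep = 30, holdout = 0.1, seed = NULL) {
  scores <- as.matrix(scores)
  groups <- as.factor(groups)
  stopifnot(nrow(scores) == length(groups), nlevels(groups) >= 2,
            all(table(groups) >= 2))
  n <- nrow(scores)
  g <- nlevels(groups)
  max_pc <- min(ncol(scores), n - g - 1)
  if (max_pc < 1) stop("too few individuals for any PC axes")
  if (!is.null(n_pc) && n_pc > max_pc) {
    warning("n_pc reduced to ", max_pc)
    n_pc <- max_pc
  }
  if (!is.null(seed)) set.seed(seed)
  cv <- NULL
  if (is.null(n_pc)) {
    candidates <- unique(round(seq(1, max_pc, length.out = min(max_pc, 12))))
    errs <- matrix(NA_real_, n_rep, length(candidates))
    for (r in seq_len(n_rep)) {
      test <- unlist(lapply(split(seq_len(n), groups), function(idx)
        sample(idx, max(1, round(length(idx) * holdout)))))
      train <- setdiff(seq_len(n), test)
      if (length(unique(groups[train])) < g) next
      for (ci in seq_along(candidates)) {
        p <- candidates[ci]
        fit <- tryCatch(suppressWarnings(
          MASS::lda(scores[train, seq_len(p), drop = FALSE], groups[train])),
          error = function(e) NULL)
        if (is.null(fit)) next
        pred <- stats::predict(fit, scores[test, seq_len(p), drop = FALSE])
        errs[r, ci] <- mean(pred$class != groups[test])
      }
    }
    rmse <- sqrt(colMeans(errs^2, na.rm = TRUE))
    n_pc <- candidates[which.min(rmse)]
    cv <- data.frame(n_pc = candidates, rmse = rmse)
  }
  fit <- suppressWarnings(
    MASS::lda(scores[, seq_len(n_pc), drop = FALSE], groups))
  pred <- stats::predict(fit, scores[, seq_len(n_pc), drop = FALSE])
  loadings <- NULL
  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "genotype_matrix"),
              nrow(genotypes$values) == n)
    X <- genotypes$values
    W <- sweep(X, 2, colMeans(X, na.rm = TRUE))
    W[is.na(W)] <- 0
    ld1 <- pred$x[, 1]
    loadings <- as.numeric(crossprod(W, ld1 - mean(ld1))) / (n - 1)
    names(loadings) <- genotypes$loci$id
  }
  structure(list(n_pc = n_pc, cv = cv, lda = fit, ld_scores = pred$x,
                 posterior = pred$posterior, assignment = pred$class,
                 accuracy = mean(pred$class == groups),
                 snp_loadings = loadings),
            class = "dapc_fit")
}

#' Detect sex-linked SNPs
#'
#' Runs the genotype covariance, PCA and a sex-group DAPC, then evaluates
#' candidate loci: those whose squared discriminant loading exceeds the
#' `loading_quantile` quantile (at least `min_candidates` inspected), plus
#' loci whose call rates differ extremely between the sexes (which carry
#' their signal in the missingness pattern rather than the genotypes).
#' Pattern rules, with strict inequalities: XY-like iff heterozygosity
#' > 0.95 in one sex while the other sex has heterozygosity < 0.05 and one
#' dominant homozygote; male-/female-only-genotyped iff the call rate is
#' < 0.05 in one sex and > 0.5 in the other. Chromosomes carrying any
#' classified SNP are flagged for removal.
#'
#' The inspection window defaults to the top 0.5% of loadings: a
#' sex-determining region carries a halo of partially sex-associated
#' variation whose loadings interleave with the fully sex-linked loci, and
#' since candidates are only ever classified by the strict genotype
#' patterns, inspecting a wider window costs nothing in specificity.
#' Loci with extreme sex-differential call rates are always inspected -
#' their signal lives in the missingness pattern, not the genotypes, so run
#' this screen before any site-missingness filtering.
#'
#' @param g a [genotype_matrix()].
#' @param putative_sex named character vector (`"male"`/`"female"`) over the
#'   individuals of `g` (see [infer_sex_groups()]).
#' @param loading_quantile quantile of squared loadings above which loci are
#'   inspected.
#' @param min_candidates minimum number of top-loading loci inspected.
#' @return object of class `sexlink_report`: `candidates` (data.frame with
#'   per-sex heterozygosity, call rates, loading rank and pattern class),
#'   `detected` (the classified subset), `flagged_chromosomes`, `dapc`.
#' @export
detect_sex_linked <- function(g, putative_sex, loading_quantile = 0.995,
                              min_candidates = 10) {
  stopifnot(inherits(g, "genotype_matrix"))
  sex <- putative_sex[g$indiv$id]
  stopifnot(all(sex %in% c("male", "female")))
  cv <- genotype_covariance(g)
  pc <- pca_genotypes(cv)
  dp <- dapc(pc$scores, sex, genotypes = g)
  l2 <- dp$snp_loadings^2
  thr <- stats::quantile(l2, loading_quantile, names = FALSE)
  cand <- which(l2 >= thr)
  if (length(cand) < min_candidates)
    cand <- order(l2, decreasing = TRUE)[seq_len(min_candidates)]

  male <- sex == "male"
  Xm <- g$values[male, , drop = FALSE]
  Xf <- g$values[!male, , drop = FALSE]
  call_m <- colMeans(!is.na(Xm))
  call_f <- colMeans(!is.na(Xf))
  screen <- which((call_m < 0.05 & call_f > 0.5) |
                    (call_f < 0.05 & call_m > 0.5))
  cand <- sort(unique(c(cand, screen)))
  if (!length(cand)) stop("no loci above the loading quantile")

  het_m <- colMeans(Xm[, cand, drop = FALSE] == 1L, na.rm = TRUE)
  het_f <- colMeans(Xf[, cand, drop = FALSE] == 1L, na.rm = TRUE)
  hom_dom <- function(X) {
    apply(X, 2, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      max(mean(v == 0L), mean(v == 2L))
    })
  }
  dom_m <- hom_dom(Xm[, cand, drop = FALSE])
  dom_f <- hom_dom(Xf[, cand, drop = FALSE])

  classify <- function(i) {
    hm <- het_m[i]; hf <- het_f[i]
    cm <- call_m[cand[i]]; cf <- call_f[cand[i]]
    if (cm < 0.05 && cf > 0.5) return("female-only-genotyped")
    if (cf < 0.05 && cm > 0.5) return("male-only-genotyped")
    if (!is.na(hm) && !is.na(hf)) {
      if (hm > 0.95 && hf < 0.05 && !is.na(dom_f[i]) && dom_f[i] > 0.9)
        return("XY-like")
      if (hf > 0.95 && hm < 0.05 && !is.na(dom_m[i]) && dom_m[i] > 0.9)
        return("XY-like")
    }
    "ambiguous"
  }
  pattern <- vapply(seq_along(cand), classify, character(1))
  rank_tab <- rank(-l2, ties.method = "min")
  candidates <- data.frame(
    locus = cand, id = g$loci$id[cand], chrom = g$loci$chrom[cand],
    pos = g$loci$pos[cand], loading_rank = rank_tab[cand],
    het_male = het_m, het_female = het_f,
    callrate_male = call_m[cand], callrate_female = call_f[cand],
    pattern = pattern, stringsAsFactors = FALSE)
  detected <- candidates[candidates$pattern != "ambiguous", , drop = FALSE]
  structure(list(candidates = candidates, detected = detected,
                 flagged_chromosomes = unique(detected$chrom),
                 dapc = dp),
            class = "sexlink_report")
}

#' Remove flagged sex chromosomes from a genotype matrix
#'
#' Drops every locus on the chromosomes implicated by a sex-linkage report
#' (whole-chromosome removal mirrors the downstream analyses' exclusion
#' policy). Names not present in the matrix are warned about and skipped;
#' flagging all chromosomes is an error.
#'
#' @param g a [genotype_matrix()].
#' @param report a `sexlink_report` or a character vector of chromosome
#'   names.
#' @return the reduced [genotype_matrix()] with a `removal_manifest`
#'   attribute.
#' @export
drop_sex_chromosomes <- function(g, report) {
  stopifnot(inherits(g, "genotype_matrix"))
  chroms <- if (inherits(report, "sexlink_report"))
    report$flagged_chromosomes else as.character(report)
  present <- unique(g$loci$chrom)
  absent <- setdiff(chroms, present)
  if (length(absent))
    warning("chromosome(s) not present, skipped: ",
            paste(absent, collapse = ", "))
  chroms <- intersect(chroms, present)
  if (length(chroms) == 0)
    return(structure(g, removal_manifest = list(chromosomes = character(0),
                                                n_loci_removed = 0L)))
  if (setequal(chroms, present))
    stop("refusing to remove every chromosome")
  keep <- !(g$loci$chrom %in% chroms)
  out <- subset_genotypes(g, loci = which(keep))
  attr(out, "removal_manifest") <- list(chromosomes = chroms,
                                        n_loci_removed = sum(!keep))
  out
}
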