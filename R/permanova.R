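#' Char density from abundance and lake area
#'
#' Published densities follow the convention of truncating abundance/area
#' toward zero to an integer number of fish per hectare.
#'
#' @param abundance estimated number of fish (>= 0).
#' @param area lake surface area in hectares (> 0).
#' @return integer fish per hectare.
#' @export
char_density <- function(abundance, area) {
  stopifnot(all(abundance >= 0))
  if (any(area <= 0)) stop("area must be positive")
  as.integer(trunc(abundance / area))
}

#' PERMANOVA with marginal (Type-II) sums of squares
#'
#' Permutational multivariate analysis of variance on the Euclidean
#' distances of the response matrix. Each term's sum of squares is marginal
#' (fitted last given all other terms, via projection of the Gower-centered
#' distance matrix); pseudo-F = (SS_term/df_term)/(SS_resid/df_resid) and
#' p = (number of permuted F >= observed + 1)/(n_perm + 1) under free
#' permutation of response rows (or within-`strata` permutation when
#' blocks are supplied). For a univariate response and a single factor the
#' pseudo-F equals the classical one-way ANOVA F. Collinear predictors are
#' dropped with a warning before fitting.
#'
#' @param response numeric matrix/data.frame (rows = observations); no
#'   missing values.
#' @param predictors data.frame of covariates aligned to the response rows.
#' @param n_perm number of permutations.
#' @param seed optional seed for the permutations.
#' @param standardize scale response columns to unit variance first.
#' @param strata optional blocking factor restricting permutations.
#' @return data.frame of class `permanova_result`: `term`, `df`, `SS`, `F`,
#'   `p` (residual and total rows included); attributes record the call
#'   details.
#' @export
permanova_test <- function(response, predictors, n_perm = 9999, seed = NULL,
                           standardize = FALSE, strata = NULL) {
  Y <- as.matrix(response)
  if (any(!is.finite(Y))) stop("response must be numeric with no missing values")
  if (any(apply(Y, 2, stats::var) == 0) && ncol(Y) == 1)
    stop("constant response")
  if (standardize) Y <- scale(Y)
  predictors <- as.data.frame(predictors)
  stopifnot(nrow(predictors) == nrow(Y))

  # drop aliased (collinear) predictors up front
  mm <- stats::model.matrix(~ ., data = predictors)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased_cols <- colnames(mm)[qr_mm$pivot[-seq_len(qr_mm$rank)]]
    bad <- names(predictors)[vapply(names(predictors), function(v)
      any(startsWith(aliased_cols, v)), logical(1))]
    warning("collinear predictor(s) dropped: ", paste(bad, collapse = ", "))
    predictors <- predictors[, setdiff(names(predictors), bad), drop = FALSE]
    if (ncol(predictors) == 0) stop("no non-collinear predictors left")
  }

  if (!is.null(seed)) set.seed(seed)
  perm <- if (is.null(strata)) n_perm else
    permute::how(blocks = as.factor(strata), nperm = n_perm)
  dat <- predictors
  form <- stats::as.formula(paste("Y ~", paste(names(dat), collapse = " + ")))
  env <- list2env(list(Y = Y), parent = environment())
  res <- vegan::adonis2(form, data = dat, permutations = perm,
                        method = "euclidean", by = "margin")
  out <- data.frame(term = rownames(res), df = res$Df, SS = res$SumOfSqs,
                    F = res$F, p = res$`Pr(>F)`, stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "formula") <- deparse(form)
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Additive PERMANOVA model search
#'
#' Evaluates all single-predictor models, then all additive combinations of
#' up to `max_terms` candidate predictors, with marginal tests throughout.
#' Models are ranked by (1) every term significant at `alpha`, then (2)
#' smallest residual sum of squares. The full model table is returned even
#' when no model has all terms significant (the best model is then empty).
#'
#' @param response numeric response matrix.
#' @param predictors data.frame holding the candidate predictor columns.
#' @param candidates character vector of predictor names to search over.
#' @param max_terms largest number of terms in a model.
#' @param n_perm permutations per test.
#' @param seed optional seed.
#' @param alpha per-term significance level.
#' @return list: `table` (one row per model: terms, residual SS, min/max
#'   term p, all_significant), `best` (character vector of terms, possibly
#'   empty), `fits` (the per-model `permanova_result`s).
#' @export
model_search <- function(response, predictors, candidates = names(predictors),
                         max_terms = 3, n_perm = 999, seed = NULL,
                         alpha = 0.05) {
  stopifnot(length(candidates) >= 1, max_terms >= 1)
  combos <- unlist(lapply(seq_len(min(max_terms, length(candidates))),
                          function(m) utils::combn(candidates, m,
                                                   simplify = FALSE)),
                   recursive = FALSE)
  fits <- vector("list", length(combos))
  rows <- vector("list", length(combos))
  for (i in seq_along(combos)) {
    terms <- combos[[i]]
    fit <- tryCatch(
      permanova_test(response, predictors[, terms, drop = FALSE],
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else seed + i),
      error = function(e) NULL, warning = function(w) NULL)
    fits[[i]] <- fit
    if (is.null(fit)) next
    term_rows <- fit[!fit$term %in% c("Residual", "Total"), , drop = FALSE]
    resid_ss <- fit$SS[fit$term == "Residual"]
    rows[[i]] <- data.frame(
      model = paste(terms, collapse = " + "), n_terms = length(terms),
      resid_ss = resid_ss, max_p = max(term_rows$p),
      all_significant = all(term_rows$p < alpha), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$all_significant, tab$resid_ss), ]
  rownames(tab) <- NULL
  best <- if (nrow(tab) && tab$all_significant[1])
    strsplit(tab$model[1], " \\+ ")[[1]] else character(0)
  list(table = tab, best = best, fits = fits)
}
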