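#' Fit per-trait allometric slopes
#'
#' For each trait, ordinary least squares of log10(trait) on log10(total
#' length) gives the allometric exponent `b` used by [size_adjust()]. The
#' reference length `L_m` is the arithmetic mean of the total lengths in the
#' fitting set (all fish for across-lake analyses; restrict the input to one
#' lake's fish for within-lake analyses).
#'
#' @param traits data.frame or matrix of trait measurements (mm), one column
#'   per trait; nonpositive values are an error, `NA`s are dropped per trait.
#' @param lengths numeric vector of total lengths (mm), aligned to rows.
#' @return object of class `allometry_model`: data.frame `coef` with `trait`,
#'   `b`, `intercept`, `resid_sd`, `n`, plus `L_m`.
#' @export
fit_allometric_slope <- function(traits, lengths) {
  traits <- as.data.frame(traits)
  stopifnot(nrow(traits) == length(lengths))
  if (any(lengths <= 0, na.rm = TRUE)) stop("nonpositive lengths")
  if (any(as.matrix(traits) <= 0, na.rm = TRUE)) stop("nonpositive trait values")
  logL <- log10(lengths)
  coefs <- lapply(names(traits), function(tr) {
    ok <- !is.na(traits[[tr]]) & !is.na(lengths)
    if (sum(ok) < 3) stop("fewer than 3 fish with trait and length for ", tr)
    if (stats::var(logL[ok]) == 0)
      stop("zero length variance; slope undefined for ", tr)
    fit <- stats::lm.fit(cbind(1, logL[ok]), log10(traits[[tr]][ok]))
    data.frame(trait = tr, b = fit$coefficients[2],
               intercept = fit$coefficients[1],
               resid_sd = stats::sd(fit$residuals), n = sum(ok))
  })
  structure(list(coef = do.call(rbind, coefs),
                 L_m = mean(lengths, na.rm = TRUE)),
            class = "allometry_model")
}

#' Allometric size adjustment of a trait
#'
#' Standardizes a measured trait to a common reference length so that shape
#' comparisons are not confounded with body size:
#' log10 Y = log10 M + b (log10 L_m - log10 L), i.e.
#' Y = M * (L_m / L)^b. At L = L_m, or with b = 0, the trait is returned
#' unchanged.
#'
#' @param M measured trait value(s), mm (> 0).
#' @param L measured total length(s), mm (> 0).
#' @param b allometric slope (any finite value).
#' @param L_m reference length, mm (> 0).
#' @return size-adjusted trait value(s), mm.
#' @export
size_adjust <- function(M, L, b, L_m) {
  if (any(M <= 0, na.rm = TRUE) || any(L <= 0, na.rm = TRUE) || L_m <= 0)
    stop("M, L and L_m must be positive")
  stopifnot(all(is.finite(b)))
  M * (L_m / L)^b
}

#' Size-adjust every trait of a fish table
#'
#' @param fish fish data.frame containing `total_length_mm` and the model's
#'   trait columns.
#' @param model an [fit_allometric_slope()] result.
#' @return `fish` with trait columns replaced by their size-adjusted values.
#' @export
size_adjust_fish <- function(fish, model) {
  stopifnot(inherits(model, "allometry_model"))
  for (i in seq_len(nrow(model$coef))) {
    tr <- model$coef$trait[i]
    fish[[tr]] <- size_adjust(fish[[tr]], fish$total_length_mm,
                              model$coef$b[i], model$L_m)
  }
  fish
}

#' Gaussian-mixture clustering with BIC model selection
#'
#' Fits Gaussian mixtures for K = 1..`K_max` over a reduced covariance
#' family (spherical, diagonal and full; shared and per-cluster - mclust
#' models EII/VII/EEI/VVI/EEE/VVV, or E/V in one dimension) and tabulates
#' BIC = 2 logL - m log n, higher being better. The selected K maximizes
#' BIC; when the gap to the best model with a different K falls below
#' `delta_threshold` the selection is flagged ambiguous and the smaller of
#' the two K values is reported (the more parsimonious morph claim).
#' Rows containing missing values are dropped and counted.
#'
#' @param X numeric matrix or data.frame of (typically size-adjusted) traits.
#' @param K_max largest number of clusters to try.
#' @param delta_threshold BIC gap below which selection is ambiguous.
#' @param models mclust model names; default is the reduced family above.
#' @param seed optional seed (mclust initialization is deterministic, but EM
#'   for singleton clusters can involve random restarts).
#' @return object of class `size_class_model`: `K`, `delta_bic`, `ambiguous`,
#'   `bic_table` (K x model), `classification`, `z` (posterior
#'   responsibilities), `model_name`, `n_dropped`, `fit`.
#' @export
gmm_cluster <- function(X, K_max = 5, delta_threshold = 3, models = NULL,
                        seed = NULL) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(X)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) <= K_max) stop("need more rows than K_max")
  d <- ncol(X)
  if (is.null(models))
    models <- if (d == 1) c("E", "V") else
      c("EII", "VII", "EEI", "VVI", "EEE", "VVV")
  if (!is.null(seed)) set.seed(seed)
  fit <- mclust::Mclust(X, G = 1:K_max, modelNames = models, verbose = FALSE)
  if (is.null(fit)) stop("mclust failed on all (K, model) combinations")
  bic <- fit$BIC
  class(bic) <- "matrix"
  bic_by_k <- apply(bic, 1, max, na.rm = TRUE)
  bic_by_k[!is.finite(bic_by_k)] <- NA
  ord <- order(bic_by_k, decreasing = TRUE)
  k_best <- as.integer(rownames(bic)[ord[1]])
  delta <- if (length(ord) > 1) bic_by_k[ord[1]] - bic_by_k[ord[2]] else Inf
  ambiguous <- is.finite(delta) && delta < delta_threshold
  selected <- k_best
  if (ambiguous) {
    k_runner <- as.integer(rownames(bic)[ord[2]])
    selected <- min(k_best, k_runner)
  }
  if (selected != fit$G) {
    model_sel <- colnames(bic)[which.max(bic[as.character(selected), ])]
    fit <- mclust::Mclust(X, G = selected, modelNames = model_sel,
                          verbose = FALSE)
  }
  structure(list(K = selected, delta_bic = unname(delta),
                 ambiguous = ambiguous, bic_table = bic,
                 classification = fit$classification, z = fit$z,
                 model_name = fit$modelName, n_dropped = n_dropped,
                 loglik = fit$loglik, fit = fit),
            class = "size_class_model")
}

#' Assign ordered size-class labels to fish
#'
#' Renames the fitted mixture clusters by increasing mean total length:
#' small/large for K = 2, small/medium/large for K = 3, otherwise
#' class-1..class-K (K = 1 collapses to a single class). Ties in mean length
#' are broken deterministically by cluster index and flagged.
#'
#' @param model a [gmm_cluster()] fit on these fish (rows with missing traits
#'   excluded in the same order).
#' @param fish fish data.frame with `total_length_mm`, same rows (post-drop)
#'   as the clustering input.
#' @return `fish` with a `size_class` column; attribute `tie` flags mean-
#'   length ties.
#' @export
assign_size_classes <- function(model, fish) {
  stopifnot(inherits(model, "size_class_model"),
            nrow(fish) == length(model$classification))
  K <- model$K
  mean_len <- tapply(fish$total_length_mm, model$classification, mean)
  tie <- anyDuplicated(mean_len) > 0
  ord <- order(mean_len, as.integer(names(mean_len)))
  labels <- if (K == 1) "class-1" else if (K == 2) c("small", "large")
    else if (K == 3) c("small", "medium", "large") else paste0("class-", 1:K)
  map <- stats::setNames(labels, names(mean_len)[ord])
  fish$size_class <- unname(map[as.character(model$classification)])
  attr(fish, "tie") <- tie
  fish
}
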