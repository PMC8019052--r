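#' Maximum-likelihood admixture estimation by EM
#'
#' Maximizes the binomial admixture likelihood
#' prod_i prod_l Binom(x_il; 2, sum_k q_ik p_lk) over ancestry proportions Q
#' and cluster allele frequencies P by block EM updates, from several seeded
#' random starts (best final likelihood kept). Missing genotypes are simply
#' skipped in the likelihood. K = 1 has the closed-form solution (Q all
#' ones, P the observed frequencies) and is returned analytically.
#'
#' @param g a [genotype_matrix()].
#' @param K number of ancestral clusters (>= 1).
#' @param seed optional seed for the random starts.
#' @param max_iter EM iteration cap per start.
#' @param tol log-likelihood convergence tolerance.
#' @param n_starts number of random starts.
#' @return object of class `ancestry_fit`: `K`, `Q` (individuals x K, rows
#'   summing to 1), `P` (loci x K), `loglik`, `loglik_path` (best start),
#'   `converged`, `n_starts`.
#' @export
admixture_em <- function(g, K, seed = NULL, max_iter = 300, tol = 1e-6,
                         n_starts = 10) {
  stopifnot(inherits(g, "genotype_matrix"), K >= 1)
  X <- g$values
  n <- nrow(X); L <- ncol(X)
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0L
  Li <- rowSums(M)
  lchoose_const <- sum(ifelse(X0 == 1L & M, log(2), 0))
  loglik_of <- function(Fm) {
    Fm <- pmin(pmax(Fm, 1e-12), 1 - 1e-12)
    sum((X0 * log(Fm) + (2 - X0) * log1p(-Fm))[M]) + lchoose_const
  }
  if (K == 1) {
    p <- colSums(X0) / (2 * colSums(M))
    p[is.nan(p)] <- 0.5
    Fm <- matrix(p, n, L, byrow = TRUE)
    return(structure(list(K = 1L, Q = matrix(1, n, 1),
                          P = matrix(p, L, 1), loglik = loglik_of(Fm),
                          loglik_path = NULL, converged = TRUE,
                          n_starts = 0L),
                     class = "ancestry_fit"))
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    Q <- matrix(stats::rexp(n * K), n, K)
    Q <- Q / rowSums(Q)
    P <- matrix(stats::runif(L * K, 0.05, 0.95), L, K)
    ll_prev <- -Inf
    path <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Fm <- Q %*% t(P)
      Fm <- pmin(pmax(Fm, 1e-9), 1 - 1e-9)
      S1 <- (X0 / Fm) * M           # expected counted-allele weight
      S0 <- ((2 - X0) / (1 - Fm)) * M
      Qn <- matrix(0, n, K)
      Pn <- matrix(0, L, K)
      for (k in seq_len(K)) {
        u1 <- as.numeric(crossprod(S1, Q[, k])) * P[, k]       # per-locus
        u0 <- as.numeric(crossprod(S0, Q[, k])) * (1 - P[, k])
        Pn[, k] <- ifelse(u1 + u0 > 0, u1 / (u1 + u0), P[, k])
        Qn[, k] <- Q[, k] * (S1 %*% P[, k] + S0 %*% (1 - P[, k]))
      }
      Qn <- Qn / pmax(2 * Li, 1)
      Qn <- Qn / rowSums(Qn)
      Q <- Qn
      P <- pmin(pmax(Pn, 1e-9), 1 - 1e-9)
      ll <- loglik_of(Q %*% t(P))
      path <- c(path, ll)
      if (is.finite(ll_prev) && ll - ll_prev < tol) { converged <- TRUE; break }
      ll_prev <- ll
    }
    ll <- path[length(path)]
    if (is.null(best) || ll > best$loglik)
      best <- list(Q = Q, P = P, loglik = ll, path = path,
                   converged = converged)
  }
  rownames(best$Q) <- g$indiv$id
  structure(list(K = as.integer(K), Q = best$Q, P = best$P,
                 loglik = best$loglik, loglik_path = best$path,
                 converged = best$converged, n_starts = n_starts),
            class = "ancestry_fit")
}

#' Choose K by cross-validated genotype masking
#'
#' For each fold, a random 1/`n_folds` of the nonmissing genotype cells is
#' masked, the admixture model is refit on the rest, and the masked cells
#' are predicted as 2 sum_k q_ik p_lk. The cross-validation error is the
#' mean squared deviation between masked genotypes and their predictions;
#' the K with the lowest mean error across folds is selected.
#'
#' @param g a [genotype_matrix()].
#' @param K_range candidate K values (default 1:5).
#' @param n_folds number of folds (default 10).
#' @param seed seed controlling fold assignment and EM starts.
#' @param n_starts EM random starts per fit (kept modest for CV).
#' @param max_iter EM iteration cap.
#' @param tol EM convergence tolerance; looser than the final-fit default
#'   because held-out prediction error is insensitive to the last digits of
#'   the likelihood.
#' @return list: `K` (selected), `cv` (data.frame K x fold errors and
#'   means).
#' @export
choose_k_cv <- function(g, K_range = 1:5, n_folds = 10, seed = NULL,
                        n_starts = 2, max_iter = 80, tol = 1e-4) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  X <- g$values
  cells <- which(!is.na(X))
  if (length(cells) < n_folds) stop("too few nonmissing genotype cells")
  fold <- sample(rep_len(seq_len(n_folds), length(cells)))
  err <- matrix(NA_real_, length(K_range), n_folds,
                dimnames = list(K_range, NULL))
  for (f in seq_len(n_folds)) {
    masked <- cells[fold == f]
    Xf <- X
    Xf[masked] <- NA_integer_
    gf <- g
    gf$values <- Xf
    for (ki in seq_along(K_range)) {
      fit <- admixture_em(gf, K_range[ki],
                          seed = if (is.null(seed)) NULL else
                            (seed + 131L * f + ki) %% .Machine$integer.max,
                          n_starts = n_starts, max_iter = max_iter,
                          tol = tol)
      pred <- (fit$Q %*% t(fit$P))[masked] * 2
      err[ki, f] <- mean((X[masked] - pred)^2)
    }
  }
  means <- rowMeans(err)
  list(K = K_range[which.min(means)],
       cv = data.frame(K = K_range, cv_error = means),
       fold_errors = err)
}

#' Stock-mixture clustering with bootstrap assignment support
#'
#' Finite-mixture model in which each individual belongs wholly to one of K
#' stocks with stock-specific allele frequencies; EM over the posterior
#' stock responsibilities. Uncertainty in the hard assignments is assessed
#' by bootstrapping loci: each replicate refits the model on a resample of
#' loci, matches stock labels to the original fit, and the per-individual
#' support is the fraction of replicates agreeing with the original
#' assignment. When size classes are supplied, their contingency with the
#' hard assignments and a two-sided Fisher exact p-value are reported.
#'
#' @param g a [genotype_matrix()].
#' @param K number of stocks (>= 2, < number of individuals).
#' @param n_boot bootstrap replicates over loci (0 disables).
#' @param seed optional seed.
#' @param size_class optional per-individual labels to cross-tabulate.
#' @param n_starts EM random starts.
#' @param max_iter EM iteration cap.
#' @return object of class `stock_assignment`: `K`, `assignment`,
#'   `posterior`, `support`, `P`, `pi`, `loglik`, `contingency`, `fisher_p`,
#'   `n_restarts`.
#' @export
stock_mixture_em <- function(g, K = 2, n_boot = 100, seed = NULL,
                             size_class = NULL, n_starts = 10,
                             max_iter = 200) {
  stopifnot(inherits(g, "genotype_matrix"), K >= 2)
  X <- g$values
  n <- nrow(X)
  if (K >= n) stop("K must be smaller than the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  fit <- .stock_em_fit(X, K, n_starts, max_iter)
  hard <- max.col(fit$R)
  support <- rep(NA_real_, n)
  if (n_boot > 0) {
    agree <- integer(n)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ncol(X), ncol(X), replace = TRUE)
      fb <- .stock_em_fit(X[, idx, drop = FALSE], K, max(2, n_starts %/% 3),
                          max_iter)
      hb <- max.col(fb$R)
      perm <- .best_label_permutation(hb, hard, K)
      agree <- agree + (perm[hb] == hard)
    }
    support <- agree / n_boot
  }
  contingency <- NULL
  fisher_p <- NULL
  if (!is.null(size_class)) {
    contingency <- table(stock = hard, size_class = size_class)
    fisher_p <- fisher_exact(contingency)$p
  }
  structure(list(K = as.integer(K), assignment = hard, posterior = fit$R,
                 support = support, P = fit$P, pi = fit$pi,
                 loglik = fit$loglik, contingency = contingency,
                 fisher_p = fisher_p, n_restarts = fit$n_restarts),
            class = "stock_assignment")
}

# EM core for the stock mixture; responsibility collapse triggers a restart.
.stock_em_fit <- function(X, K, n_starts, max_iter, tol = 1e-6) {
  n <- nrow(X); L <- ncol(X)
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0L
  best <- NULL
  n_restarts <- 0L
  for (s in seq_len(n_starts)) {
    init <- sample.int(K, n, replace = TRUE)
    R <- matrix(0.1 / max(K - 1, 1), n, K)
    R[cbind(seq_len(n), init)] <- 0.9
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      cnt <- pmax(colSums(R), 1e-8)
      P <- t(crossprod(R, X0) / (2 * crossprod(R, M + 0)))
      P <- pmin(pmax(P, 1e-6), 1 - 1e-6)    # L x K
      pi_k <- cnt / n
      logf <- (X0 * M) %*% log(P) + ((2 - X0) * M) %*% log(1 - P)
      logf <- sweep(logf, 2, log(pi_k), "+")
      mx <- apply(logf, 1, max)
      R <- exp(logf - mx)
      R <- R / rowSums(R)
      ll <- sum(mx + log(rowSums(exp(logf - mx))))
      if (any(colSums(R) < 1e-3)) { n_restarts <- n_restarts + 1L; break }
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) break
      ll_prev <- ll
    }
    if (any(colSums(R) < 1e-3)) next
    if (is.null(best) || ll > best$loglik)
      best <- list(R = R, P = P, pi = pi_k, loglik = ll)
  }
  if (is.null(best)) stop("stock mixture EM collapsed in every start")
  best$n_restarts <- n_restarts
  best
}

# Permutation of labels 1..K maximizing agreement of `from` with `to`.
.best_label_permutation <- function(from, to, K) {
  perms <- .permutations(K)
  agree <- vapply(seq_len(nrow(perms)), function(i)
    sum(perms[i, ][from] == to), integer(1))
  perms[which.max(agree), ]
}

.permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(K - 1)
  out <- do.call(rbind, lapply(seq_len(K), function(pos) {
    cbind(sub[, seq_len(pos - 1), drop = FALSE], K,
          sub[, seq(pos, K - 1, length.out = K - pos), drop = FALSE])
  }))
  storage.mode(out) <- "integer"
  out
}

#' Two-sided Fisher exact test
#'
#' Exact two-sided p for small contingency tables (hypergeometric
#' enumeration, via the standard exact machinery); a Monte-Carlo p with
#' 1e5 draws for larger tables (total count > 200). A table with an empty
#' margin yields p = 1 with a flag.
#'
#' @param table matrix of nonnegative integer counts.
#' @param seed optional seed for the Monte-Carlo branch.
#' @return list: `p`, `method`, `degenerate`.
#' @export
fisher_exact <- function(table, seed = NULL) {
  tab <- as.matrix(table)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(p = 1, method = "degenerate margin", degenerate = TRUE))
  if (sum(tab) <= 200 || (nrow(tab) == 2 && ncol(tab) == 2)) {
    list(p = stats::fisher.test(tab)$p.value, method = "exact",
         degenerate = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    list(p = stats::fisher.test(tab, simulate.p.value = TRUE,
                                B = 1e5)$p.value,
         method = "monte-carlo", degenerate = FALSE)
  }
}

#' K-means group finding on PC scores with a BIC curve
#'
#' Runs k-means on the retained principal component scores for each
#' candidate K and scores each solution as a spherical Gaussian mixture:
#' the cluster centers, mixing weights and the common variance
#' WSS/(n d) from the k-means solution define a mixture whose observed
#' log-likelihood enters BIC = -2 logL + (K d + K) log(n), lower better.
#' Scoring the mixture likelihood (rather than raw WSS) means a split
#' that merely halves one Gaussian gains almost nothing, so K tracks the
#' number of separated clusters instead of growing with every split.
#'
#' @param pca a [pca_genotypes()] result or a score matrix.
#' @param K_range candidate K values.
#' @param n_pc number of leading axes to use (default: all with positive
#'   eigenvalue, capped at 20).
#' @param seed optional seed for the k-means starts.
#' @return list: `K` (BIC-minimizing), `assignment` (for the selected K),
#'   `bic` (data.frame), `assignments` (list per K), `degenerate`.
#' @export
find_clusters_bic <- function(pca, K_range = 1:5, n_pc = NULL, seed = NULL) {
  scores <- if (inherits(pca, "geno_pca")) {
    npos <- sum(pca$eigenvalues > 1e-8)
    pca$scores[, seq_len(max(1, min(npos, 20))), drop = FALSE]
  } else as.matrix(pca)
  if (!is.null(n_pc)) scores <- scores[, seq_len(n_pc), drop = FALSE]
  n <- nrow(scores)
  stopifnot(all(K_range >= 1), all(K_range <= n))
  if (!is.null(seed)) set.seed(seed)
  total_ss <- sum(sweep(scores, 2, colMeans(scores))^2)
  degenerate <- total_ss < 1e-12
  d <- ncol(scores)
  mixture_ll <- function(centers, weights, sigma2) {
    sigma2 <- max(sigma2, 1e-12)
    lk <- sapply(seq_len(nrow(centers)), function(k) {
      dev <- sweep(scores, 2, centers[k, ])
      log(weights[k]) - rowSums(dev^2) / (2 * sigma2) -
        d / 2 * log(2 * pi * sigma2)
    })
    lk <- as.matrix(lk)
    mx <- apply(lk, 1, max)
    sum(mx + log(rowSums(exp(lk - mx))))
  }
  bic <- numeric(length(K_range))
  assignments <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    if (K == 1 || degenerate) {
      wss <- if (K == 1) total_ss else 0
      centers <- matrix(colMeans(scores), 1)
      weights <- 1
      assignments[[i]] <- rep(1L, n)
    } else {
      km <- stats::kmeans(scores, centers = K, nstart = 10, iter.max = 50)
      wss <- km$tot.withinss
      centers <- km$centers
      weights <- km$size / n
      assignments[[i]] <- km$cluster
    }
    ll <- mixture_ll(centers, weights, wss / (n * d))
    bic[i] <- -2 * ll + (K * d + K) * log(n)
  }
  sel <- which.min(bic)
  list(K = K_range[sel], assignment = assignments[[sel]],
       bic = data.frame(K = K_range, bic = bic),
       assignments = stats::setNames(assignments, K_range),
       degenerate = degenerate)
}

#' Assignment accuracy under the best label matching
#'
#' Fraction of individuals whose maximum-posterior group matches their
#' (size-class) label, maximized over label permutations - the standard
#' correction for arbitrary cluster labels. When the number of clusters
#' and labels differ, matching runs on the smaller set and the result is
#' flagged.
#'
#' @param posteriors individuals x groups posterior matrix (or a hard
#'   assignment vector).
#' @param labels per-individual reference labels.
#' @return list: `accuracy` (percent), `matching`, `flagged`.
#' @export
assignment_accuracy <- function(posteriors, labels) {
  hard <- if (is.matrix(posteriors)) max.col(posteriors)
    else as.integer(factor(posteriors))
  lab <- as.integer(factor(labels))
  stopifnot(length(hard) == length(lab))
  Kp <- max(hard); Kl <- max(lab)
  K <- max(Kp, Kl)
  flagged <- Kp != Kl
  perms <- .permutations(K)
  acc <- vapply(seq_len(nrow(perms)), function(i)
    mean(perms[i, ][hard] == lab), numeric(1))
  best <- which.max(acc)
  list(accuracy = 100 * acc[best], matching = perms[best, seq_len(Kp)],
       flagged = flagged)
}
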