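#' Estimate the biological intercept from the youngest fish
#'
#' The biological-intercept method anchors the body-length/otolith-radius
#' proportionality at size at hatch. Length at hatch is fixed at
#' `hatch_length` (17 mm by default); the matching hatch radius O_0 is
#' estimated by regressing log annual radius increments on annulus age for
#' the `n_youngest` youngest fish and extrapolating to age 0 - the growth
#' accrued by hatch. Increments are first differences of the annulus radii
#' (ages >= 2, so the unobserved hatch radius never enters the regression).
#'
#' @param otoliths long-format otolith table: `fish_id`, `age`, `radius`,
#'   `capture_radius`, `capture_length_mm` (one row per annulus).
#' @param n_youngest how many of the youngest fish feed the regression.
#' @param hatch_length length at hatch, mm.
#' @return list of class `biological_intercept`: `L_0`, `O_0`, the fitted
#'   regression coefficients, and the increment data used.
#' @export
estimate_biological_intercept <- function(otoliths, n_youngest = 5,
                                          hatch_length = 17) {
  stopifnot(all(c("fish_id", "age", "radius") %in% names(otoliths)))
  ages <- tapply(otoliths$age, otoliths$fish_id, max)
  if (length(ages) < n_youngest)
    stop("need at least ", n_youngest, " fish with otoliths")
  youngest <- names(sort(ages))[seq_len(n_youngest)]
  inc <- do.call(rbind, lapply(youngest, function(id) {
    d <- otoliths[otoliths$fish_id == id, ]
    d <- d[order(d$age), ]
    if (nrow(d) < 2) return(NULL)
    data.frame(fish_id = id, age = d$age[-1], increment = diff(d$radius))
  }))
  if (is.null(inc) || nrow(inc) < 2)
    stop("too few increments among the youngest fish")
  if (any(inc$increment <= 0)) stop("non-increasing annulus radii")
  if (stats::var(inc$age) == 0)
    stop("degenerate regression: all increments at one age")
  fit <- stats::lm(log(increment) ~ age, data = inc)
  O_0 <- exp(unname(stats::coef(fit)[1]))
  structure(list(L_0 = hatch_length, O_0 = O_0,
                 coef = stats::coef(fit),
                 resid_sd = stats::sd(stats::residuals(fit)),
                 increments = inc, fish_used = youngest),
            class = "biological_intercept")
}

#' Back-calculate lengths-at-age for one fish
#'
#' Campana's biological-intercept formula: the body-length/otolith-radius
#' relation is the line through (L_0, O_0) and (L_c, O_c), so
#' L_a = L_c + (O_a - O_c) (L_c - L_0) / (O_c - O_0).
#'
#' @param annulus_radii increasing vector of radii, one per age.
#' @param capture_radius otolith radius at capture (>= max annulus radius).
#' @param capture_length total length at capture, mm.
#' @param L_0 length at hatch, mm (default 17).
#' @param O_0 otolith radius at hatch (same units as the radii).
#' @return numeric vector of back-calculated lengths, one per annulus;
#'   nonpositive results are flagged with a warning.
#' @export
back_calculate <- function(annulus_radii, capture_radius, capture_length,
                           L_0 = 17, O_0) {
  stopifnot(length(capture_radius) == 1, length(capture_length) == 1)
  if (any(diff(annulus_radii) <= 0)) stop("annulus radii must be strictly increasing")
  if (max(annulus_radii) > capture_radius + 1e-9)
    stop("annulus radius exceeds capture radius")
  if (abs(capture_radius - O_0) < 1e-12)
    stop("capture radius equals hatch radius; slope undefined")
  L <- capture_length + (annulus_radii - capture_radius) *
    (capture_length - L_0) / (capture_radius - O_0)
  if (any(L <= 0)) warning("nonpositive back-calculated length(s)")
  L
}

#' Back-calculate lengths-at-age for every fish in an otolith table
#'
#' @param otoliths long-format otolith table (see
#'   [estimate_biological_intercept()]).
#' @param L_0,O_0 the biological intercept; `O_0` defaults to the estimate
#'   from the table itself.
#' @return data.frame `fish_id`, `age`, `length_mm`.
#' @export
back_calculate_all <- function(otoliths, L_0 = 17, O_0 = NULL) {
  if (is.null(O_0))
    O_0 <- estimate_biological_intercept(otoliths, hatch_length = L_0)$O_0
  out <- lapply(split(otoliths, otoliths$fish_id), function(d) {
    d <- d[order(d$age), ]
    data.frame(fish_id = d$fish_id[1], age = d$age,
               length_mm = back_calculate(d$radius, d$capture_radius[1],
                                          d$capture_length_mm[1], L_0, O_0))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-group growth summary of back-calculated lengths
#'
#' @param lengths data.frame `fish_id`, `age`, `length_mm` from
#'   [back_calculate_all()].
#' @param grouping named character vector mapping fish_id to group.
#' @return data.frame `group`, `age`, `mean_mm`, `sd_mm`, `n`; `sd_mm` is
#'   `NA` for single-fish cells.
#' @export
growth_summary <- function(lengths, grouping) {
  grp <- grouping[lengths$fish_id]
  if (any(is.na(grp))) stop("fish without a group assignment")
  agg <- split(lengths$length_mm, list(group = grp, age = lengths$age),
               drop = TRUE)
  out <- do.call(rbind, lapply(names(agg), function(k) {
    v <- agg[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(group = parts[1], age = as.integer(parts[2]),
               mean_mm = mean(v),
               sd_mm = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  out[order(out$group, out$age), ]
}
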