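#' Configuration for the synthetic char study generator
#'
#' Bundles every knob of the synthetic-study generator: the lake layout with
#' per-lake total-length mixtures, the hierarchical Balding--Nichols genotype
#' model (group level then lake level), planted sex-linked loci, the power-law
#' trait allometry, and the otolith growth model.
#'
#' Defaults emulate the study design the package targets: 233 fish across four
#' closed Fog lakes and three connected LTER lakes, two of which (Fog3,
#' LTER348) have bimodal length distributions; two lake groups diverged at
#' F_ST = 0.208 with weak structure (0.02) among lakes within a group; four
#' XY-like sex loci (heterozygous in males) plus one female-only-genotyped
#' locus planted on three of twelve chromosomes; trait allometry near
#' isometry with 5% lognormal noise; and otolith growth proportional to body
#' length anchored at a 17 mm hatch length.
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param lakes data.frame with columns `lake`, `group`, `n_fish`, and a
#'   list-column `mixture` of data.frames (`mean`, `sd`, `weight` in mm) giving
#'   each lake's total-length mixture. Defaults to the seven study lakes.
#' @param n_loci number of biallelic SNP loci (including planted sex loci).
#' @param fst_between_groups Balding--Nichols F separating the two lake groups.
#' @param fst_within_group Balding--Nichols F among lakes within a group.
#' @param maf_beta shape1/shape2 of the Beta distribution of ancestral allele
#'   frequencies.
#' @param missing_rate fraction of genotype calls masked at random.
#' @param n_sex_loci_xy number of planted XY-like loci (heterozygous in all
#'   males, homozygous reference in all females).
#' @param n_sex_loci_female_only number of planted loci genotyped only in
#'   females (missing in every male).
#' @param n_sex_assoc_loci number of weakly sex-associated loci planted on
#'   the sex chromosomes (allele-frequency shift `sex_assoc_dp` between the
#'   sexes). These emulate the halo of partially sex-linked variation a
#'   sex-determining region carries: they give the sex-difference axis
#'   enough weight to surface among the leading principal components, but
#'   individually they never satisfy the strict heterozygosity/call-rate
#'   detection patterns.
#' @param sex_assoc_dp allele-frequency difference (males minus females) at
#'   the weakly sex-associated loci.
#' @param sex_error_rate per-call rate at which a planted sex-locus genotype
#'   deviates from its sex pattern (<= 0.01).
#' @param n_chrom number of simulated chromosomes; sex loci are confined to
#'   the last three.
#' @param allometry data.frame with columns `trait`, `a`, `b`, `sigma`: the
#'   per-trait power law M = a * L^b * exp(N(0, sigma^2)).
#' @param otolith list with `hatch_length` (mm, default 17), `hatch_radius`
#'   (otolith units laid down by hatch), `decay` (exponential decay rate of
#'   annual radius increments), `noise_sd` (lognormal sd on increments), and
#'   `n_per_group` (otoliths sampled per lake group).
#' @param n_known_sex number of individuals whose sex is recorded as known
#'   (balanced between the sexes).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lakes = default_lake_design(),
                       n_loci = 15000L,
                       fst_between_groups = 0.208,
                       fst_within_group = 0.02,
                       maf_beta = c(0.8, 0.8),
                       missing_rate = 0.1,
                       n_sex_loci_xy = 4L,
                       n_sex_loci_female_only = 1L,
                       n_sex_assoc_loci = round(0.024 * n_loci),
                       sex_assoc_dp = 0.4,
                       sex_error_rate = 0,
                       n_chrom = 12L,
                       allometry = default_allometry(),
                       otolith = list(hatch_length = 17, hatch_radius = 0.15,
                                      decay = 0.35, noise_sd = 0.05,
                                      n_per_group = 18L),
                       n_known_sex = 6L) {
  stopifnot(is.data.frame(lakes),
            all(c("lake", "group", "n_fish", "mixture") %in% names(lakes)),
            n_loci >= n_sex_loci_xy + n_sex_loci_female_only +
              n_sex_assoc_loci,
            n_sex_assoc_loci >= 0, sex_assoc_dp >= 0, sex_assoc_dp < 0.5,
            fst_between_groups >= 0, fst_between_groups < 1,
            fst_within_group >= 0, fst_within_group < 1,
            missing_rate >= 0, missing_rate <= 1,
            sex_error_rate >= 0, sex_error_rate <= 0.01,
            n_chrom >= 4,
            otolith$hatch_length > 0, otolith$hatch_radius > 0,
            otolith$decay > 0, otolith$noise_sd >= 0)
  for (m in lakes$mixture) {
    stopifnot(is.data.frame(m), all(c("mean", "sd", "weight") %in% names(m)),
              all(m$sd >= 0), all(m$weight >= 0))
    if (abs(sum(m$weight) - 1) > 1e-8)
      stop("mixture weights within a lake must sum to 1")
  }
  structure(list(seed = as.integer(seed), lakes = lakes,
                 n_loci = as.integer(n_loci),
                 fst_between_groups = fst_between_groups,
                 fst_within_group = fst_within_group,
                 maf_beta = maf_beta, missing_rate = missing_rate,
                 n_sex_loci_xy = as.integer(n_sex_loci_xy),
                 n_sex_loci_female_only = as.integer(n_sex_loci_female_only),
                 n_sex_assoc_loci = as.integer(n_sex_assoc_loci),
                 sex_assoc_dp = sex_assoc_dp,
                 sex_error_rate = sex_error_rate,
                 n_chrom = as.integer(n_chrom),
                 allometry = allometry, otolith = otolith,
                 n_known_sex = as.integer(n_known_sex)),
            class = "sim_config")
}

#' Default lake layout for the synthetic study
#'
#' Seven lakes in two groups with sample sizes and total-length structure
#' mirroring the study catch: unimodal lengths everywhere except Fog3 and
#' LTER348, which carry bimodal mixtures (a dwarf/small component alongside
#' the normal one).
#'
#' @return data.frame with columns `lake`, `group`, `n_fish`, `mixture`.
#' @export
default_lake_design <- function() {
  mix <- function(mean, sd, weight = rep(1 / length(mean), length(mean)))
    data.frame(mean = mean, sd = sd, weight = weight)
  d <- data.frame(
    lake = c("Fog1", "Fog2", "Fog3", "Fog5", "LTER345", "LTER347", "LTER348"),
    group = c("Fog", "Fog", "Fog", "Fog", "LTER", "LTER", "LTER"),
    n_fish = c(19L, 2L, 77L, 18L, 29L, 24L, 64L),
    stringsAsFactors = FALSE
  )
  d$mixture <- list(
    mix(344, 45), mix(254, 90),
    mix(c(159, 338), c(16, 55), c(0.58, 0.42)),
    mix(351, 55), mix(485, 55), mix(447, 70),
    mix(c(400, 565), c(45, 25), c(0.75, 0.25))
  )
  d
}

#' Default trait allometry for the nine linear measurements
#'
#' Power-law coefficients M = a * L^b for snout length (SL), eye width (EW),
#' maxilla length (ML), head depth (HD), head length (HL), body depth
#' posterior (BDP), body depth anterior (BDA), postpelvic fin length (PPF)
#' and caudal peduncle depth (CP), with lognormal residual sd `sigma` on the
#' log scale. Exponents sit around 1 (near-isometric growth with mild
#' positive allometry in jaw and body-depth traits).
#'
#' @return data.frame with columns `trait`, `a`, `b`, `sigma`.
#' @export
default_allometry <- function() {
  data.frame(
    trait = c("SL", "EW", "ML", "HD", "HL", "BDP", "BDA", "PPF", "CP"),
    a = c(0.020, 0.110, 0.024, 0.085, 0.210, 0.065, 0.080, 0.095, 0.052),
    b = c(1.10, 0.80, 1.12, 1.02, 0.98, 1.08, 1.06, 1.00, 0.96),
    sigma = rep(0.05, 9),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-fish phenotypes
#'
#' Draws each fish's total length from its lake's Gaussian mixture (negative
#' draws rejected and redrawn), generates the nine linear traits from the
#' configured power-law allometry with lognormal noise, assigns sex 1:1 at
#' random, and marks a balanced subset of fish as being of known sex. The
#' mixture component a length was drawn from is recorded as the true size
#' class.
#'
#' @param cfg a [sim_config()].
#' @return data.frame of fish records: `id`, `lake`, `group`,
#'   `total_length_mm`, one column per trait (`SL` ... `CP`), `sex`,
#'   `known_sex`, `true_size_class`.
#' @export
simulate_phenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  al <- cfg$allometry
  stopifnot(all(al$a > 0), all(al$sigma >= 0))
  rows <- vector("list", nrow(cfg$lakes))
  for (i in seq_len(nrow(cfg$lakes))) {
    lk <- cfg$lakes[i, ]
    m <- lk$mixture[[1]]
    n <- lk$n_fish
    comp <- sample.int(nrow(m), n, replace = TRUE, prob = m$weight)
    len <- stats::rnorm(n, m$mean[comp], m$sd[comp])
    while (any(bad <- len <= 0))
      len[bad] <- stats::rnorm(sum(bad), m$mean[comp[bad]], m$sd[comp[bad]])
    df <- data.frame(lake = lk$lake, group = lk$group,
                     total_length_mm = len,
                     true_size_class = comp, stringsAsFactors = FALSE)
    rows[[i]] <- df
  }
  fish <- do.call(rbind, rows)
  fish$id <- sprintf("fish%03d", seq_len(nrow(fish)))
  for (j in seq_len(nrow(al))) {
    eps <- stats::rnorm(nrow(fish), 0, al$sigma[j])
    fish[[al$trait[j]]] <- al$a[j] * fish$total_length_mm^al$b[j] * exp(eps)
  }
  fish$sex <- sample(c("male", "female"), nrow(fish), replace = TRUE)
  fish$known_sex <- FALSE
  k <- cfg$n_known_sex
  if (k > 0) {
    males <- which(fish$sex == "male")
    females <- which(fish$sex == "female")
    nm <- min(length(males), ceiling(k / 2))
    nf <- min(length(females), k - nm)
    fish$known_sex[c(males[seq_len(nm)], females[seq_len(nf)])] <- TRUE
  }
  fish[, c("id", "lake", "group", "total_length_mm", al$trait,
           "sex", "known_sex", "true_size_class")]
}

#' Simulate genotypes under a two-level Balding--Nichols model
#'
#' Ancestral allele frequencies are drawn from the configured Beta
#' distribution; group-level frequencies from Beta(p(1-F)/F, (1-p)(1-F)/F)
#' with F = `fst_between_groups`, and lake-level frequencies from the same
#' construction around the group frequency with F = `fst_within_group`
#' (F = 0 collapses to the degenerate limit: frequencies identical across
#' demes). Diploid genotypes are binomial draws; missing calls are planted
#' uniformly at random. Planted sex loci override the neutral draw: XY-like
#' loci are heterozygous in every male and homozygous reference in every
#' female (up to `sex_error_rate`); female-only loci are missing in every
#' male. Sex loci are confined to the last three chromosomes so that
#' whole-chromosome exclusion can be exercised downstream.
#'
#' @param cfg a [sim_config()].
#' @param fish fish table from [simulate_phenotypes()] (supplies ids, lakes
#'   and sexes). Generated from `cfg` if omitted.
#' @return A [genotype_matrix()] whose `truth` attribute records the planted
#'   sex-locus indices and the group/lake allele frequencies.
#' @export
simulate_genotypes <- function(cfg, fish = simulate_phenotypes(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(fish)
  L <- cfg$n_loci
  groups <- unique(cfg$lakes$group)
  lakes <- cfg$lakes$lake

  p_anc <- stats::rbeta(L, cfg$maf_beta[1], cfg$maf_beta[2])
  p_anc <- pmin(pmax(p_anc, 0.02), 0.98)

  bn_draw <- function(p, f) {
    # Balding-Nichols deme frequencies; F = 0 is the degenerate limit
    if (f == 0) return(p)
    p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  p_group <- sapply(groups, function(g) bn_draw(p_anc, cfg$fst_between_groups))
  p_lake <- sapply(lakes, function(lk) {
    g <- cfg$lakes$group[cfg$lakes$lake == lk]
    bn_draw(p_group[, g], cfg$fst_within_group)
  })

  values <- matrix(0L, n, L, dimnames = list(fish$id, NULL))
  for (lk in lakes) {
    idx <- which(fish$lake == lk)
    if (!length(idx)) next
    values[idx, ] <- matrix(
      stats::rbinom(length(idx) * L, 2L, rep(p_lake[, lk], each = length(idx))),
      nrow = length(idx))
  }

  # chromosome layout: loci spread over n_chrom chromosomes, positions strictly
  # increasing; sex loci live on the last three chromosomes only
  chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chrom))
  chrom <- sort(sample.int(cfg$n_chrom, L, replace = TRUE))
  pos <- integer(L)
  for (c in seq_len(cfg$n_chrom)) {
    idx <- which(chrom == c)
    if (length(idx))
      pos[idx] <- sort(sample.int(length(idx) * 500L, length(idx)))
  }

  n_sex <- cfg$n_sex_loci_xy + cfg$n_sex_loci_female_only +
    cfg$n_sex_assoc_loci
  sex_chroms <- chrom_names[(cfg$n_chrom - 2):cfg$n_chrom]
  sex_idx <- integer(0)
  if (n_sex > 0) {
    pool <- which(chrom >= cfg$n_chrom - 2)
    if (length(pool) < n_sex)
      stop("too few loci on the sex chromosomes to plant sex loci")
    # spread planted loci over all three dedicated chromosomes
    ord <- pool[order(stats::runif(length(pool)))]
    picked <- integer(0)
    for (c in (cfg$n_chrom - 2):cfg$n_chrom)
      picked <- c(picked, ord[chrom[ord] == c][1])
    picked <- picked[!is.na(picked)]
    sex_idx <- unique(c(picked, ord))[seq_len(n_sex)]
  }
  xy_idx <- head(sex_idx, cfg$n_sex_loci_xy)
  fo_idx <- head(sex_idx[-seq_len(cfg$n_sex_loci_xy)],
                 cfg$n_sex_loci_female_only)
  assoc_idx <- tail(sex_idx, cfg$n_sex_assoc_loci)
  if (cfg$n_sex_loci_female_only == 0) fo_idx <- integer(0)
  if (cfg$n_sex_assoc_loci == 0) assoc_idx <- integer(0)

  male <- fish$sex == "male"
  for (l in xy_idx) {
    g <- ifelse(male, 1L, 0L)
    if (cfg$sex_error_rate > 0) {
      flip <- stats::runif(n) < cfg$sex_error_rate
      g[flip] <- sample(0:2, sum(flip), replace = TRUE)
    }
    values[, l] <- g
  }
  for (l in fo_idx)
    values[!male, l] <- stats::rbinom(sum(!male), 2L, 0.5)
  if (length(assoc_idx)) {
    pf <- stats::runif(length(assoc_idx), 0.05, 0.95 - cfg$sex_assoc_dp)
    for (j in seq_along(assoc_idx)) {
      l <- assoc_idx[j]
      values[!male, l] <- stats::rbinom(sum(!male), 2L, pf[j])
      values[male, l] <- stats::rbinom(sum(male), 2L,
                                       pf[j] + cfg$sex_assoc_dp)
    }
  }

  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    values[miss] <- NA_integer_
  }
  for (l in fo_idx) values[male, l] <- NA_integer_

  loci <- data.frame(
    id = sprintf("%s_%d", chrom_names[chrom], pos),
    chrom = chrom_names[chrom], pos = pos,
    ref = "A", alt = "G", counted = "alt",
    stringsAsFactors = FALSE)
  indiv <- fish[, c("id", "lake", "group", "sex", "known_sex",
                    "total_length_mm")]
  g <- genotype_matrix(values, loci, indiv)
  attr(g, "truth") <- list(
    sex_loci_xy = xy_idx, sex_loci_female_only = fo_idx,
    sex_loci_assoc = assoc_idx, sex_chromosomes = sex_chroms,
    p_anc = p_anc, p_group = p_group, p_lake = p_lake)
  g
}

#' Simulate otolith increment series
#'
#' For a subset of fish (default 18 per lake group, spanning the length
#' range), draws an integer age from the fish's growth type (dwarf mixture
#' components grow slowly, so reach a given length at an older age), then
#' builds the otolith radius series: annual radius increments decay
#' exponentially with age at rate `decay`, the radius laid down by hatch is
#' `hatch_radius`, and body length is affine in otolith radius through the
#' biological intercept (17 mm, `hatch_radius`), so that each fish's
#' trajectory ends exactly at its capture length. Lognormal noise with sd
#' `noise_sd` multiplies the increments (monotonicity is preserved).
#'
#' @param cfg a [sim_config()].
#' @param fish fish table from [simulate_phenotypes()].
#' @return data.frame with columns `fish_id`, `age` (annulus index),
#'   `radius`, `capture_radius`, `capture_length_mm`, `age_at_capture`, plus
#'   a `truth` attribute holding the true lengths-at-age and hatch radius.
#' @export
simulate_otoliths <- function(cfg, fish) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  ot <- cfg$otolith
  picks <- unlist(lapply(split(seq_len(nrow(fish)), fish$group), function(idx) {
    n <- min(length(idx), ot$n_per_group)
    idx[order(fish$total_length_mm[idx])][unique(round(seq(1, length(idx),
                                                           length.out = n)))]
  }), use.names = FALSE)
  # dwarf components (mixture mean < 250 mm) grow slowly: older at a given size
  slow <- vapply(picks, function(i) {
    m <- cfg$lakes$mixture[[match(fish$lake[i], cfg$lakes$lake)]]
    m$mean[fish$true_size_class[i]] < 250
  }, logical(1))
  growth_per_year <- ifelse(slow, 24, 55)
  rows <- vector("list", length(picks))
  truth <- vector("list", length(picks))
  for (j in seq_along(picks)) {
    i <- picks[j]
    L_c <- fish$total_length_mm[i]
    age <- max(2L, min(15L, as.integer(round((L_c - ot$hatch_length) /
                                               growth_per_year[j]))))
    inc_true <- ot$hatch_radius * exp(-ot$decay * (0:age))  # age-0 = hatch
    R_true <- cumsum(inc_true)
    k <- (L_c - ot$hatch_length) / (R_true[age + 1] - R_true[1])
    len_true <- ot$hatch_length + k * (R_true - R_true[1])
    inc_obs <- inc_true
    if (ot$noise_sd > 0)
      inc_obs[-1] <- inc_true[-1] * exp(stats::rnorm(age, 0, ot$noise_sd))
    R_obs <- cumsum(inc_obs)
    rows[[j]] <- data.frame(
      fish_id = fish$id[i], age = 1:age, radius = R_obs[-1],
      capture_radius = R_obs[age + 1], capture_length_mm = L_c,
      age_at_capture = age, stringsAsFactors = FALSE)
    truth[[j]] <- data.frame(fish_id = fish$id[i], age = 0:age,
                             length_mm = len_true, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(lengths_at_age = do.call(rbind, truth),
                             hatch_radius = ot$hatch_radius,
                             hatch_length = ot$hatch_length)
  out
}

#' Generate a complete synthetic study
#'
#' Orchestrates [simulate_phenotypes()], [simulate_genotypes()] and
#' [simulate_otoliths()] under one seed and bundles the results with the
#' study-lake table and the planted truth.
#'
#' @param cfg a [sim_config()].
#' @return list of class `synthetic_study` with elements `fish`, `genotypes`,
#'   `otoliths`, `lakes`, `truth`, `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  fish <- simulate_phenotypes(cfg)
  geno <- simulate_genotypes(cfg, fish)
  oto <- simulate_otoliths(cfg, fish)
  truth <- c(attr(geno, "truth"),
             list(otolith = attr(oto, "truth"),
                  size_class = fish$true_size_class, sex = fish$sex))
  structure(list(fish = fish, genotypes = geno, otoliths = oto,
                 lakes = study_lakes(), truth = truth, config = cfg),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Genotypes go to VCF 4.2 (`GT` field, `./.` for missing calls), fish, lakes
#' and otoliths to tab-separated tables, and the planted truth to JSON.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             fish = file.path(dir, "fish.tsv"),
             lakes = file.path(dir, "lakes.tsv"),
             otoliths = file.path(dir, "otoliths.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(study$genotypes, paths["vcf"])
  utils::write.table(study$fish, paths["fish"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(study$lakes, paths["lakes"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(study$otoliths, paths["otoliths"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tr <- study$truth
  jsonlite::write_json(list(sex_loci_xy = tr$sex_loci_xy,
                            sex_loci_female_only = tr$sex_loci_female_only,
                            sex_chromosomes = tr$sex_chromosomes,
                            size_class = tr$size_class, sex = tr$sex),
                       paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}
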