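#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates the stages in dependency order - simulate, morphometrics
#' (allometric adjustment plus raw and adjusted clustering), growth
#' (biological-intercept back-calculation), SNP filtering, sex-linkage
#' detection and chromosome removal, divergence/diversity statistics,
#' ancestry/stock structure within the bimodal lakes, and the PERMANOVA
#' model search over lake-level predictors - writing each stage's artifacts
#' under `outdir` together with a manifest (parameters, seed, file hashes)
#' and a terminal report JSON of headline results. A stage failure halts
#' the downstream stages; the partial manifest is preserved.
#'
#' @param cfg a [sim_config()] driving the synthetic study.
#' @param outdir output directory.
#' @param stages which stages to run (dependency order is enforced).
#' @param filter_cfg a [snp_filter_config()].
#' @param k_range candidate K values for the within-lake ancestry CV.
#' @param cv_folds folds for [choose_k_cv()].
#' @param n_boot bootstrap replicates for F_ST CIs and stock assignments.
#' @param n_perm PERMANOVA permutations.
#' @param structure_loci cap on the number of loci used by the within-lake
#'   structure stage (`Inf` for all retained loci).
#' @return list of class `pipeline_report` (also written as report.json).
#' @export
run_pipeline <- function(cfg = sim_config(), outdir,
                         stages = c("simulate", "morpho", "growth", "filter",
                                    "sexlink", "popstats", "structure",
                                    "permanova"),
                         filter_cfg = snp_filter_config(),
                         k_range = 1:5, cv_folds = 10, n_boot = 100,
                         n_perm = 999, structure_loci = Inf) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, stages_run = character(0))
  manifest <- list(seed = cfg$seed, started = format(Sys.time()),
                   stages = stages)
  save_manifest <- function() {
    manifest$files <- as.list(tools::md5sum(
      list.files(outdir, full.names = TRUE, pattern = "\\.(tsv|vcf|json)$")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  on.exit(save_manifest())

  study <- NULL
  run <- function(name) name %in% stages

  if (run("simulate")) {
    study <- simulate_study(cfg)
    write_study(study, outdir)
    report$stages_run <- c(report$stages_run, "simulate")
    report$n_fish <- nrow(study$fish)
    report$n_loci <- ncol(study$genotypes$values)
  }
  if (is.null(study)) stop("pipeline requires the simulate stage")
  fish <- study$fish
  traits <- default_allometry()$trait

  if (run("morpho")) {
    allo <- fit_allometric_slope(fish[, traits], fish$total_length_mm)
    adj <- size_adjust_fish(fish, allo)
    gmm_raw <- gmm_cluster(fish[, traits], K_max = 5)
    gmm_adj <- gmm_cluster(adj[, traits], K_max = 5)
    fish <- assign_size_classes(gmm_raw, fish)
    utils::write.table(fish[, c("id", "lake", "group", "total_length_mm",
                                "size_class")],
                       file.path(outdir, "size_classes.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    report$stages_run <- c(report$stages_run, "morpho")
    report$morpho <- list(K_raw = gmm_raw$K, K_adjusted = gmm_adj$K,
                          delta_bic_raw = gmm_raw$delta_bic,
                          delta_bic_adjusted = gmm_adj$delta_bic,
                          L_m = allo$L_m)
  }

  if (run("growth")) {
    bi <- estimate_biological_intercept(study$otoliths,
                                        hatch_length = cfg$otolith$hatch_length)
    bc <- back_calculate_all(study$otoliths, L_0 = bi$L_0, O_0 = bi$O_0)
    grp <- stats::setNames(fish$group, fish$id)
    gs <- growth_summary(bc, grp)
    utils::write.table(gs, file.path(outdir, "growth_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages_run <- c(report$stages_run, "growth")
    report$growth <- list(O_0 = bi$O_0, L_0 = bi$L_0,
                          n_fish = length(unique(bc$fish_id)))
  }

  # sex screening runs before site filters: loci genotyped in only one sex
  # carry their signal in the missingness pattern and would be discarded by
  # a site-missingness filter
  geno <- study$genotypes
  if (run("sexlink")) {
    pc <- pca_genotypes(genotype_covariance(geno))
    known <- stats::setNames(fish$sex, fish$id)[fish$known_sex]
    known <- known[names(known) %in% geno$indiv$id]
    sexgrp <- infer_sex_groups(pc, known)
    sl <- detect_sex_linked(geno, sexgrp$putative_sex)
    utils::write.table(sl$candidates, file.path(outdir, "sexlink.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    sex_fst <- fst_genotypes(
      geno, which(sexgrp$putative_sex[geno$indiv$id] == "male"),
      which(sexgrp$putative_sex[geno$indiv$id] == "female"),
      labels = c("male", "female"))
    geno <- drop_sex_chromosomes(geno, sl)
    report$stages_run <- c(report$stages_run, "sexlink")
    report$sexlink <- list(
      axis = sexgrp$axis, n_detected = nrow(sl$detected),
      flagged_chromosomes = sl$flagged_chromosomes,
      fst_between_sexes = sex_fst$estimate)
  }

  if (run("filter")) {
    geno <- filter_genotypes(geno, filter_cfg)
    report$stages_run <- c(report$stages_run, "filter")
    report$filter <- attr(geno, "filter_report")
  }

  if (run("popstats")) {
    ids <- geno$indiv$id
    grp <- geno$indiv$group
    groups <- unique(grp)
    fst_groups <- fst_genotypes(geno, which(grp == groups[1]),
                                which(grp == groups[2]), labels = groups)
    fst_groups <- fst_bootstrap_ci(fst_groups, n_boot = n_boot,
                                   seed = cfg$seed + 11L)
    lake_pairs <- list()
    for (g1 in groups) {
      lakes_in <- unique(geno$indiv$lake[grp == g1])
      if (length(lakes_in) >= 2) {
        prs <- utils::combn(lakes_in, 2, simplify = FALSE)
        for (pr in prs) {
          n1 <- sum(geno$indiv$lake == pr[1])
          n2 <- sum(geno$indiv$lake == pr[2])
          if (n1 < 2 || n2 < 2) next
          lake_pairs[[paste(pr, collapse = "-")]] <- fst_genotypes(
            geno, which(geno$indiv$lake == pr[1]),
            which(geno$indiv$lake == pr[2]), labels = pr)$estimate
        }
      }
    }
    div <- lapply(groups, function(g1)
      het_fis(geno, which(grp == g1), unit = g1))
    theta <- lapply(groups, function(g1)
      watterson_theta(geno, which(grp == g1))$theta_w)
    names(theta) <- groups
    div_tab <- do.call(rbind, lapply(div, function(d)
      data.frame(unit = d$unit, Ho = d$Ho, He = d$He, fis = d$fis,
                 n = d$n_individuals)))
    div_tab$theta_w <- unlist(theta)[div_tab$unit]
    utils::write.table(div_tab, file.path(outdir, "diversity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages_run <- c(report$stages_run, "popstats")
    report$popstats <- list(
      fst_groups = fst_groups$estimate,
      fst_groups_ci = c(fst_groups$ci_low, fst_groups$ci_high),
      fst_within_group_pairs = lake_pairs,
      theta_w = theta,
      fis = stats::setNames(vapply(div, `[[`, numeric(1), "fis"), groups))
  }

  if (run("structure")) {
    bimodal <- names(which(vapply(split(fish$true_size_class, fish$lake),
                                  function(x) length(unique(x)) > 1,
                                  logical(1))))
    bimodal <- intersect(bimodal, unique(geno$indiv$lake))
    res <- list()
    for (lk in bimodal) {
      idx <- which(geno$indiv$lake == lk)
      if (length(idx) < 10) next
      glake <- subset_genotypes(geno, indiv = idx)
      v <- maf(glake)
      keep <- which(!is.na(v) & v > filter_cfg$min_maf)
      if (length(keep) > structure_loci)
        keep <- sort(sample(keep, structure_loci))
      glake <- subset_genotypes(glake, loci = keep)
      cv <- choose_k_cv(glake, K_range = k_range, n_folds = cv_folds,
                        seed = cfg$seed + 23L)
      sc <- fish$size_class[match(glake$indiv$id, fish$id)]
      stocks <- stock_mixture_em(glake, K = 2, n_boot = n_boot,
                                 seed = cfg$seed + 29L, size_class = sc)
      res[[lk]] <- list(K_cv = cv$K, cv_error = cv$cv$cv_error,
                        fisher_p = stocks$fisher_p,
                        mean_support = mean(stocks$support))
    }
    report$stages_run <- c(report$stages_run, "structure")
    report$structure <- res
  }

  if (run("permanova")) {
    lakes <- study$lakes
    lakes$density_area <- char_density(lakes$abundance, lakes$surface_area_ha)
    li <- match(fish$lake, lakes$lake)
    predictors <- data.frame(
      group = lakes$group[li], secchi = lakes$secchi_depth_m[li],
      density_area = lakes$density_area[li],
      max_depth = lakes$max_depth_m[li], area = lakes$surface_area_ha[li])
    ms <- model_search(as.matrix(fish[, traits]), predictors,
                       candidates = names(predictors), max_terms = 3,
                       n_perm = n_perm, seed = cfg$seed + 31L)
    utils::write.table(ms$table, file.path(outdir, "permanova_models.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages_run <- c(report$stages_run, "permanova")
    report$permanova <- list(best_model = ms$best,
                             n_models = nrow(ms$table))
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  class(report) <- "pipeline_report"
  report
}
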