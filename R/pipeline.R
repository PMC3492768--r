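#' Pipeline configuration
#'
#' Bundles paths or in-memory inputs, seeds, permutation counts and alpha
#' levels for [run_pipeline()]. Inputs may be given as file paths (Genepop /
#' CSV, read with the package readers) or as already-constructed objects; a
#' `sim` block generates a fully synthetic run instead.
#'
#' @param genotypes a [genotype_matrix()] or Genepop path (optional if `sim`).
#' @param morphology a morphology data.frame or CSV path (optional if `sim`).
#' @param sites a site table or CSV path (optional if `sim`).
#' @param distances a distance matrix or CSV path (optional; without it the
#'   isolation-by-distance stage is skipped).
#' @param sim optional [sim_config()]; when present all four inputs are
#'   simulated and explicit inputs must be absent.
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed for all permutation tests.
#' @param n_perm_hwe,n_perm_ld,n_perm_mantel,n_perm_sexbias permutation
#'   counts per test family.
#' @param alpha_hwe_ld alpha for the HWE/LD Bonferroni families.
#' @param alpha alpha for the sequential-Bonferroni trait families.
#' @param ratio_c_h2 P_ST scaling ratio (see [pst()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, morphology = NULL, sites = NULL,
                            distances = NULL, sim = NULL, out_dir = NULL,
                            seed = 1L, n_perm_hwe = 1000, n_perm_ld = 500,
                            n_perm_mantel = 9999, n_perm_sexbias = 199,
                            alpha_hwe_ld = 0.01, alpha = 0.05,
                            ratio_c_h2 = 1) {
  if (!is.null(sim) && (!is.null(genotypes) || !is.null(morphology) ||
                        !is.null(sites) || !is.null(distances)))
    stop("give either a sim block or explicit inputs, not both")
  if (is.null(sim) && (is.null(genotypes) || is.null(morphology) ||
                       is.null(sites)))
    stop("genotypes, morphology and sites are required without a sim block")
  structure(list(genotypes = genotypes, morphology = morphology,
                 sites = sites, distances = distances, sim = sim,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_perm_hwe = n_perm_hwe, n_perm_ld = n_perm_ld,
                 n_perm_mantel = n_perm_mantel,
                 n_perm_sexbias = n_perm_sexbias,
                 alpha_hwe_ld = alpha_hwe_ld, alpha = alpha,
                 ratio_c_h2 = ratio_c_h2),
            class = "pipeline_config")
}

.load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

.write_stage <- function(df, out_dir, name) {
  if (!is.null(out_dir))
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  invisible(df)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order: diversity summaries with HWE/LD
#' tests, global and per-sex Weir-Cockerham F_ST with jackknife CIs,
#' sex-biased dispersal tests (vAIc and per-sex F_ST), isolation by distance
#' (Rousset-linearized pairwise F_ST against log distance, Mantel test, per
#' sex), pairwise P_ST per trait and sex with the P_ST-vs-F_ST verdict, and
#' the condition-index selection scan. Per-stage CSVs and a machine-readable
#' JSON summary are written when `out_dir` is set; the summary is also
#' returned.
#'
#' @param config a [pipeline_config()].
#' @return list with per-stage results and a `summary` element holding the
#'   headline verdicts (missing-data percentage, global/per-sex theta, IBD
#'   Mantel r and p per sex, sex-bias p-values, P_ST verdict per trait/sex,
#'   selection modes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$out_dir) &&
      !dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  od <- config$out_dir

  if (!is.null(config$sim)) {
    dat <- simulate_dataset(config$sim)
    gm <- dat$genotypes; morph <- dat$morphology
    sites <- dat$sites; dist_km <- dat$distances
  } else {
    gm <- .load_input(config$genotypes, read_genepop)
    morph <- .load_input(config$morphology, read_morphology)
    sites <- .load_input(config$sites, read_sites)
    dist_km <- .load_input(config$distances, read_distances)
    # Genepop blocks carry no explicit site names; when the labels recovered
    # from the file are disjoint from the site table, map blocks to the site
    # table in order
    gm_sites <- unique(gm$site)
    if (!any(gm_sites %in% sites$site)) {
      if (length(gm_sites) != nrow(sites))
        stop("cannot reconcile genotype population blocks with the site table")
      message("mapping ", length(gm_sites),
              " genotype population blocks onto the site table in order")
      gm$site <- sites$site[match(gm$site, gm_sites)]
    }
  }

  res <- list(config = config)

  ## stage 1: diversity, HWE, LD -------------------------------------------
  ms <- missing_summary(gm)
  div <- allele_stats(gm, by_site = TRUE)
  .write_stage(div, od, "diversity")

  hwe <- list(); seed_i <- config$seed
  for (s in unique(gm$site)) for (l in gm$locus_names) {
    seed_i <- seed_i + 1L
    hwe[[length(hwe) + 1L]] <- hwe_test(gm, l, s, config$n_perm_hwe, seed_i)
  }
  hwe <- do.call(rbind, hwe)
  tested <- !hwe$skipped
  hwe$significant <- FALSE
  hwe$significant[tested] <- holm_adjust(hwe$p[tested], config$alpha_hwe_ld)
  .write_stage(hwe, od, "hwe_tests")

  ld <- list()
  pairs <- utils::combn(gm$locus_names, 2)
  for (s in unique(gm$site)) for (p in seq_len(ncol(pairs))) {
    seed_i <- seed_i + 1L
    ld[[length(ld) + 1L]] <- ld_test(gm, pairs[1, p], pairs[2, p], s,
                                     config$n_perm_ld, seed_i)
  }
  ld <- do.call(rbind, ld)
  tested <- !ld$skipped
  ld$significant <- FALSE
  ld$significant[tested] <- holm_adjust(ld$p[tested], config$alpha_hwe_ld)
  .write_stage(ld, od, "ld_tests")
  res$diversity <- div; res$hwe <- hwe; res$ld <- ld

  ## stage 2: F_ST ----------------------------------------------------------
  fst_global <- wc_fst(gm, ci = TRUE)
  fst_by_sex <- lapply(c(male = "male", female = "female"), function(sx)
    wc_fst(subset_genotypes(gm, individuals = gm$sex == sx), ci = TRUE))
  pw <- lapply(c(male = "male", female = "female"), function(sx)
    pairwise_fst(subset_genotypes(gm, individuals = gm$sex == sx)))
  pw$all <- pairwise_fst(gm)
  res$fst <- list(global = fst_global, by_sex = fst_by_sex, pairwise = pw)
  .write_stage(data.frame(scope = c("global", "male", "female"),
                          theta = c(fst_global$theta, fst_by_sex$male$theta,
                                    fst_by_sex$female$theta),
                          ci_lower = c(fst_global$ci[1],
                                       fst_by_sex$male$ci[1],
                                       fst_by_sex$female$ci[1]),
                          ci_upper = c(fst_global$ci[2],
                                       fst_by_sex$male$ci[2],
                                       fst_by_sex$female$ci[2])),
               od, "fst")

  ## stage 3: sex-biased dispersal ------------------------------------------
  has_sexes <- all(c("male", "female") %in% gm$sex)
  if (has_sexes) {
    sb_vaic <- sex_bias_test(gm, "vAIc", config$n_perm_sexbias,
                             config$seed + 7001L, direction = "male_less")
    sb_fst <- sex_bias_test(gm, "per_sex_FST", config$n_perm_sexbias,
                            config$seed + 7002L, direction = "male_greater")
    sexbias <- data.frame(statistic = c(sb_vaic$statistic, sb_fst$statistic),
                          male = c(sb_vaic$male, sb_fst$male),
                          female = c(sb_vaic$female, sb_fst$female),
                          direction = c(sb_vaic$direction, sb_fst$direction),
                          p = c(sb_vaic$p, sb_fst$p),
                          n_permutations = config$n_perm_sexbias)
    res$sex_bias <- sexbias
    .write_stage(sexbias, od, "sex_bias")
  } else res$sex_bias <- NULL

  ## stage 4: isolation by distance -----------------------------------------
  if (!is.null(dist_km)) {
    ibd <- lapply(c(male = "male", female = "female", all = "all"),
                  function(sx) {
      m <- pw[[sx]]
      dsub <- dist_km[rownames(m), colnames(m)]
      lin <- linearize_fst(m)
      if (any(!is.finite(lin[upper.tri(lin)]))) return(NULL)
      mt <- mantel_test(lin, dsub, n_perm = config$n_perm_mantel,
                        seed = config$seed + 8000L, transform_b = "log")
      data.frame(scope = sx, r = mt$r, p = mt$p,
                 n_permutations = mt$n_permutations, method = mt$method)
    })
    ibd <- do.call(rbind, ibd[!vapply(ibd, is.null, TRUE)])
    rownames(ibd) <- NULL
    res$ibd <- ibd
    .write_stage(ibd, od, "ibd")
  } else {
    res["ibd"] <- list(NULL)   # keep the element so $ibd never partial-matches
    res$notes <- c(res$notes, ibd = "skipped: no distances")
  }

  ## stage 5: P_ST vs F_ST --------------------------------------------------
  pst_traits <- setdiff(trait_names(), "mass")
  pst_rows <- list()
  for (sx in c("male", "female")) for (tr in pst_traits) {
    pr <- pairwise_pst(morph, tr, sx, ratio_c_h2 = config$ratio_c_h2)
    cmp <- compare_pst_fst(pr, fst_by_sex[[sx]])
    pst_rows[[length(pst_rows) + 1L]] <- cmp
  }
  pst_tab <- do.call(rbind, pst_rows)
  res$pst <- pst_tab
  .write_stage(pst_tab, od, "pst_fst")

  ## stage 6: condition and selection scan -----------------------------------
  ci_rec <- condition_index(morph, stratify = "by_sex")
  cr <- condition_rainfall_regression(ci_rec, sites, level = "individual")
  scan <- selection_scan(morph, ci_rec, sites, alpha = config$alpha)
  res$condition <- list(records = ci_rec, rainfall_regression = cr)
  res$selection <- scan
  .write_stage(ci_rec, od, "condition_index")
  .write_stage(scan, od, "selection_scan")

  ## summary -----------------------------------------------------------------
  summary <- list(
    n_individuals = n_individuals(gm),
    n_loci = n_loci(gm),
    missing_percent = ms$percent,
    theta_global = fst_global$theta,
    theta_global_ci = unname(fst_global$ci),
    theta_male = fst_by_sex$male$theta,
    theta_female = fst_by_sex$female$theta,
    sex_bias = if (has_sexes)
      list(vAIc_p = sb_vaic$p, per_sex_fst_p = sb_fst$p) else NULL,
    ibd = if (!is.null(res$ibd))
      lapply(split(res$ibd, res$ibd$scope),
             function(d) list(r = d$r, p = d$p)) else res$notes[["ibd"]],
    condition_rainfall = list(slope = cr$slope, adj_r2 = cr$adj_r2,
                              r = cr$r, p_one_sided = cr$p_one_sided),
    pst_exceeds = sum(pst_tab$verdict == "exceeds"),
    pst_tested = nrow(pst_tab),
    selection_modes = table(scan$mode[scan$significant])
  )
  res$summary <- summary
  if (!is.null(od)) {
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    manifest <- c(
      sprintf("honeypop %s", as.character(utils::packageVersion("honeypop"))),
      sprintf("R %s", getRversion()),
      sprintf("seed %d", config$seed),
      sprintf("permutations: hwe=%d ld=%d mantel=%d sexbias=%d",
              config$n_perm_hwe, config$n_perm_ld, config$n_perm_mantel,
              config$n_perm_sexbias),
      sprintf("alpha: hwe/ld=%g traits=%g", config$alpha_hwe_ld,
              config$alpha))
    writeLines(manifest, file.path(od, "manifest.txt"))
  }
  res
}
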