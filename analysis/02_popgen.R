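#!/usr/bin/env Rscript
# Classical marker checks on the simulated panel: per-locus diversity (N_A,
# H_E, H_O, F_IS), Hardy-Weinberg and linkage-disequilibrium permutation
# tests with sequential Bonferroni, and Weir-Cockerham F_ST (global, per sex,
# pairwise) with jackknife-over-loci confidence intervals.

suppressPackageStartupMessages(library(honeypop))

seed <- 20122L
data_dir <- "results/data"
out <- "results/popgen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sites <- read_sites(file.path(data_dir, "sites.csv"))
gm <- read_genepop(file.path(data_dir, "genotypes.gen"),
                   site_names = sites$site)

ms <- missing_summary(gm)
cat(sprintf("%d birds x %d loci; %.1f%% missing genotypes\n",
            n_individuals(gm), n_loci(gm), ms$percent))

div <- allele_stats(gm)
write.csv(div, file.path(out, "diversity.csv"), row.names = FALSE)
g <- div[div$site == "global", ]
cat(sprintf("alleles/locus %d-%d (mean %.1f); H_E %.2f-%.2f (mean %.2f)\n",
            min(g$N_A), max(g$N_A), mean(g$N_A),
            min(g$H_E), max(g$H_E), mean(g$H_E)))

# HWE within each site, sequential Bonferroni at the P < 0.01 family level
hwe <- do.call(rbind, lapply(unique(gm$site), function(s)
  do.call(rbind, lapply(gm$locus_names, function(l)
    hwe_test(gm, l, s, n_perm = 2000,
             seed = seed + match(s, unique(gm$site)) * 100 +
               match(l, gm$locus_names))))))
tested <- !hwe$skipped
hwe$significant <- FALSE
hwe$significant[tested] <- holm_adjust(hwe$p[tested], alpha = 0.01)
write.csv(hwe, file.path(out, "hwe_tests.csv"), row.names = FALSE)
cat(sprintf("HWE: %d of %d locus-by-site tests significant after correction\n",
            sum(hwe$significant), sum(tested)))

# LD for each locus pair by site
pairs <- utils::combn(gm$locus_names, 2)
ld <- do.call(rbind, lapply(unique(gm$site), function(s)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(p)
    ld_test(gm, pairs[1, p], pairs[2, p], s, n_perm = 500,
            seed = seed + 5000 + match(s, unique(gm$site)) * 200 + p)))))
tested <- !ld$skipped
ld$significant <- FALSE
ld$significant[tested] <- holm_adjust(ld$p[tested], alpha = 0.01)
write.csv(ld, file.path(out, "ld_tests.csv"), row.names = FALSE)
cat(sprintf("LD: %d of %d pair-by-site tests significant after correction\n",
            sum(ld$significant), sum(tested)))

fst <- wc_fst(gm, ci = TRUE)
fst_m <- wc_fst(subset_genotypes(gm, individuals = gm$sex == "male"),
                ci = TRUE)
fst_f <- wc_fst(subset_genotypes(gm, individuals = gm$sex == "female"),
                ci = TRUE)
cat(sprintf("global theta %.4f (95%% CI %.4f-%.4f); male %.4f; female %.4f\n",
            fst$theta, fst$ci[1], fst$ci[2], fst_m$theta, fst_f$theta))
write.csv(data.frame(scope = c("global", "male", "female"),
                     theta = c(fst$theta, fst_m$theta, fst_f$theta),
                     ci_lower = c(fst$ci[1], fst_m$ci[1], fst_f$ci[1]),
                     ci_upper = c(fst$ci[2], fst_m$ci[2], fst_f$ci[2])),
          file.path(out, "fst.csv"), row.names = FALSE)

for (sx in c("male", "female")) {
  pw <- pairwise_fst(subset_genotypes(gm, individuals = gm$sex == sx))
  write.csv(data.frame(site = rownames(pw), pw, check.names = FALSE),
            file.path(out, paste0("pairwise_fst_", sx, ".csv")),
            row.names = FALSE)
}
cat("popgen tables written to", out, "\n")
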