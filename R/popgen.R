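#' Per-locus diversity summaries
#'
#' Number of alleles, unbiased expected heterozygosity, observed
#' heterozygosity and the inbreeding coefficient, per locus within each site
#' and globally. H_E uses the small-sample unbiased estimator
#' `2n/(2n-1) * (1 - sum(p^2))`; F_IS is the Nei form `1 - H_O / H_E`,
#' undefined (NA) at monomorphic loci.
#'
#' @param gm a [genotype_matrix()].
#' @param by_site if `TRUE` (default) report each locus within each site as
#'   well as globally; if `FALSE`, global rows only.
#' @return data.frame with columns `locus`, `site` (`"global"` for pooled
#'   rows), `n_typed`, `N_A`, `H_E`, `H_O`, `F_IS`.
#' @export
allele_stats <- function(gm, by_site = TRUE) {
  scopes <- list(global = rep(TRUE, n_individuals(gm)))
  if (by_site)
    for (s in unique(gm$site)) scopes[[s]] <- gm$site == s
  out <- list()
  for (sc in names(scopes)) {
    rows <- scopes[[sc]]
    for (l in seq_along(gm$locus_names)) {
      a <- gm$allele_a[rows, l]
      b <- gm$allele_b[rows, l]
      typed <- !is.na(a)
      n <- sum(typed)
      if (n == 0) next
      alle <- c(a[typed], b[typed])
      p <- table(alle) / (2 * n)
      na <- length(p)
      he <- if (n > 0) (2 * n) / (2 * n - 1) * (1 - sum(p^2)) else NA_real_
      ho <- mean(a[typed] != b[typed])
      fis <- if (na > 1 && he > 0) 1 - ho / he else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        locus = gm$locus_names[l], site = sc, n_typed = n, N_A = na,
        H_E = he, H_O = ho, F_IS = fis, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Genotype-table log-probability conditional on allele counts (Levene /
# Guo-Thompson): only the table-dependent part is needed to rank tables.
.hwe_log_prob_part <- function(a, b) {
  key <- paste(a, b)
  counts <- table(key)
  n_het <- sum(a != b)
  n_het * log(2) - sum(lfactorial(counts))
}

#' Exact Hardy-Weinberg test by Monte-Carlo re-pairing
#'
#' Conditional exact test in the Guo-Thompson spirit: the statistic is the
#' multinomial probability of the observed genotype table given the allele
#' counts, and the null distribution is generated by shuffling the `2n`
#' allele copies and re-pairing them. The p-value uses the add-one estimator
#' `(1 + k) / (1 + n_perm)`, counting permuted tables with probability at or
#' below the observed one.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name or index.
#' @param site site label.
#' @param n_perm number of Monte-Carlo re-pairings.
#' @param seed integer seed.
#' @return data.frame test record (`test`, `locus`, `site`, `n`, `p`,
#'   `n_permutations`, `skipped`, `reason`).
#' @export
hwe_test <- function(gm, locus, site, n_perm = 10000, seed = 1L) {
  l <- if (is.character(locus)) match(locus, gm$locus_names) else locus
  rows <- gm$site == site
  a <- gm$allele_a[rows, l]
  b <- gm$allele_b[rows, l]
  typed <- !is.na(a)
  a <- a[typed]; b <- b[typed]
  rec <- data.frame(test = "HWE", locus = gm$locus_names[l], site = site,
                    n = length(a), p = NA_real_, n_permutations = n_perm,
                    skipped = FALSE, reason = "", stringsAsFactors = FALSE)
  if (length(a) < 5) {
    rec$skipped <- TRUE; rec$reason <- "fewer than 5 typed individuals"
    return(rec)
  }
  alleles <- c(a, b)
  if (length(unique(alleles)) < 2) {
    rec$skipped <- TRUE; rec$reason <- "monomorphic locus at this site"
    return(rec)
  }
  set.seed(seed)
  obs <- .hwe_log_prob_part(pmin(a, b), pmax(a, b))
  n <- length(a)
  k <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(alleles)
    pa <- perm[seq_len(n)]
    pb <- perm[n + seq_len(n)]
    if (.hwe_log_prob_part(pmin(pa, pb), pmax(pa, pb)) <= obs + 1e-12)
      k <- k + 1L
  }
  rec$p <- (1 + k) / (1 + n_perm)
  rec
}

.g_statistic <- function(x, y) {
  tab <- table(x, y)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.numeric(tab)
  e <- as.numeric(e)
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / e[nz]))
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' G (log-likelihood ratio) statistic on the genotype x genotype contingency
#' table of two loci within one site; the null distribution permutes the
#' second locus's genotypes across individuals. Add-one p estimator.
#'
#' @param gm a [genotype_matrix()].
#' @param locus_a,locus_b locus names or indices.
#' @param site site label.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data.frame test record as in [hwe_test()], with `locus` holding
#'   `"locus_a:locus_b"`.
#' @export
ld_test <- function(gm, locus_a, locus_b, site, n_perm = 10000, seed = 1L) {
  la <- if (is.character(locus_a)) match(locus_a, gm$locus_names) else locus_a
  lb <- if (is.character(locus_b)) match(locus_b, gm$locus_names) else locus_b
  rows <- gm$site == site
  ga <- paste(gm$allele_a[rows, la], gm$allele_b[rows, la])
  gb <- paste(gm$allele_a[rows, lb], gm$allele_b[rows, lb])
  typed <- !is.na(gm$allele_a[rows, la]) & !is.na(gm$allele_a[rows, lb])
  ga <- ga[typed]; gb <- gb[typed]
  rec <- data.frame(test = "LD",
                    locus = paste(gm$locus_names[la], gm$locus_names[lb],
                                  sep = ":"),
                    site = site, n = length(ga), p = NA_real_,
                    n_permutations = n_perm, skipped = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  if (length(ga) < 5) {
    rec$skipped <- TRUE; rec$reason <- "fewer than 5 individuals typed at both"
    return(rec)
  }
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2) {
    rec$skipped <- TRUE; rec$reason <- "fewer than 2 genotype classes"
    return(rec)
  }
  set.seed(seed)
  obs <- .g_statistic(ga, gb)
  k <- 0L
  for (i in seq_len(n_perm)) {
    if (.g_statistic(ga, sample(gb)) >= obs - 1e-12) k <- k + 1L
  }
  rec$p <- (1 + k) / (1 + n_perm)
  rec
}

# Weir-Cockerham (1984) variance components for one locus, vectorized over
# alleles. a/b: allele code vectors; site: integer site index.
# Returns the locus totals A = sum(a) and ABC = sum(a + b + c) over alleles.
.wc_locus <- function(a, b, site) {
  typed <- !is.na(a)
  a <- a[typed]; b <- b[typed]; site <- site[typed]
  sites <- sort(unique(site))
  r <- length(sites)
  if (r < 2) return(c(A = NA_real_, ABC = NA_real_))
  grp <- match(site, sites)
  ni <- tabulate(grp, nbins = r)
  alleles <- sort(unique(c(a, b)))
  K <- length(alleles)
  if (K < 2) return(c(A = 0, ABC = 0))  # monomorphic: 0/0 upstream
  ia <- match(a, alleles); ib <- match(b, alleles)
  n <- length(a)
  # per-individual allele-copy counts (n x K), then per-site sums
  Ca <- matrix(0L, n, K); Ca[cbind(seq_len(n), ia)] <- 1L
  Cb <- matrix(0L, n, K); Cb[cbind(seq_len(n), ib)] <- 1L
  C <- Ca + Cb
  H <- (Ca != Cb) * 1L                    # carries the allele exactly once
  cnt <- rowsum(C, grp)                   # r x K allele counts
  het <- rowsum(H, grp)                   # r x K heterozygote-carrier counts
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  p_i <- cnt / (2 * ni)
  pbar <- colSums(ni * p_i) / (r * nbar)
  s2 <- colSums(ni * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(het) / (r * nbar)
  aa <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  bb <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(A = sum(aa), ABC = sum(aa + bb + cc))
}

#' Weir-Cockerham F_ST (theta)
#'
#' Multi-allelic Weir & Cockerham (1984) variance-component estimator of
#' F_ST. Components a (among populations), b (among individuals within
#' populations) and c (within individuals) are computed per allele and locus
#' from sample sizes, allele frequencies and heterozygote frequencies;
#' per-locus theta is `sum(a) / sum(a + b + c)` over alleles and the
#' multi-locus estimate sums components over loci. Individuals missing at a
#' locus are dropped from that locus only.
#'
#' @param gm a [genotype_matrix()].
#' @param sites optional character vector restricting to a site subset.
#' @param loci optional locus names or indices.
#' @param ci if `TRUE`, attach the 95% jackknife-over-loci interval
#'   (see [jackknife_ci()]).
#' @return list of class `fst_result`: `theta` (multi-locus),
#'   `theta_by_locus`, `components` (per-locus `A` = sum of a, `ABC` = sum of
#'   a+b+c), `sites`, `ci` (or NULL).
#' @export
wc_fst <- function(gm, sites = NULL, loci = NULL, ci = FALSE) {
  if (!is.null(sites)) gm <- subset_genotypes(gm, sites = sites)
  li <- if (is.null(loci)) seq_along(gm$locus_names) else {
    if (is.character(loci)) match(loci, gm$locus_names) else loci
  }
  if (length(unique(gm$site)) < 2)
    stop("wc_fst needs at least 2 sites")
  site_idx <- match(gm$site, unique(gm$site))
  comp <- t(vapply(li, function(l)
    .wc_locus(gm$allele_a[, l], gm$allele_b[, l], site_idx),
    c(A = 0, ABC = 0)))
  rownames(comp) <- gm$locus_names[li]
  theta_by_locus <- ifelse(comp[, "ABC"] != 0, comp[, "A"] / comp[, "ABC"],
                           NA_real_)
  denom <- sum(comp[, "ABC"], na.rm = TRUE)
  theta <- if (is.finite(denom) && denom != 0)
    sum(comp[, "A"], na.rm = TRUE) / denom else NA_real_
  res <- structure(list(theta = theta, theta_by_locus = theta_by_locus,
                        components = comp, sites = unique(gm$site), ci = NULL),
                   class = "fst_result")
  if (ci) res$ci <- jackknife_ci(res)
  res
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta = %.4f over %d loci, %d sites\n",
              x$theta, nrow(x$components), length(x$sites)))
  if (!is.null(x$ci))
    cat(sprintf("  95%% jackknife CI: (%.4f, %.4f)\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Jackknife-over-loci confidence interval for theta
#'
#' Delete-one-locus pseudovalues of the multi-locus theta,
#' `L * theta - (L - 1) * theta_(-l)`; the interval is the pseudovalue mean
#' +/- 1.96 standard errors.
#'
#' @param fst an `fst_result` from [wc_fst()], or a matrix of per-locus
#'   components with columns `A` and `ABC`.
#' @param conf_z normal quantile for the interval half-width (1.96 for 95%).
#' @return numeric `c(lower, upper)`, or `c(NA, NA)` with a warning when
#'   fewer than 3 loci have defined components.
#' @export
jackknife_ci <- function(fst, conf_z = 1.96) {
  comp <- if (inherits(fst, "fst_result")) fst$components else fst
  ok <- is.finite(comp[, "A"]) & is.finite(comp[, "ABC"]) & comp[, "ABC"] != 0
  comp <- comp[ok, , drop = FALSE]
  L <- nrow(comp)
  if (L < 3) {
    warning("jackknife CI needs >= 3 informative loci")
    return(c(lower = NA_real_, upper = NA_real_))
  }
  A <- sum(comp[, "A"]); ABC <- sum(comp[, "ABC"])
  theta <- A / ABC
  theta_minus <- (A - comp[, "A"]) / (ABC - comp[, "ABC"])
  pseudo <- L * theta - (L - 1) * theta_minus
  m <- mean(pseudo)
  se <- stats::sd(pseudo) / sqrt(L)
  c(lower = m - conf_z * se, upper = m + conf_z * se)
}

#' Pairwise Weir-Cockerham theta over all site pairs
#'
#' @param gm a [genotype_matrix()].
#' @param sites optional site subset (defaults to all, in order of
#'   appearance).
#' @return symmetric matrix of pairwise multi-locus theta with zero diagonal.
#' @export
pairwise_fst <- function(gm, sites = NULL) {
  if (is.null(sites)) sites <- unique(gm$site)
  k <- length(sites)
  m <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    m[i, j] <- m[j, i] <- wc_fst(gm, sites = sites[c(i, j)])$theta
  }
  m
}

#' Sequential Bonferroni (Holm) decisions
#'
#' Step-down familywise correction: p-values are sorted ascending and p_(k)
#' is compared with `alpha / (m - k + 1)`; testing stops at the first
#' failure. Decisions are returned in the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param alpha familywise error rate.
#' @return logical vector, `TRUE` where rejected.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(logical(0))
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] < alpha / (m - k + 1)) reject[ord[k]] <- TRUE
    else break
  }
  reject
}

#' Chi-square test of an even sex ratio
#'
#' Goodness-of-fit against 1:1 with one degree of freedom, no continuity
#' correction.
#'
#' @param n_male,n_female non-negative counts.
#' @return list with `chisq`, `df`, `p`.
#' @export
sex_ratio_test <- function(n_male, n_female) {
  stopifnot(n_male >= 0, n_female >= 0)
  total <- n_male + n_female
  if (total == 0) stop("no individuals")
  e <- total / 2
  chisq <- (n_male - e)^2 / e + (n_female - e)^2 / e
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}
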