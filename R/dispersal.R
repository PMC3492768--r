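#' Corrected assignment indices (AIc)
#'
#' For each individual, AI is the log10 expected frequency of its multilocus
#' genotype under the allele frequencies of its own site, summed over typed
#' loci (`p^2` for homozygotes, `2pq` for heterozygotes). Frequencies are
#' computed leave-one-out (the focal individual's two allele copies removed)
#' and zero frequencies are floored at `1 / (2 * n_site + 1)` with `n_site`
#' the remaining typed individuals. AIc centres AI on its site mean, so site
#' means of AIc are zero and AIc is comparable across sites; dispersing
#' individuals tend to have low, variable AIc.
#'
#' @param gm a [genotype_matrix()].
#' @param leave_one_out compute frequencies excluding the focal individual
#'   (default TRUE; FALSE uses plain site frequencies, handy for worked
#'   examples).
#' @return data.frame with `individual_id`, `site`, `sex`, `n_typed_loci`,
#'   `AI`, `AIc`; individuals typed at no locus are dropped with a message.
#' @export
assignment_index <- function(gm, leave_one_out = TRUE) {
  n <- n_individuals(gm)
  L <- n_loci(gm)
  AI <- numeric(n)
  typed_any <- rowSums(!is.na(gm$allele_a)) > 0
  for (s in unique(gm$site)) {
    rows <- which(gm$site == s)
    for (l in seq_len(L)) {
      a <- gm$allele_a[rows, l]
      b <- gm$allele_b[rows, l]
      typed <- !is.na(a)
      if (!any(typed)) next
      alleles <- sort(unique(c(a[typed], b[typed])))
      counts <- tabulate(match(c(a[typed], b[typed]), alleles),
                         nbins = length(alleles))
      n_typed <- sum(typed)
      idx <- which(typed)
      ia <- match(a[idx], alleles)
      ib <- match(b[idx], alleles)
      if (leave_one_out) {
        if (n_typed < 2) next   # nothing left to estimate frequencies from
        two_n <- 2 * (n_typed - 1L)
        floor_f <- 1 / (two_n + 1)
        hom <- ia == ib
        ca <- counts[ia] - ifelse(hom, 2L, 1L)  # own copies removed
        cb <- counts[ib] - ifelse(hom, 2L, 1L)
        pa <- pmax(ca / two_n, floor_f)
        pb <- pmax(cb / two_n, floor_f)
      } else {
        two_n <- 2 * n_typed
        pa <- counts[ia] / two_n
        pb <- counts[ib] / two_n
      }
      f <- ifelse(ia == ib, pa^2, 2 * pa * pb)
      AI[rows[idx]] <- AI[rows[idx]] + log10(f)
    }
  }
  keep <- typed_any
  if (any(!keep))
    message(sum(!keep), " individual(s) with no typed locus excluded from AIc")
  out <- data.frame(individual_id = gm$individual_id[keep],
                    site = gm$site[keep], sex = gm$sex[keep],
                    n_typed_loci = rowSums(!is.na(gm$allele_a))[keep],
                    AI = AI[keep], stringsAsFactors = FALSE)
  out$AIc <- out$AI - stats::ave(out$AI, out$site)
  out
}

.sex_statistic <- function(statistic, aic, sex, gm = NULL, sexes) {
  if (statistic == "vAIc") {
    vapply(sexes, function(s) stats::var(aic[sex == s], na.rm = TRUE), 0)
  } else if (statistic == "mean_AIc") {
    vapply(sexes, function(s) mean(aic[sex == s], na.rm = TRUE), 0)
  } else {  # per_sex_FST
    site_idx <- match(gm$site, unique(gm$site))
    vapply(sexes, function(s) {
      rows <- sex == s
      comp <- vapply(seq_along(gm$locus_names), function(l)
        .wc_locus(gm$allele_a[rows, l], gm$allele_b[rows, l], site_idx[rows]),
        c(A = 0, ABC = 0))
      sum(comp["A", ], na.rm = TRUE) / sum(comp["ABC", ], na.rm = TRUE)
    }, 0)
  }
}

#' Permutation tests of sex-biased dispersal
#'
#' Compares a dispersal-sensitive statistic between the sexes: the variance
#' of corrected assignment indices (`vAIc`, higher in the dispersing sex),
#' mean AIc (`mean_AIc`, lower in the dispersing sex), or the per-sex
#' multi-locus Weir-Cockerham theta (`per_sex_FST`, higher in the philopatric
#' sex). The null distribution permutes sex labels within sites; the p-value
#' is one-sided in the direction the caller states (`"male_greater"` tests
#' whether the male statistic exceeds the female one) with the add-one
#' estimator.
#'
#' @param gm a [genotype_matrix()]; individuals of unknown sex are excluded.
#' @param statistic one of `"vAIc"`, `"mean_AIc"`, `"per_sex_FST"`.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param direction `"male_greater"` or `"male_less"`.
#' @return list with `statistic`, `male`, `female`, `observed` (male minus
#'   female, or their ratio for vAIc), `p`, `n_permutations`, `direction`.
#' @export
sex_bias_test <- function(gm, statistic = c("vAIc", "mean_AIc", "per_sex_FST"),
                          n_perm = 1000, seed = 1L,
                          direction = c("male_greater", "male_less")) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  gm <- subset_genotypes(gm, individuals = gm$sex != "unknown")
  sexes <- c("male", "female")
  if (!all(sexes %in% gm$sex)) stop("both sexes must be present")
  tab <- table(gm$site, gm$sex)
  if (sum(rowSums(tab > 0) == 2) < 2)
    stop("both sexes must be present at >= 2 sites")
  single_sex_sites <- rownames(tab)[rowSums(tab > 0) < 2]
  if (length(single_sex_sites) > 0)
    warning("site(s) with a single sex contribute no permutable labels: ",
            paste(single_sex_sites, collapse = ", "))

  aic <- NULL
  if (statistic %in% c("vAIc", "mean_AIc")) {
    rec <- assignment_index(gm)
    # align to gm rows (excluded all-missing individuals get NA, dropped)
    aic <- rec$AIc[match(gm$individual_id, rec$individual_id)]
  }
  obs_pair <- .sex_statistic(statistic, aic, gm$sex, gm, sexes)
  combine <- if (statistic == "vAIc") function(v) v[1] / v[2]
             else function(v) v[1] - v[2]
  obs <- combine(obs_pair)

  set.seed(seed)
  site_rows <- split(seq_along(gm$site), gm$site)
  k <- 0L
  for (i in seq_len(n_perm)) {
    perm_sex <- gm$sex
    for (rows in site_rows) perm_sex[rows] <- sample(gm$sex[rows])
    stat <- combine(.sex_statistic(statistic, aic, perm_sex, gm, sexes))
    hit <- if (direction == "male_greater") stat >= obs - 1e-12
           else stat <= obs + 1e-12
    if (hit) k <- k + 1L
  }
  list(statistic = statistic, male = unname(obs_pair[1]),
       female = unname(obs_pair[2]), observed = unname(obs),
       p = (1 + k) / (1 + n_perm), n_permutations = n_perm,
       direction = direction)
}

#' Rousset linearization of pairwise F_ST
#'
#' Elementwise `x / (1 - x)` over a pairwise theta matrix; under
#' two-dimensional isolation by distance this quantity regresses linearly on
#' log geographic distance. Negative theta passes through (slightly negative
#' output); theta = 1 yields `Inf` and is flagged with a warning.
#'
#' @param fst_matrix symmetric matrix of pairwise theta.
#' @return symmetric matrix of linearized values.
#' @export
linearize_fst <- function(fst_matrix) {
  if (any(fst_matrix == 1, na.rm = TRUE))
    warning("theta = 1 linearizes to Inf; exclude these pairs from Mantel")
  out <- fst_matrix / (1 - fst_matrix)
  diag(out) <- 0
  out
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

.mantel_r <- function(va, mat_b, ut) stats::cor(va, mat_b[ut])

#' Mantel test of matrix association
#'
#' Pearson correlation over the upper-triangle pairs of two symmetric
#' matrices, with significance from simultaneous row-and-column permutation
#' of the second matrix. One-sided (positive association), add-one p
#' estimator. For matrices of order 6 or less an exact mode enumerates all
#' `n!` relabelings; `method = "auto"` picks exact for `n <= 6`.
#'
#' @param mat_a,mat_b symmetric numeric matrices of equal order >= 3;
#'   diagonals are ignored.
#' @param n_perm Monte-Carlo permutation count (ignored in exact mode).
#' @param seed integer seed (ignored in exact mode).
#' @param transform_b `"none"` or `"log"` (natural log of `mat_b`'s
#'   off-diagonal entries, for geographic distances).
#' @param method `"auto"`, `"exact"` or `"mc"`.
#' @return list with `r`, `p`, `n_permutations`, `method`, `transform_b`.
#' @export
mantel_test <- function(mat_a, mat_b, n_perm = 9999, seed = 1L,
                        transform_b = c("none", "log"),
                        method = c("auto", "exact", "mc")) {
  transform_b <- match.arg(transform_b)
  method <- match.arg(method)
  n <- nrow(mat_a)
  stopifnot(n >= 3, nrow(mat_b) == n, ncol(mat_a) == n, ncol(mat_b) == n)
  if (max(abs(mat_a - t(mat_a)), na.rm = TRUE) > 1e-9 ||
      max(abs(mat_b - t(mat_b)), na.rm = TRUE) > 1e-9)
    stop("Mantel inputs must be symmetric")
  if (any(!is.finite(mat_a[upper.tri(mat_a)])) ||
      any(!is.finite(mat_b[upper.tri(mat_b)])))
    stop("non-finite off-diagonal entries")
  if (transform_b == "log") {
    off <- row(mat_b) != col(mat_b)
    if (any(mat_b[off] <= 0)) stop("log transform needs positive distances")
    mat_b[off] <- log(mat_b[off])
  }
  ut <- upper.tri(mat_a)
  va <- mat_a[ut]
  if (stats::sd(va) == 0 || stats::sd(mat_b[ut]) == 0)
    stop("zero variance in a Mantel triangle")
  obs <- .mantel_r(va, mat_b, ut)
  if (method == "auto") method <- if (n <= 6) "exact" else "mc"
  if (method == "exact") {
    perms <- .all_permutations(n)
    rs <- apply(perms, 1, function(pm)
      .mantel_r(va, mat_b[pm, pm], ut))
    p <- mean(rs >= obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    k <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      if (.mantel_r(va, mat_b[pm, pm], ut) >= obs - 1e-12) k <- k + 1L
    }
    p <- (1 + k) / (1 + n_perm)
    n_used <- n_perm
  }
  list(r = obs, p = p, n_permutations = n_used, method = method,
       transform_b = transform_b)
}
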