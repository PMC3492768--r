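#' One-way ANOVA variance components
#'
#' Standard one-way ANOVA mean squares for a trait grouped by site, with the
#' method-of-moments between-group variance. The effective per-group size for
#' unbalanced designs is `n0 = (N - sum(n_i^2) / N) / (k - 1)`;
#' `sigma2_B = max(0, (MS_between - MS_within) / n0)` (negative estimates are
#' truncated at zero and counted) and `sigma2_W = MS_within`.
#'
#' @param values numeric trait values.
#' @param groups group (site) labels, same length.
#' @return list with `MS_between`, `MS_within`, `n0`, `sigma2_B`, `sigma2_W`,
#'   `F`, `p`, `df_between`, `df_within`, `truncated` (TRUE when a negative
#'   sigma2_B was clamped), `groups_used`.
#' @export
anova_components <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  n_i <- table(groups)
  small <- names(n_i)[n_i < 2]
  if (length(small) > 0) {
    warning("group(s) with < 2 observations excluded: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    n_i <- table(groups)
  }
  k <- length(n_i)
  if (k < 2) stop("anova_components needs >= 2 groups with >= 2 observations")
  N <- length(values)
  gmean <- mean(values)
  means <- tapply(values, groups, mean)
  n_i <- as.numeric(n_i)
  ss_b <- sum(n_i * (means - gmean)^2)
  ss_w <- sum((values - means[groups])^2)
  df_b <- k - 1
  df_w <- N - k
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  s2b_raw <- (ms_b - ms_w) / n0
  list(MS_between = ms_b, MS_within = ms_w, n0 = n0,
       sigma2_B = max(0, s2b_raw), sigma2_W = ms_w,
       F = ms_b / ms_w,
       p = stats::pf(ms_b / ms_w, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w,
       truncated = s2b_raw < 0, groups_used = names(means))
}

#' Phenotypic differentiation P_ST
#'
#' `P_ST = (r * sigma2_B) / (r * sigma2_B + 2 * sigma2_W)` where `r` is the
#' assumed ratio of the proportion of between-population variance due to
#' additive effects (c) to narrow-sense heritability (h^2). The default
#' `r = 1` gives the plain phenotypic form `sigma2_B / (sigma2_B +
#' 2 * sigma2_W)`; other values support sensitivity analysis.
#'
#' @param sigma2_B between-population variance component (>= 0).
#' @param sigma2_W within-population variance component (> 0).
#' @param ratio_c_h2 scaling ratio c / h^2 (> 0).
#' @return P_ST in `[0, 1)`.
#' @export
pst <- function(sigma2_B, sigma2_W, ratio_c_h2 = 1) {
  stopifnot(sigma2_B >= 0, ratio_c_h2 > 0)
  if (any(sigma2_W <= 0)) stop("sigma2_W must be positive")
  (ratio_c_h2 * sigma2_B) / (ratio_c_h2 * sigma2_B + 2 * sigma2_W)
}

#' Pairwise P_ST for one trait and sex
#'
#' Computes P_ST for every site pair (two-group ANOVA on just that pair),
#' then aggregates: the mean of the pairwise values and a +/- 1 SD interval
#' across pairs, clamped to `[0, 1]`. The SD interval is the conservative
#' spread measure used when too few populations exist for a model-based
#' global interval; it is not a nominal-coverage confidence interval.
#'
#' @param morph morphology data.frame (see [read_morphology()]).
#' @param trait trait column name.
#' @param sex `"male"` or `"female"`.
#' @param ratio_c_h2 scaling ratio passed to [pst()].
#' @param min_per_site minimum individuals per site for a pair to count.
#' @return list of class `pst_result`: `trait`, `sex`, `pairs` (data.frame
#'   site_i, site_j, sigma2_B, sigma2_W, P_ST), `mean`, `sd`, `lower`,
#'   `upper`, `ratio_c_h2`, `n_truncated`.
#' @export
pairwise_pst <- function(morph, trait, sex, ratio_c_h2 = 1,
                         min_per_site = 2) {
  stopifnot(trait %in% names(morph), sex %in% c("male", "female"))
  df <- morph[morph$sex == sex & !is.na(morph[[trait]]), ]
  counts <- table(df$site)
  sites <- names(counts)[counts >= min_per_site]
  skipped <- setdiff(unique(df$site), sites)
  if (length(skipped) > 0)
    message("site(s) skipped for ", trait, "/", sex, ": ",
            paste(skipped, collapse = ", "))
  if (length(sites) < 2) stop("need >= 2 usable sites")
  pairs <- utils::combn(sites, 2)
  out <- data.frame(site_i = pairs[1, ], site_j = pairs[2, ],
                    sigma2_B = NA_real_, sigma2_W = NA_real_,
                    P_ST = NA_real_, stringsAsFactors = FALSE)
  n_trunc <- 0L
  for (p in seq_len(ncol(pairs))) {
    sub <- df[df$site %in% pairs[, p], ]
    comp <- anova_components(sub[[trait]], sub$site)
    out$sigma2_B[p] <- comp$sigma2_B
    out$sigma2_W[p] <- comp$sigma2_W
    out$P_ST[p] <- pst(comp$sigma2_B, comp$sigma2_W, ratio_c_h2)
    if (comp$truncated) n_trunc <- n_trunc + 1L
  }
  m <- mean(out$P_ST)
  s <- stats::sd(out$P_ST)
  structure(list(trait = trait, sex = sex, pairs = out, mean = m, sd = s,
                 lower = max(0, m - s), upper = min(1, m + s),
                 ratio_c_h2 = ratio_c_h2, n_truncated = n_trunc),
            class = "pst_result")
}

#' @export
print.pst_result <- function(x, ...) {
  cat(sprintf("P_ST for %s (%s): mean %.3f, +/-1 SD interval (%.3f, %.3f), %d pairs\n",
              x$trait, x$sex, x$mean, x$lower, x$upper, nrow(x$pairs)))
  invisible(x)
}

#' Compare phenotypic and neutral genetic differentiation
#'
#' Verdict on whether a trait's P_ST exceeds neutral F_ST: `"exceeds"` when
#' the P_ST interval lower bound (mean - SD, clamped at 0) lies above the
#' F_ST jackknife upper bound; `"below"` when the P_ST upper bound lies under
#' the F_ST lower bound; `"overlaps"` otherwise; `"indeterminate"` when
#' either interval is undefined.
#'
#' @param pst_res a `pst_result` from [pairwise_pst()].
#' @param fst_res an `fst_result` from [wc_fst()] with a jackknife CI
#'   attached (`ci = TRUE`).
#' @return data.frame with the four bounds and the `verdict`.
#' @export
compare_pst_fst <- function(pst_res, fst_res) {
  if (is.null(fst_res$ci)) fst_res$ci <- jackknife_ci(fst_res)
  pl <- pst_res$lower; pu <- pst_res$upper
  fl <- fst_res$ci[1]; fu <- fst_res$ci[2]
  verdict <- if (anyNA(c(pl, pu, fl, fu))) "indeterminate"
             else if (pl > fu) "exceeds"
             else if (pu < fl) "below"
             else "overlaps"
  data.frame(trait = pst_res$trait, sex = pst_res$sex,
             pst_mean = pst_res$mean, pst_lower = pl, pst_upper = pu,
             fst = fst_res$theta, fst_lower = unname(fl),
             fst_upper = unname(fu), verdict = verdict,
             stringsAsFactors = FALSE)
}
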