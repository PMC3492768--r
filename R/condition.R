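#' Body condition index
#'
#' Standardized residuals of an ordinary least-squares regression of body
#' mass on tarsus length, fitted separately per sex by default (sexually
#' dimorphic species) or pooled. Within each fitted stratum the index has
#' mean 0 and SD 1 by construction, and is read downstream as a proxy for
#' individual fitness.
#'
#' @param morph morphology data.frame with `mass` and `tarsus_length`.
#' @param stratify `"by_sex"` or `"pooled"`.
#' @return data.frame with `individual_id`, `site`, `sex`, `CI`.
#' @export
condition_index <- function(morph, stratify = c("by_sex", "pooled")) {
  stratify <- match.arg(stratify)
  ok <- !is.na(morph$mass) & !is.na(morph$tarsus_length)
  df <- morph[ok, c("individual_id", "site", "sex", "mass", "tarsus_length")]
  strata <- if (stratify == "by_sex") split(seq_len(nrow(df)), df$sex)
            else list(all = seq_len(nrow(df)))
  df$CI <- NA_real_
  for (rows in strata) {
    if (length(rows) < 3)
      stop("condition_index needs >= 3 individuals per stratum")
    if (stats::var(df$tarsus_length[rows]) == 0)
      stop("zero tarsus variance in a stratum")
    fit <- stats::lm(mass ~ tarsus_length, data = df[rows, ])
    r <- stats::resid(fit)
    s <- stats::sd(r)
    if (s < 1e-10 * max(abs(df$mass[rows]), 1))
      stop("zero residual variance: cannot standardize")
    df$CI[rows] <- r / s
  }
  df[, c("individual_id", "site", "sex", "CI")]
}

#' Regression of condition on site rainfall
#'
#' Tests whether body condition increases with rainfall. By default
#' individual condition indices are regressed on their site's mean monthly
#' rainfall; `level = "site_mean"` regresses the six site means instead. The
#' p-value is one-sided for a positive slope.
#'
#' @param ci_records output of [condition_index()].
#' @param sites site table (see [read_sites()]).
#' @param level `"individual"` or `"site_mean"`.
#' @return list with `slope`, `intercept`, `r2`, `adj_r2`, `r`,
#'   `p_one_sided`, `n`, `level`.
#' @export
condition_rainfall_regression <- function(ci_records, sites,
                                          level = c("individual",
                                                    "site_mean")) {
  level <- match.arg(level)
  rain <- sites$rainfall_mm[match(ci_records$site, sites$site)]
  if (anyNA(rain)) stop("unknown site in condition records")
  if (length(unique(sites$rainfall_mm)) < 2)
    stop("rainfall must vary across sites")
  df <- data.frame(CI = ci_records$CI, rain = rain)
  if (level == "site_mean")
    df <- stats::aggregate(CI ~ rain, df, mean)
  if (nrow(df) < 3) stop("need >= 3 observations")
  fit <- stats::lm(CI ~ rain, data = df)
  sm <- summary(fit)
  tval <- sm$coefficients["rain", "t value"]
  p1 <- stats::pt(tval, df = fit$df.residual, lower.tail = FALSE)
  if (stats::var(df$CI) == 0) p1 <- NA_real_   # degenerate response
  list(slope = unname(stats::coef(fit)["rain"]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
       r = sign(stats::coef(fit)["rain"]) * sqrt(sm$r.squared),
       p_one_sided = p1, n = nrow(df), level = level)
}

#' Bin trait values by distance from the stratum mean
#'
#' z-scores a trait within its stratum and assigns: `mean` for `|z| <= 1`,
#' `small` for `-2 <= z < -1`, `large` for `1 < z <= 2`, `excluded` for
#' `|z| > 2`. The binning is invariant to positive affine transformation of
#' the trait.
#'
#' @param x numeric trait values from one stratum.
#' @return factor with levels `small`, `mean`, `large`, `excluded`.
#' @export
bin_traits <- function(x) {
  lev <- c("small", "mean", "large", "excluded")
  if (sum(!is.na(x)) < 3) {
    warning("stratum with < 3 values: all excluded")
    return(factor(rep("excluded", length(x)), levels = lev))
  }
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("stratum SD must be positive")
  z <- (x - mean(x, na.rm = TRUE)) / s
  out <- rep("excluded", length(x))
  out[!is.na(z) & abs(z) <= 1] <- "mean"
  out[!is.na(z) & z >= -2 & z < -1] <- "small"
  out[!is.na(z) & z > 1 & z <= 2] <- "large"
  factor(out, levels = lev)
}

.classify_mode <- function(means, eps = 0.05) {
  sm <- means["small"]; me <- means["mean"]; la <- means["large"]
  if (me > sm + eps && me > la + eps) return("stabilizing")
  if (sm > me + eps && la > me + eps) return("disruptive")
  # one extreme strictly highest, or an extreme tied with the mean bin
  if (la > sm + eps && (la > me + eps || abs(la - me) <= eps))
    return("directional_up")
  if (sm > la + eps && (sm > me + eps || abs(sm - me) <= eps))
    return("directional_down")
  "none"
}

#' Selection-mode scan from condition across trait bins
#'
#' Within each sex x rainfall-category group, individuals are binned on each
#' trait ([bin_traits()]) and mean condition is compared across the small /
#' mean / large bins with a one-way ANOVA. Raw p-values are corrected by
#' sequential Bonferroni across the whole scan. For significant cells the
#' bin-mean pattern is classified: mean bin strictly highest = stabilizing;
#' both extremes above the mean bin = disruptive; a single extreme highest
#' (or tied with the mean bin within `eps`) = directional up/down. Tarsus
#' length is barred because it defines the condition index.
#'
#' @param morph morphology data.frame.
#' @param ci_records output of [condition_index()].
#' @param sites site table with `rainfall_mm`.
#' @param traits traits to scan (default: the panel minus tarsus and mass).
#' @param alpha familywise level for the sequential Bonferroni correction.
#' @param eps tie tolerance (condition-index units) in the directional rule.
#' @return data.frame, one row per trait x sex x rainfall category, with bin
#'   counts, bin means/SEs of condition, `F`, `p`, `significant`, `mode`.
#' @export
selection_scan <- function(morph, ci_records, sites,
                           traits = setdiff(trait_names(),
                                            c("tarsus_length", "mass")),
                           alpha = 0.05, eps = 0.05) {
  if ("tarsus_length" %in% traits)
    stop("tarsus length cannot be scanned: it defines the condition index")
  ci <- ci_records$CI[match(morph$individual_id, ci_records$individual_id)]
  rain <- sites$rainfall_mm[match(morph$site, sites$site)]
  rcat <- as.character(rainfall_category(rain))
  out <- list()
  for (trait in traits) for (sex in c("male", "female"))
    for (cat in c("low", "moderate", "high")) {
      rows <- which(morph$sex == sex & rcat == cat &
                      !is.na(morph[[trait]]) & !is.na(ci))
      rec <- data.frame(trait = trait, sex = sex, rainfall_category = cat,
                        n_small = 0L, n_mean = 0L, n_large = 0L,
                        mean_small = NA_real_, mean_mean = NA_real_,
                        mean_large = NA_real_, se_small = NA_real_,
                        se_mean = NA_real_, se_large = NA_real_,
                        F = NA_real_, p = NA_real_, significant = FALSE,
                        mode = "none", reason = "", stringsAsFactors = FALSE)
      if (length(rows) < 6) {
        rec$reason <- "too few individuals"
        out[[length(out) + 1L]] <- rec
        next
      }
      bins <- suppressWarnings(bin_traits(morph[[trait]][rows]))
      keep <- bins != "excluded"
      b <- droplevels(bins[keep])
      v <- ci[rows][keep]
      cnt <- table(factor(b, levels = c("small", "mean", "large")))
      rec$n_small <- cnt["small"]; rec$n_mean <- cnt["mean"]
      rec$n_large <- cnt["large"]
      if (any(cnt == 0)) {
        rec$reason <- "empty bin"
        out[[length(out) + 1L]] <- rec
        next
      }
      mns <- tapply(v, b, mean)[c("small", "mean", "large")]
      ses <- tapply(v, b, function(x) stats::sd(x) / sqrt(length(x)))
      rec$mean_small <- mns["small"]; rec$mean_mean <- mns["mean"]
      rec$mean_large <- mns["large"]
      rec$se_small <- ses["small"]; rec$se_mean <- ses["mean"]
      rec$se_large <- ses["large"]
      if (any(cnt < 2)) {
        rec$reason <- "bin with a single individual"
        out[[length(out) + 1L]] <- rec
        next
      }
      comp <- anova_components(v, as.character(b))
      rec$F <- comp$F
      rec$p <- comp$p
      out[[length(out) + 1L]] <- rec
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  tested <- !is.na(res$p)
  res$significant[tested] <- holm_adjust(res$p[tested], alpha)
  for (i in which(res$significant)) {
    res$mode[i] <- .classify_mode(
      c(small = res$mean_small[i], mean = res$mean_mean[i],
        large = res$mean_large[i]), eps)
  }
  res
}

#' Across-site ANOVA for one trait and sex
#'
#' One-way ANOVA of a trait on site; the workhorse behind the per-trait
#' divergence table. Sequential Bonferroni across traits is applied by the
#' caller (see [site_trait_anova_table()]).
#'
#' @param morph morphology data.frame.
#' @param trait trait column name.
#' @param sex `"male"` or `"female"`.
#' @return list with `F`, `p`, `df_between`, `df_within`, `n`.
#' @export
site_trait_anova <- function(morph, trait, sex) {
  df <- morph[morph$sex == sex & !is.na(morph[[trait]]), ]
  comp <- anova_components(df[[trait]], df$site)
  list(F = comp$F, p = comp$p, df_between = comp$df_between,
       df_within = comp$df_within, n = comp$df_between + comp$df_within + 1)
}

#' Per-trait across-site ANOVA table with sequential Bonferroni
#'
#' @param morph morphology data.frame.
#' @param sex `"male"` or `"female"`.
#' @param traits traits to test (default: the seven-trait panel).
#' @param alpha familywise level.
#' @return data.frame with `trait`, `F`, `p`, `significant`.
#' @export
site_trait_anova_table <- function(morph, sex, traits = trait_names(),
                                   alpha = 0.05) {
  rows <- lapply(traits, function(tr) {
    a <- site_trait_anova(morph, tr, sex)
    data.frame(trait = tr, F = a$F, p = a$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$significant <- holm_adjust(res$p, alpha)
  res
}

#' Multiple regression of rainfall on the trait panel
#'
#' Ordinary least squares with each individual's site rainfall as the
#' response and its seven trait values as predictors; per-coefficient
#' two-sided p-values with sequential Bonferroni across coefficients. A
#' collinearity warning is raised when the predictor matrix is
#' ill-conditioned.
#'
#' @param morph morphology data.frame.
#' @param sites site table with `rainfall_mm`.
#' @param sex `"male"` or `"female"`.
#' @param traits predictor traits (default: the seven-trait panel).
#' @param alpha familywise level for the coefficient decisions.
#' @param condition_threshold condition-number threshold for the warning.
#' @return list with `coefficients` (data.frame trait, estimate, se, t, p,
#'   significant), `r2`, `adj_r2`, `overall_p`, `n`.
#' @export
rainfall_morphology_regression <- function(morph, sites, sex,
                                           traits = trait_names(),
                                           alpha = 0.05,
                                           condition_threshold = 1e6) {
  df <- morph[morph$sex == sex, c("site", traits)]
  df <- df[stats::complete.cases(df), ]
  df$rainfall_mm <- sites$rainfall_mm[match(df$site, sites$site)]
  if (nrow(df) < length(traits) + 2)
    stop("need at least 2 more observations than predictors")
  X <- as.matrix(df[, traits])
  kappa_x <- kappa(scale(X), exact = TRUE)
  if (is.finite(kappa_x) && kappa_x > condition_threshold)
    warning("ill-conditioned predictor matrix (condition number ",
            format(kappa_x, digits = 3), ")")
  fit <- stats::lm(stats::reformulate(traits, "rainfall_mm"), data = df)
  sm <- summary(fit)
  co <- sm$coefficients[traits, , drop = FALSE]
  coefs <- data.frame(trait = traits, estimate = co[, 1], se = co[, 2],
                      t = co[, 3], p = co[, 4], stringsAsFactors = FALSE)
  coefs$significant <- holm_adjust(coefs$p, alpha)
  rownames(coefs) <- NULL
  fstat <- sm$fstatistic
  list(coefficients = coefs, r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
       overall_p = stats::pf(fstat[1], fstat[2], fstat[3],
                             lower.tail = FALSE),
       n = nrow(df))
}
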