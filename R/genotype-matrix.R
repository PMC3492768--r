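#' Construct a codominant genotype matrix
#'
#' The central container for multilocus codominant genotypes: one row per
#' individual, one column per locus, each entry an unordered pair of positive
#' integer allele codes or missing. Individuals carry a sampling site and a
#' sex label.
#'
#' @param individual_id character vector of unique individual identifiers.
#' @param site character vector of site labels, one per individual.
#' @param sex character vector, one of `"male"`, `"female"`, `"unknown"`.
#' @param allele_a,allele_b integer matrices (individuals x loci) holding the
#'   two allele codes per genotype; `NA` in both marks a missing genotype.
#'   Pairs are stored unordered: the constructor sorts each pair so that
#'   `allele_a <= allele_b`.
#' @param locus_names character vector of locus names (column order).
#'
#' @return An object of class `genotype_matrix` with elements
#'   `individual_id`, `site`, `sex`, `allele_a`, `allele_b`, `locus_names`.
#' @export
genotype_matrix <- function(individual_id, site, sex, allele_a, allele_b,
                            locus_names) {
  allele_a <- as.matrix(allele_a)
  allele_b <- as.matrix(allele_b)
  n <- length(individual_id)
  stopifnot(length(site) == n, length(sex) == n,
            nrow(allele_a) == n, nrow(allele_b) == n,
            ncol(allele_a) == length(locus_names),
            ncol(allele_b) == length(locus_names))
  sex <- match.arg(as.character(sex), c("male", "female", "unknown"),
                   several.ok = TRUE)
  miss_a <- is.na(allele_a)
  miss_b <- is.na(allele_b)
  if (any(miss_a != miss_b))
    stop("half-missing genotypes are not allowed: both alleles or neither")
  if (any(allele_a[!miss_a] <= 0) || any(allele_b[!miss_b] <= 0))
    stop("allele codes must be positive integers")
  # store unordered pairs canonically
  lo <- pmin(allele_a, allele_b)
  hi <- pmax(allele_a, allele_b)
  structure(
    list(individual_id = as.character(individual_id),
         site = as.character(site),
         sex = sex,
         allele_a = matrix(as.integer(lo), n, length(locus_names),
                           dimnames = list(NULL, locus_names)),
         allele_b = matrix(as.integer(hi), n, length(locus_names),
                           dimnames = list(NULL, locus_names)),
         locus_names = as.character(locus_names)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d sites\n",
              length(x$individual_id), length(x$locus_names),
              length(unique(x$site))))
  ms <- missing_summary(x)
  cat(sprintf("  missing genotypes: %d of %d (%.1f%%)\n",
              ms$n_missing, ms$n_total, ms$percent))
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(gm) length(gm$individual_id)

#' @rdname n_individuals
#' @export
n_loci <- function(gm) length(gm$locus_names)

#' Missing-genotype accounting
#'
#' Counts missing entries over the individuals x loci grid and expresses them
#' as a percentage of all genotype cells, the form in which missing data are
#' conventionally reported for microsatellite panels.
#'
#' @param gm a `genotype_matrix`.
#' @return list with `n_missing`, `n_total`, and `percent`
#'   (= 100 * n_missing / n_total).
#' @export
missing_summary <- function(gm) {
  n_missing <- sum(is.na(gm$allele_a))
  n_total <- length(gm$allele_a)
  list(n_missing = n_missing, n_total = n_total,
       percent = 100 * n_missing / n_total)
}

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param individuals logical or integer index over individuals (optional).
#' @param sites character vector of site labels to keep (optional).
#' @param loci character vector of locus names or integer index (optional).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, individuals = NULL, sites = NULL,
                             loci = NULL) {
  keep <- rep(TRUE, n_individuals(gm))
  if (!is.null(individuals)) {
    k <- rep(FALSE, n_individuals(gm))
    k[individuals] <- TRUE
    keep <- keep & k
  }
  if (!is.null(sites)) keep <- keep & gm$site %in% sites
  li <- if (is.null(loci)) seq_along(gm$locus_names) else {
    if (is.character(loci)) match(loci, gm$locus_names) else loci
  }
  if (anyNA(li)) stop("unknown locus name")
  genotype_matrix(gm$individual_id[keep], gm$site[keep], gm$sex[keep],
                  gm$allele_a[keep, li, drop = FALSE],
                  gm$allele_b[keep, li, drop = FALSE],
                  gm$locus_names[li])
}

#' Compare two genotype matrices for equality of content
#' @param a,b `genotype_matrix` objects.
#' @return logical.
#' @export
genotypes_equal <- function(a, b) {
  isTRUE(all.equal(a$individual_id, b$individual_id)) &&
    isTRUE(all.equal(a$site, b$site)) &&
    isTRUE(all.equal(a$sex, b$sex)) &&
    identical(dim(a$allele_a), dim(b$allele_a)) &&
    isTRUE(all.equal(a$locus_names, b$locus_names)) &&
    identical(is.na(a$allele_a), is.na(b$allele_a)) &&
    all(a$allele_a == b$allele_a, na.rm = TRUE) &&
    all(a$allele_b == b$allele_b, na.rm = TRUE)
}
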