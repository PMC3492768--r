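# shared fixture builders and independent oracles

# one-locus genotype matrix from allele vectors
make_gm1 <- function(a, b, site, sex = NULL, locus = "L1") {
  n <- length(a)
  if (is.null(sex)) sex <- rep("unknown", n)
  genotype_matrix(sprintf("i%03d", seq_len(n)), site, sex,
                  matrix(a), matrix(b), locus)
}

# random symmetric matrix with zero diagonal
rand_sym <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m + t(m)
}

# independent HWE oracle: enumerate all perfect matchings of the allele
# copies and the conditional log-probability of each resulting table
all_matchings <- function(v) {
  if (length(v) == 0) return(list(list()))
  out <- list()
  for (j in 2:length(v)) {
    rest <- all_matchings(v[-c(1, j)])
    for (m in rest) out[[length(out) + 1]] <- c(list(c(v[1], v[j])), m)
  }
  out
}

table_log_prob <- function(pairs) {
  a <- vapply(pairs, min, 0)
  b <- vapply(pairs, max, 0)
  counts <- table(paste(a, b))
  sum(a != b) * log(2) - sum(lfactorial(counts))
}

# small stepping-stone config used by several simulation tests
quick_cfg <- function(seed, ...) {
  sim_config(seed = seed, missing_rate = 0, ...)
}

# genotype fixture emulating the field panel: 330 birds x 10 loci with
# exactly 192 entries masked
field_panel_gm <- function(seed = 7) {
  cfg <- sim_config(seed = seed, n_sites = 6, n_per_site_per_sex = 28,
                    missing_rate = 0)
  gm <- simulate_genotypes(simulate_allele_frequencies(cfg, seed = TRUE), cfg)
  gm <- subset_genotypes(gm, individuals = seq_len(330))
  set.seed(seed)
  mask <- sample(330 * 10, 192)
  a <- gm$allele_a; b <- gm$allele_b
  a[mask] <- NA_integer_; b[mask] <- NA_integer_
  genotype_matrix(gm$individual_id, gm$site, gm$sex, a, b, gm$locus_names)
}
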