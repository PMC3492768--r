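#' Read a Genepop genotype file
#'
#' Parses the classic Genepop text dialect: a title line, locus names (one per
#' line or comma-separated on one line), population blocks delimited by lines
#' equal to `Pop` (case-insensitive), and individual lines
#' `id , g1 g2 ...` where each genotype is 4 or 6 digits (two alleles of 2 or
#' 3 digits). An all-zero genotype is missing. Allele-code width is
#' auto-detected from the file and must be consistent throughout.
#'
#' Sex is not part of the Genepop format; individuals whose id ends in
#' `_M` / `_F` (or contains `,M` / `,F` tags written by [write_genepop()])
#' are labelled male/female, otherwise `"unknown"`.
#'
#' @param path path to a Genepop file.
#' @param site_names optional character vector naming the population blocks in
#'   order; defaults to the last individual id of each block, falling back to
#'   `pop_k`.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path, site_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t]+$", "", lines)
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  body <- lines[-1]                     # drop title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no 'Pop' line found")
  locus_lines <- body[seq_len(first_pop - 1)]
  locus_lines <- locus_lines[nzchar(trimws(locus_lines))]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("not a Genepop file: no locus names")

  pop_idx <- cumsum(is_pop)
  ind_lines <- which(!is_pop & seq_along(body) > first_pop)
  ind_lines <- ind_lines[nzchar(trimws(body[ind_lines]))]
  if (length(ind_lines) == 0) stop("format error: no individuals")
  blocks <- pop_idx[ind_lines]
  n_blocks <- max(pop_idx)
  if (length(unique(blocks)) != n_blocks)
    stop("format error: empty population block")

  n <- length(ind_lines)
  ids <- character(n)
  geno <- matrix(NA_character_, n, length(loci))
  for (k in seq_len(n)) {
    ln <- body[ind_lines[k]]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("record error at line %d: missing ',' separator",
                   ind_lines[k] + 1L))
    ids[k] <- trimws(parts[1])
    g <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
    g <- g[nzchar(g)]
    if (length(g) != length(loci))
      stop(sprintf("record error at line %d: %d genotypes for %d loci",
                   ind_lines[k] + 1L, length(g), length(loci)))
    geno[k, ] <- g
  }

  widths <- unique(as.vector(nchar(geno)))
  if (!all(widths %in% c(4L, 6L)))
    stop("format error: genotypes must be 4 or 6 digits wide")
  if (length(widths) != 1)
    stop("format error: mixed 2- and 3-digit allele codes in one file")
  cw <- widths / 2L
  if (any(!grepl("^[0-9]+$", geno)))
    stop("format error: non-numeric genotype codes")

  a <- matrix(as.integer(substr(geno, 1L, cw)), n)
  b <- matrix(as.integer(substr(geno, cw + 1L, 2L * cw)), n)
  half_missing <- xor(a == 0L, b == 0L)
  if (any(half_missing))
    stop("format error: half-missing genotype (one allele zero)")
  a[a == 0L] <- NA_integer_
  b[b == 0L] <- NA_integer_

  if (is.null(site_names)) {
    last_ids <- tapply(ids, blocks, function(v) v[length(v)])
    site_names <- as.character(last_ids)
    if (anyDuplicated(site_names))
      site_names <- paste0("pop_", seq_len(n_blocks))
  }
  if (length(site_names) != n_blocks)
    stop("site_names length does not match the number of population blocks")

  sex <- rep("unknown", n)
  sex[grepl("_M$", ids)] <- "male"
  sex[grepl("_F$", ids)] <- "female"

  genotype_matrix(ids, site_names[blocks], sex, a, b, loci)
}

#' Write a genotype matrix as a Genepop file
#'
#' Inverse of [read_genepop()]: writes one population block per site (in
#' order of first appearance), with missing genotypes encoded as all zeros.
#' Individual ids are suffixed `_M` / `_F` for sexed individuals so that sex
#' survives a round trip.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param code_width allele code width in digits, 2 or 3.
#' @param title title line content.
#' @return `path`, invisibly. `read_genepop(write_genepop(gm, path))`
#'   reproduces `gm` exactly.
#' @export
write_genepop <- function(gm, path, code_width = 3, title = "honeypop export") {
  code_width <- as.integer(code_width)
  stopifnot(code_width %in% c(2L, 3L))
  mx <- suppressWarnings(max(gm$allele_b, na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^code_width)
    stop(sprintf("encoding error: allele code %d does not fit in %d digits",
                 mx, code_width))
  fmt <- sprintf("%%0%dd%%0%dd", code_width, code_width)
  a <- gm$allele_a; b <- gm$allele_b
  a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
  geno <- matrix(sprintf(fmt, a, b), nrow(a))

  sex_tag <- c(male = "_M", female = "_F", unknown = "")[gm$sex]
  ids <- ifelse(grepl("_[MF]$", gm$individual_id), gm$individual_id,
                paste0(gm$individual_id, sex_tag))

  out <- c(title, gm$locus_names)
  for (s in unique(gm$site)) {
    out <- c(out, "Pop")
    rows <- which(gm$site == s)
    out <- c(out, paste0(ids[rows], " , ",
                         apply(geno[rows, , drop = FALSE], 1, paste,
                               collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
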