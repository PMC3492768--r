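#' Rainfall categories
#'
#' Assigns each site's mean monthly rainfall (mm) to one of three categories:
#' low below 32 mm, moderate from 32 to 44 mm inclusive, high above 44 mm.
#' Every non-negative value maps to exactly one category.
#'
#' @param rainfall_mm numeric vector, mean monthly rainfall in mm.
#' @return factor with levels `low`, `moderate`, `high`.
#' @export
rainfall_category <- function(rainfall_mm) {
  stopifnot(is.numeric(rainfall_mm), all(rainfall_mm >= 0, na.rm = TRUE))
  cut(rainfall_mm, breaks = c(-Inf, 32, 44, Inf), right = FALSE,
      labels = c("low", "moderate", "high")) -> f
  # right = FALSE puts 44 in "high"; the moderate band is closed at 44
  f[!is.na(rainfall_mm) & rainfall_mm == 44] <- "moderate"
  f
}

.trait_names <- c("bill_head_length", "bill_nostril_length", "bill_depth",
                  "bill_width", "wing_length", "tarsus_length", "mass")

#' Trait panel
#'
#' Names of the seven-trait morphology panel: four bill measures, wing and
#' tarsus length (mm), and body mass (g).
#' @return character vector of length 7.
#' @export
trait_names <- function() .trait_names

#' Read the site table
#'
#' CSV with columns `site` and `rainfall_mm`; a `rainfall_category` column, if
#' present, is cross-checked against the categories recomputed from
#' `rainfall_mm`.
#'
#' @param path CSV path or connection.
#' @return data.frame with `site`, `rainfall_mm`, `rainfall_category`.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site", "rainfall_mm")
  if (!all(req %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (!is.numeric(df$rainfall_mm)) stop("rainfall_mm must be numeric")
  if (any(df$rainfall_mm < 0)) stop("rainfall_mm must be non-negative")
  cat_new <- rainfall_category(df$rainfall_mm)
  if ("rainfall_category" %in% names(df) &&
      !all(as.character(cat_new) == df$rainfall_category))
    stop("rainfall_category column inconsistent with rainfall_mm thresholds")
  df$rainfall_category <- cat_new
  df
}

#' Read the morphology table
#'
#' CSV with columns `individual_id`, `site`, `sex`, and the seven traits of
#' [trait_names()]. Trait values must be numeric and strictly positive where
#' present.
#'
#' @param path CSV path or connection.
#' @return data.frame.
#' @export
read_morphology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "site", "sex", .trait_names)
  if (!all(req %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  for (tr in .trait_names) {
    if (!is.numeric(df[[tr]])) stop("non-numeric trait column: ", tr)
    if (any(df[[tr]] <= 0, na.rm = TRUE))
      stop("non-positive values in trait column: ", tr)
  }
  if (!all(df$sex %in% c("male", "female", "unknown")))
    stop("sex must be male, female or unknown")
  df
}

#' Read a pairwise geographic distance matrix
#'
#' CSV with a header of site names and a leading column of site names; entries
#' are distances in km. The matrix must be symmetric (tolerance 1e-9), have a
#' zero diagonal and positive off-diagonal entries.
#'
#' @param path CSV path or connection.
#' @return numeric matrix with dimnames set to the site labels.
#' @export
read_distances <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sites <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- sites
  if (!identical(colnames(m), sites))
    stop("distance matrix row and column site labels disagree")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-9)) stop("distance matrix diagonal must be zero")
  if (any(m[upper.tri(m)] <= 0))
    stop("off-diagonal distances must be positive")
  m
}
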