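## Loading, harmonization, and description of ordinal symptom data.

#' Load an ordinal symptom dataset from CSV
#'
#' Reads a UTF-8 CSV with a header row of symptom labels and integer cells;
#' empty cells or `NA` mark missing ratings (no numeric sentinel is used, so
#' missingness can never collide with a valid code). Cells outside the range
#' of the declared source scale are rejected.
#'
#' @param path CSV file path
#' @param scale source instrument scale: `"PSS_0_3"` (codes 0..3) or
#'   `"PCL_1_5"` (raw codes 1..5, to be harmonized with [rescalePclc()])
#' @return a [SymptomDataset-class]
#' @export
loadDataset <- function(path, scale = c("PSS_0_3", "PCL_1_5")) {
  scale <- match.arg(scale)
  raw <- read.csv(path, header = TRUE, check.names = FALSE,
                  colClasses = "character", na.strings = c("", "NA"))
  if (anyDuplicated(names(raw)))
    stop("duplicate symptom labels in header: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  m <- matrix(NA_integer_, nrow(raw), ncol(raw),
              dimnames = list(NULL, names(raw)))
  for (j in seq_along(raw)) {
    x <- trimws(raw[[j]])
    miss <- is.na(x)
    ok <- grepl("^-?[0-9]+$", x[!miss])
    if (!all(ok)) {
      bad <- which(!miss)[which(!ok)[1]]
      stop(sprintf("non-integer cell at row %d, column '%s': '%s'",
                   bad, names(raw)[j], x[bad]))
    }
    m[!miss, j] <- as.integer(x[!miss])
  }
  nl <- if (scale == "PCL_1_5") 5L else 4L
  rng <- if (scale == "PCL_1_5") c(1L, 5L) else c(0L, 3L)
  bad <- which(!is.na(m) & (m < rng[1] | m > rng[2]), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("code %d out of range [%d, %d] at row %d, column '%s'",
                 m[bad[1, , drop = FALSE]], rng[1], rng[2],
                 bad[1, 1], colnames(m)[bad[1, 2]]))
  SymptomDataset(m, nLevels = nl, sourceScale = scale)
}

#' Harmonize PCL-C 1-5 ratings onto the 0-3 interview scale
#'
#' Applies the elementwise map 1 -> 0, 2 -> 1, 3 -> 2, and 4, 5 -> 3: the two
#' most extreme questionnaire points are collapsed onto the single most
#' extreme interview point, so both instruments share a 4-level scale.
#' Missing values stay missing. A dataset already on the `PSS_0_3` scale is
#' returned unchanged. The map is many-to-one at the top, so it is not
#' invertible and, read as 0-3 codes, not idempotent for the value 3.
#'
#' @param x a [SymptomDataset-class] or an integer vector/matrix of 1-5 codes
#' @return the harmonized object on the 0-3 scale (4 levels)
#' @export
rescalePclc <- function(x) {
  if (is(x, "SymptomDataset")) {
    if (x@sourceScale == "PSS_0_3") return(x)
    v <- rescalePclc(x@values)
    return(new("SymptomDataset", values = v, nLevels = 4L,
               sourceScale = "PCL_1_5"))
  }
  v <- x
  obs <- v[!is.na(v)]
  if (length(obs) && (min(obs) < 1L || max(obs) > 5L))
    stop("PCL-C codes must lie in 1..5")
  out <- v
  out[!is.na(v)] <- pmin(v[!is.na(v)] - 1L, 3L)
  storage.mode(out) <- "integer"
  out
}

#' Keep only participants with complete ratings
#'
#' Listwise deletion: every row containing at least one missing cell is
#' dropped; row order is preserved.
#'
#' @param ds a [SymptomDataset-class]
#' @return the complete-case [SymptomDataset-class]
#' @export
listwiseComplete <- function(ds) {
  stopifnot(is(ds, "SymptomDataset"))
  keep <- complete.cases(ds@values)
  if (!any(keep)) stop("listwise deletion removed every participant")
  new("SymptomDataset", values = ds@values[keep, , drop = FALSE],
      nLevels = ds@nLevels, sourceScale = ds@sourceScale)
}

# Adjusted Fisher-Pearson skewness: g1 scaled by sqrt(n(n-1))/(n-2).
adjustedSkewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Per-symptom descriptive statistics
#'
#' Mean, standard deviation (denominator n - 1), and adjusted Fisher-Pearson
#' skewness over the non-missing cells of each symptom. A constant column
#' gets SD 0 and is flagged degenerate (its skewness is undefined and
#' reported as `NA`, never silently zeroed).
#'
#' @param ds a [SymptomDataset-class]
#' @return data.frame with columns node, n, mean, sd, skewness, degenerate
#' @export
describeDataset <- function(ds) {
  stopifnot(is(ds, "SymptomDataset"))
  v <- ds@values
  res <- lapply(seq_len(ncol(v)), function(j) {
    x <- v[, j][!is.na(v[, j])]
    if (length(x) < 2)
      stop("column '", colnames(v)[j], "' has fewer than 2 observed values")
    s <- sd(x)
    data.frame(node = colnames(v)[j], n = length(x), mean = mean(x), sd = s,
               skewness = if (s > 0) adjustedSkewness(x) else NA_real_,
               degenerate = s == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a SymptomDataset as CSV
#'
#' Same dialect as [loadDataset()] reads: header of symptom labels, integer
#' cells, empty cells for missing values.
#'
#' @param ds a [SymptomDataset-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeSymptomCsv <- function(ds, path) {
  stopifnot(is(ds, "SymptomDataset"))
  write.csv(as.data.frame(ds@values), path, row.names = FALSE, na = "")
  invisible(path)
}
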