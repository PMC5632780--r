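## Polychoric correlation estimation (two-step profile likelihood).

#' Latent thresholds from ordinal category counts
#'
#' Two-step estimator, step one: cut-point k is the standard-normal quantile
#' of the cumulative proportion through category k. Boundary categories with
#' zero mass yield infinite cut-points, handled downstream as open
#' intervals. A variable with all mass in one category has no finite
#' thresholds and is flagged degenerate.
#'
#' @param counts non-negative category counts for one variable
#' @return numeric vector of L-1 increasing cut-points with attribute
#'   `degenerate`
#' @export
estimateThresholds <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  total <- sum(counts)
  cuts <- qnorm(cumsum(counts)[-length(counts)] / total)
  attr(cuts, "degenerate") <- sum(counts > 0) < 2
  cuts
}

#' Polychoric correlation of one ordinal pair
#'
#' Maximizes the two-step profile likelihood sum n_ij log pi_ij(rho), where
#' pi_ij is the bivariate-normal rectangle probability between consecutive
#' cut-points, over rho in [-0.999, 0.999] (interior clipping keeps the
#' downstream matrices workable; a perfectly concordant table sits at the
#' bound). Cells with zero expected mass are floored at 1e-12 inside the
#' likelihood so the objective stays finite.
#'
#' @param tab two-way category count table (rows = variable A)
#' @param cutsA,cutsB finite inner cut-points for each margin
#' @return the profile-ML correlation estimate
#' @export
polychoricRho <- function(tab, cutsA, cutsB) {
  tab <- as.matrix(tab)
  storage.mode(tab) <- "integer"
  if (sum(tab) < 2) stop("pair table must contain at least 2 observations")
  if (sum(rowSums(tab) > 0) < 2 || sum(colSums(tab) > 0) < 2)
    stop("both margins must be non-degenerate")
  stopifnot(length(cutsA) == nrow(tab) - 1, length(cutsB) == ncol(tab) - 1)
  r <- .polyFitCpp(tab, as.numeric(cutsA), as.numeric(cutsB))
  max(min(r, 0.999), -0.999)
}

# profile log-likelihood, exposed for oracle comparisons
polychoricLoglik <- function(tab, cutsA, cutsB, rho) {
  tab <- as.matrix(tab)
  storage.mode(tab) <- "integer"
  .polyLoglikCpp(tab, as.numeric(cutsA), as.numeric(cutsB), rho)
}

#' Polychoric (or Pearson) correlation matrix of a dataset
#'
#' Every off-diagonal entry is estimated from that pair's complete
#' observations (`pairwise`, the default) or from the listwise-complete
#' subset (`listwise`). Thresholds are estimated from each pair's own
#' margins. If the assembled matrix is not positive semi-definite it is
#' projected to the nearest correlation matrix (Higham alternating
#' projections via [Matrix::nearPD()], tolerance 1e-8) and the projection is
#' recorded in the result.
#'
#' @param ds a [SymptomDataset-class] on the harmonized scale
#' @param pairPolicy `"pairwise"` or `"listwise"` observation handling
#' @param method `"polychoric"` (default) or `"pearson"` on the raw codes
#' @return a [CorrelationMatrix-class]
#' @export
polychoricMatrix <- function(ds, pairPolicy = c("pairwise", "listwise"),
                             method = c("polychoric", "pearson")) {
  stopifnot(is(ds, "SymptomDataset"))
  pairPolicy <- match.arg(pairPolicy)
  method <- match.arg(method)
  if (ds@sourceScale == "PCL_1_5" && ds@nLevels != 4L)
    stop("harmonize PCL-C data with rescalePclc() first")
  v <- ds@values
  if (pairPolicy == "listwise") v <- v[complete.cases(v), , drop = FALSE]
  if (nrow(v) < 2) stop("need at least 2 usable participants")
  p <- ncol(v)
  if (p < 2) stop("need at least 2 symptoms")
  # column-level degeneracy first: a single observed category is fatal
  nObsCat <- vapply(seq_len(p), function(j)
    length(unique(v[, j][!is.na(v[, j])])), integer(1))
  if (any(nObsCat < 2))
    stop("degenerate variable(s) with a single observed category: ",
         paste(colnames(v)[nObsCat < 2], collapse = ", "))
  if (method == "pearson") {
    rho <- cor(v, use = "pairwise.complete.obs")
    obs <- !is.na(v)
    pn <- crossprod(obs)
  } else {
    fit <- .polyMatrixCpp(v, ds@nLevels)
    if (any(fit$degenerate)) {
      bad <- which(fit$degenerate & upper.tri(fit$degenerate), arr.ind = TRUE)
      stop("degenerate pairwise margins for pair(s): ",
           paste(sprintf("%s-%s", colnames(v)[bad[, 1]],
                         colnames(v)[bad[, 2]]), collapse = ", "))
    }
    rho <- fit$rho
    pn <- fit$pair_n
  }
  rho[rho > 0.999] <- 0.999
  rho[rho < -0.999] <- -0.999
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  projected <- FALSE
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    np <- nearPD(rho, corr = TRUE, conv.tol = 1e-8)
    rho <- as.matrix(np$mat)
    off <- row(rho) != col(rho)
    rho[off] <- pmax(pmin(rho[off], 0.999), -0.999)
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
    projected <- TRUE
  }
  dimnames(rho) <- dimnames(pn) <- list(colnames(v), colnames(v))
  diag(pn) <- colSums(!is.na(v))
  new("CorrelationMatrix", rho = rho, pairN = pn, method = method,
      pairPolicy = pairPolicy, projected = projected)
}
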