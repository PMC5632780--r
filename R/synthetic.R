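## Synthetic ordinal datasets with known ground truth, for recovery and
## stability testing of both branches.

defaultLabels <- function(p) {
  # the 17 DSM-IV PTSD symptom short labels; generic names beyond 17
  lab <- c("intrusion", "dreams", "flash", "upset", "physior", "avoidth",
           "avoidact", "amnesia", "lossint", "distant", "numb", "future",
           "sleep", "anger", "concen", "hyper", "startle")
  if (p <= length(lab)) lab[seq_len(p)]
  else c(lab, sprintf("sym%02d", seq_len(p - length(lab))))
}

# A mix of symmetric and right-skewed latent cut-points (standard-normal
# scale): even-index variables get balanced categories, odd-index ones the
# positively skewed marginals typical of infrequently endorsed symptoms.
defaultThresholds <- function(p, L = 4L) {
  sym <- qnorm(seq_len(L - 1) / L)
  skw <- qnorm(cumsum(c(0.55, 0.25, 0.12))[seq_len(L - 1)])
  t(vapply(seq_len(p), function(i) if (i %% 2 == 0) sym else skw,
           numeric(L - 1)))
}

#' Random sparse Gaussian graphical model ground truth
#'
#' Samples a sparse symmetric precision matrix with unit diagonal whose
#' off-diagonal entries are (minus) the desired partial correlations, so the
#' implied partial-correlation matrix has exactly the sampled weights on the
#' sampled edges. Positive definiteness is checked and the draw is retried
#' (new edges and weights) up to `maxTries` times before erroring.
#'
#' @param p number of variables (>= 2)
#' @param edgeDensity fraction of the p(p-1)/2 pairs carrying an edge
#' @param weightRange magnitude range of the true partial correlations
#' @param seed integer seed for this draw
#' @param probPositive probability an edge weight is positive (symptom
#'   networks are predominantly positive; default 0.85)
#' @param thresholds optional p x (L-1) matrix of latent cut-points; default
#'   a mix of symmetric and right-skewed marginals
#' @param nLevels number of ordinal levels L for later discretization
#' @param maxTries bounded retries for positive definiteness
#' @return list of class `GroundTruthGGM`: precision, partials, latentCor,
#'   thresholds, labels
#' @export
randomGGM <- function(p, edgeDensity, weightRange = c(0.25, 0.4), seed = NULL,
                      probPositive = 0.85, thresholds = NULL, nLevels = 4L,
                      maxTries = 100L) {
  stopifnot(p >= 2, edgeDensity >= 0, edgeDensity <= 1,
            length(weightRange) == 2, weightRange[1] <= weightRange[2])
  withLocalSeed(seed, {
    pairs <- which(upper.tri(matrix(0, p, p)))
    for (try in seq_len(maxTries)) {
      A <- matrix(0, p, p)
      nE <- round(edgeDensity * length(pairs))
      if (nE > 0) {
        e <- sample(pairs, nE)
        w <- runif(nE, weightRange[1], weightRange[2]) *
          ifelse(runif(nE) < probPositive, 1, -1)
        A[e] <- w
        A <- A + t(A)
      }
      Omega <- diag(p) - A     # unit-diagonal precision; partials == A
      ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
      if (ev > 1e-3) {
        Sigma <- solve(Omega)
        lab <- defaultLabels(p)
        thr <- thresholds %||% defaultThresholds(p, nLevels)
        stopifnot(nrow(thr) == p, all(apply(thr, 1, function(x)
          all(diff(x) > 0))))
        R <- stats::cov2cor(Sigma)
        dimnames(Omega) <- dimnames(A) <- dimnames(R) <- list(lab, lab)
        out <- list(precision = Omega, partials = A,
                    latentCor = R, thresholds = thr,
                    labels = lab, nLevels = as.integer(nLevels))
        class(out) <- "GroundTruthGGM"
        return(out)
      }
    }
    stop("could not draw a positive-definite precision in ", maxTries,
         " tries; weight range infeasible at this density")
  })
}

#' Random linear-Gaussian DAG ground truth
#'
#' Edges are sampled only in the upper triangle of a random node permutation,
#' so the graph is acyclic by construction. Data are generated by the linear
#' structural model x_j = sum_i b_ij x_i + e_j with independent Gaussian
#' noise.
#'
#' @param p number of variables
#' @param edgeProb probability of each admissible edge
#' @param coeffRange magnitude range of structural coefficients
#' @param seed integer seed
#' @param probPositive probability a coefficient is positive
#' @param thresholds,nLevels as in [randomGGM()]
#' @param noiseSd per-node residual standard deviation (recycled)
#' @return list of class `GroundTruthDAG`: adjacency, coefficients, noiseSd,
#'   thresholds, labels
#' @export
randomDAG <- function(p, edgeProb, coeffRange = c(0.4, 0.8), seed = NULL,
                      probPositive = 0.9, thresholds = NULL, nLevels = 4L,
                      noiseSd = 1) {
  stopifnot(p >= 2, edgeProb >= 0, edgeProb <= 1)
  withLocalSeed(seed, {
    ord <- sample.int(p)
    adj <- matrix(0L, p, p)
    coef <- matrix(0, p, p)
    for (a in seq_len(p - 1)) for (b in seq((a + 1), p)) {
      i <- ord[a]; j <- ord[b]        # i precedes j topologically
      if (runif(1) < edgeProb) {
        adj[i, j] <- 1L
        coef[i, j] <- runif(1, coeffRange[1], coeffRange[2]) *
          ifelse(runif(1) < probPositive, 1, -1)
      }
    }
    lab <- defaultLabels(p)
    dimnames(adj) <- dimnames(coef) <- list(lab, lab)
    thr <- thresholds %||% defaultThresholds(p, nLevels)
    out <- list(adjacency = adj, coefficients = coef,
                noiseSd = rep_len(noiseSd, p), thresholds = thr,
                labels = lab, nLevels = as.integer(nLevels))
    class(out) <- "GroundTruthDAG"
    out
  })
}

#' Implied latent covariance of a GroundTruthDAG
#'
#' Closed form Sigma = (I - B')^-1 D (I - B')^-T for the linear structural
#' model, with B the coefficient matrix (entry i, j = effect of i on j) and
#' D the diagonal of noise variances.
#'
#' @param truth a `GroundTruthDAG`
#' @return p x p covariance matrix of the latent variables
#' @export
dagLatentCovariance <- function(truth) {
  stopifnot(inherits(truth, "GroundTruthDAG"))
  p <- nrow(truth$adjacency)
  M <- solve(diag(p) - t(truth$coefficients))
  M %*% diag(truth$noiseSd^2, p) %*% t(M)
}

#' Draw an ordinal dataset from a ground-truth model
#'
#' Latent draws come from the implied multivariate normal (GGM: correlation
#' matrix of the inverse precision; DAG: simulation in topological order,
#' then standardization by the analytic latent SDs) and each variable is
#' discretized by its cut-points into codes 0..L-1.
#'
#' @param truth a `GroundTruthGGM` or `GroundTruthDAG`
#' @param n sample size (>= 1)
#' @param seed integer seed
#' @return a [SymptomDataset-class] on the harmonized 0..L-1 scale
#' @export
sampleOrdinal <- function(truth, n, seed = NULL) {
  stopifnot(n >= 1)
  withLocalSeed(seed, {
    if (inherits(truth, "GroundTruthGGM")) {
      R <- truth$latentCor
      ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
      if (ev <= 0) stop("latent correlation matrix is not positive definite")
      Z <- matrix(rnorm(n * nrow(R)), n) %*% chol(R)
    } else if (inherits(truth, "GroundTruthDAG")) {
      p <- nrow(truth$adjacency)
      Z <- matrix(0, n, p)
      remaining <- seq_len(p)
      placed <- logical(p)
      while (any(!placed)) {
        ready <- which(!placed &
                         colSums(truth$adjacency[!placed, , drop = FALSE]) == 0)
        if (!length(ready)) stop("ground-truth adjacency contains a cycle")
        for (j in ready) {
          pa <- which(truth$adjacency[, j] == 1)
          mu <- if (length(pa))
            Z[, pa, drop = FALSE] %*% truth$coefficients[pa, j] else 0
          Z[, j] <- mu + rnorm(n, sd = truth$noiseSd[j])
          placed[j] <- TRUE
        }
      }
      Z <- sweep(Z, 2, sqrt(diag(dagLatentCovariance(truth))), "/")
    } else stop("truth must be a GroundTruthGGM or GroundTruthDAG")
    L <- truth$nLevels
    codes <- vapply(seq_len(ncol(Z)), function(j)
      as.integer(findInterval(Z[, j], truth$thresholds[j, ])),
      integer(n))
    codes <- matrix(codes, nrow = n,
                    dimnames = list(NULL, truth$labels))
    SymptomDataset(codes, nLevels = L, sourceScale = "PSS_0_3")
  })
}

#' Inject missing cells into a dataset
#'
#' Exactly `nRows` distinct participants receive one missing cell each,
#' chosen uniformly at random, emulating scattered item non-response.
#'
#' @param ds a [SymptomDataset-class]
#' @param nRows number of rows to receive a missing cell
#' @param seed integer seed
#' @return the dataset with injected missingness
#' @export
injectMissing <- function(ds, nRows, seed = NULL) {
  stopifnot(is(ds, "SymptomDataset"))
  d <- dim(ds@values)
  if (nRows > d[1]) stop("nRows exceeds the number of participants")
  if (nRows == 0) return(ds)
  withLocalSeed(seed, {
    v <- ds@values
    rows <- sample.int(d[1], nRows)
    cols <- sample.int(d[2], nRows, replace = TRUE)
    v[cbind(rows, cols)] <- NA_integer_
    new("SymptomDataset", values = v, nLevels = ds@nLevels,
        sourceScale = ds@sourceScale)
  })
}

#' The default study-shaped simulation preset
#'
#' Emulates the shape of a 17-symptom PTSD dataset: 17 ordinal variables on
#' 4 levels, 179 participants, 14 rows containing one missing cell, sparse
#' positive latent structure, and a mix of symmetric and right-skewed
#' marginals. The values are generic, not a reconstruction of any real
#' sample.
#'
#' @param seed integer seed controlling truth, sampling, and missingness
#' @param n sample size (default 179)
#' @param nMissingRows rows receiving a missing cell (default 14)
#' @param edgeDensity,weightRange passed to [randomGGM()]
#' @return list with elements `truth` (GroundTruthGGM) and `dataset`
#' @export
csaPtsdPreset <- function(seed = 1L, n = 179L, nMissingRows = 14L,
                          edgeDensity = 0.15, weightRange = c(0.25, 0.4)) {
  truth <- randomGGM(17L, edgeDensity, weightRange, seed = seed)
  ds <- sampleOrdinal(truth, n, seed = seed + 1L)
  ds <- injectMissing(ds, nMissingRows, seed = seed + 2L)
  list(truth = truth, dataset = ds)
}

#' Serialize a ground-truth model to JSON
#'
#' Writes precision/adjacency, coefficients, thresholds and labels so that
#' recovery analyses can be reproduced from files alone.
#'
#' @param truth a `GroundTruthGGM` or `GroundTruthDAG`
#' @param path output JSON path
#' @param seed optional seed to record
#' @return `path`, invisibly
#' @export
writeGroundTruthJson <- function(truth, path, seed = NULL) {
  x <- unclass(truth)
  x$kind <- class(truth)[1]
  if (!is.null(seed)) x$seed <- seed
  write_json(x, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
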