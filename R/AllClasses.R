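## Central S4 containers for both analysis branches.

#' SymptomDataset: participants x symptoms ordinal ratings
#'
#' Holds an integer matrix of ordinal codes with `NA` marking missing cells,
#' the number of ordinal levels, and the source instrument scale. Codes are
#' `0..nLevels-1` for the interview-style `PSS_0_3` scale and `1..5` for the
#' raw questionnaire `PCL_1_5` scale before harmonization (see
#' [rescalePclc()]). Column names are the symptom labels and are required to
#' be unique.
#'
#' @slot values integer matrix (participants in rows, symptoms in columns)
#' @slot nLevels integer, number of ordinal levels (4 after harmonization)
#' @slot sourceScale `"PSS_0_3"` or `"PCL_1_5"`
#' @export
setClass("SymptomDataset",
  representation(values = "matrix", nLevels = "integer",
                 sourceScale = "character"))

setValidity("SymptomDataset", function(object) {
  v <- object@values
  if (!is.integer(v)) return("values must be an integer matrix")
  if (is.null(colnames(v)) || anyNA(colnames(v)) || any(colnames(v) == ""))
    return("values must have non-empty column labels")
  if (anyDuplicated(colnames(v)))
    return("symptom labels must be unique")
  L <- object@nLevels
  if (length(L) != 1L || is.na(L) || L < 2L)
    return("nLevels must be a single integer >= 2")
  if (!object@sourceScale %in% c("PSS_0_3", "PCL_1_5"))
    return("sourceScale must be 'PSS_0_3' or 'PCL_1_5'")
  # raw PCL-C carries codes 1..5; once harmonized (L == 4) both sources
  # share the 0..3 interview coding
  rng <- if (object@sourceScale == "PCL_1_5" && L == 5L) c(1L, 5L)
         else c(0L, L - 1L)
  x <- v[!is.na(v)]
  if (length(x) && (min(x) < rng[1] || max(x) > rng[2]))
    return(sprintf("non-missing codes must lie in [%d, %d]", rng[1], rng[2]))
  TRUE
})

#' Construct a SymptomDataset
#'
#' @param values numeric or integer matrix of ordinal codes; `NA` = missing.
#'   Must carry unique column names (symptom labels).
#' @param nLevels number of ordinal levels (default 4, the harmonized scale)
#' @param sourceScale `"PSS_0_3"` (codes 0..nLevels-1) or `"PCL_1_5"`
#'   (raw 1..5 questionnaire codes, `nLevels = 5`)
#' @return a [SymptomDataset-class] object
#' @export
SymptomDataset <- function(values, nLevels = 4L, sourceScale = "PSS_0_3") {
  values <- as.matrix(values)
  if (!is.integer(values)) {
    if (any(values[!is.na(values)] %% 1 != 0))
      stop("ordinal codes must be integers")
    storage.mode(values) <- "integer"
  }
  new("SymptomDataset", values = values, nLevels = as.integer(nLevels),
      sourceScale = sourceScale)
}

#' @describeIn SymptomDataset number of participants and symptoms
#' @param x a SymptomDataset
#' @export
setMethod("dim", "SymptomDataset", function(x) dim(x@values))

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("ordinalValues", function(x) standardGeneric("ordinalValues"))
#' @rdname accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' Accessors for symnet containers
#'
#' `nodeLabels()` returns the symptom labels; `missingMask()` the logical
#' matrix of missing cells; `ordinalValues()` the raw code matrix;
#' `nLevels()` the number of ordinal levels.
#'
#' @param x a symnet container
#' @name accessors
NULL

#' @rdname accessors
setMethod("nodeLabels", "SymptomDataset", function(x) colnames(x@values))
#' @rdname accessors
setMethod("missingMask", "SymptomDataset", function(x) is.na(x@values))
#' @rdname accessors
setMethod("ordinalValues", "SymptomDataset", function(x) x@values)
#' @rdname accessors
setMethod("nLevels", "SymptomDataset", function(x) x@nLevels)

setMethod("show", "SymptomDataset", function(object) {
  d <- dim(object@values)
  nm <- sum(is.na(object@values))
  cat(sprintf("SymptomDataset: %d participants x %d symptoms (%s, %d levels)\n",
              d[1], d[2], object@sourceScale, object@nLevels))
  cat(sprintf("  missing cells: %d in %d row(s)\n", nm,
              sum(rowSums(is.na(object@values)) > 0)))
  cat("  symptoms:", paste(head(colnames(object@values), 8), collapse = ", "),
      if (d[2] > 8) "..." else "", "\n")
})

#' CorrelationMatrix: polychoric (or Pearson) correlations among symptoms
#'
#' @slot rho symmetric correlation matrix with unit diagonal, off-diagonal
#'   entries clipped to the interior `[-0.999, 0.999]`
#' @slot pairN per-pair observation counts actually used
#' @slot method `"polychoric"` or `"pearson"`
#' @slot pairPolicy `"pairwise"` or `"listwise"`
#' @slot projected `TRUE` if a nearest-correlation projection was needed to
#'   restore positive semi-definiteness of the pairwise assembly
#' @export
setClass("CorrelationMatrix",
  representation(rho = "matrix", pairN = "matrix", method = "character",
                 pairPolicy = "character", projected = "logical"))

setValidity("CorrelationMatrix", function(object) {
  r <- object@rho
  if (nrow(r) != ncol(r)) return("rho must be square")
  if (max(abs(r - t(r))) > 1e-8) return("rho must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-12) return("rho diagonal must be 1")
  if (max(abs(r[row(r) != col(r)])) > 0.999 + 1e-12)
    return("off-diagonal correlations must lie within [-0.999, 0.999]")
  TRUE
})

#' @rdname accessors
#' @export
setGeneric("pairN", function(x) standardGeneric("pairN"))
#' @rdname accessors
setMethod("pairN", "CorrelationMatrix", function(x) x@pairN)
#' @rdname accessors
setMethod("nodeLabels", "CorrelationMatrix", function(x) colnames(x@rho))

#' @rdname accessors
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))
#' @rdname accessors
setMethod("corValues", "CorrelationMatrix", function(x) x@rho)

setMethod("show", "CorrelationMatrix", function(object) {
  p <- ncol(object@rho)
  off <- object@rho[upper.tri(object@rho)]
  cat(sprintf("CorrelationMatrix: %d x %d (%s, %s deletion%s)\n", p, p,
              object@method, object@pairPolicy,
              if (object@projected) ", PSD-projected" else ""))
  cat(sprintf("  off-diagonal range: [%.3f, %.3f]\n", min(off), max(off)))
})

#' WeightedNetwork: regularized partial-correlation network (GGM)
#'
#' The result of [ebicGlasso()]: symmetric partial-correlation edge weights
#' with zero diagonal, the selected lasso penalty, and the full EBIC path.
#'
#' @slot weights symmetric p x p matrix of partial correlations, zero diagonal
#' @slot lambdaSelected penalty at the EBIC optimum
#' @slot ebicPath data.frame with columns lambda, nEdges, loglik, ebic
#' @slot gamma EBIC hyperparameter used
#' @slot n sample size used for the likelihood term
#' @export
setClass("WeightedNetwork",
  representation(weights = "matrix", lambdaSelected = "numeric",
                 ebicPath = "data.frame", gamma = "numeric", n = "numeric"))

setValidity("WeightedNetwork", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (max(abs(w - t(w))) > 1e-8) return("weights must be symmetric")
  if (max(abs(diag(w))) > 1e-12) return("weights diagonal must be 0")
  if (max(abs(w)) >= 1) return("partial correlations must have |w| < 1")
  TRUE
})

#' @rdname accessors
setMethod("nodeLabels", "WeightedNetwork", function(x) colnames(x@weights))
#' @describeIn WeightedNetwork the partial-correlation weight matrix
#' @param object a WeightedNetwork
#' @param ... unused
#' @export
setMethod("weights", "WeightedNetwork", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname accessors
setMethod("edgeCount", "WeightedNetwork", function(x)
  sum(abs(x@weights[upper.tri(x@weights)]) > 1e-10))

setMethod("show", "WeightedNetwork", function(object) {
  p <- ncol(object@weights)
  cat(sprintf("WeightedNetwork: %d nodes, %d edges (of %d possible)\n",
              p, edgeCount(object), p * (p - 1) / 2))
  cat(sprintf("  lambda = %.4g selected by EBIC (gamma = %.2f, n = %g)\n",
              object@lambdaSelected, object@gamma, object@n))
})

#' DirectedModel: bootstrap-averaged directed acyclic graph
#'
#' @slot adjacency p x p 0/1 matrix, `adjacency[i, j] == 1` for edge i -> j;
#'   guaranteed acyclic
#' @slot edgeStrength symmetric matrix: fraction of bootstrap networks
#'   containing each unordered pair in either direction
#' @slot directionProb for retained edges, fraction of edge-containing
#'   bootstrap networks pointing in the depicted direction (>= 0.5)
#' @slot threshold edge-retention cut-point on the strengths
#' @slot edgeBic BIC importance (model-fit loss on removal) per retained edge
#' @slot B number of bootstrap replicates behind the averages
#' @slot repairs log of acyclicity repairs applied during averaging
#' @slot ties labels of pairs whose direction was an exact 50/50 tie
#' @export
setClass("DirectedModel",
  representation(adjacency = "matrix", edgeStrength = "matrix",
                 directionProb = "matrix", threshold = "numeric",
                 edgeBic = "matrix", B = "integer",
                 repairs = "character", ties = "character"))

setValidity("DirectedModel", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (!all(a %in% c(0, 1))) return("adjacency must be 0/1")
  if (any(a == 1 & t(a) == 1)) return("adjacency contains a 2-cycle")
  if (!isAcyclic(a)) return("adjacency contains a cycle")
  dp <- object@directionProb[a == 1]
  if (length(dp) && any(dp < 0.5 - 1e-12))
    return("direction probabilities of depicted edges must be >= 0.5")
  TRUE
})

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
setMethod("adjacency", "DirectedModel", function(x) x@adjacency)
#' @rdname accessors
#' @export
setGeneric("edgeStrength", function(x) standardGeneric("edgeStrength"))
#' @rdname accessors
setMethod("edgeStrength", "DirectedModel", function(x) x@edgeStrength)
#' @rdname accessors
#' @export
setGeneric("directionProb", function(x) standardGeneric("directionProb"))
#' @rdname accessors
setMethod("directionProb", "DirectedModel", function(x) x@directionProb)
#' @rdname accessors
setMethod("nodeLabels", "DirectedModel", function(x) colnames(x@adjacency))
#' @rdname accessors
setMethod("edgeCount", "DirectedModel", function(x) sum(x@adjacency))

#' @rdname accessors
#' @export
setGeneric("retentionThreshold", function(x) standardGeneric("retentionThreshold"))
#' @rdname accessors
setMethod("retentionThreshold", "DirectedModel", function(x) x@threshold)

setMethod("show", "DirectedModel", function(object) {
  cat(sprintf("DirectedModel: %d nodes, %d directed edges (B = %d bootstraps)\n",
              ncol(object@adjacency), sum(object@adjacency), object@B))
  cat(sprintf("  retention threshold on edge strength: %.4g\n",
              object@threshold))
  if (length(object@repairs))
    cat("  acyclicity repairs:", length(object@repairs), "\n")
  if (length(object@ties))
    cat("  direction ties broken lexicographically:",
        paste(object@ties, collapse = "; "), "\n")
})

#' Edge table of a DirectedModel
#'
#' One row per retained directed edge with its bootstrap strength, direction
#' probability, and (when annotated by [edgeBicImportance()]) BIC importance.
#'
#' @param x a [DirectedModel-class]
#' @return data.frame with columns from, to, strength, direction_prob,
#'   bic_importance
#' @export
edgeTable <- function(x) {
  stopifnot(is(x, "DirectedModel"))
  idx <- which(x@adjacency == 1, arr.ind = TRUE)
  lab <- nodeLabels(x)
  df <- data.frame(
    from = lab[idx[, 1]], to = lab[idx[, 2]],
    strength = x@edgeStrength[idx],
    direction_prob = x@directionProb[idx],
    bic_importance = x@edgeBic[idx],
    stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}
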