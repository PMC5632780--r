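## End-to-end orchestration and the GGM-vs-DAG comparison.

stageLog <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[symnet] ", fmt), ...))
}

#' Run the undirected (GGM) branch
#'
#' Polychoric correlations -> EBIC-tuned graphical lasso -> centrality ->
#' stability (bootstrap edge CIs, CS-coefficients, bootstrapped centrality
#' difference test) -> restricted-variance diagnostics. With `outDir` set,
#' all artifacts are written as CSV/JSON together with run metadata.
#'
#' @param ds a [SymptomDataset-class] on the harmonized scale
#' @param cfg a [glassoConfig()]
#' @param B bootstrap resamples for edge CIs and the difference test
#' @param BPerDrop subsamples per drop proportion for the CS-coefficient
#' @param dropGrid case-dropping grid
#' @param seed integer seed for all bootstrap stages
#' @param pairPolicy observation policy for the polychoric step
#' @param stability set `FALSE` to skip the (expensive) bootstrap stages
#' @param outDir optional output directory
#' @param verbose log one line per stage
#' @return list with `correlation`, `network`, `centrality`, `descriptives`,
#'   `diagnostics`, and (unless skipped) `stability` (edge CIs, `cs`,
#'   `diffTest`)
#' @export
runGgmBranch <- function(ds, cfg = glassoConfig(), B = 1000L,
                         BPerDrop = 250L,
                         dropGrid = c(0.10, 0.25, 0.40, 0.55, 0.70, 0.75),
                         seed = NULL, pairPolicy = "pairwise",
                         stability = TRUE, outDir = NULL, verbose = FALSE) {
  stopifnot(is(ds, "SymptomDataset"))
  stageLog(verbose, "GGM branch: %d rows, %d symptoms (%s)", nrow(ds@values),
           ncol(ds@values), pairPolicy)
  S <- polychoricMatrix(ds, pairPolicy = pairPolicy)
  net <- ebicGlasso(S, nrow(ds@values), cfg)
  stageLog(verbose, "selected lambda %.4g with %d edges", net@lambdaSelected,
           edgeCount(net))
  cent <- nodeCentrality(net)
  desc <- describeDataset(ds)
  diag_ <- tryCatch(varianceDiagnostics(desc, cent), error = function(e) {
    warning("variance diagnostics unavailable: ", conditionMessage(e))
    NULL
  })
  out <- list(correlation = S, network = net, centrality = cent,
              descriptives = desc, diagnostics = diag_)
  if (stability) {
    stageLog(verbose, "bootstrapping %d edge resamples", B)
    out$stability <- list(
      edgeCi = bootstrapEdges(ds, cfg, B = B, seed = seed,
                              pairPolicy = pairPolicy),
      cs = csCoefficient(ds, cfg, dropGrid = dropGrid, BPerDrop = BPerDrop,
                         seed = if (is.null(seed)) NULL else seed + 1L,
                         pairPolicy = pairPolicy),
      diffTest = centralityDifferenceTest(ds, cfg, B = B,
                                          seed = if (is.null(seed)) NULL
                                                 else seed + 2L,
                                          pairPolicy = pairPolicy))
    stageLog(verbose, "CS-coefficients: %s",
             paste(sprintf("%s %.2f", names(out$stability$cs$cs),
                           out$stability$cs$cs), collapse = ", "))
  }
  if (!is.null(outDir)) writeGgmArtifacts(out, ds, cfg, seed, outDir)
  out
}

#' Run the directed (Bayesian network) branch
#'
#' Listwise-complete data -> bootstrap ensemble of hill-climbing DAGs ->
#' statistically driven edge retention and majority-direction averaging ->
#' BIC edge-importance annotation.
#'
#' @param ds a [SymptomDataset-class]; incomplete rows are dropped here
#' @param cfg a [searchConfig()] (its `seed` drives the whole branch)
#' @param outDir optional output directory
#' @param verbose log one line per stage
#' @return list with `model` (a [DirectedModel-class] with BIC annotation),
#'   `bootstrap` (strength/direction tables), `data` (the complete-case
#'   dataset used)
#' @export
runDagBranch <- function(ds, cfg = searchConfig(), outDir = NULL,
                         verbose = FALSE) {
  stopifnot(is(ds, "SymptomDataset"))
  cc <- listwiseComplete(ds)
  stageLog(verbose, "DAG branch: %d of %d rows complete", nrow(cc@values),
           nrow(ds@values))
  bs <- bootstrapDags(cc, cfg)
  stageLog(verbose, "bootstrap done (B = %d, %d redraws)", bs$B, bs$failures)
  model <- averagedNetwork(bs$strength, bs$dirCounts, cfg)
  model <- edgeBicImportance(model, cc)
  stageLog(verbose, "averaged model: %d edges above threshold %.3f",
           sum(model@adjacency), model@threshold)
  if (!is.null(outDir)) writeDagArtifacts(model, bs, cfg, outDir)
  list(model = model, bootstrap = bs, data = cc)
}

#' Compare the undirected and directed networks
#'
#' Maps DAG edges to unordered pairs, partitions the GGM edges into
#' DAG-shared and DAG-absent groups, and reports counts, the mean and SD of
#' absolute GGM weights per group, and the sign composition of the
#' DAG-absent group. For a like-for-like comparison the GGM should be
#' re-estimated on the same complete-case participants as the DAG (see
#' [runGgmBranch()] with a listwise dataset).
#'
#' @param ggm a [WeightedNetwork-class]
#' @param dag a [DirectedModel-class] over the same node labels
#' @return list of class `ComparisonReport`
#' @export
compareNetworks <- function(ggm, dag) {
  stopifnot(is(ggm, "WeightedNetwork"), is(dag, "DirectedModel"))
  if (!identical(nodeLabels(ggm), nodeLabels(dag)))
    stop("node label sets differ between the two networks")
  w <- ggm@weights
  ut <- upper.tri(w)
  dagPairs <- (dag@adjacency + t(dag@adjacency)) > 0
  ggmEdge <- ut & abs(w) > 1e-10
  shared <- ggmEdge & dagPairs
  ggmOnly <- ggmEdge & !dagPairs
  msd <- function(mask) {
    x <- abs(w[mask])
    if (!length(x)) c(mean = NA_real_, sd = NA_real_)
    else c(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_)
  }
  out <- list(
    dagEdgeCount = sum(dag@adjacency),
    ggmEdgeCount = sum(ggmEdge),
    sharedPairCount = sum(shared),
    dagOnlyPairCount = sum(dagPairs & ut & !ggmEdge),
    sharedAbsWeight = msd(shared),
    ggmOnlyAbsWeight = msd(ggmOnly),
    ggmOnlySigns = c(positive = sum(w[ggmOnly] > 0),
                     negative = sum(w[ggmOnly] < 0)))
  class(out) <- "ComparisonReport"
  out
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("Network comparison (GGM vs DAG)\n")
  cat(sprintf("  DAG edges: %d   GGM edges: %d   shared pairs: %d\n",
              x$dagEdgeCount, x$ggmEdgeCount, x$sharedPairCount))
  cat(sprintf("  |GGM weight| shared:   M = %.3f, SD = %.3f\n",
              x$sharedAbsWeight["mean"], x$sharedAbsWeight["sd"]))
  cat(sprintf("  |GGM weight| GGM-only: M = %.3f, SD = %.3f\n",
              x$ggmOnlyAbsWeight["mean"], x$ggmOnlyAbsWeight["sd"]))
  cat(sprintf("  GGM-only signs: %d positive, %d negative\n",
              x$ggmOnlySigns["positive"], x$ggmOnlySigns["negative"]))
  invisible(x)
}
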