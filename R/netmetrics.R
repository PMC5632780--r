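## Centrality indices and bootstrap/case-dropping stability analyses.

netGraph <- function(w) {
  g <- graph_from_adjacency_matrix(abs(w) > 1e-10, mode = "undirected",
                                   diag = FALSE)
  igraph::E(g)$weight <- NA_real_
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$weight <- 1 / abs(w[el])   # path length = 1/|weight|
  }
  g
}

#' Node centrality of a weighted network
#'
#' Strength is the sum of absolute incident edge weights; shortest paths use
#' edge lengths `1/|weight|`; closeness is the inverse of the summed
#' shortest-path distances to all other nodes; betweenness counts how often
#' a node lies on shortest paths between other pairs, with credit split
#' equally among tied geodesics. All three indices therefore ignore edge
#' signs. If the network is disconnected, a node with any unreachable
#' partner gets closeness 0 and the result carries a `disconnected`
#' attribute; a z-scored column whose raw values are constant is `NA`.
#'
#' @param net a [WeightedNetwork-class] or symmetric weight matrix
#' @return data.frame with columns node, betweenness, closeness, strength
#'   and their z-scored versions, plus attribute `disconnected`
#' @export
nodeCentrality <- function(net) {
  w <- if (is(net, "WeightedNetwork")) net@weights else as.matrix(net)
  checkSquareLabelled(w, "weight matrix")
  p <- ncol(w)
  if (p < 2) stop("need at least 2 nodes")
  g <- netGraph(w)
  strength <- rowSums(abs(w))
  btw <- betweenness(g, directed = FALSE,
                     weights = if (igraph::ecount(g)) igraph::E(g)$weight
                               else NULL)
  D <- distances(g, weights = if (igraph::ecount(g)) igraph::E(g)$weight
                              else NULL)
  disconnected <- any(!is.finite(D[upper.tri(D)]))
  clo <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    if (any(!is.finite(d))) 0 else 1 / sum(d)
  }, numeric(1))
  safeZ <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(NA_real_, length(x)) else (x - mean(x)) / s
  }
  out <- data.frame(node = colnames(w), betweenness = as.numeric(btw),
                    closeness = clo, strength = strength,
                    z_betweenness = safeZ(as.numeric(btw)),
                    z_closeness = safeZ(clo), z_strength = safeZ(strength),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "disconnected") <- disconnected
  if (disconnected)
    warning("network is disconnected; closeness uses the unreachable -> 0 rule")
  out
}

#' z-score a per-node metric
#'
#' `(x - mean(x)) / sd(x)` across nodes, SD with denominator n - 1.
#'
#' @param x numeric vector over nodes
#' @return z-scores with mean 0 and SD 1
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  s <- sd(x)
  if (is.na(s) || s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

# One full estimation pass: dataset rows -> polychoric -> EBIC glasso.
# Returns NULL when the draw is degenerate (caller redraws).
fitNetworkOnce <- function(values, nLevels, cfg, pairPolicy) {
  ds <- new("SymptomDataset", values = values, nLevels = nLevels,
            sourceScale = "PSS_0_3")
  tryCatch({
    S <- polychoricMatrix(ds, pairPolicy = pairPolicy)
    ebicGlasso(S, nrow(values), cfg)
  }, error = function(e) NULL)
}

#' Bootstrap confidence intervals for edge weights
#'
#' Nonparametric row resampling: the full polychoric -> EBIC-glasso pipeline
#' is re-estimated on each of `B` resamples and percentile 95% intervals are
#' formed per edge. Degenerate resamples (e.g. a column collapsing to one
#' category) are re-drawn up to a cap and counted.
#'
#' @param ds a [SymptomDataset-class]
#' @param cfg a [glassoConfig()]
#' @param B number of bootstrap resamples (>= 2)
#' @param seed integer seed
#' @param pairPolicy passed to [polychoricMatrix()]
#' @return list with `edges` (data.frame: node_a, node_b, estimate, lower,
#'   upper, ci_excludes_zero), `boots` (B x nPairs weight matrix),
#'   `failures` (redrawn resample count)
#' @export
bootstrapEdges <- function(ds, cfg = glassoConfig(), B = 10000L, seed = NULL,
                           pairPolicy = "pairwise") {
  stopifnot(is(ds, "SymptomDataset"), B >= 2)
  v <- ds@values
  n <- nrow(v)
  full <- fitNetworkOnce(v, ds@nLevels, cfg, pairPolicy)
  if (is.null(full)) stop("the full dataset itself is degenerate")
  p <- ncol(v)
  ut <- upper.tri(matrix(0, p, p))
  lab <- colnames(v)
  pairIdx <- which(ut, arr.ind = TRUE)
  withLocalSeed(seed, {
    boots <- matrix(NA_real_, B, sum(ut))
    failures <- 0L
    cap <- 5L * B
    b <- 1L
    while (b <= B) {
      net <- fitNetworkOnce(v[sample.int(n, n, replace = TRUE), , drop = FALSE],
                            ds@nLevels, cfg, pairPolicy)
      if (is.null(net)) {
        failures <- failures + 1L
        if (failures > cap)
          stop("too many degenerate bootstrap resamples (", failures, ")")
        next
      }
      boots[b, ] <- net@weights[ut]
      b <- b + 1L
    }
    est <- full@weights[ut]
    ci <- apply(boots, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    edges <- data.frame(
      node_a = lab[pairIdx[, 1]], node_b = lab[pairIdx[, 2]],
      estimate = est, lower = ci[1, ], upper = ci[2, ],
      ci_excludes_zero = ci[1, ] > 0 | ci[2, ] < 0,
      stringsAsFactors = FALSE)
    list(edges = edges, boots = boots, failures = failures,
         network = full)
  })
}

#' Bootstrapped centrality difference test
#'
#' For every node pair and metric, bootstrap the centrality difference; the
#' pair differs significantly iff the 95% percentile interval of the
#' difference excludes 0. No multiplicity correction is applied (the
#' convention of the bootstrap toolkits this mirrors).
#'
#' @inheritParams bootstrapEdges
#' @param metrics which centrality indices to test
#' @return named list of symmetric logical matrices (TRUE = significant),
#'   with attribute `failures`
#' @export
centralityDifferenceTest <- function(ds, cfg = glassoConfig(), B = 1000L,
                                     seed = NULL,
                                     metrics = c("betweenness", "closeness",
                                                 "strength"),
                                     pairPolicy = "pairwise") {
  stopifnot(is(ds, "SymptomDataset"), B >= 2)
  metrics <- match.arg(metrics, several.ok = TRUE)
  v <- ds@values
  n <- nrow(v)
  p <- ncol(v)
  lab <- colnames(v)
  withLocalSeed(seed, {
    cent <- array(NA_real_, c(B, p, length(metrics)),
                  dimnames = list(NULL, lab, metrics))
    failures <- 0L
    cap <- 5L * B
    b <- 1L
    while (b <= B) {
      net <- fitNetworkOnce(v[sample.int(n, n, replace = TRUE), , drop = FALSE],
                            ds@nLevels, cfg, pairPolicy)
      if (is.null(net)) {
        failures <- failures + 1L
        if (failures > cap) stop("too many degenerate bootstrap resamples")
        next
      }
      ct <- suppressWarnings(nodeCentrality(net))
      for (m in metrics) cent[b, , m] <- ct[[m]]
      b <- b + 1L
    }
    out <- lapply(metrics, function(m) {
      sig <- matrix(FALSE, p, p, dimnames = list(lab, lab))
      for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
        d <- cent[, i, m] - cent[, j, m]
        q <- quantile(d, c(0.025, 0.975), names = FALSE)
        sig[i, j] <- sig[j, i] <- q[1] > 0 | q[2] < 0
      }
      sig
    })
    names(out) <- metrics
    attr(out, "failures") <- failures
    out
  })
}

# Decision rule of the CS-coefficient, separated out so it can be exercised
# on injected correlation draws: corByDrop is a list (one per grid value) of
# numeric vectors of full-vs-subsample centrality correlations.
csFromCorrelations <- function(corByDrop, dropGrid, corThreshold = 0.70,
                               probLevel = 0.95) {
  stopifnot(length(corByDrop) == length(dropGrid), all(diff(dropGrid) > 0))
  ok <- vapply(corByDrop, function(r)
    isTRUE(mean(r >= corThreshold, na.rm = TRUE) >= probLevel), logical(1))
  if (!any(ok)) return(0)
  max(dropGrid[ok])
}

#' Case-dropping centrality stability (CS) coefficient
#'
#' For each drop proportion on the grid, `BPerDrop` subsamples are drawn
#' without replacement, the network is re-estimated, and subsample
#' centralities are correlated with the full-sample ones across nodes. The
#' CS-coefficient per metric is the largest grid proportion at which at
#' least 95% of those correlations are >= 0.70 (0 if none). Values >= .50
#' indicate stable centrality orderings; .25 is the usual minimum for
#' interpreting them at all.
#'
#' @inheritParams bootstrapEdges
#' @param metrics which centrality indices to track
#' @param dropGrid increasing drop proportions in (0, 1)
#' @param BPerDrop subsamples per drop proportion (>= 20)
#' @param corThreshold,probLevel the .70 / 95% rule
#' @return list with `cs` (named per metric), `correlations` (list of
#'   BPerDrop x metric matrices per drop value), `discarded` (failed draws)
#' @export
csCoefficient <- function(ds, cfg = glassoConfig(),
                          metrics = c("betweenness", "closeness", "strength"),
                          dropGrid = c(0.10, 0.25, 0.40, 0.55, 0.70, 0.75),
                          BPerDrop = 250L, seed = NULL,
                          corThreshold = 0.70, probLevel = 0.95,
                          pairPolicy = "pairwise") {
  stopifnot(is(ds, "SymptomDataset"), BPerDrop >= 20,
            all(dropGrid > 0), all(dropGrid < 1), all(diff(dropGrid) > 0))
  metrics <- match.arg(metrics, several.ok = TRUE)
  v <- ds@values
  n <- nrow(v)
  full <- fitNetworkOnce(v, ds@nLevels, cfg, pairPolicy)
  if (is.null(full)) stop("the full dataset itself is degenerate")
  fullCent <- suppressWarnings(nodeCentrality(full))
  withLocalSeed(seed, {
    discarded <- 0L
    correlations <- lapply(dropGrid, function(d) {
      m <- round((1 - d) * n)
      out <- matrix(NA_real_, BPerDrop, length(metrics),
                    dimnames = list(NULL, metrics))
      for (b in seq_len(BPerDrop)) {
        net <- fitNetworkOnce(v[sample.int(n, m), , drop = FALSE],
                              ds@nLevels, cfg, pairPolicy)
        if (is.null(net)) { discarded <<- discarded + 1L; next }
        ct <- suppressWarnings(nodeCentrality(net))
        for (k in seq_along(metrics)) {
          x <- fullCent[[metrics[k]]]
          y <- ct[[metrics[k]]]
          out[b, k] <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
        }
      }
      out
    })
    cs <- vapply(seq_along(metrics), function(k)
      csFromCorrelations(lapply(correlations, function(m) m[, k]),
                         dropGrid, corThreshold, probLevel), numeric(1))
    names(cs) <- metrics
    list(cs = cs, correlations = correlations, dropGrid = dropGrid,
         discarded = discarded)
  })
}

#' Restricted-variance diagnostics
#'
#' Two-tailed Pearson correlations (t-based p on n - 2 degrees of freedom)
#' between per-symptom SD and strength centrality, and between skewness and
#' strength centrality. A strong SD-strength correlation would warn that
#' differential variability, not network structure, drives apparent node
#' importance.
#'
#' @param desc output of [describeDataset()]
#' @param cent output of [nodeCentrality()] on the matching network
#' @return list with elements `sd_strength` and `skewness_strength`, each a
#'   named vector `c(r, p)`
#' @export
varianceDiagnostics <- function(desc, cent) {
  stopifnot(nrow(desc) == nrow(cent), nrow(desc) >= 3)
  stopifnot(identical(desc$node, cent$node))
  run <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance in a diagnostic vector")
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  list(sd_strength = run(desc$sd, cent$strength),
       skewness_strength = run(desc$skewness, cent$strength))
}
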