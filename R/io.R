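## Artifact writers: labelled CSV matrices, edge lists, Graphviz DOT,
## JSON metadata. Every run directory gets a metadata file with the config
## and seeds so runs are self-describing.

writeMatrixCsv <- function(m, path) {
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

writeRunMetadata <- function(.file, ...) {
  meta <- list(...)
  meta$package_version <- as.character(utils::packageVersion("symnet"))
  meta$r_version <- R.version.string
  write_json(meta, .file, auto_unbox = TRUE, digits = NA, null = "null",
             force = TRUE)
  invisible(.file)
}

#' Write WeightedNetwork artifacts
#'
#' Edge list CSV (node_a, node_b, weight), full weight-matrix CSV, and the
#' EBIC path CSV.
#'
#' @param net a [WeightedNetwork-class]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return the directory, invisibly
#' @export
writeNetworkCsv <- function(net, dir, prefix = "ggm") {
  stopifnot(is(net, "WeightedNetwork"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(networkEdgeList(net), file.path(dir, paste0(prefix, "_edges.csv")),
            row.names = FALSE)
  writeMatrixCsv(net@weights, file.path(dir, paste0(prefix, "_weights.csv")))
  write.csv(net@ebicPath, file.path(dir, paste0(prefix, "_ebic_path.csv")),
            row.names = FALSE)
  invisible(dir)
}

#' Write CorrelationMatrix artifacts
#'
#' Labelled matrix CSV plus JSON metadata (method, pair policy, projection
#' flag).
#'
#' @param S a [CorrelationMatrix-class]
#' @param dir output directory
#' @param prefix file-name prefix
#' @export
writeCorrelationCsv <- function(S, dir, prefix = "polychoric") {
  stopifnot(is(S, "CorrelationMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixCsv(S@rho, file.path(dir, paste0(prefix, "_rho.csv")))
  writeRunMetadata(file.path(dir, paste0(prefix, "_meta.json")),
                   method = S@method, pair_policy = S@pairPolicy,
                   projected = S@projected)
  invisible(dir)
}

#' Write DirectedModel artifacts
#'
#' Edge-list CSV (from, to, strength, direction_prob, bic_importance) and
#' two Graphviz DOT renderings: edge thickness by direction probability and
#' by BIC importance.
#'
#' @param model a [DirectedModel-class]
#' @param dir output directory
#' @param prefix file-name prefix
#' @export
writeDirectedModelCsv <- function(model, dir, prefix = "dag") {
  stopifnot(is(model, "DirectedModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(edgeTable(model), file.path(dir, paste0(prefix, "_edges.csv")),
            row.names = FALSE)
  writeLines(directedModelDot(model, thickness = "direction"),
             file.path(dir, paste0(prefix, "_direction.dot")))
  writeLines(directedModelDot(model, thickness = "bic"),
             file.path(dir, paste0(prefix, "_bic.dot")))
  invisible(dir)
}

#' Graphviz DOT rendering of an averaged DAG
#'
#' The two renderings of the averaged network: `"direction"` scales edge
#' penwidth by the direction probability (thick = confident orientation),
#' `"bic"` by the BIC importance of the edge (thick = more damaging to
#' remove).
#'
#' @param model a [DirectedModel-class]
#' @param thickness `"direction"` or `"bic"`
#' @return character vector of DOT lines
#' @export
directedModelDot <- function(model, thickness = c("direction", "bic")) {
  thickness <- match.arg(thickness)
  et <- edgeTable(model)
  val <- if (thickness == "direction") {
    (et$direction_prob - 0.5) / 0.5
  } else {
    v <- et$bic_importance
    if (all(is.na(v))) rep(0.5, nrow(et)) else v / max(v, na.rm = TRUE)
  }
  pw <- 0.5 + 4.5 * pmax(val, 0)
  c("digraph symnet {",
    "  node [shape=ellipse, fontsize=10];",
    sprintf('  "%s" -> "%s" [penwidth=%.2f];', et$from, et$to, pw),
    "}")
}

#' Write a StabilityReport bundle as JSON + CSV
#'
#' @param stab the `stability` element of a [runGgmBranch()] result
#' @param dir output directory
#' @export
writeStabilityReport <- function(stab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(stab$edgeCi$edges, file.path(dir, "edge_ci.csv"),
            row.names = FALSE)
  write_json(list(cs = as.list(stab$cs$cs), drop_grid = stab$cs$dropGrid,
                  discarded = stab$cs$discarded),
             file.path(dir, "cs.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

writeGgmArtifacts <- function(res, ds, cfg, seed, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeCorrelationCsv(res$correlation, outDir)
  writeNetworkCsv(res$network, outDir)
  write.csv(res$centrality, file.path(outDir, "centrality.csv"),
            row.names = FALSE)
  write.csv(res$descriptives, file.path(outDir, "descriptives.csv"),
            row.names = FALSE)
  if (!is.null(res$stability)) writeStabilityReport(res$stability, outDir)
  writeRunMetadata(file.path(outDir, "ggm_run.json"),
                   branch = "ggm", seed = seed, config = unclass(cfg),
                   n = nrow(ds@values), p = ncol(ds@values),
                   lambda_selected = res$network@lambdaSelected,
                   n_edges = edgeCount(res$network))
  invisible(outDir)
}

writeDagArtifacts <- function(model, bs, cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeDirectedModelCsv(model, outDir)
  writeMatrixCsv(bs$strength, file.path(outDir, "dag_strength.csv"))
  writeRunMetadata(file.path(outDir, "dag_run.json"),
                   branch = "dag", config = unclass(cfg),
                   threshold = model@threshold, n_edges = sum(model@adjacency),
                   repairs = model@repairs, failures = bs$failures)
  invisible(outDir)
}
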