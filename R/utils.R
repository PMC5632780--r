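## Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a private RNG stream: seed if given, and always restore the
# caller's .Random.seed so no operation leaks global RNG state.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(code)
}

# Kahn's algorithm on a 0/1 adjacency (edge i -> j at [i, j]).
isAcyclic <- function(adj) {
  p <- nrow(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, p)
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    for (u in src) {
      indeg <- indeg - adj[u, ]
      active[u] <- FALSE
    }
  }
  !any(active)
}

# Return node indices of one directed cycle, or NULL if acyclic.
findCycle <- function(adj) {
  p <- nrow(adj)
  color <- integer(p)   # 0 white, 1 on stack, 2 done
  parent <- integer(p)
  cyc <- NULL
  visit <- function(u) {
    color[u] <<- 1L
    for (v in which(adj[u, ] == 1)) {
      if (!is.null(cyc)) return()
      if (color[v] == 0L) { parent[v] <<- u; visit(v) }
      else if (color[v] == 1L) {
        path <- u
        w <- u
        while (w != v) { w <- parent[w]; path <- c(w, path) }
        cyc <<- c(path, v)
      }
    }
    color[u] <<- 2L
  }
  for (s in seq_len(p)) {
    if (!is.null(cyc)) break
    if (color[s] == 0L) visit(s)
  }
  cyc
}

# Unordered pair weights above the structural-zero guard.
upperWeights <- function(w, guard = 1e-10) {
  x <- w[upper.tri(w)]
  x[abs(x) <= guard] <- 0
  x
}

checkSquareLabelled <- function(m, what = "matrix") {
  if (nrow(m) != ncol(m)) stop(what, " must be square")
  if (is.null(colnames(m))) stop(what, " must carry node labels")
  invisible(m)
}
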