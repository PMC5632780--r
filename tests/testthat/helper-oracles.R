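# Independent oracles used across the suite. These deliberately use naive,
# exhaustive algorithms so they share no code path with the package.

# Exhaustive simple-path enumeration centrality (feasible for p <= 8).
# Edge length = 1/|weight|; betweenness credit split over tied geodesics.
oracleCentrality <- function(w, tol = 1e-12) {
  p <- ncol(w)
  len <- 1 / abs(w)
  len[abs(w) < 1e-10] <- Inf
  btw <- numeric(p)
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  allPaths <- function(i, j) {
    res <- list()
    rec <- function(path, visited, d) {
      last <- path[length(path)]
      if (last == j) {
        res[[length(res) + 1]] <<- list(path = path, d = d)
        return(invisible())
      }
      for (k in seq_len(p)) {
        if (!visited[k] && is.finite(len[last, k])) {
          visited[k] <- TRUE
          rec(c(path, k), visited, d + len[last, k])
          visited[k] <- FALSE
        }
      }
    }
    v <- rep(FALSE, p)
    v[i] <- TRUE
    rec(i, v, 0)
    res
  }
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    ps <- allPaths(i, j)
    if (!length(ps)) next
    ds <- vapply(ps, `[[`, numeric(1), "d")
    dm <- min(ds)
    D[i, j] <- D[j, i] <- dm
    sel <- which(ds <= dm + tol)
    for (s in sel) {
      mid <- setdiff(ps[[s]]$path, c(i, j))
      btw[mid] <- btw[mid] + 1 / length(sel)
    }
  }
  clo <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    if (any(!is.finite(d))) 0 else 1 / sum(d)
  }, numeric(1))
  list(betweenness = btw, closeness = clo,
       strength = unname(rowSums(abs(w))))
}

# All 25 DAGs on 3 labelled nodes, as a list of adjacency matrices.
allThreeNodeDags <- function(labels = c("a", "b", "c")) {
  pairs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  out <- list()
  for (mask in 0:63) {
    adj <- matrix(0L, 3, 3, dimnames = list(labels, labels))
    for (b in 1:6) if (bitwAnd(mask, bitwShiftL(1L, b - 1L))) {
      adj[pairs[b, 1], pairs[b, 2]] <- 1L
    }
    if (!oracleHasCycle(adj)) out[[length(out) + 1]] <- adj
  }
  out
}

# Direct central-moment skewness (adjusted Fisher-Pearson), no shortcuts.
oracleSkewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  (m3 / m2^(3 / 2)) * sqrt(n * (n - 1)) / (n - 2)
}

# High-accuracy bivariate normal CDF by adaptive 1-D integration of the
# conditional representation.
oraclePbvnorm <- function(h, k, r) {
  if (!is.finite(h) && h < 0) return(0)
  if (!is.finite(k) && k < 0) return(0)
  if (!is.finite(h)) return(pnorm(k))
  if (!is.finite(k)) return(pnorm(h))
  f <- function(x) dnorm(x) * pnorm((k - r * x) / sqrt(1 - r^2))
  integrate(f, -Inf, h, rel.tol = 1e-11)$value
}

# Grid-search maximiser of the polychoric profile likelihood.
oracleGridPolychoric <- function(tab, cutsA, cutsB, step = 1e-3) {
  grid <- seq(-0.999, 0.999, by = step)
  ll <- vapply(grid, function(r)
    symnet:::polychoricLoglik(tab, cutsA, cutsB, r), numeric(1))
  grid[which.max(ll)]
}

# Cycle detection by brute-force path matrix powers.
oracleHasCycle <- function(adj) {
  p <- nrow(adj)
  reach <- (adj > 0) * 1
  acc <- reach
  for (i in seq_len(p)) acc <- (acc %*% reach > 0 | acc > 0) * 1
  any(diag(acc) > 0)
}

# A tiny deterministic labelled weight matrix for network tests.
randomWeightMatrix <- function(p, density = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, p, p)
  ut <- which(upper.tri(w))
  on <- ut[runif(length(ut)) < density]
  w[on] <- runif(length(on), 0.1, 0.9) * sample(c(-1, 1), length(on), TRUE)
  w <- w + t(w)
  dimnames(w) <- list(letters[seq_len(p)], letters[seq_len(p)])
  w
}

# Quick ordinal dataset straight from codes.
makeDs <- function(values, nLevels = 4L) {
  m <- as.matrix(values)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  SymptomDataset(m, nLevels = nLevels)
}
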