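# continuous data from a linear-Gaussian DAG, for score-based search tests
simLinear <- function(adj, coef, n, seed, noiseSd = 1) {
  set.seed(seed)
  p <- nrow(adj)
  X <- matrix(0, n, p, dimnames = list(NULL, colnames(adj)))
  done <- logical(p)
  while (!all(done)) {
    ready <- which(!done & colSums(adj[!done, , drop = FALSE] == 1) == 0)
    for (j in ready) {
      pa <- which(adj[, j] == 1)
      mu <- if (length(pa)) X[, pa, drop = FALSE] %*% coef[pa, j] else 0
      X[, j] <- mu + rnorm(n, sd = noiseSd)
      done[j] <- TRUE
    }
  }
  X
}

labAdj <- function(p, labels = letters[seq_len(p)]) {
  matrix(0L, p, p, dimnames = list(labels, labels))
}

test_that("the BIC score assembles from hand-computed family terms", {
  set.seed(51)
  X <- cbind(a = rnorm(10), b = rnorm(10))
  adj <- labAdj(2)
  n <- 10
  famEmpty <- function(x) {
    s2 <- mean((x - mean(x))^2)
    -n / 2 * (log(2 * pi * s2) + 1) - (2 / 2) * log(n)
  }
  expect_equal(bicScore(adj, X), famEmpty(X[, 1]) + famEmpty(X[, 2]),
               tolerance = 1e-10)
  # adding a -> b changes only b's family component (decomposability)
  adj2 <- adj; adj2["a", "b"] <- 1L
  fit <- lm(X[, 2] ~ X[, 1])
  s2 <- mean(residuals(fit)^2)
  famB <- -n / 2 * (log(2 * pi * s2) + 1) - (3 / 2) * log(n)
  expect_equal(bicScore(adj2, X), famEmpty(X[, 1]) + famB, tolerance = 1e-10)
  expect_error(bicScore({a <- labAdj(2); a["a","b"] <- 1L; a["b","a"] <- 1L; a},
                        X), "cycle")
})

test_that("Markov-equivalent structures score identically", {
  adj <- labAdj(2); adj["a", "b"] <- 1L
  coef <- matrix(0, 2, 2, dimnames = dimnames(adj)); coef["a", "b"] <- 2
  X <- simLinear(adj, coef, 500, seed = 52)
  fwd <- labAdj(2); fwd["a", "b"] <- 1L
  rev <- labAdj(2); rev["b", "a"] <- 1L
  expect_gt(bicScore(fwd, X), bicScore(labAdj(2), X))
  expect_equal(bicScore(fwd, X), bicScore(rev, X), tolerance = 1e-6)
})

test_that("hill climbing finds empty and chain structures", {
  set.seed(53)
  X0 <- matrix(rnorm(4000), 1000, 4,
               dimnames = list(NULL, letters[1:4]))
  f0 <- hillClimb(X0, searchConfig(restarts = 3, seed = 54))
  expect_identical(sum(f0$adjacency), 0L)
  # chain a -> b -> c: skeleton a-b-c with no a-c adjacency
  adj <- labAdj(3); adj["a", "b"] <- 1L; adj["b", "c"] <- 1L
  coef <- matrix(0, 3, 3, dimnames = dimnames(adj))
  coef["a", "b"] <- 1; coef["b", "c"] <- 1
  X <- simLinear(adj, coef, 1000, seed = 55)
  f <- hillClimb(X, searchConfig(restarts = 5, seed = 56))
  sk <- (f$adjacency + t(f$adjacency)) > 0
  expect_true(sk["a", "b"] && sk["b", "c"])
  expect_false(sk["a", "c"])
  expect_false(oracleHasCycle(f$adjacency))
  # determinism under a fixed seed
  f2 <- hillClimb(X, searchConfig(restarts = 5, seed = 56))
  expect_identical(f$adjacency, f2$adjacency)
})

test_that("hill climbing attains the exhaustive 3-node optimum", {
  dags <- allThreeNodeDags()
  expect_length(dags, 25)
  hits <- 0
  for (s in 1:100) {
    truth <- randomDAG(3, 0.5, c(0.4, 0.9), seed = 5000 + s)
    X <- simLinear(truth$adjacency, truth$coefficients, 500, seed = 6000 + s)
    colnames(X) <- c("a", "b", "c")
    f <- hillClimb(X, searchConfig(restarts = 10, seed = 7000 + s))
    best <- max(vapply(dags, function(a) bicScore(a, X), numeric(1)))
    if (abs(f$score - best) < 1e-9 * abs(best)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("bootstrap strengths and direction counts obey the accounting identity", {
  adj <- labAdj(3); adj["a", "b"] <- 1L; adj["b", "c"] <- 1L
  coef <- matrix(0, 3, 3, dimnames = dimnames(adj))
  coef["a", "b"] <- 1; coef["b", "c"] <- 1
  X <- simLinear(adj, coef, 300, seed = 61)
  cfg <- searchConfig(restarts = 2, B = 40, seed = 62)
  bs <- bootstrapDags(X, cfg)
  # direction counts sum to strength * B per unordered pair
  expect_equal(bs$dirCounts + t(bs$dirCounts), bs$strength * cfg$B,
               tolerance = 1e-12)
  expect_true(all(bs$strength >= 0 & bs$strength <= 1))
  # B = 1: strengths are indicator values
  bs1 <- bootstrapDags(X, searchConfig(restarts = 0, B = 1, seed = 63))
  expect_true(all(bs1$strength %in% c(0, 1)))
  # strong 2-node dependence is essentially always detected
  adj2 <- labAdj(2); adj2["a", "b"] <- 1L
  coef2 <- matrix(0, 2, 2, dimnames = dimnames(adj2)); coef2["a", "b"] <- 1.5
  X2 <- simLinear(adj2, coef2, 400, seed = 64)
  bs2 <- bootstrapDags(X2, searchConfig(restarts = 1, B = 200, seed = 65))
  expect_gte(bs2$strength["a", "b"], 0.95)
})

test_that("the retention threshold matches a dense grid-search oracle", {
  cases <- list(c(1, 1, 1, 0, 0, 0),
                rep(1, 5),
                rep(0, 5),
                c(0.9, 0.8, 0.6, 0.3, 0.2, 0.1),
                c(0.97, 0.95, 0.9, 0.15, 0.1, 0.02, 0.01))
  for (s in cases) {
    thr <- snThreshold(s)
    grid <- seq(0, 1, by = 1e-4)
    l1 <- vapply(grid, function(t) symnet:::snL1(s, t), numeric(1))
    expect_lte(thr$l1, min(l1) + 1e-9)
  }
  # spec'd fixtures: all-ones keeps everything, all-zeros keeps nothing
  expect_identical(sum(c(1, 1, 1) > snThreshold(rep(1, 3))$cut), 3L)
  expect_identical(sum(numeric(0) > snThreshold(rep(0, 3))$cut) +
                     sum(rep(0, 3) > snThreshold(rep(0, 3))$cut), 0L)
  # mixed case: exactly the three strength-1 edges survive
  thr <- snThreshold(c(1, 1, 1, 0, 0, 0))
  expect_identical(sum(c(1, 1, 1, 0, 0, 0) > thr$cut), 3L)
})

test_that("averaging orients by majority, breaks ties, and stays acyclic", {
  lab <- c("a", "b", "c")
  strength <- matrix(0, 3, 3, dimnames = list(lab, lab))
  strength["a", "b"] <- strength["b", "a"] <- 0.995
  strength["b", "c"] <- strength["c", "b"] <- 0.55
  dirCounts <- matrix(0L, 3, 3, dimnames = list(lab, lab))
  dirCounts["a", "b"] <- 9950L; dirCounts["b", "a"] <- 50L
  dirCounts["b", "c"] <- 2750L; dirCounts["c", "b"] <- 2750L
  cfg <- searchConfig(B = 10000)
  m <- averagedNetwork(strength, dirCounts, cfg)
  expect_identical(m@adjacency["a", "b"], 1L)
  expect_equal(directionProb(m)["a", "b"], 0.995)
  # exact 50/50: lexicographic tie-break, flagged
  expect_identical(m@adjacency["b", "c"], 1L)
  expect_equal(directionProb(m)["b", "c"], 0.5)
  expect_match(m@ties, "b->c")
  # a forced directed cycle is repaired by flipping the weakest edge
  s2 <- matrix(0.9, 3, 3, dimnames = list(lab, lab)); diag(s2) <- 0
  d2 <- matrix(0L, 3, 3, dimnames = list(lab, lab))
  d2["a", "b"] <- 80L; d2["b", "a"] <- 20L
  d2["b", "c"] <- 70L; d2["c", "b"] <- 30L
  d2["c", "a"] <- 55L; d2["a", "c"] <- 45L
  cfg2 <- searchConfig(B = 100)
  expect_warning(m2 <- averagedNetwork(s2, d2, cfg2), "cycle")
  expect_false(oracleHasCycle(m2@adjacency))
  expect_identical(length(m2@repairs), 1L)
})

test_that("edge BIC importance separates strong edges from absent ones", {
  adj <- labAdj(2); adj["a", "b"] <- 1L
  coef <- matrix(0, 2, 2, dimnames = dimnames(adj)); coef["a", "b"] <- 1.5
  X <- simLinear(adj, coef, 500, seed = 71)
  lab <- c("a", "b")
  strength <- matrix(c(0, 1, 1, 0), 2, dimnames = list(lab, lab))
  dirCounts <- matrix(0L, 2, 2, dimnames = list(lab, lab))
  dirCounts["a", "b"] <- 100L
  m <- averagedNetwork(strength, dirCounts, searchConfig(B = 100))
  m <- edgeBicImportance(m, X)
  imp <- edgeTable(m)$bic_importance
  expect_gt(imp, 50)   # dropping the only real edge is very damaging
  expect_equal(imp, abs(bicScore(adj, X) - bicScore(labAdj(2), X)),
               tolerance = 1e-9)
  # single-edge query and the absent-pair domain rule
  expect_equal(edgeBicImportance(m, X, from = "a", to = "b"), imp,
               tolerance = 1e-12)
  expect_error(edgeBicImportance(m, X, from = "b", to = "a"), "not in the model")
  # removing a null edge costs only about the penalty term
  adj3 <- labAdj(2); adj3["a", "b"] <- 1L
  set.seed(72)
  Xn <- cbind(a = rnorm(2000), b = rnorm(2000))
  lossNull <- abs(bicScore(adj3, Xn) - bicScore(labAdj(2), Xn))
  expect_lt(lossNull, log(2000))   # penalty-scale, not fit-scale
})

test_that("collider orientation is recovered while 2-node direction is not", {
  # v-structure a -> c <- b
  lab <- c("a", "b", "c")
  adj <- labAdj(3, lab); adj["a", "c"] <- 1L; adj["b", "c"] <- 1L
  coef <- matrix(0, 3, 3, dimnames = dimnames(adj))
  coef["a", "c"] <- 0.8; coef["b", "c"] <- 0.8
  X <- simLinear(adj, coef, 2000, seed = 81)
  cfg <- searchConfig(restarts = 2, B = 200, seed = 82)
  bs <- bootstrapDags(X, cfg)
  m <- averagedNetwork(bs$strength, bs$dirCounts, cfg)
  expect_identical(m@adjacency["a", "c"], 1L)
  expect_identical(m@adjacency["b", "c"], 1L)
  expect_gt(directionProb(m)["a", "c"], 0.51)
  expect_gt(directionProb(m)["b", "c"], 0.51)
  # two dependent nodes: the orientation is not identifiable, so the
  # direction fraction hovers near one half
  adj2 <- labAdj(2); adj2["a", "b"] <- 1L
  coef2 <- matrix(0, 2, 2, dimnames = dimnames(adj2)); coef2["a", "b"] <- 1
  X2 <- simLinear(adj2, coef2, 1000, seed = 83)
  bs2 <- bootstrapDags(X2, searchConfig(restarts = 1, B = 300, seed = 84))
  frac <- bs2$dirCounts["a", "b"] /
    (bs2$dirCounts["a", "b"] + bs2$dirCounts["b", "a"])
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.75)
})
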