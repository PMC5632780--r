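wnet <- function(w) {
  new("WeightedNetwork", weights = w, lambdaSelected = 0,
      ebicPath = data.frame(), gamma = 0.5, n = 100)
}

test_that("hand-computed centralities on a path and a star", {
  # A - B - C with both weights 0.5 (edge lengths 2)
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 0.5
  w["B", "C"] <- w["C", "B"] <- 0.5
  ct <- nodeCentrality(wnet(w))
  expect_equal(ct$strength, c(0.5, 1.0, 0.5))
  expect_equal(ct$betweenness, c(0, 1, 0))
  expect_equal(ct$closeness[1], 1 / (2 + 4))
  expect_equal(ct$closeness[2], 1 / (2 + 2))
  # star with 4 leaves: center lies between all C(4,2) pairs
  p <- 5
  s <- matrix(0, p, p, dimnames = list(LETTERS[1:p], LETTERS[1:p]))
  s[1, 2:5] <- s[2:5, 1] <- 0.3
  cs <- nodeCentrality(wnet(s))
  expect_equal(cs$betweenness[1], choose(4, 2))
  expect_equal(cs$betweenness[-1], rep(0, 4))
})

test_that("all metrics match exhaustive path enumeration on small graphs", {
  for (seed in 1:12) {
    p <- 4 + (seed %% 5)
    w <- randomWeightMatrix(p, density = 0.5, seed = seed)
    ct <- suppressWarnings(nodeCentrality(wnet(w)))
    o <- oracleCentrality(w)
    expect_equal(ct$betweenness, o$betweenness, tolerance = 1e-10)
    expect_equal(ct$closeness, o$closeness, tolerance = 1e-10)
    expect_equal(ct$strength, o$strength, tolerance = 1e-12)
  }
})

test_that("centrality ignores edge signs and applies the disconnection rule", {
  w <- randomWeightMatrix(6, density = 0.6, seed = 77)
  ctp <- suppressWarnings(nodeCentrality(wnet(abs(w))))
  ctm <- suppressWarnings(nodeCentrality(wnet(w)))
  expect_equal(ctp$strength, ctm$strength)
  expect_equal(ctp$betweenness, ctm$betweenness)
  expect_equal(ctp$closeness, ctm$closeness)
  # isolated node: closeness 0 everywhere it cannot reach
  w2 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w2["A", "B"] <- w2["B", "A"] <- 0.4
  expect_warning(ct2 <- nodeCentrality(wnet(w2)), "disconnected")
  expect_equal(ct2$closeness, c(0, 0, 0))
  expect_true(attr(ct2, "disconnected"))
})

test_that("z-scoring normalizes exactly and rejects constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(9)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_error(zscore(rep(2, 5)), "constant")
  ct <- nodeCentrality(wnet(randomWeightMatrix(5, 0.8, seed = 3)))
  for (col in c("z_betweenness", "z_closeness", "z_strength")) {
    if (all(is.na(ct[[col]]))) next
    expect_equal(mean(ct[[col]]), 0, tolerance = 1e-10)
    expect_equal(sd(ct[[col]]), 1, tolerance = 1e-10)
  }
})

test_that("bootstrap edge intervals separate real edges from noise", {
  # strong 4-node model with one |partial| = 0.4 edge
  g <- randomGGM(4, 0, seed = 201)
  g$partials["intrusion", "dreams"] <- g$partials["dreams", "intrusion"] <- 0.4
  g$precision <- diag(4) - g$partials
  dimnames(g$precision) <- dimnames(g$partials)
  g$latentCor <- stats::cov2cor(solve(g$precision))
  ds <- sampleOrdinal(g, 1000, seed = 202)
  be <- bootstrapEdges(ds, B = 500, seed = 203)
  row <- be$edges[be$edges$node_a == "intrusion" & be$edges$node_b == "dreams", ]
  expect_true(row$ci_excludes_zero)
  expect_lte(row$lower, row$estimate)
  expect_gte(row$upper, row$estimate)
  # independence: at least 90% of intervals cover zero
  g0 <- randomGGM(4, 0, seed = 204)
  ds0 <- sampleOrdinal(g0, 1000, seed = 205)
  be0 <- bootstrapEdges(ds0, B = 500, seed = 206)
  expect_gte(mean(!be0$edges$ci_excludes_zero), 0.9)
  # a degenerate dataset is rejected outright
  expect_error(bootstrapEdges(makeDs(matrix(2L, 30, 3)), B = 10, seed = 1),
               "degenerate")
})

test_that("the bootstrapped difference test respects exchangeable nodes", {
  # duplicated columns are exchangeable: never significantly different
  g <- randomGGM(3, 0.5, c(0.3, 0.4), seed = 211, probPositive = 1)
  v <- ordinalValues(sampleOrdinal(g, 400, seed = 212))
  v <- cbind(v, twin = v[, 1])
  # perfect duplication collapses the polychoric matrix; jitter a few cells
  set.seed(213)
  flip <- sample.int(nrow(v), 25)
  v[flip, 4] <- pmin(v[flip, 4] + 1L, 3L)
  dt <- centralityDifferenceTest(makeDs(v), B = 120, seed = 214)
  expect_false(dt$strength[colnames(v)[1], "twin"])
  for (m in names(dt)) {
    expect_true(isSymmetric(dt[[m]]))
    expect_false(any(diag(dt[[m]])))
  }
})

test_that("a hub node is detected as significantly stronger than leaves", {
  g <- randomGGM(5, 0, seed = 221)
  lab <- g$labels
  A <- g$partials
  A[1, 2:5] <- A[2:5, 1] <- 0.35   # hub with four strong spokes
  g$partials <- A
  g$precision <- diag(5) - A
  dimnames(g$precision) <- list(lab, lab)
  g$latentCor <- stats::cov2cor(solve(g$precision))
  ds <- sampleOrdinal(g, 2000, seed = 222)
  dt <- centralityDifferenceTest(ds, B = 120, seed = 223,
                                 metrics = "strength")
  expect_true(all(dt$strength[1, 2:5]))
})

test_that("the CS decision rule reproduces its defining extremes", {
  grid <- c(0.1, 0.25, 0.5, 0.75)
  ones <- lapply(grid, function(d) rep(1, 50))
  expect_identical(symnet:::csFromCorrelations(ones, grid), 0.75)
  zeros <- lapply(grid, function(d) rep(0, 50))
  expect_identical(symnet:::csFromCorrelations(zeros, grid), 0)
  # raising the correlation threshold can only lower the CS value
  set.seed(231)
  mixed <- lapply(grid, function(d) runif(200, 0.8 - d, 1))
  cs70 <- symnet:::csFromCorrelations(mixed, grid, corThreshold = 0.70)
  cs85 <- symnet:::csFromCorrelations(mixed, grid, corThreshold = 0.85)
  expect_lte(cs85, cs70)
})

test_that("variance diagnostics equal the direct formula", {
  g <- randomGGM(17, 0.15, seed = 241)
  ds <- sampleOrdinal(g, 300, seed = 242)
  S <- polychoricMatrix(ds)
  net <- ebicGlasso(S, 300)
  desc <- describeDataset(ds)
  cent <- nodeCentrality(net)
  vd <- varianceDiagnostics(desc, cent)
  r <- unname(vd$sd_strength["r"])
  n <- 17
  tval <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(unname(vd$sd_strength["p"]), 2 * pt(-abs(tval), n - 2),
               tolerance = 1e-10)
  expect_equal(unname(vd$sd_strength["r"]),
               unname(cor(desc$sd, cent$strength)), tolerance = 1e-12)
  # perfect linear relation: r = 1, vanishing p
  fake <- cent
  fake$strength <- 2 * desc$sd
  vd2 <- varianceDiagnostics(desc, fake)
  expect_equal(unname(vd2$sd_strength["r"]), 1, tolerance = 1e-12)
  expect_lt(vd2$sd_strength["p"], 1e-6)
  # orthogonalized strength: r = 0
  fake$strength <- residuals(lm(cent$strength ~ desc$sd)) + mean(cent$strength)
  vd3 <- varianceDiagnostics(desc, fake)
  expect_equal(unname(vd3$sd_strength["r"]), 0, tolerance = 1e-10)
})
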