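test_that("CSV round trip preserves codes, missingness, and labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,3", "2,1", "3,0"), f)
  ds <- loadDataset(f)
  expect_identical(dim(ds), c(3L, 2L))
  expect_identical(nodeLabels(ds), c("a", "b"))
  expect_false(any(missingMask(ds)))
  expect_identical(ordinalValues(ds)[, "a"], c(0L, 2L, 3L))

  writeLines(c("a,b", "0,", "2,1"), f)
  ds2 <- loadDataset(f)
  expect_identical(sum(missingMask(ds2)), 1L)
  expect_true(missingMask(ds2)[1, 2])

  g <- makeDs(matrix(c(1L, 0L, NA, 2L), 2))
  writeSymptomCsv(g, f)
  back <- loadDataset(f)
  expect_identical(ordinalValues(back), ordinalValues(g))
})

test_that("a raw questionnaire file loads and harmonizes end to end", {
  f <- system.file("extdata", "pclc_synthetic.csv", package = "symnet")
  raw <- loadDataset(f, scale = "PCL_1_5")
  expect_identical(dim(raw), c(12L, 5L))
  expect_identical(nLevels(raw), 5L)
  expect_identical(sum(missingMask(raw)), 2L)
  h <- rescalePclc(raw)
  expect_identical(nLevels(h), 4L)
  expect_true(all(ordinalValues(h)[!missingMask(h)] %in% 0:3))
  # harmonization preserves missingness and ordering
  expect_identical(missingMask(h), missingMask(raw))
  expect_identical(ordinalValues(h)[1, "intrusion"],
                   ordinalValues(raw)[1, "intrusion"] - 1L)
})

test_that("malformed input is rejected with a located error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,7"), f)
  expect_error(loadDataset(f), "out of range.*row 1.*'b'")
  writeLines(c("a,b", "0,x"), f)
  expect_error(loadDataset(f), "non-integer.*row 1.*'b'")
  writeLines(c("a,a", "0,1"), f)
  expect_error(loadDataset(f), "duplicate")
  expect_error(SymptomDataset(matrix(0.5, 2, 2,
                                     dimnames = list(NULL, c("a", "b")))),
               "integer")
})

test_that("PCL-C harmonization collapses the scale top exactly", {
  expect_identical(rescalePclc(1:5), c(0L, 1L, 2L, 3L, 3L))
  x <- matrix(c(1L, 4L, NA, 5L, 2L, 3L), 2)
  y <- rescalePclc(x)
  expect_identical(y, matrix(c(0L, 3L, NA, 3L, 1L, 2L), 2))
  expect_error(rescalePclc(c(0L, 2L)), "1\\.\\.5")
  expect_error(rescalePclc(c(2L, 6L)), "1\\.\\.5")
  # many-to-one at the top: both 4 and 5 land on 3, so the map read on its
  # own output range is idempotent only for codes that came from 1..3
  expect_identical(rescalePclc(rescalePclc(1:3) + 1L), rescalePclc(1:3))
  expect_false(identical(rescalePclc(pmax(rescalePclc(4:5), 1L)),
                         rescalePclc(4:5)))
  # a dataset already on the interview scale passes through unchanged
  ds <- makeDs(matrix(0:3, 2))
  expect_identical(rescalePclc(ds), ds)
  # full dataset path: raw questionnaire codes land on 4 levels
  raw <- SymptomDataset(matrix(c(1L, 5L, 3L, 4L), 2,
                               dimnames = list(NULL, c("a", "b"))),
                        nLevels = 5L, sourceScale = "PCL_1_5")
  h <- rescalePclc(raw)
  expect_identical(nLevels(h), 4L)
  expect_identical(sort(unique(as.vector(ordinalValues(h)))), c(0L, 2L, 3L))
})

test_that("listwise deletion drops exactly the incomplete rows in order", {
  v <- matrix(0L, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  v[2, 1] <- NA
  v[4, 3] <- NA
  v[5, ] <- c(1L, 2L, 3L)
  ds <- makeDs(v)
  cc <- listwiseComplete(ds)
  expect_identical(nrow(ordinalValues(cc)), 3L)
  expect_identical(ordinalValues(cc)[3, ], c(a = 1L, b = 2L, c = 3L))
  # complement identity: kept + incomplete == total
  expect_identical(nrow(ordinalValues(cc)) +
                     sum(rowSums(missingMask(ds)) > 0), 5L)
  # identity on complete data
  ds0 <- makeDs(matrix(1L, 4, 2))
  expect_identical(ordinalValues(listwiseComplete(ds0)), ordinalValues(ds0))
  # everything missing is an error
  expect_error(listwiseComplete(makeDs(matrix(NA_integer_, 2, 2))), "every")
})

test_that("descriptives match hand arithmetic and the moment oracle", {
  ds <- makeDs(cbind(a = c(0L, 1L, 2L, 3L), b = c(0L, 1L, 1L, 2L),
                     c = c(0L, 0L, 0L, 3L), d = c(1L, 1L, 1L, 1L)))
  d <- describeDataset(ds)
  expect_equal(d$mean[1], 1.5)
  expect_equal(d$sd[1], sqrt(sum((0:3 - 1.5)^2) / 3))
  expect_equal(d$skewness[2], 0)               # symmetric column
  expect_equal(d$skewness[3], oracleSkewness(c(0, 0, 0, 3)))
  # constant column: flagged, skewness NA rather than silently zero
  expect_true(d$degenerate[4])
  expect_true(is.na(d$skewness[4]))
  expect_false(any(d$degenerate[1:3]))
})
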