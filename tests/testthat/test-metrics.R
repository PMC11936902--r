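test_that("DSC closed forms and empty-mask convention", {
  m <- blobMask(16, 16, 1)
  expect_equal(dsc(m, m), 1)
  a <- matrix(0, 8, 8); a[2:3, 2:3] <- 1
  b <- matrix(0, 8, 8); b[6:7, 6:7] <- 1
  expect_equal(dsc(a, b), 0)
  ## 2x2 block vs the same block shifted one column: overlap 2 of 4+4
  sh <- matrix(0, 8, 8); sh[2:3, 3:4] <- 1
  expect_equal(dsc(a, sh), 0.5)
  expect_equal(dsc(matrix(0, 4, 4), matrix(0, 4, 4)), 1.0)
})

test_that("Hausdorff and ASSD closed forms", {
  m1 <- matrix(0, 8, 8); m1[1, 1] <- 1
  m2 <- matrix(0, 8, 8); m2[4, 5] <- 1          # 3-4-5 triangle
  expect_equal(hausdorff(m1, m2), 5)
  expect_equal(assd(m1, m2), 5)
  expect_equal(hausdorff(m1, m1), 0)
  expect_equal(assd(m2, m2), 0)
  ## A = {(0,0), (10,0)}, B = {(0,0)} -> directed max 10
  a <- matrix(0, 12, 12); a[1, 1] <- 1; a[11, 1] <- 1
  b <- matrix(0, 12, 12); b[1, 1] <- 1
  expect_equal(hausdorff(a, b), 10)
  expect_error(hausdorff(matrix(0, 4, 4), b[1:4, 1:4]), "empty")
})

test_that("fast surface metrics equal the quadratic brute-force oracles", {
  set.seed(11)
  for (r in 1:100) {
    h <- sample(12:32, 1); w <- sample(12:32, 1)
    m1 <- blobMask(h, w, seed = r)
    m2 <- blobMask(h, w, seed = r + 1000)
    expect_lt(abs(hausdorff(m1, m2) - bruteHausdorff(m1, m2)), 1e-9)
    expect_lt(abs(assd(m1, m2) - bruteAssd(m1, m2)), 1e-9)
  }
})

test_that("MSD is the scaled mean squared intensity difference", {
  a <- matrix(0.3, 8, 8)
  expect_equal(msd(a, a), 0)
  expect_equal(msd(a, a + 0.1, scale = 1), 0.1^2, tolerance = 1e-12)
  expect_equal(msd(a, a + 0.1), (0.1 * 255)^2, tolerance = 1e-9)
  set.seed(12)
  x <- matrix(runif(256), 16); y <- matrix(runif(256), 16)
  expect_lt(abs(msd(x, y) - bruteMsd(x, y)), 1e-9)
})

test_that("all four metrics are symmetric and translation invariant", {
  set.seed(13)
  m1 <- blobMask(24, 24, 5); m2 <- blobMask(24, 24, 6)
  expect_equal(dsc(m1, m2), dsc(m2, m1))
  expect_equal(hausdorff(m1, m2), hausdorff(m2, m1))
  expect_equal(assd(m1, m2), assd(m2, m1))
  i1 <- matrix(runif(24 * 24), 24); i2 <- matrix(runif(24 * 24), 24)
  expect_equal(msd(i1, i2), msd(i2, i1))
  ## shifting both masks by the same interior offset changes nothing
  shift <- function(m, d) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + d):nrow(m), (1 + d):ncol(m)] <-
      m[1:(nrow(m) - d), 1:(ncol(m) - d)]
    out
  }
  s1 <- blobMask(40, 40, 7); s1[c(1:5, 36:40), ] <- 0; s1[, c(1:5, 36:40)] <- 0
  s2 <- blobMask(40, 40, 8); s2[c(1:5, 36:40), ] <- 0; s2[, c(1:5, 36:40)] <- 0
  expect_equal(hausdorff(shift(s1, 3), shift(s2, 3)), hausdorff(s1, s2))
  expect_equal(assd(shift(s1, 3), shift(s2, 3)), assd(s1, s2))
  expect_equal(dsc(shift(s1, 3), shift(s2, 3)), dsc(s1, s2))
})

test_that("evaluatePairs builds per-pair rows with recomputed aggregates", {
  m <- blobMask(16, 16, 2); img <- matrix(runif(256), 16)
  same <- list(fixedMask = m, movingMask = m, fixedImage = img,
               movingImage = img)
  rep1 <- evaluatePairs(list(same))
  r <- reportRows(rep1)
  expect_equal(unlist(r[1, c("dsc", "hd", "assd", "msd")]),
               c(dsc = 1, hd = 0, assd = 0, msd = 0))
  set.seed(14)
  pairs <- lapply(1:110, function(k)
    list(fixedMask = blobMask(16, 16, k), movingMask = blobMask(16, 16, k + 7),
         fixedImage = matrix(runif(256), 16),
         movingImage = matrix(runif(256), 16)))
  rep2 <- evaluatePairs(pairs)
  expect_equal(nrow(reportRows(rep2)), 110)
  agg <- reportAggregates(rep2)
  expect_equal(agg$mean[agg$metric == "dsc"], mean(reportRows(rep2)$dsc),
               tolerance = 1e-12)
  expect_equal(agg$sd[agg$metric == "hd"], sd(reportRows(rep2)$hd),
               tolerance = 1e-12)
  ## an empty mask flags the row and drops it from aggregation
  bad <- list(fixedMask = matrix(0, 16, 16), movingMask = m,
              fixedImage = img, movingImage = img)
  expect_warning(rep3 <- evaluatePairs(c(pairs[1:3], list(bad))), "flagged")
  expect_equal(sum(reportRows(rep3)$flagged), 1)
  expect_equal(reportAggregates(rep3)$mean[1],
               mean(reportRows(rep3)$dsc[1:3]), tolerance = 1e-12)
})

test_that("paired significance testing behaves at its boundaries", {
  set.seed(15)
  a <- runif(110)
  expect_equal(pairedSignificance(a, a), 1)
  expect_lt(pairedSignificance(a, a + 0.5), 1e-4)
  expect_equal(pairedSignificance(a, a + 0.5),
               pairedSignificance(a + 0.5, a))      # two-sided symmetry
  expect_lt(pairedSignificance(a, a + 0.5 + rnorm(110, 0, 0.05),
                               method = "ttest"), 1e-10)
  expect_error(pairedSignificance(a, a[1:5]), "equal length")
})
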