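test_that("inverse square root reconstructs the identity", {
  expect_equal(inverseSqrtMatrix(diag(3)), diag(3), tolerance = 1e-12)
  expect_equal(inverseSqrtMatrix(diag(c(4, 1))), diag(c(0.5, 1)),
               tolerance = 1e-12)
  set.seed(4)
  B <- matrix(rnorm(25), 5)
  K <- crossprod(B) + diag(5)
  M <- inverseSqrtMatrix(K)
  expect_equal(M %*% K %*% M, diag(5), tolerance = 1e-8)
  expect_equal(M, t(M), tolerance = 1e-12)
  expect_error(inverseSqrtMatrix(diag(c(1, -1))), "positive definite")
})

test_that("residual basis satisfies its contracts", {
  set.seed(14)
  n <- 20
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  B <- matrix(rnorm(n * n), n)
  K <- crossprod(B) / n + diag(n)
  y <- rnorm(n)
  for (m in c("qr", "svd")) {
    rb <- residualBasis(K, X, y, method = m)
    expect_equal(rb@rankX, 3L)
    expect_lt(max(abs(rb@A %*% rb@KinvSqrt %*% X)), 1e-10)
    expect_lt(max(abs(tcrossprod(rb@A) - diag(n - 3))), 1e-10)
  }
})

test_that("phenotype in the covariate span yields y* = 0", {
  n <- 10
  X <- cbind(1, seq_len(n))
  y <- drop(X %*% c(2, -1))
  rb <- residualBasis(diag(n), X, y)
  expect_lt(max(abs(rb@yStar)), 1e-10)
  gp <- buildSimilarityPair(matrix(0.5, n, n) + diag(0.5, n), 0.2)
  expect_error(jcarTest(rb, genetic = gp), "identically zero")
})

test_that("rank-deficient covariates reduce the rank with a warning", {
  n <- 12
  X <- cbind(1, rnorm(n), 1)    # duplicated intercept
  expect_warning(rb <- residualBasis(diag(n), X, rnorm(n)), "rank deficient")
  expect_equal(rb@rankX, 2L)
})

test_that("quadratic ratios are invariant to the basis construction", {
  set.seed(15)
  n <- 15
  X <- cbind(1, rnorm(n))
  K <- diag(n)
  y <- rnorm(n)
  rb1 <- residualBasis(K, X, y, method = "qr")
  rb2 <- residualBasis(K, X, y, method = "svd")
  M <- crossprod(matrix(rnorm(n * n), n))
  r <- function(rb) {
    Q <- rb@A %*% M %*% t(rb@A)
    drop(crossprod(rb@yStar, Q %*% rb@yStar)) / sum(rb@yStar^2)
  }
  expect_equal(r(rb1), r(rb2), tolerance = 1e-10)
})

test_that("layer score matches the hand-derived equal-similarity case", {
  # n = 3, K = I, intercept-only X, off-diagonal similarity 0.5, gamma = 0:
  # D = I so Q = AA' = I and S_l = df/2 - 3/2 = -0.5 for any phenotype
  y <- c(1, 0, -1)
  rb <- residualBasis(diag(3), matrix(1, 3, 1), y)
  pair <- buildSimilarityPair(matrix(0.5, 3, 3) + diag(0.5, 3), 0)
  expect_equal(scoreStatisticLayer(rb, pair), -0.5, tolerance = 1e-10)
})

test_that("layer score agrees with an independent dense evaluation", {
  set.seed(16)
  for (rep in 1:5) {
    n <- 12
    d <- makeTestData(n = n, seed = 100 + rep)
    S <- ibsSimilarity(d$G)
    gamma <- defaultGamma(assayValues(d$G))
    K <- assayValues(d$kinship)
    rb <- residualBasis(d$kinship, d$X, d$y)
    pair <- buildSimilarityPair(S, gamma)
    expect_equal(scoreStatisticLayer(rb, pair),
                 oracleLayerScore(d$y, d$X, K, S, gamma)$S,
                 tolerance = 1e-8)
  }
})

test_that("score statistic is invariant to affine phenotype changes", {
  d <- makeTestData(n = 24, seed = 9, family = TRUE)
  pair <- buildSimilarityPair(ibsSimilarity(d$G), 0.3)
  rb0 <- residualBasis(d$kinship, d$X, d$y)
  s0 <- scoreStatisticLayer(rb0, pair)
  y2 <- 3.7 * d$y + drop(d$X %*% c(-2, 1, 0.5))
  rb2 <- residualBasis(d$kinship, d$X, y2)
  expect_equal(scoreStatisticLayer(rb2, pair), s0, tolerance = 1e-8)
})

test_that("the observed quadratic form sits exactly at the threshold", {
  d <- makeTestData(n = 32, seed = 19, family = TRUE)
  rb <- residualBasis(d$kinship, d$X, d$y)
  gp <- buildSimilarityPair(ibsSimilarity(d$G),
                            defaultGamma(assayValues(d$G)))
  mp <- buildSimilarityPair(gaussianSimilarity(d$M),
                            defaultGamma(assayValues(d$M)))
  res <- jcarTest(rb, genetic = gp, methylation = mp)
  # rebuild B independently and evaluate the observed quadratic form
  K <- assayValues(d$kinship)
  o1 <- oracleLayerScore(d$y, d$X, K, gp@S + diag(nrow(K)), gp@gamma)
  o2 <- oracleLayerScore(d$y, d$X, K, mp@S + diag(nrow(K)), mp@gamma)
  df <- o1$df
  cc <- (4 * res@S + o1$trW + o2$trW) / df
  ys <- o1$ys
  obs <- drop(crossprod(ys, (o1$Q + o2$Q) %*% ys)) - cc * sum(ys^2)
  expect_lt(abs(obs) / sum(ys^2), 1e-8)
  # and the stored spectrum reproduces the same event structure
  expect_equal(res@S, (res@S1 + res@S2) / 2, tolerance = 1e-12)
})

test_that("single-layer results match the joint code path with one layer", {
  d <- makeTestData(n = 20, seed = 23)
  rb <- residualBasis(d$kinship, d$X, d$y)
  gp <- buildSimilarityPair(ibsSimilarity(d$G), 0.25)
  r1 <- jcarTest(rb, genetic = gp)
  expect_identical(r1@mode, "genetic")
  expect_true(is.na(r1@S2))
  expect_equal(r1@S, r1@S1, tolerance = 1e-12)
  full <- carAssociationTest(d$y, d$X, genotypes = d$G,
                             kinship = d$kinship, gamma1 = 0.25)
  expect_equal(pValue(full), pValue(r1), tolerance = 1e-10)
})

test_that("p-values are invariant to affine shifts, bases and permutations", {
  d <- makeTestData(n = 28, seed = 29, family = TRUE)
  gp <- buildSimilarityPair(ibsSimilarity(d$G), 0.3)
  mp <- buildSimilarityPair(gaussianSimilarity(d$M), 0.4)
  rb <- residualBasis(d$kinship, d$X, d$y)
  p0 <- pValue(jcarTest(rb, gp, mp))

  # affine phenotype change
  y2 <- -2 * d$y + drop(d$X %*% c(1, -1, 2))
  p2 <- pValue(jcarTest(residualBasis(d$kinship, d$X, y2), gp, mp))
  expect_lt(abs(p2 - p0), 1e-8)

  # independent basis construction
  p3 <- pValue(jcarTest(residualBasis(d$kinship, d$X, d$y, method = "svd"),
                        gp, mp))
  expect_lt(abs(p3 - p0), 1e-8)

  # consistent subject permutation
  set.seed(1)
  pm <- sample(length(d$y))
  Kp <- kinshipMatrix(assayValues(d$kinship)[pm, pm],
                      subjectIds(d$kinship)[pm])
  gpP <- buildSimilarityPair(ibsSimilarity(assayValues(d$G)[pm, ]), 0.3)
  mpP <- buildSimilarityPair(gaussianSimilarity(assayValues(d$M)[pm, ],
                                                defaultBandwidth(d$M)), 0.4)
  rbP <- residualBasis(Kp, d$X[pm, ], d$y[pm])
  p4 <- pValue(jcarTest(rbP, gpP, mpP))
  expect_lt(abs(p4 - p0), 1e-8)
})

test_that("null p-values are roughly uniform in a small calibration run", {
  sc <- simScenario(nSubjects = 40L, familySizes = integer(0),
                    maf = seq(0.1, 0.5, length.out = 5),
                    cpgMean = rep(0.5, 3), cpgSd = rep(0.1, 3), seed = 77L)
  rr <- rejectionRate(sc, nReps = 150, alpha = 0.05, mode = "joint")
  expect_gt(suppressWarnings(ks.test(rr$pValues, "punif"))$p.value, 0.01)
  expect_true(rr$rate >= 0 && rr$rate <= 0.15)
})
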