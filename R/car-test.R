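## The CAR linear score test on the profiled restricted likelihood.
##
## Model: y = X beta + g + m + eps, with CAR priors
##   g ~ N(0, sigmaG2 (D1 - gamma1 S1)^-1),
##   m ~ N(0, sigmaM2 (D2 - gamma2 S2)^-1),
##   eps ~ N(0, sigma2 K).
## The score test of sigmaG2 = sigmaM2 = 0 profiles beta and sigma2 out: with
## y* = A K^{-1/2} y (A an orthonormal basis of the complement of the
## whitened covariate space), the layer statistic is
##   S_l = (df/2) * y*' Q_l y* / (y*'y*) - tr(W_l)/2,
## where W_l = K^{-1/2} (D_l - gamma_l S_l)^{-1} K^{-1/2}, Q_l = A W_l A',
## and df = n - rank(X).  The p-value is P[z' B z > 0] for z ~ N(0, I) with
## B = sum_l Q_l - c I and c chosen so the observed point sits exactly at
## the threshold; the tail is computed by characteristic-function inversion.

#' Symmetric inverse square root of a positive-definite matrix
#'
#' Computed by eigendecomposition; the result `M` satisfies
#' `M %*% K %*% M = I` to high accuracy.
#'
#' @param Kin a [KinshipMatrix-class] or symmetric PD matrix.
#' @param tol smallest admissible eigenvalue.
#' @param jitter when `TRUE`, add `1e-8 * I` before decomposing (off by
#'   default; near-singular input is otherwise rejected).
#' @return Symmetric matrix `K^(-1/2)`.
#' @export
inverseSqrtMatrix <- function(Kin, tol = 1e-10, jitter = FALSE) {
  K <- if (is(Kin, "KinshipMatrix")) Kin@values else as.matrix(Kin)
  if (max(abs(K - t(K))) > 1e-8) stop("matrix must be symmetric")
  if (jitter) K <- K + diag(1e-8, nrow(K))
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) <= tol)
    stop(sprintf("matrix is not positive definite (eigenvalue %.3g <= %.3g)",
                 min(e$values), tol))
  M <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  (M + t(M)) / 2
}

#' Whitened residual basis for the score test
#'
#' Builds `K^(-1/2)`, an orthonormal basis A of the orthogonal complement of
#' the column space of `K^(-1/2) X` (so `A K^(-1/2) X = 0`, `AA' = I`), and
#' the transformed phenotype `y* = A K^(-1/2) y`.  Under the null and for
#' any error variance, `y* ~ N(0, sigma2 I)`.
#'
#' The numerical rank of X is determined from its singular values at
#' tolerance `max(dim) * eps * largest singular value`; rank-deficient
#' covariates reduce the rank with a warning.  Two independent basis
#' constructions are available (`"qr"` and `"svd"`); all downstream results
#' are invariant to the choice.
#'
#' @param Kin a [KinshipMatrix-class] or PD matrix.
#' @param X covariate matrix including an intercept column.
#' @param y numeric phenotype vector.
#' @param method basis construction, `"qr"` (default) or `"svd"`.
#' @return A [ResidualBasis-class] object.
#' @export
residualBasis <- function(Kin, X, y, method = c("qr", "svd")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  Kih <- inverseSqrtMatrix(Kin)
  if (nrow(Kih) != n) stop("kinship dimension must match nrow(X)")
  KX <- Kih %*% X
  sv <- svd(KX, nu = if (method == "svd") n else 0, nv = 0)
  r <- sum(sv$d > max(dim(KX)) * .Machine$double.eps * sv$d[1])
  if (r < ncol(X))
    warning(sprintf("covariate matrix is rank deficient (rank %d of %d)",
                    r, ncol(X)))
  if (n <= r) stop("no residual degrees of freedom: n <= rank(X)")
  A <- if (method == "svd") {
    t(sv$u[, (r + 1):n, drop = FALSE])
  } else {
    qq <- qr(KX, LAPACK = TRUE)
    t(qr.Q(qq, complete = TRUE)[, (r + 1):n, drop = FALSE])
  }
  scl <- max(1, max(abs(KX)))
  if (max(abs(A %*% KX)) > 1e-8 * scl ||
      max(abs(tcrossprod(A) - diag(n - r))) > 1e-8)
    stop("internal error: residual basis failed its invariants")
  wy <- Kih %*% y
  new("ResidualBasis", A = A, KinvSqrt = Kih,
      yStar = as.numeric(A %*% wy),
      rankX = as.integer(r), n = as.integer(n),
      yNorm2 = sum(wy^2))
}

## Per-layer ingredients: W = Kih Pinv Kih, Q = A W A', trace of W.
layerMatrices <- function(rb, pair) {
  prec <- diag(pair@D) - pair@gamma * pair@S
  Pinv <- chol2inv(chol((prec + t(prec)) / 2))
  W <- rb@KinvSqrt %*% Pinv %*% rb@KinvSqrt
  W <- (W + t(W)) / 2
  Q <- rb@A %*% W %*% t(rb@A)
  list(Q = (Q + t(Q)) / 2, trW = sum(diag(W)))
}

#' Single-layer CAR score statistic
#'
#' `S_l = (df/2) * y*' Q_l y* / (y*' y*) - tr(W_l) / 2` with
#' `df = n - rank(X)`; see the package vignette for the derivation.  The
#' statistic is invariant to replacing y by `a*y + X b` for any nonzero `a`.
#'
#' @param rb a [ResidualBasis-class] from [residualBasis()].
#' @param pair a [SimilarityPair-class] for the layer.
#' @return Scalar score statistic.
#' @export
scoreStatisticLayer <- function(rb, pair) {
  ys <- rb@yStar
  if (sum(ys^2) <= 1e-20 * max(rb@yNorm2, .Machine$double.xmin))
    stop("y* is identically zero (phenotype lies in the covariate span)")
  lm_ <- layerMatrices(rb, pair)
  df <- rb@n - rb@rankX
  ratio <- drop(crossprod(ys, lm_$Q %*% ys)) / sum(ys^2)
  df / 2 * ratio - lm_$trW / 2
}

#' CAR score test of genetic, methylation or joint association
#'
#' Runs the linear score test for the layers supplied: genetic only,
#' methylation only, or the joint test combining both with
#' `S = (S1 + S2) / 2`.  The p-value is the tail probability
#' `P[y*' B y* > 0]` where B centres the summed layer matrix at the observed
#' statistic (the observed quadratic form is exactly zero by construction),
#' evaluated on B's spectrum by [daviesTail()].  Under the null hypothesis
#' the p-value is exactly uniform.
#'
#' @param rb a [ResidualBasis-class].
#' @param genetic,methylation [SimilarityPair-class] objects; supply at
#'   least one.
#' @param accuracy absolute accuracy of the tail computation.
#' @return A [ScoreTestResult-class] object.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(100 * 5, 2, 0.3), 100)
#' y <- rnorm(100); X <- cbind(1, rnorm(100))
#' rb <- residualBasis(diag(100), X, y)
#' gp <- buildSimilarityPair(ibsSimilarity(G), defaultGamma(G))
#' jcarTest(rb, genetic = gp)
#' @export
jcarTest <- function(rb, genetic = NULL, methylation = NULL,
                     accuracy = 1e-6) {
  if (is.null(genetic) && is.null(methylation))
    stop("supply at least one similarity layer")
  ys <- rb@yStar
  if (sum(ys^2) <= 1e-20 * max(rb@yNorm2, .Machine$double.xmin))
    stop("y* is identically zero (phenotype lies in the covariate span)")
  df <- rb@n - rb@rankX
  mode <- if (!is.null(genetic) && !is.null(methylation)) "joint"
          else if (!is.null(genetic)) "genetic" else "methylation"

  Qsum <- 0; trSum <- 0
  S1 <- S2 <- NA_real_
  if (!is.null(genetic)) {
    lm1 <- layerMatrices(rb, genetic)
    S1 <- df / 2 * drop(crossprod(ys, lm1$Q %*% ys)) / sum(ys^2) - lm1$trW / 2
    Qsum <- Qsum + lm1$Q; trSum <- trSum + lm1$trW
  }
  if (!is.null(methylation)) {
    lm2 <- layerMatrices(rb, methylation)
    S2 <- df / 2 * drop(crossprod(ys, lm2$Q %*% ys)) / sum(ys^2) - lm2$trW / 2
    Qsum <- Qsum + lm2$Q; trSum <- trSum + lm2$trW
  }
  S <- if (mode == "joint") (S1 + S2) / 2
       else if (mode == "genetic") S1 else S2
  # threshold constant: the observed ratio y*'Qsum y*/y*'y*, written in
  # terms of the reported statistic(s)
  cc <- if (mode == "joint") (4 * S + trSum) / df else (2 * S + trSum) / df
  spectrum <- eigen(Qsum, symmetric = TRUE, only.values = TRUE)$values - cc
  mx <- max(abs(spectrum))
  diagnostics <- list(gamma1 = if (!is.null(genetic)) genetic@gamma else NA,
                      gamma2 = if (!is.null(methylation)) methylation@gamma
                               else NA,
                      df = df)
  if (mx <= 1e-12) {
    warning("quadratic-form matrix B is numerically zero; p-value set to 1")
    p <- 1
    diagnostics$pMethod <- "degenerate"
  } else {
    spectrum <- spectrum[abs(spectrum) > 1e-10 * mx]
    p <- daviesTail(spectrum, q = 0, accuracy = accuracy)
    diagnostics$pMethod <- attr(p, "method")
    if (identical(diagnostics$pMethod, "moment"))
      diagnostics$fallback <- TRUE
    p <- as.numeric(p)
  }
  new("ScoreTestResult", S1 = S1, S2 = S2, S = S, pValue = p,
      spectrum = as.numeric(spectrum), mode = mode,
      diagnostics = diagnostics)
}

#' One-call CAR association test on matrices
#'
#' Convenience wrapper assembling the residual basis, kernels and
#' autocorrelations from raw inputs, then calling [jcarTest()].  All inputs
#' must share subject order.
#'
#' @param y numeric phenotype vector.
#' @param X covariate matrix (include an intercept column).
#' @param genotypes a [GenotypeMatrix-class] or 0/1/2 matrix, or `NULL`.
#' @param methylation a [MethylationMatrix-class] or matrix, or `NULL`.
#' @param kinship a [KinshipMatrix-class] or PD matrix; identity when `NULL`.
#' @param gamma1,gamma2 autocorrelation overrides; data-driven defaults via
#'   [defaultGamma()] when `NULL`.
#' @param bandwidth Gaussian-kernel bandwidth override.
#' @param accuracy tail-probability accuracy.
#' @return A [ScoreTestResult-class] object.
#' @export
carAssociationTest <- function(y, X, genotypes = NULL, methylation = NULL,
                               kinship = NULL, gamma1 = NULL, gamma2 = NULL,
                               bandwidth = NULL, accuracy = 1e-6) {
  n <- length(y)
  Kin <- if (is.null(kinship)) diag(n) else kinship
  rb <- residualBasis(Kin, X, y)
  gp <- mp <- NULL
  if (!is.null(genotypes)) {
    G <- imputeMean(genotypes)
    g1 <- if (is.null(gamma1)) defaultGamma(G) else gamma1
    gp <- buildSimilarityPair(ibsSimilarity(G), g1)
  }
  if (!is.null(methylation)) {
    M <- imputeMean(methylation)
    bw <- if (is.null(bandwidth)) defaultBandwidth(M) else bandwidth
    g2 <- if (is.null(gamma2)) defaultGamma(M) else gamma2
    mp <- buildSimilarityPair(gaussianSimilarity(M, bw), g2)
    attr(mp, "bandwidth") <- bw
  }
  res <- jcarTest(rb, genetic = gp, methylation = mp, accuracy = accuracy)
  if (!is.null(mp)) res@diagnostics$bandwidth <- attr(mp, "bandwidth")
  res
}
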