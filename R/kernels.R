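## Similarity kernels and the CAR ingredients built from them.

asValues <- function(x) {
  if (is(x, "GenotypeMatrix") || is(x, "MethylationMatrix")) x@values
  else as.matrix(x)
}

#' Normalized identity-by-state (IBS) genetic similarity
#'
#' For additive genotype codes, the IBS similarity between subjects i and j
#' is `s_ij = sum_k (2 - |g_ik - g_jk|) / (2K)`, the average allele sharing
#' over the gene's K SNPs, normalized to \[0, 1\].  Identical genotype
#' profiles give 1; opposite homozygotes at every SNP give 0.
#'
#' @param G a [GenotypeMatrix-class] or numeric matrix of 0/1/2 codes with
#'   no missing values (impute first, see [imputeMean()]).
#' @return n x n symmetric similarity matrix with unit diagonal.
#' @examples
#' G <- rbind(a = c(0, 1, 2), b = c(1, 1, 0))
#' ibsSimilarity(G)[1, 2]  # 0.5
#' @export
ibsSimilarity <- function(G) {
  v <- asValues(G)
  if (anyNA(v))
    stop("genotype matrix contains missing values; apply imputeMean() first")
  if (ncol(v) < 1) stop("at least one SNP is required")
  K <- ncol(v)
  # sum_k |g_ik - g_jk| is the Manhattan distance between genotype rows
  d <- as.matrix(stats::dist(v, method = "manhattan"))
  S <- 1 - d / (2 * K)
  dimnames(S) <- list(rownames(v), rownames(v))
  S
}

#' Gaussian methylation similarity
#'
#' `s_ij = exp(-sum_l (m_il - m_jl)^2 / (2 sigma^2))`, the Gaussian
#' (radial-basis) kernel over the gene's CpG profiles.  Values lie in
#' (0, 1] with unit diagonal.
#'
#' @param M a [MethylationMatrix-class] or numeric matrix with no missing
#'   values.
#' @param sigma positive bandwidth; defaults to the pooled standard
#'   deviation of the matrix entries, see [defaultBandwidth()].
#' @return n x n symmetric similarity matrix with unit diagonal.
#' @export
gaussianSimilarity <- function(M, sigma = defaultBandwidth(M)) {
  v <- asValues(M)
  if (anyNA(v))
    stop("methylation matrix contains missing values; apply imputeMean() first")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a positive scalar")
  d2 <- as.matrix(stats::dist(v, method = "euclidean"))^2
  S <- exp(-d2 / (2 * sigma^2))
  dimnames(S) <- list(rownames(v), rownames(v))
  S
}

#' Default Gaussian-kernel bandwidth
#'
#' The bandwidth is the sample standard deviation of the gene's methylation
#' values, pooled over all entries of the matrix (flattened, unbiased n-1
#' denominator).  A constant matrix has zero spread and is rejected, since a
#' zero bandwidth degenerates the kernel.
#'
#' @param M a [MethylationMatrix-class] or numeric matrix; missing entries
#'   are ignored.
#' @return Positive scalar bandwidth.
#' @export
defaultBandwidth <- function(M) {
  v <- as.vector(asValues(M))
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 non-missing methylation values")
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0)
    stop("methylation values are constant; bandwidth would be zero")
  s
}

#' Default CAR autocorrelation from marker correlations
#'
#' The autocorrelation gamma of a layer is fixed at the average of the
#' entries of the marker-by-marker Pearson correlation matrix (SNP columns
#' for the genetic layer, CpG columns for the methylation layer).  Constant
#' columns have undefined correlations and are dropped first; if fewer than
#' two non-constant columns remain, gamma falls back to 0 with a warning.
#'
#' @param X numeric matrix (or Genotype/Methylation container), subjects in
#'   rows and markers in columns; missing values are handled pairwise.
#' @param includeDiagonal average over all entries including the unit
#'   diagonal (default) or off-diagonal entries only.
#' @return Scalar gamma in \[-1, 1\].
#' @export
defaultGamma <- function(X, includeDiagonal = TRUE) {
  v <- asValues(X)
  sds <- apply(v, 2, stats::sd, na.rm = TRUE)
  keep <- is.finite(sds) & sds > 0
  if (sum(keep) < 2) {
    warning("fewer than 2 non-constant columns; falling back to gamma = 0")
    return(0)
  }
  C <- stats::cor(v[, keep, drop = FALSE], use = "pairwise.complete.obs")
  C[is.na(C)] <- 0  # pairs with no overlapping observations
  m <- ncol(C)
  if (includeDiagonal) mean(C)
  else (sum(C) - sum(diag(C))) / (m^2 - m)
}

#' Assemble the CAR similarity pair
#'
#' Masks the diagonal of a raw similarity matrix to zero, computes the
#' diagonal D of row sums, stores gamma, and verifies that the CAR precision
#' `D - gamma S` is positive definite (smallest eigenvalue above `tol`).
#' When it is not, the error message reports the admissible gamma interval
#' computed from the generalized eigenvalues of S with respect to D.
#'
#' @param Sraw n x n symmetric similarity matrix with unit diagonal.
#' @param gamma autocorrelation scalar.
#' @param tol positive-definiteness tolerance on the smallest eigenvalue.
#' @return A [SimilarityPair-class] object.
#' @export
buildSimilarityPair <- function(Sraw, gamma, tol = 1e-8) {
  S <- as.matrix(Sraw)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("similarity matrix must be square and symmetric")
  if (max(abs(diag(S) - 1)) > 1e-8)
    stop("raw similarity matrix must have unit diagonal")
  S <- (S + t(S)) / 2
  diag(S) <- 0
  D <- rowSums(S)
  if (any(D < 1e-10)) {
    bad <- rownames(S)[D < 1e-10] %||% which(D < 1e-10)
    stop("subject(s) with no similarity mass (zero row sum): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  prec <- diag(D) - gamma * S
  ev <- eigen((prec + t(prec)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol) {
    # D - gamma*S is PD iff 1 - gamma*mu > 0 for generalized eigenvalues mu
    # of D^{-1/2} S D^{-1/2}
    W <- diag(1 / sqrt(D)) %*% S %*% diag(1 / sqrt(D))
    mu <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lo <- if (min(mu) < 0) 1 / min(mu) else -Inf
    hi <- if (max(mu) > 0) 1 / max(mu) else Inf
    stop(sprintf(paste0("D - gamma*S is not positive definite at gamma = %g; ",
                        "admissible interval is (%g, %g)"), gamma, lo, hi))
  }
  new("SimilarityPair", S = S, D = D, gamma = as.numeric(gamma))
}
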