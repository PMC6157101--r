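## Synthetic-data generator: family-structured genotypes by Mendelian gene
## dropping, logit-normal CpG beta values, and phenotypes under the null or
## the CAR alternative, plus a rejection-rate harness.

#' Pedigree implied by a simulation scenario
#'
#' Unrelated scenarios give a founders-only pedigree.  Family scenarios
#' build one nuclear family per entry of `familySizes`: two founder parents
#' and `size - 2` full-sib children.
#'
#' @param sc a [SimScenario-class].
#' @return A [Pedigree-class] object with ids `F<fam>_I<member>` (or
#'   `U<i>` when unrelated).
#' @export
simulatePedigree <- function(sc) {
  if (length(sc@familySizes) == 0) {
    ids <- paste0("U", seq_len(sc@nSubjects))
    return(pedigree(ids, NA, NA, famId = ids))
  }
  id <- father <- mother <- fam <- character(0)
  sex <- integer(0)
  for (f in seq_along(sc@familySizes)) {
    s <- sc@familySizes[f]
    ids <- sprintf("F%d_I%d", f, seq_len(s))
    id <- c(id, ids)
    father <- c(father, NA, NA, rep(ids[1], s - 2))
    mother <- c(mother, NA, NA, rep(ids[2], s - 2))
    sex <- c(sex, 1L, 2L, rep(NA_integer_, s - 2))
    fam <- c(fam, rep(sprintf("F%d", f), s))
  }
  pedigree(id, father, mother, sex = sex, famId = fam)
}

#' Simulate genotypes by Mendelian gene dropping
#'
#' Founder alleles are drawn independently as Bernoulli(MAF) per SNP
#' (Hardy-Weinberg), and each offspring inherits one uniformly chosen allele
#' from each parent, dropped through the pedigree in topological order.
#'
#' @param sc a [SimScenario-class].
#' @param ped pedigree (defaults to [simulatePedigree()] of the scenario).
#' @param seed integer seed (defaults to the scenario seed).
#' @return A [GenotypeMatrix-class] with subjects in pedigree order.
#' @export
simulateGenotypes <- function(sc, ped = simulatePedigree(sc),
                              seed = sc@seed) {
  K <- length(sc@maf)
  n <- length(ped@id)
  idx <- stats::setNames(seq_len(n), ped@id)
  fa <- idx[ped@father]; mo <- idx[ped@mother]
  ord <- pedigreeOrder(ped)
  withSeed(seed, {
    a1 <- matrix(NA_integer_, n, K)
    a2 <- matrix(NA_integer_, n, K)
    for (i in ord) {
      a1[i, ] <- if (is.na(fa[i])) stats::rbinom(K, 1, sc@maf)
        else ifelse(stats::runif(K) < 0.5, a1[fa[i], ], a2[fa[i], ])
      a2[i, ] <- if (is.na(mo[i])) stats::rbinom(K, 1, sc@maf)
        else ifelse(stats::runif(K) < 0.5, a1[mo[i], ], a2[mo[i], ])
    }
    genotypeMatrix(a1 + a2, ped@id, paste0("snp", seq_len(K)))
  })
}

#' Simulate CpG beta values
#'
#' Per-site logit-normal draws whose logit-scale location and scale are set
#' by the delta method from the target beta-scale mean and SD
#' (`mu = qlogis(mean)`, `sd = cpgSd / (mean * (1 - mean))`), so values are
#' bounded in (0, 1) by construction.  A per-family random intercept of SD
#' `familySd` (logit scale) induces within-family correlation when nonzero.
#'
#' @inheritParams simulateGenotypes
#' @return A [MethylationMatrix-class] with subjects in pedigree order.
#' @export
simulateMethylation <- function(sc, ped = simulatePedigree(sc),
                                seed = sc@seed + 1L) {
  L <- length(sc@cpgMean)
  n <- length(ped@id)
  famFac <- match(ped@famId, unique(ped@famId))
  withSeed(seed, {
    famInt <- if (sc@familySd > 0)
      stats::rnorm(max(famFac), 0, sc@familySd)[famFac] else numeric(n)
    m <- sapply(seq_len(L), function(l) {
      mu <- stats::qlogis(sc@cpgMean[l])
      sdl <- sc@cpgSd[l] / (sc@cpgMean[l] * (1 - sc@cpgMean[l]))
      stats::plogis(stats::rnorm(n, mu, sdl) + famInt)
    })
    methylationMatrix(m, ped@id, paste0("cg", seq_len(L)))
  })
}

#' Simulate covariates (intercept, age, sex)
#'
#' @inheritParams simulateGenotypes
#' @return n x 3 matrix with columns `intercept`, `age` (standard normal),
#'   `sex` (Bernoulli 0/1).
#' @export
simulateCovariates <- function(sc, seed = sc@seed + 2L) {
  n <- sc@nSubjects
  withSeed(seed, cbind(intercept = rep(1, n), age = stats::rnorm(n),
                       sex = stats::rbinom(n, 1, 0.5)))
}

## Draw one CAR effect vector with covariance sigma2 * (D - gamma S)^{-1}.
## If prec = R'R (Cholesky), then solve(R, z) has covariance prec^{-1}.
drawCarEffect <- function(pair, sigma2) {
  prec <- diag(pair@D) - pair@gamma * pair@S
  R <- chol((prec + t(prec)) / 2)
  sqrt(sigma2) * backsolve(R, stats::rnorm(nrow(prec)))
}

#' Draw CAR-distributed effect vectors
#'
#' Samples from the joint law implied by the CAR conditionals,
#' `N(0, sigma2 * (D - gamma S)^{-1})`, via the Cholesky factor of the
#' precision matrix.
#'
#' @param pair a [SimilarityPair-class].
#' @param sigma2 conditional variance scale.
#' @param nReps number of independent vectors.
#' @param seed optional integer seed (caller's RNG state is preserved when
#'   given).
#' @return `nReps` x n matrix of draws.
#' @export
rcarEffect <- function(pair, sigma2 = 1, nReps = 1, seed = NULL) {
  draw <- function() t(vapply(seq_len(nReps),
                              function(i) drawCarEffect(pair, sigma2),
                              numeric(length(pair@D))))
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Simulate a phenotype under the CAR mixed model
#'
#' `y = X beta + g + m + eps` with `g ~ N(0, sigmaG2 (D1 - gamma1 S1)^-1)`,
#' `m ~ N(0, sigmaM2 (D2 - gamma2 S2)^-1)` (the joint laws implied by the
#' CAR conditionals) and `eps ~ N(0, sigma2 K)`.  Setting
#' `sigmaG2 = sigmaM2 = 0` yields the exact null.  Similarities are the IBS
#' kernel of `G` and the Gaussian kernel of `M` at the pooled-SD bandwidth;
#' the scenario's `gamma1`/`gamma2` parameterize the generative precision.
#'
#' @param sc a [SimScenario-class].
#' @param G a [GenotypeMatrix-class] (complete).
#' @param M a [MethylationMatrix-class] (complete).
#' @param Kin a [KinshipMatrix-class] for the error covariance.
#' @param X covariate matrix with `length(sc@beta)` columns.
#' @param seed integer seed.
#' @return Named numeric phenotype vector in subject order.
#' @export
simulatePhenotype <- function(sc, G, M, Kin, X, seed = sc@seed + 3L) {
  n <- sc@nSubjects
  stopifnot(nrow(X) == n, ncol(X) == length(sc@beta))
  withSeed(seed, {
    g <- if (sc@sigmaG2 > 0)
      drawCarEffect(buildSimilarityPair(ibsSimilarity(G), sc@gamma1),
                    sc@sigmaG2) else numeric(n)
    m <- if (sc@sigmaM2 > 0)
      drawCarEffect(buildSimilarityPair(gaussianSimilarity(M), sc@gamma2),
                    sc@sigmaM2) else numeric(n)
    eps <- sqrt(sc@sigma2) *
      drop(crossprod(chol(Kin@values), stats::rnorm(n)))
    stats::setNames(drop(X %*% sc@beta) + g + m + eps, subjectIds(G))
  })
}

#' Simulate a complete analysis-ready dataset
#'
#' Draws pedigree, kinship (relationship scaling), genotypes, methylation,
#' covariates and phenotype for a scenario.  Identical scenario and seed
#' give identical output.
#'
#' @param sc a [SimScenario-class].
#' @return List with elements `pedigree`, `kinship`, `G`, `M`, `X`, `y`,
#'   `scenario`.
#' @export
simulateDataset <- function(sc) {
  ped <- simulatePedigree(sc)
  Kin <- errorCovariance(kinshipCoefficients(ped), "relationship")
  G <- simulateGenotypes(sc, ped)
  M <- simulateMethylation(sc, ped)
  X <- simulateCovariates(sc)
  y <- simulatePhenotype(sc, G, M, Kin, X)
  list(pedigree = ped, kinship = Kin, G = G, M = M, X = X, y = y,
       scenario = sc)
}

#' Empirical rejection rate of the CAR test under a scenario
#'
#' Runs the full analysis pipeline (kernels with data-driven gamma and
#' bandwidth, kinship-adjusted residual basis, score test) on `nReps`
#' independently simulated datasets and reports the frequency of
#' `p <= alpha` with an exact binomial confidence interval.  Per-replicate
#' seeds are derived deterministically from the scenario seed; the pedigree
#' and kinship matrix are fixed across replicates.
#'
#' @param sc a [SimScenario-class].
#' @param nReps number of replicates.
#' @param alpha rejection level.
#' @param mode `"joint"`, `"genetic"` or `"methylation"`.
#' @param conf confidence level of the binomial interval.
#' @return List with `rate`, `ci` (length-2 vector), `pValues`, `nReps`,
#'   `alpha`.
#' @export
rejectionRate <- function(sc, nReps, alpha = 0.05,
                          mode = c("joint", "genetic", "methylation"),
                          conf = 0.95) {
  mode <- match.arg(mode)
  ped <- simulatePedigree(sc)
  Kin <- errorCovariance(kinshipCoefficients(ped), "relationship")
  ps <- vapply(seq_len(nReps), function(r) {
    scr <- sc
    scr@seed <- deriveSeed(sc@seed, r)
    G <- simulateGenotypes(scr, ped)
    M <- simulateMethylation(scr, ped)
    X <- simulateCovariates(scr)
    y <- simulatePhenotype(scr, G, M, Kin, X)
    res <- suppressWarnings(carAssociationTest(
      y, X,
      genotypes = if (mode != "methylation") G else NULL,
      methylation = if (mode != "genetic") M else NULL,
      kinship = Kin))
    pValue(res)
  }, numeric(1))
  k <- sum(ps <= alpha)
  ci <- stats::binom.test(k, nReps, conf.level = conf)$conf.int
  list(rate = k / nReps, ci = as.numeric(ci), pValues = ps,
       nReps = nReps, alpha = alpha)
}
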