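#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers.  Subject order is the single source of truth for row
## alignment: every matrix-valued object carries subjectIds, and downstream
## code reorders inputs to the phenotype table's order before mixing them.
## ---------------------------------------------------------------------------

#' GenotypeMatrix: subjects x SNPs additive genotype codes
#'
#' Additive coding counts copies of the alternate allele, so every
#' non-missing entry is 0, 1 or 2.  Missing genotypes are allowed and must be
#' mean-imputed (see [imputeMean()]) before kernel computation.
#'
#' @slot values numeric matrix, subjects in rows, SNPs in columns.
#' @slot subjectIds character vector of row identifiers.
#' @slot snpIds character vector of column identifiers.
#' @export
setClass("GenotypeMatrix",
  representation(values = "matrix", subjectIds = "character",
                 snpIds = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != length(object@subjectIds))
      msg <- c(msg, "nrow(values) must match length(subjectIds)")
    if (ncol(v) != length(object@snpIds))
      msg <- c(msg, "ncol(values) must match length(snpIds)")
    if (nrow(v) < 2) msg <- c(msg, "at least 2 subjects are required")
    if (ncol(v) < 1) msg <- c(msg, "at least 1 SNP is required")
    if (anyDuplicated(object@subjectIds))
      msg <- c(msg, "subjectIds must be unique")
    obs <- v[!is.na(v)]
    if (length(obs) && !all(obs %in% c(0, 1, 2)))
      msg <- c(msg, "non-missing genotype codes must be 0, 1 or 2")
    if (length(msg)) msg else TRUE
  })

#' MethylationMatrix: subjects x CpG beta values
#'
#' Beta values are methylation proportions in \[0, 1\].  In difference mode
#' (visit-to-visit change, see [visitDifference()]) entries lie in \[-1, 1\].
#'
#' @slot values numeric matrix, subjects in rows, CpG sites in columns.
#' @slot subjectIds character vector of row identifiers.
#' @slot cpgIds character vector of column identifiers.
#' @slot valueType `"beta"` for raw proportions, `"difference"` for
#'   visit differences.
#' @export
setClass("MethylationMatrix",
  representation(values = "matrix", subjectIds = "character",
                 cpgIds = "character", valueType = "character"),
  prototype(valueType = "beta"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != length(object@subjectIds))
      msg <- c(msg, "nrow(values) must match length(subjectIds)")
    if (ncol(v) != length(object@cpgIds))
      msg <- c(msg, "ncol(values) must match length(cpgIds)")
    if (nrow(v) < 2) msg <- c(msg, "at least 2 subjects are required")
    if (ncol(v) < 1) msg <- c(msg, "at least 1 CpG site is required")
    if (anyDuplicated(object@subjectIds))
      msg <- c(msg, "subjectIds must be unique")
    if (!object@valueType %in% c("beta", "difference"))
      msg <- c(msg, "valueType must be 'beta' or 'difference'")
    obs <- v[!is.na(v)]
    lim <- if (identical(object@valueType, "difference")) c(-1, 1) else c(0, 1)
    if (length(obs) && (min(obs) < lim[1] || max(obs) > lim[2]))
      msg <- c(msg, sprintf("values must lie in [%g, %g]", lim[1], lim[2]))
    if (length(msg)) msg else TRUE
  })

#' SimilarityPair: zero-diagonal similarity matrix with CAR ingredients
#'
#' Holds the similarity matrix S (diagonal masked to zero), the diagonal D of
#' its row sums, and the autocorrelation gamma.  The CAR prior on the random
#' effects has precision (D - gamma S) / sigma2, so D - gamma S must be
#' positive definite; [buildSimilarityPair()] enforces this.
#'
#' @slot S symmetric numeric matrix with zero diagonal.
#' @slot D numeric vector of row sums of S.
#' @slot gamma autocorrelation scalar.
#' @export
setClass("SimilarityPair",
  representation(S = "matrix", D = "numeric", gamma = "numeric"),
  validity = function(object) {
    msg <- character()
    S <- object@S
    if (nrow(S) != ncol(S)) msg <- c(msg, "S must be square")
    if (max(abs(S - t(S))) > 1e-8) msg <- c(msg, "S must be symmetric")
    if (any(abs(diag(S)) > 1e-12)) msg <- c(msg, "diag(S) must be zero")
    if (length(object@D) != nrow(S))
      msg <- c(msg, "D must have one entry per row of S")
    if (max(abs(object@D - rowSums(S))) > 1e-8)
      msg <- c(msg, "D must equal the row sums of S")
    if (length(object@gamma) != 1) msg <- c(msg, "gamma must be a scalar")
    if (length(msg)) msg else TRUE
  })

#' KinshipMatrix: error-correlation structure of the sample
#'
#' Symmetric positive-definite matrix used as the correlation structure of
#' the residual errors (identity for unrelated subjects, twice the kinship
#' coefficient matrix for outbred families in `relationship` scaling).
#'
#' @slot values symmetric positive-definite numeric matrix.
#' @slot subjectIds character vector of identifiers.
#' @export
setClass("KinshipMatrix",
  representation(values = "matrix", subjectIds = "character"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (nrow(v) != length(object@subjectIds))
      msg <- c(msg, "dimension must match length(subjectIds)")
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
    if (length(msg)) msg else TRUE
  })

#' Pedigree: family records for kinship computation
#'
#' Unknown parents are `NA`; a missing single parent is treated as a unique
#' unnamed founder.  The graph must be acyclic.
#'
#' @slot id character identifiers, unique.
#' @slot father,mother character identifiers or `NA`.
#' @slot sex integer (1 male, 2 female, NA unknown); informational.
#' @slot famId character family labels; informational.
#' @export
setClass("Pedigree",
  representation(id = "character", father = "character", mother = "character",
                 sex = "integer", famId = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@id)
    if (anyDuplicated(object@id)) msg <- c(msg, "ids must be unique")
    if (length(object@father) != n || length(object@mother) != n)
      msg <- c(msg, "father/mother must match length(id)")
    known <- c(object@father, object@mother)
    known <- known[!is.na(known)]
    if (!all(known %in% object@id))
      msg <- c(msg, "all named parents must appear as individuals")
    if (length(msg)) msg else TRUE
  })

#' ResidualBasis: covariate-free whitened residual space
#'
#' Encodes the transform used by the score test: `KinvSqrt` is the symmetric
#' inverse square root of the kinship matrix, and the rows of `A` are an
#' orthonormal basis of the orthogonal complement of the column space of
#' `KinvSqrt %*% X`, so that `A %*% KinvSqrt %*% X = 0` and `AA' = I`.
#' `yStar = A %*% KinvSqrt %*% y` is the whitened, covariate-free phenotype.
#'
#' @slot A (n - rankX) x n matrix with orthonormal rows.
#' @slot KinvSqrt n x n symmetric inverse square root of the kinship matrix.
#' @slot yStar numeric vector of length n - rankX.
#' @slot rankX integer, numerical rank of the covariate matrix.
#' @slot n integer, number of subjects.
#' @slot yNorm2 squared norm of the whitened phenotype `K^(-1/2) y`, used to
#'   detect numerically degenerate `y*`.
#' @export
setClass("ResidualBasis",
  representation(A = "matrix", KinvSqrt = "matrix", yStar = "numeric",
                 rankX = "integer", n = "integer", yNorm2 = "numeric"))

#' ScoreTestResult: outcome of the CAR score test
#'
#' @slot S1,S2 per-layer score statistics (genetic, methylation); `NA` when
#'   the layer is absent.
#' @slot S combined statistic: `(S1 + S2) / 2` in joint mode, the single
#'   layer's statistic otherwise.
#' @slot pValue tail probability of the association test.
#' @slot spectrum eigenvalues of the threshold-centred quadratic-form matrix
#'   B passed to the tail computation.
#' @slot mode `"genetic"`, `"methylation"` or `"joint"`.
#' @slot diagnostics list: gamma values, bandwidth, p-value method, flags.
#' @export
setClass("ScoreTestResult",
  representation(S1 = "numeric", S2 = "numeric", S = "numeric",
                 pValue = "numeric", spectrum = "numeric", mode = "character",
                 diagnostics = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("genetic", "methylation", "joint"))
      msg <- c(msg, "mode must be genetic, methylation or joint")
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
      msg <- c(msg, "pValue must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' SimScenario: generative conditions for the synthetic-data simulator
#'
#' Defaults emulate a family study of a quantile-transformed lipid phenotype:
#' nuclear quartets, a gene with a block of common SNPs and a handful of CpG
#' sites, unit residual variance with kinship-correlated errors, and CAR
#' structured genetic/methylation effects under the alternative
#' (`sigmaG2`/`sigmaM2` > 0; both zero gives the exact null).
#'
#' @slot nSubjects total sample size.
#' @slot familySizes integer vector of nuclear-family sizes (2 parents plus
#'   children); empty means unrelated subjects.
#' @slot maf minor-allele frequencies of the gene's SNPs, in (0, 0.5].
#' @slot cpgMean,cpgSd per-site beta-value means and standard deviations.
#' @slot sigmaG2,sigmaM2 CAR conditional variances of the genetic and
#'   methylation effects.
#' @slot sigma2 residual variance (> 0).
#' @slot gamma1,gamma2 CAR autocorrelations used for generation.
#' @slot beta fixed effects for (intercept, age, sex).
#' @slot familySd SD of a per-family random intercept added to CpG values on
#'   the logit scale (0 disables it).
#' @slot seed integer seed; all draws are reproducible given the scenario.
#' @export
setClass("SimScenario",
  representation(nSubjects = "integer", familySizes = "integer",
                 maf = "numeric", cpgMean = "numeric", cpgSd = "numeric",
                 sigmaG2 = "numeric", sigmaM2 = "numeric", sigma2 = "numeric",
                 gamma1 = "numeric", gamma2 = "numeric", beta = "numeric",
                 familySd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjects < 2) msg <- c(msg, "nSubjects must be >= 2")
    if (length(object@familySizes) &&
        sum(object@familySizes) != object@nSubjects)
      msg <- c(msg, "familySizes must sum to nSubjects")
    if (length(object@familySizes) && any(object@familySizes < 2))
      msg <- c(msg, "each nuclear family needs at least the 2 parents")
    if (any(object@maf <= 0 | object@maf > 0.5))
      msg <- c(msg, "maf entries must lie in (0, 0.5]")
    if (length(object@cpgMean) != length(object@cpgSd))
      msg <- c(msg, "cpgMean and cpgSd must have equal length")
    if (any(object@cpgMean <= 0 | object@cpgMean >= 1))
      msg <- c(msg, "cpgMean entries must lie in (0, 1)")
    if (any(object@cpgSd <= 0)) msg <- c(msg, "cpgSd entries must be > 0")
    if (object@sigmaG2 < 0 || object@sigmaM2 < 0)
      msg <- c(msg, "variance components must be >= 0")
    if (object@sigma2 <= 0) msg <- c(msg, "sigma2 must be > 0")
    if (length(object@beta) != 3)
      msg <- c(msg, "beta must have length 3: (intercept, age, sex)")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

#' Construct a GenotypeMatrix
#'
#' @param values subjects x SNPs matrix of additive codes (0/1/2, NA allowed).
#' @param subjectIds,snpIds identifiers; taken from dimnames when missing.
#' @return A [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(values, subjectIds = rownames(values),
                           snpIds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(subjectIds)) subjectIds <- paste0("S", seq_len(nrow(values)))
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(ncol(values)))
  dimnames(values) <- list(subjectIds, snpIds)
  new("GenotypeMatrix", values = values,
      subjectIds = as.character(subjectIds), snpIds = as.character(snpIds))
}

#' Construct a MethylationMatrix
#'
#' @param values subjects x CpG matrix of beta values (NA allowed).
#' @param subjectIds,cpgIds identifiers; taken from dimnames when missing.
#' @param valueType `"beta"` or `"difference"`.
#' @return A [MethylationMatrix-class] object.
#' @export
methylationMatrix <- function(values, subjectIds = rownames(values),
                              cpgIds = colnames(values), valueType = "beta") {
  values <- as.matrix(values)
  if (is.null(subjectIds)) subjectIds <- paste0("S", seq_len(nrow(values)))
  if (is.null(cpgIds)) cpgIds <- paste0("cg", seq_len(ncol(values)))
  dimnames(values) <- list(subjectIds, cpgIds)
  new("MethylationMatrix", values = values,
      subjectIds = as.character(subjectIds), cpgIds = as.character(cpgIds),
      valueType = valueType)
}

#' Construct a KinshipMatrix
#'
#' @param values symmetric positive-definite matrix.
#' @param subjectIds identifiers; taken from rownames when missing.
#' @return A [KinshipMatrix-class] object.
#' @export
kinshipMatrix <- function(values, subjectIds = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(subjectIds)) subjectIds <- paste0("S", seq_len(nrow(values)))
  dimnames(values) <- list(subjectIds, subjectIds)
  new("KinshipMatrix", values = values, subjectIds = as.character(subjectIds))
}

#' Construct a Pedigree
#'
#' @param id unique individual identifiers.
#' @param father,mother parent identifiers; `NA` (or `"0"`) for unknown.
#' @param sex optional integer codes (1 male, 2 female).
#' @param famId optional family labels.
#' @return A [Pedigree-class] object; an error names a cycle if one exists.
#' @export
pedigree <- function(id, father, mother, sex = NA_integer_, famId = NA_character_) {
  id <- as.character(id)
  clean <- function(p) {
    p <- as.character(p)
    p[p %in% c("0", "", "NA")] <- NA_character_
    p
  }
  ped <- new("Pedigree", id = id,
             father = rep_len(clean(father), length(id)),
             mother = rep_len(clean(mother), length(id)),
             sex = rep_len(as.integer(sex), length(id)),
             famId = rep_len(as.character(famId), length(id)))
  pedigreeOrder(ped)  # errors on cycles, result discarded here
  ped
}

#' Construct a simulation scenario
#'
#' Defaults describe the package's reference study conditions: 50 nuclear
#' quartets (n = 200), a gene carrying 10 SNPs with MAFs spread over
#' \[0.05, 0.5\], 5 CpG sites with intermediate beta values, unit residual
#' variance, CAR autocorrelations 0.5, and a null phenotype
#' (`sigmaG2 = sigmaM2 = 0`).
#'
#' @param nSubjects total sample size.
#' @param familySizes integer vector of nuclear family sizes; `integer(0)`
#'   for unrelated subjects.
#' @param maf SNP minor-allele frequencies.
#' @param cpgMean,cpgSd CpG beta-value means and SDs.
#' @param sigmaG2,sigmaM2,sigma2 variance components.
#' @param gamma1,gamma2 CAR autocorrelations for generation.
#' @param beta fixed effects (intercept, age, sex).
#' @param familySd logit-scale SD of the per-family methylation intercept.
#' @param seed integer seed.
#' @return A [SimScenario-class] object.
#' @export
simScenario <- function(nSubjects = 200L,
                        familySizes = rep(4L, 50L),
                        maf = seq(0.05, 0.5, length.out = 10),
                        cpgMean = c(0.2, 0.35, 0.5, 0.65, 0.8),
                        cpgSd = rep(0.1, 5),
                        sigmaG2 = 0, sigmaM2 = 0, sigma2 = 1,
                        gamma1 = 0.5, gamma2 = 0.5,
                        beta = c(1, 0.5, 0.5),
                        familySd = 0, seed = 1L) {
  new("SimScenario", nSubjects = as.integer(nSubjects),
      familySizes = as.integer(familySizes), maf = maf,
      cpgMean = cpgMean, cpgSd = cpgSd, sigmaG2 = sigmaG2,
      sigmaM2 = sigmaM2, sigma2 = sigma2, gamma1 = gamma1, gamma2 = gamma2,
      beta = beta, familySd = familySd, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Show methods and light accessors
## ---------------------------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d subjects x %d SNPs (%d missing)\n",
              nrow(object@values), ncol(object@values),
              sum(is.na(object@values))))
})

setMethod("show", "MethylationMatrix", function(object) {
  cat(sprintf("MethylationMatrix (%s): %d subjects x %d CpGs (%d missing)\n",
              object@valueType, nrow(object@values), ncol(object@values),
              sum(is.na(object@values))))
})

setMethod("show", "SimilarityPair", function(object) {
  cat(sprintf("SimilarityPair: n = %d, gamma = %.4f, mean D = %.3f\n",
              nrow(object@S), object@gamma, mean(object@D)))
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d subjects, diagonal in [%.3f, %.3f]\n",
              nrow(object@values), min(diag(object@values)),
              max(diag(object@values))))
})

setMethod("show", "Pedigree", function(object) {
  cat(sprintf("Pedigree: %d individuals (%d founders)\n",
              length(object@id),
              sum(is.na(object@father) & is.na(object@mother))))
})

setMethod("show", "ScoreTestResult", function(object) {
  cat(sprintf("CAR score test (%s mode)\n", object@mode))
  if (!is.na(object@S1)) cat(sprintf("  S1 (genetic)     = %.4f\n", object@S1))
  if (!is.na(object@S2)) cat(sprintf("  S2 (methylation) = %.4f\n", object@S2))
  cat(sprintf("  S                = %.4f\n", object@S))
  cat(sprintf("  p-value          = %.4g  [%s]\n", object@pValue,
              object@diagnostics$pMethod %||% "cf-inversion"))
})

setMethod("show", "SimScenario", function(object) {
  fam <- if (length(object@familySizes))
    sprintf("%d families", length(object@familySizes)) else "unrelated"
  cat(sprintf(paste0("SimScenario: n = %d (%s), %d SNPs, %d CpGs, ",
                     "sigmaG2 = %.2f, sigmaM2 = %.2f, sigma2 = %.2f\n"),
              object@nSubjects, fam, length(object@maf),
              length(object@cpgMean), object@sigmaG2, object@sigmaM2,
              object@sigma2))
})

#' Subject identifiers of a data container
#'
#' @param x a GenotypeMatrix, MethylationMatrix, KinshipMatrix or Pedigree.
#' @return Character vector of subject ids.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname subjectIds
setMethod("subjectIds", "GenotypeMatrix", function(x) x@subjectIds)
#' @rdname subjectIds
setMethod("subjectIds", "MethylationMatrix", function(x) x@subjectIds)
#' @rdname subjectIds
setMethod("subjectIds", "KinshipMatrix", function(x) x@subjectIds)
#' @rdname subjectIds
setMethod("subjectIds", "Pedigree", function(x) x@id)

#' Numeric values of a data container
#'
#' @param x a GenotypeMatrix, MethylationMatrix or KinshipMatrix.
#' @return The underlying numeric matrix with dimnames.
#' @export
setGeneric("assayValues", function(x) standardGeneric("assayValues"))

#' @rdname assayValues
setMethod("assayValues", "GenotypeMatrix", function(x) x@values)
#' @rdname assayValues
setMethod("assayValues", "MethylationMatrix", function(x) x@values)
#' @rdname assayValues
setMethod("assayValues", "KinshipMatrix", function(x) x@values)

#' P-value of a score test result
#' @param x a [ScoreTestResult-class].
#' @return Numeric p-value in \[0, 1\].
#' @export
pValue <- function(x) x@pValue

#' Score statistics of a score test result
#' @param x a [ScoreTestResult-class].
#' @return Named numeric vector with elements `S1`, `S2`, `S`.
#' @export
scoreStats <- function(x) c(S1 = x@S1, S2 = x@S2, S = x@S)
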