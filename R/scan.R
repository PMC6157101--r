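## Genome-wide gene-based scan: per-gene marker grouping, imputation, kernel
## construction and the CAR score test, with per-gene failure isolation.

#' Scan configuration
#'
#' Validated container of paths and options for [runScan()].  The subject
#' order of the phenotype table is canonical; all other inputs are reordered
#' to it and unmatched subjects are dropped with a message.
#'
#' @param mode `"genetic"`, `"methylation"` or `"joint"`.
#' @param design `"baseline"` (single-visit values) or `"difference"`
#'   (later minus earlier visit for both methylation and phenotype,
#'   phenotype difference quantile-transformed).
#' @param genotypes path to a VCF or dosage TSV (required unless mode is
#'   `"methylation"`).
#' @param methylation path to a methylation TSV (baseline design).
#' @param methylationVisit1,methylationVisit2 paths to the earlier/later
#'   visit TSVs (difference design).
#' @param phenotype path to the phenotype/covariate TSV.
#' @param phenotypeCol phenotype column name (baseline), or the earlier
#'   visit's column in the difference design.
#' @param phenotypeCol2 later visit's phenotype column (difference design).
#' @param covariates character vector of covariate column names (an
#'   intercept is always added).
#' @param regions path to a BED file of gene regions.
#' @param pedigree path to a PED file, or `NULL`.
#' @param kinship path to a kinship TSV, or `NULL`; when both are `NULL`
#'   subjects are treated as unrelated.
#' @param kinshipScale `"relationship"` or `"kinship"` scaling for
#'   pedigree-derived matrices.
#' @param snpPositions,cpgPositions data.frames (`id`, `chrom`, `pos`,
#'   0-based) locating markers; for VCF input SNP positions are taken from
#'   the file when `NULL`.  CpG positions are required to assign CpGs to
#'   genes unless `cpgAll = TRUE`.
#' @param cpgAll when `TRUE`, every methylation column is used for every
#'   gene (for single-gene matrices).
#' @param gamma1,gamma2,bandwidth numeric overrides of the data-driven
#'   defaults.
#' @param flank flanking window around gene bodies, in bases.
#' @param alpha level used for summary flagging.
#' @param quantileTransformPhenotype apply [quantileTransform()] to the
#'   phenotype (default TRUE, matching the analysis the model is built for).
#' @param out optional output TSV path.
#' @return A classed list of options for [runScan()].
#' @export
scanConfig <- function(mode = c("joint", "genetic", "methylation"),
                       design = c("baseline", "difference"),
                       genotypes = NULL, methylation = NULL,
                       methylationVisit1 = NULL, methylationVisit2 = NULL,
                       phenotype, phenotypeCol, phenotypeCol2 = NULL,
                       covariates = character(0), regions,
                       pedigree = NULL, kinship = NULL,
                       kinshipScale = c("relationship", "kinship"),
                       snpPositions = NULL, cpgPositions = NULL,
                       cpgAll = FALSE,
                       gamma1 = NULL, gamma2 = NULL, bandwidth = NULL,
                       flank = 0, alpha = 0.05,
                       quantileTransformPhenotype = TRUE, out = NULL) {
  mode <- match.arg(mode)
  design <- match.arg(design)
  if (mode != "methylation" && is.null(genotypes))
    stop("mode '", mode, "' requires a genotype input")
  if (mode != "genetic") {
    if (design == "baseline" && is.null(methylation))
      stop("baseline design requires a methylation input")
    if (design == "difference" &&
        (is.null(methylationVisit1) || is.null(methylationVisit2)))
      stop("difference design requires both visit methylation inputs")
  }
  if (design == "difference" && is.null(phenotypeCol2))
    stop("difference design requires phenotypeCol2 (later visit)")
  structure(list(mode = mode, design = design, genotypes = genotypes,
                 methylation = methylation,
                 methylationVisit1 = methylationVisit1,
                 methylationVisit2 = methylationVisit2,
                 phenotype = phenotype, phenotypeCol = phenotypeCol,
                 phenotypeCol2 = phenotypeCol2, covariates = covariates,
                 regions = regions, pedigree = pedigree, kinship = kinship,
                 kinshipScale = match.arg(kinshipScale),
                 snpPositions = snpPositions, cpgPositions = cpgPositions,
                 cpgAll = cpgAll, gamma1 = gamma1, gamma2 = gamma2,
                 bandwidth = bandwidth, flank = flank, alpha = alpha,
                 quantileTransformPhenotype = quantileTransformPhenotype,
                 out = out),
            class = "ScanConfig")
}

#' Run a gene-based association scan
#'
#' For every region: group markers, mean-impute the gene's genotype and
#' methylation blocks, build the IBS and Gaussian kernels with their
#' autocorrelations, and run the mode-appropriate CAR score test.  Genes
#' missing a required layer are emitted with a skip flag, never dropped;
#' per-gene numerical failures are caught and flagged.  The residual basis
#' (kinship, covariates, phenotype) is shared by all genes.
#'
#' @param cfg a [scanConfig()] object.
#' @return data.frame with one row per region: `gene`, `chrom`, `n_snps`,
#'   `n_cpgs`, `S1`, `S2`, `S`, `p_value`, `flags`; written to `cfg$out`
#'   as TSV when set.
#' @export
runScan <- function(cfg) {
  stopifnot(inherits(cfg, "ScanConfig"))
  regions <- readRegions(cfg$regions)
  phen <- readPhenotype(cfg$phenotype)

  ## assemble phenotype vector and methylation according to the design
  M <- NULL
  if (cfg$design == "baseline") {
    yRaw <- stats::setNames(as.numeric(phen[[cfg$phenotypeCol]]), phen$id)
    if (cfg$mode != "genetic")
      M <- readMethylation(cfg$methylation)
  } else {
    y1 <- stats::setNames(as.numeric(phen[[cfg$phenotypeCol]]), phen$id)
    y2 <- stats::setNames(as.numeric(phen[[cfg$phenotypeCol2]]), phen$id)
    yRaw <- y2 - y1
    if (cfg$mode != "genetic")
      M <- visitDifference(readMethylation(cfg$methylationVisit1),
                           readMethylation(cfg$methylationVisit2))
  }

  G <- if (cfg$mode != "methylation") readGenotypes(cfg$genotypes) else NULL
  snpPos <- cfg$snpPositions %||% attr(G, "positions")

  ## canonical subject order: phenotype table order, intersected with all
  ## required inputs and complete covariate rows
  ids <- phen$id
  covs <- cfg$covariates
  if (length(covs)) {
    ok <- stats::complete.cases(phen[, covs, drop = FALSE])
    ids <- ids[ok]
  }
  ids <- ids[!is.na(yRaw[ids])]
  if (!is.null(G)) ids <- intersect(ids, subjectIds(G))
  if (!is.null(M)) ids <- intersect(ids, subjectIds(M))

  Kin <- if (!is.null(cfg$kinship)) readKinship(cfg$kinship)
    else if (!is.null(cfg$pedigree))
      errorCovariance(kinshipCoefficients(readPedigree(cfg$pedigree)),
                      cfg$kinshipScale)
    else NULL
  if (!is.null(Kin)) ids <- intersect(ids, subjectIds(Kin))

  nDropped <- length(phen$id) - length(ids)
  if (nDropped)
    message(sprintf("dropped %d subject(s) without complete data", nDropped))
  p <- 1 + length(covs)
  if (length(ids) < 3 + p)
    stop("fewer than rank(X) + 3 subjects with complete data")

  y <- yRaw[ids]
  if (cfg$quantileTransformPhenotype) y <- quantileTransform(y)
  X <- cbind(intercept = 1,
             as.matrix(phen[match(ids, phen$id), covs, drop = FALSE]))
  storage.mode(X) <- "double"
  if (!is.null(G)) G <- reorderSubjects(G, ids)
  if (!is.null(M)) M <- reorderSubjects(M, ids)
  KinM <- if (is.null(Kin)) kinshipMatrix(diag(length(ids)), ids)
          else reorderSubjects(Kin, ids)

  rb <- residualBasis(KinM, X, y)
  assign <- groupMarkers(regions, snpPos, cfg$cpgPositions, cfg$flank)

  rows <- lapply(seq_len(nrow(regions)), function(i) {
    row <- data.frame(gene = regions$gene[i], chrom = regions$chrom[i],
                      n_snps = 0L, n_cpgs = 0L, S1 = NA_real_,
                      S2 = NA_real_, S = NA_real_, p_value = NA_real_,
                      flags = "", stringsAsFactors = FALSE)
    snps <- assign[[i]]$snps
    cpgs <- if (cfg$cpgAll && !is.null(M)) M@cpgIds else assign[[i]]$cpgs
    flags <- character(0)
    Gg <- Mg <- NULL
    if (cfg$mode != "methylation") {
      snps <- intersect(snps, G@snpIds)
      row$n_snps <- length(snps)
      if (length(snps) == 0) flags <- c(flags, "no_snps")
      else Gg <- genotypeMatrix(G@values[, snps, drop = FALSE],
                                G@subjectIds, snps)
    }
    if (cfg$mode != "genetic") {
      cpgs <- intersect(cpgs, M@cpgIds)
      row$n_cpgs <- length(cpgs)
      if (length(cpgs) == 0) flags <- c(flags, "no_cpgs")
      else Mg <- methylationMatrix(M@values[, cpgs, drop = FALSE],
                                   M@subjectIds, cpgs, M@valueType)
    }
    required <- switch(cfg$mode, joint = !is.null(Gg) && !is.null(Mg),
                       genetic = !is.null(Gg), methylation = !is.null(Mg))
    if (!required) {
      row$flags <- paste(c(flags, "skipped"), collapse = ";")
      return(row)
    }
    res <- tryCatch(
      suppressWarnings(carAssociationTest(
        y, X, genotypes = Gg, methylation = Mg, kinship = KinM,
        gamma1 = cfg$gamma1, gamma2 = cfg$gamma2,
        bandwidth = cfg$bandwidth)),
      error = function(e) e)
    if (inherits(res, "error")) {
      row$flags <- paste(c(flags, paste0("error:", conditionMessage(res))),
                         collapse = ";")
      return(row)
    }
    row$S1 <- res@S1; row$S2 <- res@S2; row$S <- res@S
    row$p_value <- pValue(res)
    if (isTRUE(res@diagnostics$fallback)) flags <- c(flags, "moment_fallback")
    row$flags <- paste(flags, collapse = ";")
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(cfg$out))
    utils::write.table(out, cfg$out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Summarize a scan result table
#'
#' Top-n genes by ascending p-value (ties broken by gene id), a
#' genomic-inflation-style diagnostic (the median p-value of tested genes,
#' 0.5 under the global null), counts of skipped/failed genes, and the
#' Bonferroni threshold printed for reference; no multiple-testing
#' correction is applied to the results themselves.
#'
#' @param results data.frame from [runScan()].
#' @param topN number of top genes to report.
#' @param alpha nominal level for the Bonferroni reference threshold.
#' @return List with `top`, `nTested`, `nSkipped`, `medianP`,
#'   `bonferroni`; printed compactly by `print()`.
#' @export
summarizeScan <- function(results, topN = 10, alpha = 0.05) {
  tested <- results[!is.na(results$p_value), , drop = FALSE]
  ord <- order(tested$p_value, tested$gene)
  top <- tested[utils::head(ord, topN),
                c("gene", "chrom", "p_value"), drop = FALSE]
  rownames(top) <- NULL
  out <- list(top = top, nTested = nrow(tested),
              nSkipped = nrow(results) - nrow(tested),
              medianP = stats::median(tested$p_value),
              bonferroni = if (nrow(tested)) alpha / nrow(tested) else NA)
  class(out) <- "scanSummary"
  out
}

#' @export
print.scanSummary <- function(x, ...) {
  cat(sprintf("Gene-based CAR scan: %d genes tested, %d skipped\n",
              x$nTested, x$nSkipped))
  cat(sprintf("Median p-value: %.3f (0.5 expected under the global null)\n",
              x$medianP))
  cat(sprintf("Bonferroni reference threshold: %.3g\n", x$bonferroni))
  cat("Top genes:\n")
  print(x$top, ...)
  invisible(x)
}
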