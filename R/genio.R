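## Readers, writers and preprocessing.  All genomic coordinates are 0-based
## half-open internally; VCF positions (1-based) and BED intervals (already
## 0-based half-open) are converted on input.

#' Read gene regions from BED
#'
#' BED intervals are 0-based half-open; they are kept in that convention.
#' Track names (column 4) become gene ids; unnamed intervals receive
#' `region_<i>`.  A leading `chr` prefix is stripped from chromosome names.
#'
#' @param path BED file path (3+ columns).
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
readRegions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm)))
    nm <- paste0("region_", seq_along(gr))
  out <- data.frame(
    gene = as.character(nm),
    chrom = normChrom(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("regions must satisfy start < end")
  out
}

#' Write gene regions to BED
#'
#' @param regions data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegions <- function(regions, path) {
  utils::write.table(
    regions[, c("chrom", "start", "end", "gene")], path, sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Parse a VCF into an additive-dosage GenotypeMatrix (biallelic rows only).
readVcfGenotypes <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  keep <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
  nMulti <- sum(!keep)
  if (nMulti)
    message(sprintf("skipping %d multiallelic/invalid VCF record(s)", nMulti))
  pos0 <- as.integer(fix[, "POS"]) - 1L  # VCF is 1-based
  chrom <- normChrom(fix[, "CHROM"])
  if (!is.null(region))
    keep <- keep & chrom == normChrom(region$chrom) &
      pos0 >= region$start & pos0 < region$end
  if (!any(keep)) return(NULL)  # empty-gene sentinel
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(chrom[keep], ":", pos0[keep] + 1L)[is.na(ids) | ids == "."]
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  })
  pos <- data.frame(id = ids, chrom = chrom[keep], pos = pos0[keep],
                    stringsAsFactors = FALSE)
  structure(genotypeMatrix(t(dose), colnames(gt), ids), positions = pos)
}

## Parse a dosage TSV (header = SNP ids, first column = subject id).
readDosageGenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1,
                           colClasses = "character")
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab)), nrow(tab), ncol(tab),
           dimnames = dimnames(tab)))
  badNew <- is.na(m) & !(as.matrix(tab) %in% c("NA", "", ".") | is.na(tab))
  if (any(badNew)) {
    w <- which(badNew, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric genotype at row %d (%s), column %d (%s)",
                 w[1], rownames(tab)[w[1]], w[2], colnames(tab)[w[2]]))
  }
  bad <- !is.na(m) & !m %in% c(0, 1, 2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("genotype code %g at row %d, column %d is not 0/1/2",
                 m[w[1], w[2]], w[1], w[2]))
  }
  genotypeMatrix(m, rownames(tab), colnames(tab))
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF files (`.vcf`, `.vcf.gz`) are parsed with additive coding (count of
#' alternate alleles; biallelic records only, multiallelic rows skipped with
#' a message; `./.` preserved as missing).  Any other extension is read as a
#' dosage TSV: header of SNP ids, first column of subject ids, entries
#' 0/1/2 or missing.
#'
#' @param path input file.
#' @param region optional single-row region (list or data.frame with
#'   `chrom`, `start`, `end`, 0-based half-open); VCF only.
#' @return A [GenotypeMatrix-class], or `NULL` when no variant survives the
#'   region filter (the empty-gene sentinel).  For VCF input the result
#'   carries a `positions` attribute (data.frame `id`, `chrom`, `pos`).
#' @export
readGenotypes <- function(path, region = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    readVcfGenotypes(path, region)
  else
    readDosageGenotypes(path)
}

#' Write genotypes as a dosage TSV
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(G, path) {
  out <- data.frame(id = G@subjectIds, G@values, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation matrix from TSV
#'
#' Subjects in rows (first column = subject id), CpG sites in columns
#' (header).  `NA` and empty tokens are preserved as missing; any other
#' non-numeric token is rejected with its cell coordinates.
#'
#' @param path input file.
#' @param sites optional CpG id filter, returned in the requested order.
#' @param valueType `"beta"` or `"difference"`.
#' @return A [MethylationMatrix-class], or `NULL` for an empty site filter
#'   (the empty-gene sentinel).
#' @export
readMethylation <- function(path, sites = NULL, valueType = "beta") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1,
                           colClasses = "character")
  raw <- as.matrix(tab)
  m <- suppressWarnings(
    matrix(as.numeric(raw), nrow(tab), ncol(tab), dimnames = dimnames(tab)))
  badNew <- is.na(m) & !(raw %in% c("NA", "") | is.na(raw))
  if (any(badNew)) {
    w <- which(badNew, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric methylation value at row %d (%s), column %d (%s)",
                 w[1], rownames(tab)[w[1]], w[2], colnames(tab)[w[2]]))
  }
  if (!is.null(sites)) {
    sites <- intersect(sites, colnames(m))
    if (length(sites) == 0) return(NULL)  # empty-gene sentinel
    m <- m[, sites, drop = FALSE]
  }
  methylationMatrix(m, rownames(tab), colnames(m), valueType)
}

#' Write a methylation matrix to TSV
#'
#' @param M a [MethylationMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMethylation <- function(M, path) {
  out <- data.frame(id = M@subjectIds, M@values, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table from TSV
#'
#' First column (or column `id`) holds subject ids; remaining columns are
#' the phenotype and covariates.  Rows with missing phenotype or covariate
#' values are removed downstream by [runScan()] (listwise deletion).
#'
#' @param path input file.
#' @return data.frame with an `id` column of character subject ids.
#' @export
readPhenotype <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  idCol <- if ("id" %in% names(tab)) "id" else names(tab)[1]
  tab$id <- as.character(tab[[idCol]])
  if (anyDuplicated(tab$id)) stop("duplicate subject ids in phenotype table")
  tab[, c("id", setdiff(names(tab), idCol)), drop = FALSE]
}

#' Mean imputation of missing entries
#'
#' Replaces each missing entry by the mean of the non-missing entries of its
#' column (its SNP or CpG site); observed entries are untouched, so column
#' means are preserved exactly.  A column with no observed entry is an
#' error.
#'
#' @param x a matrix, [GenotypeMatrix-class] or [MethylationMatrix-class].
#' @return Object of the same class with no missing values.  Note that
#'   imputed genotype dosages are generally fractional; kernel computation
#'   accepts them.
#' @export
setGeneric("imputeMean", function(x) standardGeneric("imputeMean"))

imputeMeanMatrix <- function(x) {
  v <- x
  if (!anyNA(v)) return(v)
  allMiss <- colSums(!is.na(v)) == 0
  if (any(allMiss)) {
    nm <- colnames(v) %||% as.character(seq_len(ncol(v)))
    stop("column(s) with all values missing: ",
         paste(utils::head(nm[allMiss], 5), collapse = ", "))
  }
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- mu[idx[, 2]]
  v
}

#' @rdname imputeMean
setMethod("imputeMean", "matrix", imputeMeanMatrix)

#' @rdname imputeMean
setMethod("imputeMean", "GenotypeMatrix", function(x) {
  out <- x
  out@values <- imputeMeanMatrix(x@values)
  out
})

#' @rdname imputeMean
setMethod("imputeMean", "MethylationMatrix", function(x) {
  out <- x
  out@values <- imputeMeanMatrix(x@values)
  out
})

#' Rank-based normal quantile transformation
#'
#' Maps the value of rank r (average ranks for ties) to
#' `qnorm((r - 0.5) / n)`.  The transform is monotone and its output is
#' centred close to zero for distinct inputs.
#'
#' @param y numeric vector, length >= 3, not all values equal; missing
#'   values are propagated.
#' @return Transformed vector in the input order.
#' @export
quantileTransform <- function(y) {
  obs <- !is.na(y)
  v <- y[obs]
  n <- length(v)
  if (n < 3) stop("need at least 3 non-missing values")
  if (max(v) == min(v)) stop("constant phenotype cannot be transformed")
  r <- rank(v, ties.method = "average")
  out <- y
  out[obs] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Visit-to-visit differences on the shared subjects
#'
#' Restricts both inputs to their common subjects (in the order of
#' `earlier`) and returns elementwise `later - earlier` differences.
#' Subjects present in only one visit are dropped with a message.  For
#' methylation containers the CpG sets are intersected the same way and the
#' result is flagged as `difference` values; the phenotype difference should
#' subsequently be quantile-transformed by the caller.
#'
#' @param earlier,later two [MethylationMatrix-class] objects, matrices with
#'   subject rownames, or named numeric vectors.
#' @return Same shape as the inputs, restricted to shared subjects.
#' @export
visitDifference <- function(earlier, later) {
  if (is(earlier, "MethylationMatrix") && is(later, "MethylationMatrix")) {
    ids <- intersect(earlier@subjectIds, later@subjectIds)
    if (length(ids) < 2) stop("fewer than 2 shared subjects between visits")
    drop <- length(union(earlier@subjectIds, later@subjectIds)) - length(ids)
    if (drop) message(sprintf("dropping %d subject(s) missing a visit", drop))
    sites <- intersect(earlier@cpgIds, later@cpgIds)
    if (!length(sites)) stop("no shared CpG sites between visits")
    d <- later@values[ids, sites, drop = FALSE] -
      earlier@values[ids, sites, drop = FALSE]
    methylationMatrix(d, ids, sites, valueType = "difference")
  } else if (is.numeric(earlier) && is.null(dim(earlier))) {
    ids <- intersect(names(earlier), names(later))
    if (length(ids) < 2) stop("fewer than 2 shared subjects between visits")
    drop <- length(union(names(earlier), names(later))) - length(ids)
    if (drop) message(sprintf("dropping %d subject(s) missing a visit", drop))
    later[ids] - earlier[ids]
  } else {
    ids <- intersect(rownames(earlier), rownames(later))
    if (length(ids) < 2) stop("fewer than 2 shared subjects between visits")
    later[ids, , drop = FALSE] - earlier[ids, , drop = FALSE]
  }
}

#' Assign markers to gene regions
#'
#' A marker belongs to a gene iff its 0-based position lies in
#' `[start - flank, end + flank)` on the matching chromosome; overlapping
#' genes each receive shared markers.  Assignment uses interval overlap via
#' `IRanges`.
#'
#' @param regions data.frame from [readRegions()] (`gene`, `chrom`,
#'   `start`, `end`; 0-based half-open).
#' @param snpPositions,cpgPositions data.frames with columns `id`, `chrom`,
#'   `pos` (0-based), or `NULL`.
#' @param flank symmetric flanking window in bases (default 0: gene body).
#' @return Named list (one element per gene, in region order) of lists with
#'   character vectors `snps` and `cpgs`.
#' @export
groupMarkers <- function(regions, snpPositions = NULL, cpgPositions = NULL,
                         flank = 0) {
  gr <- GenomicRanges::GRanges(
    normChrom(regions$chrom),
    IRanges::IRanges(start = pmax(regions$start - flank, 0) + 1L,
                     end = regions$end + flank))
  assign1 <- function(pos) {
    if (is.null(pos) || nrow(pos) == 0)
      return(replicate(nrow(regions), character(0), simplify = FALSE))
    mr <- GenomicRanges::GRanges(normChrom(pos$chrom),
                                 IRanges::IRanges(start = pos$pos + 1L,
                                                  width = 1L))
    hits <- GenomicRanges::findOverlaps(gr, mr)
    out <- replicate(nrow(regions), character(0), simplify = FALSE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (g in unique(qh)) out[[g]] <- as.character(pos$id[sh[qh == g]])
    out
  }
  snps <- assign1(snpPositions)
  cpgs <- assign1(cpgPositions)
  stats::setNames(lapply(seq_len(nrow(regions)), function(i)
    list(snps = snps[[i]], cpgs = cpgs[[i]])), regions$gene)
}
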