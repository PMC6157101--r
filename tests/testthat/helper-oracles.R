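## Independent oracles used across the suite.  These re-derive quantities
## along code paths separate from the package implementation.

## Dense, from-first-principles evaluation of the layer score statistic and
## the joint p-value threshold pieces.  Square roots and null spaces are
## built here with their own linear algebra.
oracleLayerScore <- function(y, X, Kmat, Sraw, gamma) {
  n <- length(y)
  S <- Sraw
  diag(S) <- 0
  D <- diag(rowSums(S))
  e <- eigen(Kmat, symmetric = TRUE)
  Kih <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  KX <- Kih %*% X
  sv <- svd(KX, nu = n)
  r <- sum(sv$d > max(dim(KX)) * .Machine$double.eps * sv$d[1])
  A <- t(sv$u[, (r + 1):n, drop = FALSE])
  ys <- drop(A %*% Kih %*% y)
  Pinv <- solve(D - gamma * S)
  W <- Kih %*% Pinv %*% Kih
  Q <- A %*% W %*% t(A)
  df <- n - r
  list(S = df / 2 * drop(t(ys) %*% Q %*% ys) / sum(ys^2) - sum(diag(W)) / 2,
       trW = sum(diag(W)), df = df, ys = ys, Q = Q)
}

## Brute-force all-pairs marker-to-region containment ([start, end), 0-based,
## with flank).
oracleGroupMarkers <- function(regions, pos, flank = 0) {
  lapply(seq_len(nrow(regions)), function(i) {
    hit <- vapply(seq_len(nrow(pos)), function(j) {
      pos$chrom[j] == regions$chrom[i] &&
        pos$pos[j] >= max(regions$start[i] - flank, 0) &&
        pos$pos[j] < regions$end[i] + flank
    }, logical(1))
    as.character(pos$id[hit])
  })
}

## One-pass mean/variance over all entries of a matrix (pooled SD oracle).
oraclePooledSd <- function(m) {
  v <- as.vector(m[!is.na(m)])
  n <- length(v)
  mu <- sum(v) / n
  sqrt(sum((v - mu)^2) / (n - 1))
}

## Pearson correlation from the definition, then the mean over all entries
## of the column correlation matrix.
oracleMeanCor <- function(x, includeDiagonal = TRUE) {
  p <- ncol(x)
  corFun <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  C <- outer(seq_len(p), seq_len(p),
             Vectorize(function(i, j) corFun(x[, i], x[, j])))
  if (includeDiagonal) mean(C) else (sum(C) - p) / (p^2 - p)
}

## Fixture pedigrees with textbook kinship values.
pedFullSibs <- function() {
  pedigree(c("f", "m", "a", "b"), c(NA, NA, "f", "f"),
           c(NA, NA, "m", "m"))
}
pedHalfSibs <- function() {
  pedigree(c("f", "m1", "m2", "a", "b"), c(NA, NA, NA, "f", "f"),
           c(NA, NA, NA, "m1", "m2"))
}
pedFirstCousins <- function() {
  # two full sibs marry unrelated spouses; their children are first cousins
  pedigree(c("g1", "g2", "p1", "p2", "s1", "s2", "c1", "c2"),
           c(NA, NA, "g1", "g1", NA, NA, "p1", "p2"),
           c(NA, NA, "g2", "g2", NA, NA, "s1", "s2"))
}

## Small analysis-ready dataset for invariance tests.
makeTestData <- function(n = 30, K = 6, L = 4, seed = 42, family = FALSE) {
  sc <- simScenario(
    nSubjects = as.integer(n),
    familySizes = if (family) rep(4L, n %/% 4) else integer(0),
    maf = seq(0.1, 0.5, length.out = K),
    cpgMean = seq(0.3, 0.7, length.out = L), cpgSd = rep(0.1, L),
    seed = as.integer(seed))
  simulateDataset(sc)
}

## Multi-gene scan fixture: writes dosage/methylation/phenotype/regions/PED
## files into `dir`.  Gene `signalGene` carries a CAR methylation effect of
## conditional variance sigmaM2.
makeScanFixture <- function(dir, nGenes = 6, n = 80, signalGene = 0,
                            sigmaM2 = 0, seed = 1, snpsPerGene = 4,
                            cpgsPerGene = 3) {
  nfam <- n %/% 4
  sc0 <- simScenario(nSubjects = as.integer(n),
                     familySizes = rep(4L, nfam),
                     maf = rep(0.3, snpsPerGene),
                     cpgMean = rep(0.5, cpgsPerGene),
                     cpgSd = rep(0.12, cpgsPerGene),
                     seed = as.integer(seed))
  ped <- simulatePedigree(sc0)
  Kin <- errorCovariance(kinshipCoefficients(ped), "relationship")
  Gs <- Ms <- list()
  snpPos <- cpgPos <- NULL
  regions <- data.frame(gene = paste0("gene", seq_len(nGenes)),
                        chrom = "1",
                        start = (seq_len(nGenes) - 1) * 10000,
                        end = (seq_len(nGenes) - 1) * 10000 + 5000)
  for (g in seq_len(nGenes)) {
    scg <- sc0; scg@seed <- as.integer(seed + 1000 * g)
    Gg <- simulateGenotypes(scg, ped)
    Mg <- simulateMethylation(scg, ped)
    sid <- paste0("g", g, "_snp", seq_len(snpsPerGene))
    cid <- paste0("g", g, "_cg", seq_len(cpgsPerGene))
    Gs[[g]] <- `colnames<-`(assayValues(Gg), sid)
    Ms[[g]] <- `colnames<-`(assayValues(Mg), cid)
    snpPos <- rbind(snpPos, data.frame(
      id = sid, chrom = "1",
      pos = regions$start[g] + seq_len(snpsPerGene) * 100))
    cpgPos <- rbind(cpgPos, data.frame(
      id = cid, chrom = "1",
      pos = regions$start[g] + seq_len(cpgsPerGene) * 150))
  }
  G <- genotypeMatrix(do.call(cbind, Gs), subjectIds(ped))
  M <- methylationMatrix(do.call(cbind, Ms), subjectIds(ped))
  X <- simulateCovariates(sc0)
  set.seed(seed + 77)
  eps <- drop(crossprod(chol(assayValues(Kin)), rnorm(n)))
  y <- drop(X %*% sc0@beta) + eps
  if (signalGene > 0 && sigmaM2 > 0) {
    Msig <- Ms[[signalGene]]
    pair <- buildSimilarityPair(gaussianSimilarity(Msig), 0.5)
    y <- y + drop(rcarEffect(pair, sigmaM2, 1))
  }
  names(y) <- subjectIds(ped)
  writeGenotypes(G, file.path(dir, "geno.tsv"))
  writeMethylation(M, file.path(dir, "meth.tsv"))
  writeRegions(regions, file.path(dir, "regions.bed"))
  writePedigree(ped, file.path(dir, "ped.tsv"))
  phen <- data.frame(id = subjectIds(ped), tg = as.numeric(y),
                     age = X[, "age"], sex = X[, "sex"])
  utils::write.table(phen, file.path(dir, "phen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(snpPos, file.path(dir, "snp_pos.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cpgPos, file.path(dir, "cpg_pos.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(regions = regions, snpPos = snpPos, cpgPos = cpgPos, n = n)
}
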