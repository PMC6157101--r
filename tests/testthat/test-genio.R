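writeTinyVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t101\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t150\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t1|1",
    "1\t200\trs3\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",
    "1\t250\trs4\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"), path)
  path
}

test_that("VCF genotypes are additively coded with missing preserved", {
  f <- writeTinyVcf(tempfile(fileext = ".vcf"))
  G <- suppressMessages(readGenotypes(f))
  v <- assayValues(G)
  expect_equal(v[, "rs1"], c(S1 = 0, S2 = 1, S3 = 2))
  expect_true(is.na(v["S1", "rs2"]))
  expect_equal(v[c("S2", "S3"), "rs2"], c(S2 = 1, S3 = 2))
  expect_false("rs4" %in% colnames(v))   # multiallelic row skipped
  expect_message(readGenotypes(f), "multiallelic")
  pos <- attr(G, "positions")
  expect_equal(pos$pos, c(100, 149, 199))   # 0-based internal positions
})

test_that("VCF region filtering is 0-based half-open", {
  f <- writeTinyVcf(tempfile(fileext = ".vcf"))
  # VCF pos 101 is 0-based 100: included at start; pos 200 (0-based 199)
  # excluded at end
  G <- suppressMessages(
    readGenotypes(f, region = list(chrom = "1", start = 100, end = 199)))
  expect_equal(colnames(assayValues(G)), c("rs1", "rs2"))
  expect_null(suppressMessages(
    readGenotypes(f, region = list(chrom = "2", start = 0, end = 1e6))))
})

test_that("dosage TSV round-trips losslessly and rejects bad codes", {
  set.seed(2)
  G <- genotypeMatrix(matrix(rbinom(20, 2, 0.4), 5, 4,
                             dimnames = list(paste0("s", 1:5),
                                             paste0("snp", 1:4))))
  f <- tempfile(fileext = ".tsv")
  writeGenotypes(G, f)
  G2 <- readGenotypes(f)
  expect_equal(assayValues(G2), assayValues(G))
  expect_identical(subjectIds(G2), subjectIds(G))

  bad <- rbind(c("id\ta\tb"), c("s1\t0\t3"), c("s2\t1\t2"))
  f2 <- tempfile(fileext = ".tsv")
  writeLines(bad, f2)
  expect_error(readGenotypes(f2), "not 0/1/2")
})

test_that("methylation TSV round-trips, filters sites and flags bad cells", {
  set.seed(6)
  M <- methylationMatrix(matrix(runif(12), 4, 3,
                                dimnames = list(paste0("s", 1:4),
                                                c("cgA", "cgB", "cgC"))))
  f <- tempfile(fileext = ".tsv")
  writeMethylation(M, f)
  M2 <- readMethylation(f)
  expect_equal(assayValues(M2), assayValues(M), tolerance = 1e-12)

  M3 <- readMethylation(f, sites = c("cgC", "cgA"))
  expect_identical(M3@cpgIds, c("cgC", "cgA"))
  expect_null(readMethylation(f, sites = "cgZ"))

  writeLines(c("id\tcgA", "s1\t0.5", "s2\toops"), f)
  expect_error(readMethylation(f), "non-numeric.*row 2")
})

test_that("mean imputation fills by column mean and preserves means", {
  m <- cbind(a = c(0, NA, 2), b = c(1, NA, NA))
  out <- imputeMean(m)
  expect_equal(out[, "a"], c(0, 1, 2))
  expect_equal(out[, "b"], c(1, 1, 1))
  expect_equal(colMeans(out), colMeans(m, na.rm = TRUE))
  expect_identical(imputeMean(cbind(c(1, 2))), cbind(c(1, 2)))
  expect_error(imputeMean(cbind(a = c(NA_real_, NA_real_))), "all values")
  G <- genotypeMatrix(rbind(c(0, NA), c(2, 1), c(NA, 1)))
  Gi <- imputeMean(G)
  expect_s4_class(Gi, "GenotypeMatrix")
  expect_equal(assayValues(Gi)[3, 1], 1)
})

test_that("quantile transform maps ranks to normal quantiles", {
  y <- c(5, -2, 9)
  out <- quantileTransform(y)
  expect_equal(sort(out), qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(out[1], 0)                     # middle value maps to 0
  expect_identical(order(out), order(y))      # monotone
  # two-way tie at the bottom of n = 4 shares the average-rank quantile
  yt <- c(1, 1, 2, 3)
  ot <- quantileTransform(yt)
  expect_equal(ot[1], ot[2])
  expect_equal(ot[1], qnorm((1.5 - 0.5) / 4), tolerance = 1e-12)
  expect_error(quantileTransform(rep(2, 5)), "constant")
  expect_error(quantileTransform(c(1, 2)), "at least 3")
})

test_that("quantile transform output is nearly centred", {
  set.seed(10)
  y <- rnorm(501)
  expect_lt(abs(mean(quantileTransform(y))), 1e-3)
})

test_that("visit differences restrict to shared subjects and anti-commute", {
  m1 <- methylationMatrix(matrix(runif(6), 3, 2,
                                 dimnames = list(c("a", "b", "c"), NULL)))
  m2 <- methylationMatrix(matrix(runif(6), 3, 2,
                                 dimnames = list(c("b", "c", "d"), NULL)))
  d <- suppressMessages(visitDifference(m1, m2))
  expect_identical(subjectIds(d), c("b", "c"))
  expect_identical(d@valueType, "difference")
  dRev <- suppressMessages(visitDifference(m2, m1))
  expect_equal(assayValues(dRev)[c("b", "c"), ], -assayValues(d),
               tolerance = 1e-12)
  expect_equal(max(abs(assayValues(visitDifference(m1, m1)))), 0)
  v1 <- c(a = 1, b = 2); v2 <- c(b = 5, a = 0)
  expect_equal(visitDifference(v1, v2), c(a = -1, b = 3))
})

test_that("marker grouping matches brute-force containment", {
  regions <- data.frame(gene = c("g1", "g2", "g3"), chrom = c("1", "1", "2"),
                        start = c(100, 150, 0), end = c(200, 300, 50))
  pos <- data.frame(id = paste0("m", 1:10),
                    chrom = c(rep("1", 7), rep("2", 3)),
                    pos = c(99, 100, 150, 199, 200, 250, 300, 0, 49, 50))
  got <- groupMarkers(regions, snpPositions = pos)
  want <- oracleGroupMarkers(regions, pos)
  for (i in 1:3) expect_setequal(got[[i]]$snps, want[[i]])
  # half-open convention: start included, end excluded
  expect_true("m2" %in% got$g1$snps)
  expect_false("m5" %in% got$g1$snps)
  # shared marker between overlapping genes
  expect_true(all(c("m3", "m4") %in% got$g1$snps) &&
                all(c("m3", "m4") %in% got$g2$snps))
  # flanking window widens the assignment, brute force agrees
  gotF <- groupMarkers(regions, snpPositions = pos, flank = 10)
  wantF <- oracleGroupMarkers(regions, pos, flank = 10)
  for (i in 1:3) expect_setequal(gotF[[i]]$snps, wantF[[i]])
  expect_true("m1" %in% gotF$g1$snps)
})

test_that("BED regions round-trip through rtracklayer in 0-based half-open", {
  regions <- data.frame(gene = c("gA", "gB"), chrom = c("1", "X"),
                        start = c(1000L, 0L), end = c(2000L, 500L))
  f <- tempfile(fileext = ".bed")
  writeRegions(regions, f)
  r2 <- readRegions(f)
  expect_equal(r2$start, regions$start)
  expect_equal(r2$end, regions$end)
  expect_identical(r2$gene, regions$gene)
})
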