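test_that("scan configuration validates mode and design requirements", {
  expect_error(scanConfig(mode = "joint", phenotype = "p", phenotypeCol = "y",
                          regions = "r", methylation = "m"),
               "genotype input")
  expect_error(scanConfig(mode = "methylation", design = "difference",
                          phenotype = "p", phenotypeCol = "y", regions = "r"),
               "both visit")
  cfg <- scanConfig(mode = "genetic", genotypes = "g", phenotype = "p",
                    phenotypeCol = "y", regions = "r")
  expect_s3_class(cfg, "ScanConfig")
})

scanFixtureDir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- tempfile("scanfix")
      dir.create(dir)
      fx <- makeScanFixture(dir, nGenes = 5, n = 60, signalGene = 0,
                            seed = 4)
      attr(dir, "fx") <<- fx
    }
    dir
  }
})

baseCfg <- function(dir, ...) {
  fx <- attr(dir, "fx")
  scanConfig(mode = "joint", genotypes = file.path(dir, "geno.tsv"),
             methylation = file.path(dir, "meth.tsv"),
             phenotype = file.path(dir, "phen.tsv"), phenotypeCol = "tg",
             covariates = c("age", "sex"),
             regions = file.path(dir, "regions.bed"),
             pedigree = file.path(dir, "ped.tsv"),
             snpPositions = fx$snpPos, cpgPositions = fx$cpgPos, ...)
}

test_that("the scan emits one row per region with flags, never drops genes", {
  dir <- scanFixtureDir()
  res <- suppressMessages(runScan(baseCfg(dir)))
  expect_equal(nrow(res), 5)
  expect_true(all(!is.na(res$p_value)))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$n_snps == 4) && all(res$n_cpgs == 3))
  expect_equal(res$S, (res$S1 + res$S2) / 2, tolerance = 1e-12)

  # a region with no markers is flagged, not dropped
  fx <- attr(dir, "fx")
  regions2 <- rbind(fx$regions,
                    data.frame(gene = "desert", chrom = "9",
                               start = 0, end = 100))
  f2 <- file.path(dir, "regions2.bed")
  writeRegions(regions2, f2)
  cfg2 <- baseCfg(dir)
  cfg2$regions <- f2
  res2 <- suppressMessages(runScan(cfg2))
  expect_equal(nrow(res2), 6)
  expect_true(grepl("skipped", res2$flags[res2$gene == "desert"]))
  expect_true(is.na(res2$p_value[res2$gene == "desert"]))
})

test_that("scan output is deterministic and mode-consistent", {
  dir <- scanFixtureDir()
  out1 <- tempfile(fileext = ".tsv"); out2 <- tempfile(fileext = ".tsv")
  cfg <- baseCfg(dir); cfg$out <- out1
  suppressMessages(runScan(cfg))
  cfg$out <- out2
  suppressMessages(runScan(cfg))
  expect_identical(readLines(out1), readLines(out2))

  # genetic mode ignores the methylation input entirely
  cfgG1 <- baseCfg(dir); cfgG1$mode <- "genetic"
  cfgG2 <- baseCfg(dir); cfgG2$mode <- "genetic"; cfgG2$methylation <- NULL
  r1 <- suppressMessages(runScan(cfgG1))
  r2 <- suppressMessages(runScan(cfgG2))
  expect_identical(r1, r2)
  expect_true(all(is.na(r1$S2)))

  # joint p differs from single-layer p on the same data
  rj <- suppressMessages(runScan(baseCfg(dir)))
  expect_false(isTRUE(all.equal(rj$p_value, r1$p_value)))
})

test_that("gamma and bandwidth overrides reach the per-gene tests", {
  dir <- scanFixtureDir()
  cfg <- baseCfg(dir, gamma1 = 0, gamma2 = 0, bandwidth = 0.2)
  res <- suppressMessages(runScan(cfg))
  resDef <- suppressMessages(runScan(baseCfg(dir)))
  expect_false(isTRUE(all.equal(res$p_value, resDef$p_value)))
})

test_that("a methylation-signal gene attains the smallest p in most runs", {
  wins <- 0L
  nRuns <- 7
  for (r in seq_len(nRuns)) {
    dir <- tempfile("sig"); dir.create(dir)
    fx <- makeScanFixture(dir, nGenes = 6, n = 100, signalGene = 3,
                          sigmaM2 = 8, seed = 300 + r)
    cfg <- scanConfig(mode = "joint",
                      genotypes = file.path(dir, "geno.tsv"),
                      methylation = file.path(dir, "meth.tsv"),
                      phenotype = file.path(dir, "phen.tsv"),
                      phenotypeCol = "tg", covariates = c("age", "sex"),
                      regions = file.path(dir, "regions.bed"),
                      pedigree = file.path(dir, "ped.tsv"),
                      snpPositions = fx$snpPos, cpgPositions = fx$cpgPos)
    res <- suppressMessages(runScan(cfg))
    if (which.min(res$p_value) == 3) wins <- wins + 1L
    unlink(dir, recursive = TRUE)
  }
  expect_gt(wins, nRuns / 2)
})

test_that("scan summaries sort, break ties and diagnose uniformity", {
  res <- data.frame(gene = c("b", "a", "c", "d"), chrom = "1",
                    n_snps = 1, n_cpgs = 1, S1 = 0, S2 = 0, S = 0,
                    p_value = c(0.01, 0.01, NA, 0.5), flags = "")
  s <- summarizeScan(res, topN = 10)
  expect_equal(s$nTested, 3)
  expect_equal(s$nSkipped, 1)
  expect_identical(s$top$gene, c("a", "b", "d"))   # tie broken by gene id
  expect_equal(s$bonferroni, 0.05 / 3)
  expect_output(print(s), "Top genes")

  set.seed(40)
  resU <- data.frame(gene = paste0("g", 1:2000), chrom = "1", n_snps = 1,
                     n_cpgs = 1, S1 = 0, S2 = 0, S = 0,
                     p_value = runif(2000), flags = "")
  expect_true(summarizeScan(resU)$medianP > 0.45 &&
                summarizeScan(resU)$medianP < 0.55)
})

test_that("the command-line driver runs a scan end to end", {
  script <- system.file("scripts", "jcar", package = "jcar")
  skip_if(script == "", "CLI script not installed")
  dir <- tempfile("cli"); dir.create(dir)
  fx <- makeScanFixture(dir, nGenes = 3, n = 40, seed = 9)
  out <- file.path(dir, "res.tsv")
  status <- system2("Rscript",
                    c(script, "scan", "--mode", "joint",
                      "--dosage", file.path(dir, "geno.tsv"),
                      "--methylation", file.path(dir, "meth.tsv"),
                      "--phenotype", file.path(dir, "phen.tsv"),
                      "--phenotype-col", "tg",
                      "--covariates", "age,sex",
                      "--regions", file.path(dir, "regions.bed"),
                      "--pedigree", file.path(dir, "ped.tsv"),
                      "--snp-positions", file.path(dir, "snp_pos.tsv"),
                      "--cpg-positions", file.path(dir, "cpg_pos.tsv"),
                      "--out", out),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  res <- read.delim(out)
  expect_equal(nrow(res), 3)
  unlink(dir, recursive = TRUE)
})
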