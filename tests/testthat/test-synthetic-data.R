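test_that("reference generation is deterministic under a fixed seed", {
  cfg <- referenceConfig(
    chromLengths = c(chr1 = 200000L, chr21 = 2200000L),
    nMirna = 20L, nCluster = 10L, nForeign = 4L,
    nForeignIdenticalPairs = 1L, nForeignAdd3 = 1L,
    nRepeats = 10L, nGenes = 10L, nTargetGenes = 4L, nTargetMirnas = 2L,
    nNovel = 1L, nDecoy = 1L)
  b1 <- suppressWarnings(buildReference(cfg, seed = 11L))
  b2 <- suppressWarnings(buildReference(cfg, seed = 11L))
  expect_identical(as.character(b1@genome), as.character(b2@genome))
  expect_identical(as.data.frame(precursors(b1)), as.data.frame(precursors(b2)))
  expect_identical(b1@mrnaFC, b2@mrnaFC)
  d1 <- file.path(tempdir(), "bundle1"); d2 <- file.path(tempdir(), "bundle2")
  writeReferenceBundle(b1, d1); writeReferenceBundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]])
  }
  b3 <- suppressWarnings(buildReference(cfg, seed = 12L))
  expect_false(identical(as.character(b1@genome), as.character(b3@genome)))
})

test_that("the planted cluster lies inside its 1 Mb window and the bundle is valid", {
  bundle <- smallBundle()
  cfg <- smallConfig()
  p <- as.data.frame(precursors(bundle, ownOnly = TRUE))
  cl <- p[p$chrom == cfg$clusterChrom, ]
  expect_equal(nrow(cl), cfg$nCluster)
  expect_true(all(cl$start >= cfg$clusterStart))
  expect_true(all(cl$end <= cfg$clusterStart + cfg$clusterSpan))
  expect_true(validObject(bundle))
  expect_true(validObject(bundle@registry))
})

test_that("zero foreign donors give an empty homolog section", {
  cfg <- referenceConfig(
    chromLengths = c(chr1 = 200000L, chr21 = 2200000L),
    nMirna = 15L, nCluster = 10L, nForeign = 0L,
    nForeignIdenticalPairs = 0L, nForeignAdd3 = 0L,
    nRepeats = 8L, nGenes = 8L, nTargetGenes = 3L, nTargetMirnas = 2L,
    nNovel = 1L, nDecoy = 1L)
  b <- suppressWarnings(buildReference(cfg, seed = 3L))
  expect_equal(sum(!matureArms(b)$own), 0L)
  hm <- matchHomolog(randomSeq(10, 22), b@registry)
  expect_true(all(is.na(hm$entity)))
})

test_that("undersized chromosomes raise a sizing error", {
  cfg <- referenceConfig(chromLengths = c(chr1 = 1000L, chr21 = 1500000L))
  expect_error(suppressWarnings(buildReference(cfg, seed = 1L)),
               "too short|too crowded")
})

test_that("simulated libraries follow the design and truth composition", {
  sim <- smallSim()
  design <- smallDesign()
  expect_equal(length(sim$libraries), 8L)
  expect_identical(names(sim$libraries), libraryNames(design))
  N <- design@readsPerLibrary
  for (l in names(sim$libraries)) {
    expect_equal(length(sim$libraries[[l]]$sequences), N)
    expect_true(all(nchar(sim$libraries[[l]]$sequences) == design@readLength))
  }
  # multinomial class-composition conservation within 3 sigma
  fr <- smallTruth()@fractions
  cc <- sim$classCounts
  mirRows <- c("mirna", "homolog")
  frVec <- c(fr[mirRows], fr[setdiff(names(fr), mirRows)])
  for (l in colnames(cc)) {
    z <- (cc[names(frVec), l] - N * frVec) / sqrt(N * frVec * (1 - frVec))
    expect_true(all(abs(z) <= 3.5))
  }
})

test_that("per-miRNA read counts match stored proportions within binomial error", {
  truth <- smallTruth()
  x <- smallExperiment()
  N <- smallDesign()@readsPerLibrary
  cnt <- SummarizedExperiment::assay(x, "counts")
  common <- intersect(rownames(cnt), rownames(truth@proportions))
  P <- truth@proportions[common, colnames(cnt)]
  Z <- (cnt[common, ] - N * P) / sqrt(pmax(N * P * (1 - P), 1e-9))
  expect_gt(mean(abs(Z) <= 3), 0.985)
})

test_that("simulation is deterministic and a zero-read design warns", {
  s1 <- simulateLibraries(smallBundle(), smallDesign(), smallTruth(), seed = 9L)
  s2 <- simulateLibraries(smallBundle(), smallDesign(), smallTruth(), seed = 9L)
  expect_identical(s1$libraries[[1]]$sequences, s2$libraries[[1]]$sequences)
  expect_identical(s1$libraries[[8]]$qualities, s2$libraries[[8]]$qualities)
  d0 <- studyDesign(readsPerLibrary = 0L)
  expect_warning(s0 <- simulateLibraries(smallBundle(), d0,
                                         smallTruth(), seed = 1L),
                 "0 reads")
  expect_equal(length(s0$libraries[[1]]$sequences), 0L)
})

test_that("miRNA-class inserts are templated isomiR windows of their arms", {
  # an all-miRNA composition: every insert must match a +/-2 nt window or
  # a planted edited variant
  fr <- c(mirna = 1, homolog = 0, ncrna = 0, "repeat" = 0, exon = 0,
          novel = 0, decoy = 0, background = 0, adapterDimer = 0,
          lowQuality = 0, polyA = 0, adapter5 = 0, nBases = 0)
  design <- studyDesign(readsPerLibrary = 2000L)
  truth <- buildTruthTable(smallBundle(), design, seed = 5L,
                           config = smallConfig(), fractions = fr,
                           nDE = 5L, nEdits = 2L, nLow = 2L)
  sim <- simulateLibraries(smallBundle(), design, truth, seed = 5L)
  p <- qcParams()
  f <- filterReads(sim$libraries[[1]]$sequences,
                   sim$libraries[[1]]$qualities, p)
  ins <- f$insert[f$keep]
  kn <- matchKnownMiRNA(unique(ins), smallBundle()@registry)
  ed <- detectEdited(unique(ins), smallBundle()@registry)
  expect_true(all(!is.na(kn$matureId) | !is.na(ed$matureId)))
})

test_that("truth table validity rules hold", {
  truth <- smallTruth()
  expect_true(validObject(truth))
  expect_true(all(abs(truth@de$log2fc) >= 1))
  expect_equal(sum(truth@isomir$p5), 1)
  expect_equal(sum(truth@fractions), 1)
})
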