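mkExperiment <- function(counts, denom, stages, libs = colnames(counts)) {
  rpm <- sweep(counts, 2, 1e6 / denom, "*")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, rpm = rpm),
    rowData = S4Vectors::DataFrame(id = rownames(counts),
                                   type = rep("known", nrow(counts))),
    colData = S4Vectors::DataFrame(library = libs, stage = stages,
                                   mappedReads = denom, row.names = libs))
  new("MiRNAExperiment", se)
}

test_that("RPM normalization follows counts x 1e6 / mapped denominator", {
  cnt <- matrix(9L, 1, 1, dimnames = list("m1", "L1"))
  x <- mkExperiment(cnt, 9e6, "E45")
  expect_equal(unname(rpm(x)[1, 1]), 1)
  # scale invariance: doubling counts and denominators leaves RPM unchanged
  x2 <- mkExperiment(cnt * 2L, 18e6, "E45")
  expect_equal(rpm(x)[1, 1], rpm(x2)[1, 1])
  # zero denominator is a configuration error
  annot <- smallAnnot()
  tags <- smallTags()
  badAnnot <- annot
  badAnnot$mapped <- FALSE
  expect_error(buildExpressionMatrix(badAnnot, tags, smallDesign()),
               "denominator")
})

test_that("aggregation counts isomiRs and edits under their mature id", {
  x <- smallExperiment()
  annot <- smallAnnot()
  tags <- smallTags()
  cnt <- tagCounts(tags)
  id <- annot$assignedMirna[annot$category == "edited-miRNA"][1]
  manual <- sum(cnt[annot$assignedMirna %in% id &
                      annot$category %in% c("known-miRNA", "edited-miRNA"), ])
  expect_equal(sum(SummarizedExperiment::assay(x, "counts")[id, ]), manual)
  expect_true(validObject(x))
})

test_that("retention and tier boundaries are exact", {
  cnt <- matrix(c(0.9, 1.1, 99.9, 100, 999.9, 1000, 10500) * 10, 7, 1,
                dimnames = list(paste0("m", 1:7), "L1"))
  x <- mkExperiment(cnt, 1e7, "E45")
  tiers <- filterAndTier(x)
  expect_equal(tiers$retained, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(as.character(tiers$tier),
               c("low", "low", "low", "moderate", "moderate", "high", "high"))
  expect_equal(tiers$over10k, c(rep(FALSE, 6), TRUE))
  # monotone step function of overall average
  avg <- sort(10^runif(50, -1, 5))
  cnt <- matrix(avg * 10, length(avg), 1,
                dimnames = list(paste0("x", seq_along(avg)), "L1"))
  t2 <- filterAndTier(mkExperiment(cnt, 1e7, "E45"))
  expect_true(!is.unsorted(as.integer(t2$tier)))
})

test_that("stage summaries satisfy the replication identity", {
  x <- smallExperiment()
  tiers <- filterAndTier(x)
  ab <- summarizeAbundance(x, tiers)
  stagesL <- unique(stages(x))
  r <- rpm(x)
  sm <- as.matrix(ab[match(rownames(r), ab$id), stagesL])
  expect_equal(unname(rowSums(sm) * 2), unname(rowSums(r)),
               tolerance = 1e-12)
  expect_equal(ab$overallRPM, unname(rowMeans(r)[ab$id]),
               tolerance = 1e-12)
  # percent of total computed over retained known miRNAs sums to 100
  expect_equal(sum(ab$pctTotal, na.rm = TRUE), 100, tolerance = 1e-9)
  # a single-miRNA matrix gives 100 percent
  cnt <- matrix(500L, 1, 2, dimnames = list("m1", c("L1", "L2")))
  x1 <- mkExperiment(cnt, c(1e6, 1e6), c("E45", "E45"))
  ab1 <- summarizeAbundance(x1, filterAndTier(x1))
  expect_equal(ab1$pctTotal, 100)
})

test_that("pairwise correlations are symmetric with unit diagonal", {
  x <- smallExperiment()
  tiers <- filterAndTier(x)
  cc <- pairwiseCorrelation(x, tiers)
  expect_equal(diag(cc), setNames(rep(1, ncol(cc)), colnames(cc)))
  expect_equal(cc, t(cc))
  # scale invariance of r
  r <- rpm(x)[tiers$id[tiers$retained & tiers$type == "known"], 1]
  expect_equal(cor(r, 2 * r), 1)
  # replicate libraries correlate far better than distant stages
  expect_gt(cc["E45-1", "E45-2"], cc["E45-1", "B3-2"])
  # zero-variance library warns
  cnt <- matrix(c(5L, 5L, 5L, 7L), 2, 2, dimnames = list(c("a", "b"),
                                                         c("L1", "L2")))
  xz <- mkExperiment(cnt, c(1e6, 1e6), c("E45", "E60"))
  expect_warning(pairwiseCorrelation(xz), "zero-variance")
})

test_that("cluster detection honors window, size and abundance rules", {
  bundle <- smallBundle()
  tiers <- filterAndTier(smallExperiment())
  cl <- detectGenomicClusters(bundle@registry, tiers, window = 100000L)
  cfg <- smallConfig()
  big <- cl[cl$chrom == cfg$clusterChrom, ]
  expect_equal(nrow(big), 1L)
  mem <- strsplit(big$members, ",")[[1]]
  p <- as.data.frame(precursors(bundle@registry, ownOnly = TRUE))
  m <- as.data.frame(matureArms(bundle@registry, ownOnly = TRUE))
  truthMem <- m$id[m$precursorId %in% p$id[p$chrom == cfg$clusterChrom]]
  truthMem <- intersect(truthMem, tiers$id[tiers$overallRPM > 100])
  expect_setequal(mem, truthMem)
  # genes spaced beyond the window never cluster
  preSeq <- randomSeq(5, 80)
  reg <- new("MiRNARegistry",
             precursors = S4Vectors::DataFrame(
               id = paste0("p", 1:5),
               sequence = preSeq,
               chrom = "chr1", start = (1:5) * 200000L,
               end = (1:5) * 200000L + 79L, strand = "+",
               species = "chi", own = TRUE),
             matures = S4Vectors::DataFrame(
               id = paste0("p", 1:5, "-5p"),
               sequence = substr(preSeq, 5, 26),
               precursorId = paste0("p", 1:5), offset = 5L,
               species = "chi", own = TRUE))
  expect_equal(nrow(detectGenomicClusters(reg, NULL, window = 100000L)), 0L)
  # an infinite window chains every gene on the chromosome
  clAll <- detectGenomicClusters(reg, NULL, window = .Machine$integer.max)
  expect_equal(clAll$n, 5L)
})

test_that("cluster detection is order- and translation-invariant", {
  reg <- smallBundle()@registry
  cl1 <- detectGenomicClusters(reg, NULL, window = 50000L)
  # shuffle mature rows
  reg2 <- reg
  perm <- sample(nrow(reg2@matures))
  reg2@matures <- reg2@matures[perm, ]
  cl2 <- detectGenomicClusters(reg2, NULL, window = 50000L)
  expect_equal(cl1, cl2)
  # translate all coordinates by a constant
  reg3 <- reg
  reg3@precursors$start <- reg3@precursors$start + 1000L
  reg3@precursors$end <- reg3@precursors$end + 1000L
  cl3 <- detectGenomicClusters(reg3, NULL, window = 50000L)
  expect_equal(cl3$n, cl1$n)
  expect_equal(cl3$start, cl1$start + 1000L)
})

test_that("hierarchical ordering splits planted co-expression programs", {
  set.seed(31)
  shapeA <- c(1, 2, 4, 1.5)
  shapeB <- c(4, 2.5, 1.2, 0.6)
  rows <- rbind(
    t(replicate(10, shapeA * exp(rnorm(4, 0, 0.05)))),
    t(replicate(10, shapeB * exp(rnorm(4, 0, 0.05)))))
  rownames(rows) <- sprintf("m%02d", 1:20)
  h <- hierarchicalOrder(rows)
  g <- h$groups
  expect_equal(length(unique(g[1:10])), 1L)
  expect_equal(length(unique(g[11:20])), 1L)
  expect_false(g[1] == g[11])
  # two rows split into singletons
  h2 <- hierarchicalOrder(rows[c(1, 11), ])
  expect_equal(sort(unname(h2$groups)), c(1L, 2L))
  # identical rows: determinism enforced by id order
  same <- rows[c(1, 1, 1), ]
  rownames(same) <- c("a", "b", "c")
  expect_equal(hierarchicalOrder(same)$order,
               hierarchicalOrder(same[c(3, 1, 2), ])$order)
})

test_that("tier summary reproduces headline shares", {
  tiers <- data.frame(
    id = paste0("m", 1:410), type = "known",
    overallRPM = c(rep(50, 216), rep(500, 116), rep(5000, 59),
                   rep(20000, 19)),
    retained = TRUE,
    tier = factor(c(rep("low", 216), rep("moderate", 116),
                    rep("high", 78)), levels = c("low", "moderate", "high")),
    over10k = c(rep(FALSE, 391), rep(TRUE, 19)))
  ts <- tierSummary(tiers)
  expect_equal(ts$n, 410L)
  expect_equal(ts$pctOver10k, 4.63)
})
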