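test_that("folding reproduces closed-form energies", {
  stem <- paste0(strrep("G", 20), "AAAA", strrep("C", 20))
  r <- foldHairpin(stem)
  expect_equal(r$mfe, -3 * 19 + 3)      # 19 stacked GC pairs + hairpin loop
  expect_equal(sum(r$partner > 0) / 2, 20)
  expect_equal(foldHairpin(strrep("A", 60))$mfe, 0)
  expect_equal(foldHairpin(strrep("A", 60))$structure, strrep(".", 60))
  expect_error(foldHairpin("ACGTNNACGT"), "non-ACGU")
  # U is accepted as T
  expect_equal(foldHairpin(paste0(strrep("G", 10), "AAAA",
                                  strrep("C", 10)))$mfe,
               foldHairpin(paste0(strrep("G", 10), "UUUU",
                                  strrep("C", 10)))$mfe,
               tolerance = 1e-9)
})

test_that("the folding DP equals exhaustive structure enumeration", {
  set.seed(23)
  for (len in c(8, 10, 12, 14, 16)) {
    for (rep in 1:4) {
      s <- randomSeq(1, len)
      expect_equal(foldHairpin(s)$mfe, bruteForceFold(s),
                   tolerance = 1e-9, label = s)
    }
  }
  # a structured case with a bulge
  s <- paste0("GGGG", "AA", "GG", "AAAA", "CC", "CCCC")
  expect_equal(foldHairpin(s)$mfe, bruteForceFold(s), tolerance = 1e-9)
})

test_that("candidate excision yields two flanked windows per stack", {
  genome <- Biostrings::DNAStringSet(c(chrA = randomSeq(1, 2000)))
  tagSeq <- as.character(Biostrings::subseq(genome[[1]], 1001, 1022))
  loci <- data.frame(tag = 1L, sequence = tagSeq, chrom = "chrA",
                     pos = 1001L, strand = "+", stringsAsFactors = FALSE)
  cands <- exciseCandidates(loci, counts = c(20), genome, flank = 70L)
  expect_equal(nrow(cands), 2L)
  expect_equal(cands$start, c(1001L - 70L, 1001L - 15L))
  expect_equal(cands$end, c(1022L + 15L, 1022L + 70L))
  # stacks on both strands yield candidates per strand independently
  loci2 <- rbind(loci,
                 data.frame(tag = 2L, sequence = revcomp(tagSeq),
                            chrom = "chrA", pos = 1001L, strand = "-"))
  c2 <- exciseCandidates(loci2, counts = c(20, 20), genome, flank = 70L)
  expect_setequal(unique(c2$strand), c("+", "-"))
  expect_equal(nrow(c2), 4L)
  # window truncation at the contig end is tolerated
  lociEdge <- data.frame(tag = 1L, sequence = tagSeq, chrom = "chrA",
                         pos = 30L, strand = "+", stringsAsFactors = FALSE)
  lociEdge$sequence <- as.character(Biostrings::subseq(genome[[1]], 30, 51))
  cEdge <- exciseCandidates(lociEdge, counts = c(20), genome, flank = 70L)
  expect_true(all(cEdge$start >= 1L))
})

test_that("detector rules fire on thresholds and read-stack structure", {
  # build a strong synthetic hairpin with read support
  set.seed(41)
  mature <- randomSeq(1, 22)
  star <- revcomp(mature)
  for (pos in c(6, 12, 17)) {
    cur <- substr(star, pos, pos)
    substr(star, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  fl5 <- randomSeq(1, 8)
  pre <- paste0(fl5, mature, randomSeq(1, 10), star, revcomp(fl5))
  genome <- Biostrings::DNAStringSet(
    c(chrA = paste0(randomSeq(1, 500), pre, randomSeq(1, 500))))
  mPos <- 500L + 8L + 1L
  sPos <- mPos + 22L + 10L
  loci <- data.frame(
    tag = 1:3,
    sequence = c(mature,
                 substr(pre, 10L, 32L),  # mature shifted by +1
                 as.character(Biostrings::subseq(genome[[1]], sPos,
                                                 sPos + 21L))),
    chrom = "chrA", pos = c(mPos, 501L + 9L, sPos), strand = "+",
    stringsAsFactors = FALSE)
  counts <- c(90, 8, 6)
  cands <- exciseCandidates(loci, counts, genome, flank = 70L)
  scored <- scoreCandidates(cands, counts, shuffles = 60L, seed = 2L)
  best <- scored[which.max(scored$score), ]
  expect_true(best$detectorA)
  expect_true(best$detectorB)
  expect_lt(best$pShuffle, 0.05)
  expect_equal(best$mature, mature)
  calls <- callNovel(scored)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$mature, mature)
  # calls are a subset of both detector pass sets
  expect_true(all(scored$detectorA[scored$mature %in% calls$mature &
                                     scored$cluster %in% scored$cluster]))
  # a weak stem fails detector B on the MFE rule regardless of reads
  weak <- paste0(randomSeq(1, 30), substr(mature, 1, 8),
                 randomSeq(1, 10), revcomp(substr(mature, 1, 8)),
                 randomSeq(1, 30))
  fold <- foldHairpin(weak)
  if (fold$mfe >= -18) {
    genomeW <- Biostrings::DNAStringSet(c(chrA = paste0(
      randomSeq(1, 200), weak, randomSeq(1, 200))))
    lw <- data.frame(tag = 1L, sequence = substr(weak, 31L, 52L),
                     chrom = "chrA", pos = 231L, strand = "+",
                     stringsAsFactors = FALSE)
    sw <- scoreCandidates(exciseCandidates(lw, c(50), genomeW, flank = 30L),
                          c(50), shuffles = 10L, seed = 1L)
    expect_true(all(!sw$detectorB))
  }
})

test_that("dinucleotide shuffling preserves dinucleotide composition", {
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  set.seed(12)
  for (rep in 1:10) {
    s <- randomSeq(1, 80)
    sh <- smallRNAome:::.dinucShuffle(s)
    expect_equal(nchar(sh), 80L)
    expect_equal(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
})

test_that("planted hairpins are recovered and decoy loci yield no calls", {
  bundle <- smallBundle()
  truth <- smallTruth()
  nv <- findNovelMiRNAs(smallAnnot(), smallTags(), bundle@genome,
                        shuffles = 100L, seed = 7L)
  truthMat <- unique(truth@novel$matureSeq)
  recall <- mean(truthMat %in% nv$calls$mature)
  expect_gte(recall, 0.9)
  # the duplicated hairpin collapses to one mature with two precursors
  dupName <- names(which(table(truth@novel$name) == 2L))
  dupMat <- truth@novel$matureSeq[truth@novel$name == dupName][1]
  call <- nv$calls[nv$calls$mature == dupMat, ]
  expect_equal(call$nPrecursors, 2L)
  # no call overlaps a decoy locus
  dec <- bundle@planted[bundle@planted$kind == "decoy", ]
  for (i in seq_len(nrow(nv$calls))) {
    for (pc in strsplit(nv$calls$precursors[i], ";")[[1]]) {
      ch <- sub(":.*", "", pc)
      st <- as.integer(sub(".*:(\\d+)-.*", "\\1", pc))
      expect_false(any(dec$chrom == ch & abs(dec$start - st) < 500L))
    }
  }
  # names follow descending total count
  expect_true(!is.unsorted(rev(nv$calls$reads)))
  # empty candidate set gives an empty call list
  empty <- scoreCandidates(
    exciseCandidates(attr(smallAnnot(), "loci")[0, ], numeric(0),
                     bundle@genome),
    numeric(0))
  expect_equal(nrow(callNovel(empty)), 0L)
})
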