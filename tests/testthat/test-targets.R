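test_that("seed-site classes follow the canonical definitions", {
  mirna <- "TGAGGTAGTAGGTTGTATAGTT"   # let-7 style
  m8 <- revcomp(substr(mirna, 2, 8))
  utr8 <- paste0(randomSeq(1, 30), m8, "A", randomSeq(1, 30))
  s <- findSeedSites(mirna, utr8)
  expect_equal(nrow(s), 1L)
  expect_equal(s$class, "8mer")
  expect_equal(s$position, 31L)
  utr7 <- paste0(randomSeq(1, 30), m8, "C", randomSeq(1, 30))
  expect_equal(findSeedSites(mirna, utr7)$class, "7mer-m8")
  m7A <- paste0(revcomp(substr(mirna, 2, 7)), "A")
  # 7mer-A1 only: G flanks cannot complete the position-8 match
  utrA1 <- paste0(strrep("G", 30), m7A, strrep("G", 30))
  sA1 <- findSeedSites(mirna, utrA1)
  expect_equal(sA1$class, "7mer-A1")
  # G-free seed against an all-C UTR finds nothing
  expect_equal(nrow(findSeedSites("TATTAATTAATTAATTAATTAA", strrep("C", 60))),
               0L)
})

test_that("seed scans agree with a naive oracle and recover planted sites", {
  set.seed(55)
  mirna <- randomSeq(1, 22)
  m8 <- revcomp(substr(mirna, 2, 8))
  naiveCount <- function(utr) {
    hits <- gregexpr(m8, utr, fixed = TRUE)[[1]]
    n8 <- sum(hits > 0)
    a1 <- gregexpr(paste0(revcomp(substr(mirna, 2, 7)), "A"), utr,
                   fixed = TRUE)[[1]]
    a1 <- a1[a1 > 0]
    a1 <- a1[!(a1 - 1) %in% hits[hits > 0]]
    n8 + length(a1)
  }
  recall <- 0
  for (k in 1:100) {
    utr <- randomSeq(1, 300)
    if (k <= 50) {
      pos <- sample(50:200, 1)
      substr(utr, pos, pos + 7L) <- paste0(m8, "A")
      if (nrow(findSeedSites(mirna, utr)) > 0) recall <- recall + 1
    }
    expect_equal(nrow(findSeedSites(mirna, utr)), naiveCount(utr))
  }
  expect_equal(recall, 50L)
})

test_that("complementarity scoring weights the seed region", {
  mirna <- randomSeq(1, 22)
  perfect <- revcomp(mirna)
  expect_equal(scoreComplementarity(mirna, perfect), 145)  # 7x10 + 15x5
  # a seed mismatch costs strictly more than a 3' mismatch; the
  # substitution must be neither the complement nor the wobble partner
  mismatchAt <- function(win, mirPos) {
    p <- 22 - mirPos + 1
    mb <- substr(mirna, mirPos, mirPos)
    forbidden <- c(chartr("ACGT", "TGCA", mb),
                   if (mb == "G") "T", if (mb == "T") "G")
    substr(win, p, p) <- setdiff(c("A", "C", "G", "T"), forbidden)[1]
    win
  }
  seedMM <- mismatchAt(perfect, 4)
  tailMM <- mismatchAt(perfect, 15)
  expect_lt(scoreComplementarity(mirna, seedMM),
            scoreComplementarity(mirna, tailMM))
  expect_equal(scoreComplementarity(mirna, ""), 0)
})

test_that("duplex energies match closed forms and brute-force enumeration", {
  expect_equal(duplexEnergy(strrep("G", 22), strrep("C", 22)), -3 * 21)
  expect_equal(duplexEnergy(strrep("A", 20), strrep("A", 20)), 0)
  # brute force over monotone intermolecular pairings for short sequences
  bruteDuplex <- function(x, y, loopP = 2, maxLoop = 8) {
    xc <- strsplit(x, "")[[1]]
    zc <- rev(strsplit(y, "")[[1]])
    pe <- function(a, b) {
      if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
      if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(-2)
      if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(-1)
      NA_real_
    }
    best <- 0
    n <- length(xc); m <- length(zc)
    recurse <- function(i, k, energy, lastI, lastK) {
      if (energy < best) best <<- energy
      if (i > n || k > m) return()
      for (p in i:n) for (q in k:m) {
        if (!is.na(pe(xc[p], zc[q]))) {
          if (is.na(lastI)) {
            recurse(p + 1, q + 1, energy, p, q)
          } else {
            gap <- (p - lastI - 1) + (q - lastK - 1)
            if (gap == 0) {
              st <- 0.5 * (pe(xc[p], zc[q]) + pe(xc[lastI], zc[lastK]))
              recurse(p + 1, q + 1, energy + st, p, q)
            } else if (gap <= maxLoop) {
              recurse(p + 1, q + 1, energy + loopP, p, q)
            }
          }
        }
      }
    }
    recurse(1, 1, 0, NA, NA)
    best
  }
  set.seed(66)
  for (rep in 1:8) {
    x <- randomSeq(1, sample(6:9, 1))
    y <- randomSeq(1, sample(6:9, 1))
    expect_equal(duplexEnergy(x, y), bruteDuplex(x, y), tolerance = 1e-9,
                 label = paste(x, y))
  }
})

test_that("three-method intersection retains only unanimous pairs", {
  pm <- list(
    a = data.frame(mirna = c("m1", "m1", "m2"), gene = c("g1", "g2", "g1")),
    b = data.frame(mirna = c("m1", "m2"), gene = c("g1", "g1")),
    c = data.frame(mirna = c("m1", "m1"), gene = c("g1", "g2")))
  it <- intersectTargets(pm)
  expect_equal(nrow(it), 1L)
  expect_equal(it$mirna, "m1")
  expect_equal(it$gene, "g1")
  pm$c <- pm$c[0, ]
  expect_equal(nrow(intersectTargets(pm)), 0L)
  # a planted strong site survives the full three-method pipeline
  mirna <- c(mir1 = randomSeq(1, 22))
  utrs <- c(gHit = paste0(randomSeq(1, 100), revcomp(mirna[[1]]),
                          randomSeq(1, 100)),
            gMiss = randomSeq(1, 220))
  pred <- predictTargets(mirna, utrs)
  expect_true(any(pred$pairs$gene == "gHit"))
  key <- paste(pred$pairs$mirna, pred$pairs$gene)
  for (m in pred$perMethod)
    expect_true(all(key %in% paste(m$mirna, m$gene)))
})

test_that("the anti-correlation filter applies sign and abundance rules", {
  targets <- data.frame(mirna = c("m1", "m1", "m2", "m3"),
                        gene = c("g1", "g2", "g1", "g3"),
                        stringsAsFactors = FALSE)
  de <- data.frame(
    id = c("m1", "m2", "m3"), comparison = "E45_vs_B3",
    log2fc = c(2, -1.5, 1.2), pvalue = 0.001, fdr = 0.01,
    call = c("up", "down", "up"), stringsAsFactors = FALSE)
  mrnaFC <- data.frame(
    gene = c("g1", "g2"), comparison = "E45_vs_B3",
    log2fc = c(-1.2, 0.8), stringsAsFactors = FALSE)
  tiers <- data.frame(id = c("m1", "m2", "m3"), type = "known",
                      overallRPM = c(500, 300, 80), retained = TRUE,
                      tier = "moderate", over10k = FALSE,
                      stringsAsFactors = FALSE)
  out <- anticorrelationFilter(targets, de, mrnaFC, "E45_vs_B3", tiers)
  # m1/g1: up vs down -> kept; m1/g2: up vs up -> dropped;
  # m2/g1: down vs down -> dropped; m3: below the 100 RPM focus -> excluded
  expect_equal(nrow(out), 1L)
  expect_equal(out$mirna, "m1")
  expect_equal(out$gene, "g1")
  expect_equal(attr(out, "missingGenes"), 0L)
  # missing genes are dropped and counted
  t2 <- rbind(targets, data.frame(mirna = "m1", gene = "gX"))
  expect_equal(attr(anticorrelationFilter(t2, de, mrnaFC, "E45_vs_B3",
                                          tiers), "missingGenes"), 1L)
  # antisymmetry: flipping every mRNA sign swaps retained and dropped
  flipped <- mrnaFC
  flipped$log2fc <- -flipped$log2fc
  outF <- anticorrelationFilter(targets, de, flipped, "E45_vs_B3", tiers)
  expect_equal(sort(paste(outF$mirna, outF$gene)),
               sort(c("m1 g2", "m2 g1")))
})

test_that("enrichment p-values follow the hypergeometric law", {
  r <- enrichGeneSets(letters[1:5], letters[1:20], list(s = letters[1:5]))
  expect_equal(r$pvalue, 1 / choose(20, 5))
  r0 <- enrichGeneSets(letters[6:10], letters[1:20], list(s = letters[1:5]))
  expect_equal(r0$pvalue, 1, tolerance = 1e-12)
  # EASE decrements singleton overlaps to zero
  rE <- enrichGeneSets(letters[1], letters[1:20], list(s = letters[1:5]),
                       mode = "EASE")
  expect_gt(rE$pvalue, 0.99)
  expect_error(enrichGeneSets("a", character(0), list(s = "a")), "background")
  # Monte-Carlo agreement within 3 standard errors
  set.seed(77)
  N <- 60; K <- 15; n <- 12
  bg <- sprintf("g%02d", 1:N)
  set <- bg[1:K]
  lst <- bg[sample(N, n)]
  k <- length(intersect(lst, set))
  p <- enrichGeneSets(lst, bg, list(s = set))$pvalue
  draws <- replicate(1e5, length(intersect(sample(bg, n), set)) >= k)
  se <- sqrt(mean(draws) * (1 - mean(draws)) / 1e5)
  expect_lt(abs(p - mean(draws)), 3 * se + 1e-12)
  # BH FDR across sets is monotone
  sets <- lapply(1:8, function(i) sample(bg, 10))
  names(sets) <- paste0("s", 1:8)
  rr <- enrichGeneSets(lst, bg, sets)
  expect_true(!is.unsorted(rr$fdr[order(rr$pvalue)]))
})
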