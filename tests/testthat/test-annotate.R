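test_that("ncRNA matching is exact substring containment", {
  bundle <- smallBundle()
  nc <- as.character(bundle@ncrna)
  frag <- substr(nc[1], 11, 30)
  res <- matchNcRNA(c(frag, randomSeq(1, 20)), bundle@ncrna)
  expect_true(res$hit[1])
  expect_equal(res$name[1], names(nc)[1])
  expect_false(res$hit[2])
})

test_that("known-miRNA matching tolerates +/-2 nt templated end shifts", {
  bundle <- smallBundle()
  m <- as.data.frame(matureArms(bundle@registry, ownOnly = TRUE))
  p <- as.data.frame(precursors(bundle@registry, ownOnly = TRUE))
  i <- 3L
  pre <- p$sequence[match(m$precursorId[i], p$id)]
  mlen <- nchar(m$sequence[i])
  exact <- m$sequence[i]
  ext3 <- substr(pre, m$offset[i], m$offset[i] + mlen + 1L)   # (0, +2)
  shift3 <- substr(pre, m$offset[i] + 3L, m$offset[i] + mlen + 2L) # 5' shift +3
  res <- matchKnownMiRNA(c(exact, ext3, shift3), bundle@registry)
  expect_equal(res$matureId[1], m$id[i])
  expect_equal(c(res$off5[1], res$off3[1]), c(0L, 0L))
  expect_equal(res$matureId[2], m$id[i])
  expect_equal(c(res$off5[2], res$off3[2]), c(0L, 2L))
  expect_true(is.na(res$matureId[3]))
})

test_that("edit detection reports the substitution in mature coordinates", {
  bundle <- smallBundle()
  m <- as.data.frame(matureArms(bundle@registry, ownOnly = TRUE))
  s <- m$sequence[5]
  from <- substr(s, 10, 10)
  to <- setdiff(c("A", "C", "G", "T"), from)[1]
  edited <- s
  substr(edited, 10, 10) <- to
  res <- detectEdited(edited, bundle@registry)
  expect_equal(res$matureId, m$id[5])
  expect_equal(res$position, 10L)
  expect_equal(res$from, from)
  expect_equal(res$to, to)
  # two substitutions are beyond the edit matcher
  twice <- edited
  from2 <- substr(twice, 15, 15)
  substr(twice, 15, 15) <- setdiff(c("A", "C", "G", "T"), from2)[1]
  expect_true(is.na(detectEdited(twice, bundle@registry)$matureId))
})

test_that("homolog matching tolerates two mismatches and collapses entities", {
  bundle <- smallBundle()
  fm <- as.data.frame(matureArms(bundle@registry))
  fm <- fm[!fm$own, ]
  res <- matchHomolog(fm$sequence[1], bundle@registry)
  expect_false(is.na(res$entity[1]))
  expect_equal(res$mismatches[1], 0L)
  # entity names drop the species prefix
  expect_false(grepl("^[a-z]{3}-mir", res$entity[1]))
  # identical foreign sequences across species collapse to one entity
  dup <- fm$sequence[duplicated(fm$sequence)]
  if (length(dup)) {
    ids <- fm$id[fm$sequence == dup[1]]
    r <- matchHomolog(dup[1], bundle@registry)
    expect_equal(r$entity, sub("^[a-z]{3}-", "", sort(ids)[1]))
  }
  # three mismatches -> none
  s <- fm$sequence[2]
  for (pos in c(3, 9, 15)) {
    cur <- substr(s, pos, pos)
    substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  expect_true(is.na(matchHomolog(s, bundle@registry)$entity))
})

test_that("a 3'-extended arm recorded as a foreign entry matches as homolog", {
  bundle <- smallBundle()
  fm <- as.data.frame(matureArms(bundle@registry))
  fm <- fm[!fm$own, ]
  ownSeqs <- matureArms(bundle@registry, ownOnly = TRUE)$sequence
  add3 <- fm[vapply(fm$sequence, function(s)
    any(startsWith(s, ownSeqs) & nchar(s) > nchar(ownSeqs)), logical(1)), ]
  expect_gte(nrow(add3), 1L)
  tag <- add3$sequence[1]
  expect_true(is.na(matchKnownMiRNA(tag, bundle@registry)$matureId))
  expect_true(is.na(detectEdited(tag, bundle@registry)$matureId))
  r <- matchHomolog(tag, bundle@registry)
  expect_equal(r$mismatches, 0L)
})

test_that("tolerant matchers agree with brute-force enumeration on 500 tags", {
  bundle <- smallBundle()
  reg <- bundle@registry
  m <- as.data.frame(matureArms(reg))
  p <- as.data.frame(precursors(reg))
  own <- m[m$own, ]; pOwn <- p[p$own, ]
  fm <- m[!m$own, ]; pFor <- p[!p$own, ]
  set.seed(99)
  tags <- character(500)
  for (k in 1:500) {
    if (k <= 350) {
      # perturbed window: random arm, random offsets, 0-3 substitutions
      i <- sample(nrow(own), 1)
      pre <- pOwn$sequence[match(own$precursorId[i], pOwn$id)]
      st <- own$offset[i] + sample(-3:3, 1)
      en <- own$offset[i] + nchar(own$sequence[i]) - 1L + sample(-3:3, 1)
      st <- max(st, 1L); en <- min(en, nchar(pre))
      s <- substr(pre, st, en)
      for (q in seq_len(sample(0:3, 1))) {
        pos <- sample(nchar(s), 1)
        cur <- substr(s, pos, pos)
        substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
      tags[k] <- s
    } else {
      tags[k] <- randomSeq(1, sample(16:26, 1))
    }
  }
  tags <- tags[nchar(tags) >= 16]
  kn <- matchKnownMiRNA(tags, reg)
  ed <- detectEdited(tags, reg)
  hm <- matchHomolog(tags, reg)
  for (k in seq_along(tags)) {
    bf0 <- bruteForceMatch(tags[k], own, pOwn, 0L)
    if (is.null(bf0)) {
      expect_true(is.na(kn$matureId[k]))
    } else {
      expect_equal(kn$matureId[k], bf0$matureId)
      expect_equal(kn$off5[k], bf0$off5)
      expect_equal(kn$off3[k], bf0$off3)
    }
    bf1 <- bruteForceMatch(tags[k], own, pOwn, 1L)
    if (is.null(bf0) && !is.null(bf1)) {
      expect_equal(ed$matureId[k], bf1$matureId)
    } else if (is.null(bf1)) {
      expect_true(is.na(ed$matureId[k]))
    }
    if (nrow(fm)) {
      bf2 <- bruteForceMatch(tags[k], fm, pFor, 2L)
      if (is.null(bf2)) {
        expect_true(is.na(hm$entity[k]))
      } else {
        expect_equal(hm$mismatches[k], bf2$mismatches)
        expect_equal(abs(hm$off5[k]) + abs(hm$off3[k]), bf2$totOff)
      }
    }
  }
})

test_that("genome mapping finds all exact loci on both strands", {
  genome <- Biostrings::DNAStringSet(c(chrA = randomSeq(1, 5000)))
  g <- as.character(genome[[1]])
  tag <- substr(g, 1001, 1022)
  # plant a second copy and a minus-strand copy
  substr(g, 3001, 3022) <- tag
  substr(g, 4001, 4022) <- revcomp(tag)
  genome <- Biostrings::DNAStringSet(c(chrA = g))
  loci <- mapToGenome(tag, genome)
  expect_equal(loci$pos, c(1001L, 3001L, 4001L))
  expect_equal(loci$strand, c("+", "+", "-"))
  expect_equal(nrow(mapToGenome(strrep("ACGT", 6), genome)), 0L)
  # naive full-scan oracle on random 22-mers
  set.seed(5)
  tags <- c(randomSeq(20, 22), substr(g, 101, 122))
  loci <- mapToGenome(tags, genome)
  rcg <- revcomp(g)
  n <- nchar(g)
  for (k in seq_along(tags)) {
    fwd <- length(gregexpr(tags[k], g, fixed = TRUE)[[1]][
      gregexpr(tags[k], g, fixed = TRUE)[[1]] > 0])
    rev <- length(gregexpr(tags[k], rcg, fixed = TRUE)[[1]][
      gregexpr(tags[k], rcg, fixed = TRUE)[[1]] > 0])
    expect_equal(sum(loci$tag == k), fwd + rev)
  }
})

test_that("classification respects the priority hierarchy and partitions tags", {
  bundle <- smallBundle()
  annot <- smallAnnot()
  tags <- smallTags()
  expect_equal(sum(table(annot$category)), length(tagSequences(tags)))
  expect_false(any(is.na(annot$category)))
  # ncRNA outranks known miRNA: a mature arm planted inside an ncRNA ref
  m <- matureArms(bundle@registry, ownOnly = TRUE)
  nc <- bundle@ncrna
  ncChar <- as.character(nc)
  ncChar[1] <- paste0(substr(ncChar[1], 1, 50), m$sequence[1],
                      substr(ncChar[1], 51, nchar(ncChar[1])))
  nc2 <- Biostrings::DNAStringSet(ncChar)
  S4Vectors::mcols(nc2) <- S4Vectors::mcols(nc)
  b2 <- bundle
  b2@ncrna <- nc2
  a2 <- classifyTags(m$sequence[1], b2)
  expect_equal(a2$category, "ncRNA")
  # without the ncRNA hit the same tag is a known miRNA even though it has
  # genomic loci (known miRNA outranks the positional categories)
  a3 <- classifyTags(m$sequence[1], bundle)
  expect_equal(a3$category, "known-miRNA")
  expect_true(a3$nLoci >= 1)
  # every simulated ncRNA-pool fragment is annotated ncRNA
  ncFrag <- substr(as.character(bundle@ncrna)[3], 5, 27)
  expect_equal(classifyTags(ncFrag, bundle)$category, "ncRNA")
})

test_that("priority is monotone: lower-priority evidence never changes a category", {
  bundle <- smallBundle()
  annot <- smallAnnot()
  # known-miRNA tags keep their category whether or not they also overlap
  # repeats/exons (their loci are unrestricted)
  kn <- annot[annot$category == "known-miRNA", ]
  expect_true(all(!is.na(kn$assignedMirna)))
  expect_true(all(kn$mismatches == 0L))
  ed <- annot[annot$category == "edited-miRNA", ]
  expect_true(all(ed$mismatches == 1L))
  hm <- annot[annot$category == "homolog-miRNA", ]
  expect_true(all(hm$mismatches <= 2L))
})
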