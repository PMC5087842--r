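# Shared fixtures, built once per session and cached.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

smallConfig <- function() {
  referenceConfig(
    chromLengths = c(chr1 = 400000L, chr2 = 400000L, chr21 = 2200000L),
    nMirna = 60L, nCluster = 15L, nForeign = 12L,
    nForeignIdenticalPairs = 2L, nForeignAdd3 = 2L,
    nRepeats = 30L, nGenes = 30L, nTargetGenes = 12L, nTargetMirnas = 5L,
    nNovel = 3L, nDecoy = 3L)
}

smallBundle <- function() .cached("smallBundle", function() {
  suppressWarnings(buildReference(smallConfig(), seed = 7L))
})

smallDesign <- function() studyDesign(readsPerLibrary = 20000L)

smallTruth <- function() .cached("smallTruth", function() {
  buildTruthTable(smallBundle(), smallDesign(), seed = 7L,
                  config = smallConfig(), nDE = 15L, nEdits = 4L, nLow = 3L)
})

smallSim <- function() .cached("smallSim", function() {
  simulateLibraries(smallBundle(), smallDesign(), smallTruth(), seed = 7L)
})

smallTags <- function() .cached("smallTags", function() {
  p <- qcParams()
  ins <- lapply(smallSim()$libraries, function(l) {
    f <- filterReads(l$sequences, l$qualities, p)
    f$insert[f$keep]
  })
  collapseReads(ins)
})

smallAnnot <- function() .cached("smallAnnot", function() {
  classifyTags(smallTags(), smallBundle())
})

smallExperiment <- function() .cached("smallExperiment", function() {
  buildExpressionMatrix(smallAnnot(), smallTags(), smallDesign(),
                        smallBundle()@registry)
})

randomSeq <- function(n, len) {
  stringi::stri_rand_strings(n, len, "[ACGT]")
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", stringi::stri_reverse(x))
}

# Independent brute-force tolerant matcher: slides a tag over every
# precursor with Biostrings::neditStartingAt and applies the end-offset
# window and tie-break rules directly.
bruteForceMatch <- function(tag, matures, precursors, maxMismatch,
                            maxOffset = 2L) {
  best <- NULL
  tlen <- nchar(tag)
  tseq <- Biostrings::DNAString(tag)
  for (i in seq_len(nrow(matures))) {
    p <- precursors[match(matures$precursorId[i], precursors$id), ]
    plen <- nchar(p$sequence)
    if (tlen > plen) next
    subj <- Biostrings::DNAString(p$sequence)
    starts <- seq_len(plen - tlen + 1L)
    mm <- Biostrings::neditStartingAt(tseq, subj, starting.at = starts,
                                      with.indels = FALSE)
    mStart <- matures$offset[i]
    mEnd <- mStart + nchar(matures$sequence[i]) - 1L
    for (s in starts) {
      off5 <- s - mStart
      off3 <- (s + tlen - 1L) - mEnd
      if (abs(off5) > maxOffset || abs(off3) > maxOffset) next
      if (mm[s] > maxMismatch) next
      cand <- list(matureId = matures$id[i], mismatches = mm[s],
                   off5 = off5, off3 = off3,
                   totOff = abs(off5) + abs(off3))
      if (is.null(best) ||
          cand$mismatches < best$mismatches ||
          (cand$mismatches == best$mismatches &&
             (cand$totOff < best$totOff ||
                (cand$totOff == best$totOff &&
                   cand$matureId < best$matureId))))
        best <- cand
    }
  }
  best
}

# Exhaustive enumeration of nested secondary structures (pair sets) with
# the same energy semantics as the folding DP; the reference oracle for
# short sequences.
bruteForceFold <- function(seq, hairpinP = 3, loopP = 2, multiP = 3) {
  ch <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  n <- length(ch)
  pairE <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(-2)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(-1)
    NA_real_
  }
  canPair <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    j - i >= 4 && !is.na(pairE(ch[i], ch[j]))))
  energyOf <- function(pairs) {
    if (!nrow(pairs)) return(0)
    e <- 0
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      inner <- pairs[pairs[, 1] > i & pairs[, 2] < j, , drop = FALSE]
      # direct children: inner pairs not nested in another inner pair
      direct <- inner
      if (nrow(inner) > 1) {
        keep <- vapply(seq_len(nrow(inner)), function(q) {
          !any(inner[, 1] < inner[q, 1] & inner[, 2] > inner[q, 2])
        }, logical(1))
        direct <- inner[keep, , drop = FALSE]
      }
      if (nrow(direct) == 0) {
        e <- e + hairpinP
      } else if (nrow(direct) == 1) {
        if (direct[1, 1] == i + 1 && direct[1, 2] == j - 1) {
          e <- e + 0.5 * (pairE(ch[i], ch[j]) +
                            pairE(ch[i + 1], ch[j - 1]))
        } else {
          e <- e + loopP
        }
      } else {
        e <- e + multiP
      }
    }
    e
  }
  best <- 0
  enumerate <- function(pairs, minI) {
    e <- energyOf(pairs)
    if (e < best) best <<- e
    used <- c(pairs[, 1], pairs[, 2])
    for (i in minI:n) {
      if (i %in% used) next
      for (j in (i + 4):n) {
        if (j > n) break
        if (j %in% used || !canPair[i, j]) next
        # nesting constraint: (i,j) must not cross existing pairs
        crosses <- any((pairs[, 1] < i & pairs[, 2] > i & pairs[, 2] < j) |
                         (pairs[, 1] > i & pairs[, 1] < j & pairs[, 2] > j))
        if (crosses) next
        enumerate(rbind(pairs, c(i, j)), i + 1L)
      }
    }
  }
  if (n >= 5) enumerate(matrix(integer(0), 0, 2), 1L)
  best
}

# Independent conditional NB exact-test oracle via dnbinom enumeration.
exactTestOracle <- function(a, b, nA, nB, phi) {
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    pr <- dbinom(k, t, nA / (nA + nB))
  } else {
    mu <- 10  # arbitrary: the conditional law is mean-free
    num <- dnbinom(k, size = nA / phi, mu = nA * mu) *
      dnbinom(t - k, size = nB / phi, mu = nB * mu)
    pr <- num / sum(num)
  }
  sum(pr[pr <= pr[a + 1] * (1 + 1e-10)])
}
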