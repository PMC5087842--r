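#' Fold a candidate precursor with the simplified energy model
#'
#' Minimum-free-energy nested secondary structure by dynamic programming
#' under a stacking-only nearest-neighbor model: stacked pair energies
#' GC/CG -3.0, AU/UA -2.0, GU/UG -1.0 kcal/mol (a stacked adjacency
#' contributes the mean of its two pair energies), hairpin loops of at
#' least 3 nt, flat closure penalties for hairpin (+3), interior/bulge
#' (+2) and multibranch (+3) loops. The traceback is deterministic.
#'
#' @param sequence A/C/G/T (or U) string, 40-150 nt for candidate
#'   scoring; shorter sequences are accepted for testing.
#' @param hairpinPenalty,loopPenalty,multiPenalty,maxLoop energy model
#'   parameters (kcal/mol; `maxLoop` caps interior-loop size).
#' @return A list: `structure` (dot-bracket), `mfe` (kcal/mol, <= 0),
#'   `partner` (1-based pairing vector, 0 = unpaired).
#' @examples
#' foldHairpin(paste0(strrep("G", 20), "AAAA", strrep("C", 20)))$mfe
#' @export
foldHairpin <- function(sequence, hairpinPenalty = 3, loopPenalty = 2,
                        multiPenalty = 3, maxLoop = 30L) {
  fold_hairpin_cpp(sequence, hairpinPenalty, loopPenalty, multiPenalty,
                   as.integer(maxLoop), 3L)
}

#' Excise hairpin candidates around unannotated read stacks
#'
#' Genome-mapped loci of novel-candidate tags are merged into read
#' clusters (same chromosome and strand, gaps <= `mergeGap`); clusters
#' with at least `minReads` total reads yield two candidate precursor
#' windows (read block extended by `flank` upstream, and by `flank`
#' downstream), truncated at contig ends.
#'
#' @param loci data.frame of tag loci (`tag`, `sequence`, `chrom`, `pos`,
#'   `strand`) as attached by [classifyTags()], restricted to
#'   novel-candidate tags.
#' @param counts total read count per tag index (named or indexed by tag).
#' @param genome `DNAStringSet`.
#' @param flank precursor flank (nt).
#' @param mergeGap maximum gap between stacked reads in a cluster.
#' @param minReads minimum total reads per cluster.
#' @return A data.frame of candidate windows: `cluster`, `chrom`,
#'   `start`, `end`, `strand`, `sequence`, plus the read-stack table as
#'   `attr(x, "stacks")`.
#' @export
exciseCandidates <- function(loci, counts, genome, flank = 70L,
                             mergeGap = 30L, minReads = 5L) {
  empty <- data.frame(cluster = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(loci)) return(empty)
  loci <- loci[order(loci$chrom, loci$strand, loci$pos), , drop = FALSE]
  loci$readEnd <- loci$pos + nchar(loci$sequence) - 1L
  grp <- paste(loci$chrom, loci$strand)
  runEnd <- stats::ave(loci$readEnd, grp, FUN = cummax)
  newCl <- c(TRUE, grp[-1] != grp[-nrow(loci)] |
               loci$pos[-1] - runEnd[-nrow(loci)] - 1L > mergeGap)
  loci$cluster <- cumsum(newCl)
  chrLen <- setNames(Biostrings::width(genome), names(genome))
  tot <- rowsum(as.numeric(counts[loci$tag]), loci$cluster)
  keep <- as.integer(rownames(tot))[tot[, 1] >= minReads]
  loci <- loci[loci$cluster %in% keep, , drop = FALSE]
  rows <- list()
  for (cl in split(loci, loci$cluster)) {
    # windows are anchored on the dominant (highest-count) read of the
    # stack so that candidate precursors stay at hairpin scale even when
    # scattered reads chain into long blocks
    dom <- which.max(counts[cl$tag])
    blockStart <- cl$pos[dom]
    blockEnd <- cl$readEnd[dom]
    ch <- cl$chrom[1]
    for (win in list(c(blockStart - flank, blockEnd + 15L),
                     c(blockStart - 15L, blockEnd + flank))) {
      st <- max(win[1], 1L)
      en <- min(win[2], chrLen[[ch]])
      sq <- as.character(Biostrings::subseq(genome[[ch]], st, en))
      if (cl$strand[1] == "-") sq <- .revcomp(sq)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl$cluster[1], chrom = ch, start = st, end = en,
        strand = cl$strand[1], sequence = sq, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "stacks") <- loci
  out
}

# Dinucleotide-preserving shuffle (random Eulerian rearrangement by
# repeated adjacent-edge swaps keeping first and last base fixed).
.dinucShuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 4L) return(seq)
  # shuffle via random walk on the dinucleotide multigraph
  edges <- split(2:n, ch[1:(n - 1L)])
  edges <- lapply(edges, sample)
  out <- integer(n)
  out[1] <- 1L
  ptr <- setNames(rep(1L, length(edges)), names(edges))
  ok <- TRUE
  for (k in 2:n) {
    b <- ch[out[k - 1L]]
    i <- ptr[[b]]
    if (is.null(edges[[b]]) || i > length(edges[[b]])) { ok <- FALSE; break }
    out[k] <- edges[[b]][i]
    ptr[[b]] <- i + 1L
  }
  if (!ok) {
    # walk got stuck (non-Eulerian draw); fall back to a plain shuffle of
    # interior bases, which preserves mononucleotide composition
    mid <- sample(ch[2:(n - 1L)])
    return(paste(c(ch[1], mid, ch[n]), collapse = ""))
  }
  paste(ch[out], collapse = "")
}

#' Score a hairpin candidate and evaluate both detectors
#'
#' Detector A (score-based): composite score
#' `wDominant * (fraction of reads consistent with one dominant mature
#' arm +/-2 nt) + wStar * star-arm support + wMfe * (MFE below the
#' threshold) + wPaired * (>= 14 mature bases paired)`; pass iff the
#' score is at least 5. Detector B (rule-based): pass iff MFE < -18
#' kcal/mol, the mature arm lies fully within one stem arm, read 5'-end
#' variability is at most 4 nt and the precursor is 60-110 nt. The
#' structure-randomization p-value is the fraction of
#' dinucleotide-preserving shuffles whose MFE is at or below the
#' observed one; a call requires p < 0.05.
#'
#' @param candidates data.frame from [exciseCandidates()] (with its
#'   `stacks` attribute) or a compatible table.
#' @param counts total read count per tag index.
#' @param shuffles number of dinucleotide shuffles.
#' @param seed RNG seed for the shuffles.
#' @param minReads minimum reads inside the candidate window.
#' @param mfeThreshold MFE threshold (kcal/mol).
#' @param weights detector-A weights.
#' @param scoreThreshold detector-A pass threshold.
#' @return A data.frame per candidate: locus columns, `mature`, `star`,
#'   `mfe`, `structure`, `score`, `detectorA`, `detectorB`, `pShuffle`,
#'   `reads`.
#' @export
scoreCandidates <- function(candidates, counts, shuffles = 100L, seed = 1L,
                            minReads = 5L, mfeThreshold = -18,
                            weights = c(dominant = 3, star = 1.5,
                                        mfe = 1.5, paired = 1.5),
                            scoreThreshold = 5) {
  stacks <- attr(candidates, "stacks")
  out <- list()
  set.seed(.subSeed(seed, 7L))
  for (k in seq_len(nrow(candidates))) {
    cand <- candidates[k, ]
    n <- nchar(cand$sequence)
    if (n < 40L) next
    stack <- stacks[stacks$cluster == cand$cluster, , drop = FALSE]
    stack$count <- counts[stack$tag]
    # positions relative to the candidate window, strand-aware
    if (cand$strand == "+") {
      relStart <- stack$pos - cand$start + 1L
      relEnd <- stack$readEnd - cand$start + 1L
    } else {
      relStart <- cand$end - stack$readEnd + 1L
      relEnd <- cand$end - stack$pos + 1L
    }
    inWin <- relStart >= 1L & relEnd <= n
    if (!any(inWin)) next
    stack <- stack[inWin, , drop = FALSE]
    relStart <- relStart[inWin]
    relEnd <- relEnd[inWin]
    total <- sum(stack$count)
    if (total < minReads) next
    dom <- which.max(stack$count)
    mStart <- relStart[dom]
    mEnd <- relEnd[dom]
    consistent <- abs(relStart - mStart) <= 2L & abs(relEnd - mEnd) <= 2L
    fracDom <- sum(stack$count[consistent]) / total
    overhang <- diff(range(relStart[consistent]))

    fold <- foldHairpin(cand$sequence)
    partner <- fold$partner
    mIdx <- mStart:mEnd
    paired <- sum(partner[mIdx] > 0)
    partners <- partner[mIdx][partner[mIdx] > 0]
    oneArm <- length(partners) > 0 &&
      (all(partners > mEnd) || all(partners < mStart))
    starSupport <- FALSE
    star <- NA_character_
    if (length(partners)) {
      sRange <- range(partners)
      starHits <- !consistent &
        pmin(relEnd, sRange[2]) - pmax(relStart, sRange[1]) + 1L >=
          0.6 * (relEnd - relStart + 1L)
      starSupport <- any(starHits)
      star <- substr(cand$sequence, sRange[1], sRange[2])
    }
    mfeOk <- fold$mfe < mfeThreshold
    score <- weights[["dominant"]] * fracDom +
      weights[["star"]] * starSupport +
      weights[["mfe"]] * mfeOk +
      weights[["paired"]] * (paired >= 14L)
    detA <- score >= scoreThreshold
    detB <- mfeOk && oneArm && overhang <= 4L && n >= 60L && n <= 110L

    pShuffle <- NA_real_
    if (detA && detB) {
      shuf <- vapply(seq_len(shuffles), function(i)
        foldHairpin(.dinucShuffle(cand$sequence))$mfe, numeric(1))
      pShuffle <- mean(shuf <= fold$mfe)
    }
    out[[length(out) + 1L]] <- data.frame(
      cluster = cand$cluster, chrom = cand$chrom, start = cand$start,
      end = cand$end, strand = cand$strand, sequence = cand$sequence,
      mature = substr(cand$sequence, mStart, mEnd), star = star,
      mfe = fold$mfe, structure = fold$structure, score = score,
      detectorA = detA, detectorB = detB, pShuffle = pShuffle,
      reads = total, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(cluster = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0),
                      mature = character(0), star = character(0),
                      mfe = numeric(0), structure = character(0),
                      score = numeric(0), detectorA = logical(0),
                      detectorB = logical(0), pShuffle = numeric(0),
                      reads = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Call novel miRNAs from scored candidates
#'
#' A mature sequence is called iff some candidate passes both detectors
#' with a shuffle p-value below `pThreshold` (the two-detector
#' intersection). Candidates sharing a mature sequence collapse to one
#' mature with all precursor records; names are assigned by descending
#' total raw count.
#'
#' @param scored a data.frame from [scoreCandidates()].
#' @param pThreshold structure-randomization threshold.
#' @param prefix species prefix for names (`<prefix>-miR-new-N`).
#' @return A data.frame per called mature: `name`, `mature`,
#'   `nPrecursors`, `reads`, `mfe`, `precursors` (semicolon-joined
#'   loci).
#' @export
callNovel <- function(scored, pThreshold = 0.05, prefix = "chi") {
  pass <- scored[scored$detectorA & scored$detectorB &
                   !is.na(scored$pShuffle) & scored$pShuffle < pThreshold, ,
                 drop = FALSE]
  if (!nrow(pass)) {
    return(data.frame(name = character(0), mature = character(0),
                      nPrecursors = integer(0), reads = numeric(0),
                      mfe = numeric(0), precursors = character(0),
                      stringsAsFactors = FALSE))
  }
  # the best-scoring window per read cluster represents that locus
  pass <- pass[order(-pass$score, pass$mfe), , drop = FALSE]
  pass <- pass[!duplicated(pass$cluster), , drop = FALSE]
  sp <- split(pass, pass$mature)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(mature = g$mature[1], nPrecursors = nrow(g),
               reads = sum(g$reads), mfe = min(g$mfe),
               precursors = paste(sprintf("%s:%d-%d(%s)", g$chrom, g$start,
                                          g$end, g$strand), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$reads, out$mature), , drop = FALSE]
  out$name <- sprintf("%s-miR-new-%d", prefix, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("name", "mature", "nPrecursors", "reads", "mfe", "precursors")]
}

#' Novel miRNA discovery from an annotation run
#'
#' Convenience wrapper: excises candidates from novel-candidate tags,
#' scores them against both detectors and intersects the calls.
#'
#' @param annot annotation data.frame from [classifyTags()] (with its
#'   `loci` attribute).
#' @param tags the matching [TagSet].
#' @param genome `DNAStringSet`.
#' @param flank,mergeGap,minReads see [exciseCandidates()].
#' @param shuffles,seed see [scoreCandidates()].
#' @param prefix species prefix for names.
#' @return A list: `candidates`, `scored`, `calls`.
#' @export
findNovelMiRNAs <- function(annot, tags, genome, flank = 70L,
                            mergeGap = 30L, minReads = 5L,
                            shuffles = 100L, seed = 1L, prefix = "chi") {
  loci <- attr(annot, "loci")
  novIdx <- which(annot$category == "novel-candidate")
  loci <- loci[loci$tag %in% novIdx, , drop = FALSE]
  counts <- rowSums(tagCounts(tags))
  cands <- exciseCandidates(loci, counts, genome, flank, mergeGap, minReads)
  scored <- scoreCandidates(cands, counts, shuffles, seed, minReads)
  calls <- callNovel(scored, prefix = prefix)
  list(candidates = cands, scored = scored, calls = calls)
}
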