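#' Simulate small-RNA sequencing libraries with planted truths
#'
#' Emits single-end reads for every library of the design. Each read is
#' `(optional 5'-adapter) + insert + 3'-adapter + padding`, truncated to
#' the read length, with Phred+33 qualities (high-quality baseline, Phred
#' 35-40). Inserts are drawn by a multinomial over the truth table's
#' per-library proportions: mature-arm isomiRs (templated end offsets) and
#' planted edits, homolog entities, ncRNA fragments, repeat/exon and
#' intergenic background fragments, novel hairpin arms, decoy-locus reads,
#' and the rejection classes (adapter dimers, planted low-quality reads
#' with two sub-Phred-20 bases, poly(A) inserts, 5'-adapter contamination
#' and N-containing reads).
#'
#' @param bundle a [ReferenceBundle].
#' @param design a [StudyDesign].
#' @param truth a [TruthTable] built for this bundle and design.
#' @param seed integer master seed; per-library seeds are derived
#'   deterministically from it by library index.
#' @param outdir optional directory; when given, gzipped FASTQ files and
#'   the truth tables are written there.
#' @return Invisibly, a list with `libraries` (per-library list of
#'   `sequences` and `qualities` character vectors), `classCounts` (read
#'   class x library matrix of emitted reads) and `libNames`.
#' @export
simulateLibraries <- function(bundle, design, truth, seed = 1L,
                              outdir = NULL) {
  libs <- libraryNames(design)
  N <- design@readsPerLibrary
  rl <- design@readLength
  adapter3 <- design@adapter3
  adapter5 <- design@adapter5
  pad <- strrep("A", rl)

  mat <- as.data.frame(matureArms(bundle@registry))
  own <- mat[mat$own, , drop = FALSE]
  pre <- as.data.frame(precursors(bundle@registry))
  preSeqOf <- setNames(pre$sequence, pre$id)
  ent <- .homologEntities(bundle@registry)
  ncSeq <- as.character(bundle@ncrna)
  genomeChar <- as.character(bundle@genome)
  feat <- as.data.frame(bundle@features)
  repInt <- feat[feat$class == "repeat", , drop = FALSE]
  exInt <- feat[feat$class == "exon", , drop = FALSE]
  novel <- truth@novel
  decoy <- bundle@planted[bundle@planted$kind == "decoy", , drop = FALSE]
  fr <- truth@fractions
  p5 <- truth@isomir$p5
  p3 <- truth@isomir$p3
  edits <- truth@edits
  editedSeq <- setNames(
    .substituteAt(own$sequence[match(edits$matureId, own$id)],
                  edits$position, edits$to),
    edits$matureId)
  rateOf <- setNames(rep(0, nrow(own)), own$id)
  rateOf[edits$matureId] <- edits$rate

  # intergenic background sampling avoids every planted locus so that the
  # per-miRNA binomial recovery bounds stay exact
  avoid <- GenomicRanges::GRanges(
    c(pre$chrom[pre$own], bundle@planted$chrom[bundle@planted$kind != "target"]),
    IRanges::IRanges(
      c(pmax(pre$start[pre$own] - 3L, 1L),
        bundle@planted$start[bundle@planted$kind != "target"]),
      c(pre$end[pre$own] + 3L,
        bundle@planted$end[bundle@planted$kind != "target"])))
  chrLen <- setNames(Biostrings::width(bundle@genome), names(bundle@genome))

  ownIds <- own$id
  unitNames <- c(ownIds, ent$name)
  classNames <- c("ncrna", "repeat", "exon", "novel", "decoy", "background",
                  "adapterDimer", "lowQuality", "polyA", "adapter5", "nBases")
  libraries <- vector("list", length(libs))
  names(libraries) <- libs
  classCounts <- matrix(0L, length(classNames) + 2L, length(libs),
                        dimnames = list(c("mirna", "homolog", classNames), libs))

  .extractGenome <- function(chrom, st, en, strand) {
    s <- stri_sub(genomeChar[chrom], st, en)
    rc <- strand == "-"
    s[rc] <- .revcomp(s[rc])
    s
  }

  for (li in seq_along(libs)) {
    set.seed(.subSeed(seed, 100L + li))
    if (N == 0L) {
      warning(sprintf("library %s: 0 reads requested, emitting empty library",
                      libs[li]))
      libraries[[li]] <- list(sequences = character(0), qualities = character(0))
      next
    }
    probs <- c(truth@proportions[unitNames, li],
               fr["ncrna"],
               fr["repeat"], fr["exon"],
               fr["novel"] * novel$readShare,
               fr["decoy"] * rep(1 / max(nrow(decoy), 1L), nrow(decoy)),
               fr["background"], fr["adapterDimer"], fr["lowQuality"],
               fr["polyA"], fr["adapter5"], fr["nBases"])
    cnt <- as.vector(rmultinom(1L, N, probs))
    nUnits <- length(unitNames)
    iNc <- nUnits + 1L
    iRep <- iNc + 1L; iEx <- iRep + 1L
    iNov <- iEx + seq_len(nrow(novel))
    iDec <- iEx + nrow(novel) + seq_len(nrow(decoy))
    iAfter <- iEx + nrow(novel) + nrow(decoy)
    iBg <- iAfter + 1L; iDim <- iAfter + 2L; iLow <- iAfter + 3L
    iPa <- iAfter + 4L; iA5 <- iAfter + 5L; iN <- iAfter + 6L

    parts <- list(); labs <- character(0)
    add <- function(seqs, lab) {
      if (!length(seqs)) return(invisible())
      parts[[length(parts) + 1L]] <<- seqs
      labs[length(labs) + 1L] <<- lab
      invisible()
    }

    # own miRNAs: isomiR offsets, planted edits
    for (u in seq_len(nrow(own))) {
      n <- cnt[u]
      if (n == 0L) next
      id <- ownIds[u]
      nEdit <- if (rateOf[id] > 0) rbinom(1L, n, rateOf[id]) else 0L
      out <- character(n)
      if (nEdit > 0L) out[seq_len(nEdit)] <- editedSeq[id]
      nIso <- n - nEdit
      if (nIso > 0L) {
        preS <- preSeqOf[own$precursorId[u]]
        o5 <- sample(c(-2L, -1L, 0L, 1L, 2L), nIso, TRUE, prob = p5)
        o3 <- sample(c(-2L, -1L, 0L, 1L, 2L), nIso, TRUE, prob = p3)
        st <- own$offset[u] + o5
        en <- own$offset[u] + nchar(own$sequence[u]) - 1L + o3
        out[(nEdit + 1L):n] <- stri_sub(preS, st, en)
      }
      add(out, "mirna")
    }
    # homolog entities
    for (h in seq_len(nrow(ent))) {
      n <- cnt[nrow(own) + h]
      if (n > 0L) add(rep(ent$sequence[h], n), "homolog")
    }
    # ncRNA fragments
    n <- cnt[iNc]
    if (n > 0L) {
      idx <- sample.int(length(ncSeq), n, TRUE)
      len <- sample(18:30, n, TRUE)
      len <- pmin(len, nchar(ncSeq)[idx])
      st <- floor(runif(n) * (nchar(ncSeq)[idx] - len + 1L)) + 1L
      add(stri_sub(ncSeq[idx], st, st + len - 1L), "ncrna")
    }
    # repeat / exon fragments
    for (pair in list(list(iRep, repInt, "repeat"), list(iEx, exInt, "exon"))) {
      n <- cnt[pair[[1]]]
      if (n == 0L) next
      iv <- pair[[2]]
      j <- sample.int(nrow(iv), n, TRUE, prob = iv$width)
      len <- sample(18:28, n, TRUE)
      st <- iv$start[j] + floor(runif(n) * pmax(iv$width[j] - len, 1L))
      strand <- sample(c("+", "-"), n, TRUE)
      add(.extractGenome(as.character(iv$seqnames[j]), st,
                         st + len - 1L, strand), pair[[3]])
    }
    # novel hairpin arms (93% mature with +/-1 offsets, 7% star)
    for (v in seq_len(nrow(novel))) {
      n <- cnt[iNov[v]]
      if (n == 0L) next
      hp <- novel[v, ]
      mOff <- as.integer(regexpr(hp$matureSeq, hp$precursorSeq, fixed = TRUE))
      sOff <- as.integer(regexpr(hp$starSeq, hp$precursorSeq, fixed = TRUE))
      isStar <- runif(n) < 0.07
      o5 <- sample(c(-1L, 0L, 1L), n, TRUE, prob = c(0.15, 0.7, 0.15))
      o3 <- sample(c(-1L, 0L, 1L), n, TRUE, prob = c(0.15, 0.7, 0.15))
      st <- ifelse(isStar, sOff, mOff + o5)
      en <- ifelse(isStar, sOff + nchar(hp$starSeq) - 1L,
                   mOff + nchar(hp$matureSeq) - 1L + o3)
      add(stri_sub(hp$precursorSeq, st, en), "novel")
    }
    # decoy loci: scattered stacks, no hairpin signal
    for (dk in seq_len(nrow(decoy))) {
      n <- cnt[iDec[dk]]
      if (n == 0L) next
      len <- sample(20:26, n, TRUE)
      st <- decoy$start[dk] + floor(runif(n) * (decoy$end[dk] - decoy$start[dk] - len))
      add(.extractGenome(rep(decoy$chrom[dk], n), st, st + len - 1L,
                         rep("+", n)), "decoy")
    }
    # intergenic background
    n <- cnt[iBg]
    if (n > 0L) {
      got <- character(0)
      while (length(got) < n) {
        m <- ceiling((n - length(got)) * 1.3) + 10L
        chrom <- sample(names(chrLen), m, TRUE, prob = chrLen)
        len <- sample(18:28, m, TRUE)
        st <- floor(runif(m) * (chrLen[chrom] - len)) + 1L
        gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, st + len - 1L))
        free <- GenomicRanges::countOverlaps(gr, avoid) == 0L
        strand <- sample(c("+", "-"), m, TRUE)
        got <- c(got, .extractGenome(chrom[free], st[free],
                                     st[free] + len[free] - 1L, strand[free]))
      }
      add(got[seq_len(n)], "background")
    }
    # rejection classes
    if (cnt[iDim] > 0L) add(rep("", cnt[iDim]), "adapterDimer")
    if (cnt[iLow] > 0L)
      add(own$sequence[sample.int(nrow(own), cnt[iLow], TRUE)], "lowQuality")
    n <- cnt[iPa]
    if (n > 0L) {
      s <- rep(strrep("A", 22L), n)
      sub1 <- which(runif(n) < 0.5)
      if (length(sub1)) {
        posn <- sample.int(22L, length(sub1), TRUE)
        s[sub1] <- .substituteAt(s[sub1], posn,
                                 sample(c("C", "G", "T"), length(sub1), TRUE))
      }
      add(s, "polyA")
    }
    if (cnt[iA5] > 0L)
      add(own$sequence[sample.int(nrow(own), cnt[iA5], TRUE)], "adapter5")
    n <- cnt[iN]
    if (n > 0L) {
      s <- own$sequence[sample.int(nrow(own), n, TRUE)]
      s <- .substituteAt(s, sample(2:8, n, TRUE), "N")
      s <- .substituteAt(s, sample(10:16, n, TRUE), "N")
      add(s, "nBases")
    }

    inserts <- unlist(parts, use.names = FALSE)
    clsLab <- rep(labs, lengths(parts))

    prefix <- ifelse(clsLab == "adapter5", adapter5, "")
    reads <- stri_sub(paste0(prefix, inserts, adapter3, pad), 1L, rl)
    perm <- sample.int(length(reads))
    reads <- reads[perm]
    clsLab <- clsLab[perm]
    quals <- stri_rand_strings(length(reads), rl, "[D-I]")
    lowIdx <- which(clsLab == "lowQuality")
    if (length(lowIdx)) {
      pA <- sample(3:20, length(lowIdx), TRUE)
      pB <- sample(25:45, length(lowIdx), TRUE)
      stri_sub(quals[lowIdx], pA, pA) <- "#"
      stri_sub(quals[lowIdx], pB, pB) <- "#"
    }
    tb <- table(factor(clsLab, levels = rownames(classCounts)))
    classCounts[, li] <- as.integer(tb)
    libraries[[li]] <- list(sequences = reads, qualities = quals)
  }

  res <- list(libraries = libraries, classCounts = classCounts,
              libNames = libs)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (li in seq_along(libs)) {
      writeFastq(libraries[[li]]$sequences, libraries[[li]]$qualities,
                 file.path(outdir, paste0(libs[li], ".fastq.gz")),
                 idPrefix = libs[li])
    }
    writeTruthTable(truth, outdir)
  }
  invisible(res)
}
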