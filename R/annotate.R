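#' @importFrom data.table data.table rbindlist setorder setorderv := .N
NULL

# Exact-window dictionary for known-miRNA matching: every +/-2 nt end-shift
# window of every own-species mature arm, deduplicated with the tie-break
# (smaller |off5| + |off3|, then lexicographic mature id).
.knownDict <- function(registry, maxOffset = 2L) {
  m <- as.data.frame(matureArms(registry, ownOnly = TRUE))
  p <- as.data.frame(precursors(registry, ownOnly = TRUE))
  w <- .armWindows(m, p, maxOffset)
  dt <- data.table::as.data.table(w)
  dt[, totOff := abs(off5) + abs(off3)]
  setorderv(dt, c("seq", "totOff", "matureId"))
  unique(dt, by = "seq")
}

# Single-mismatch variant dictionary for edit/SNP detection, built from the
# exact windows; collisions with exact windows are removed.
.editDict <- function(registry, maxOffset = 2L) {
  exact <- .knownDict(registry, maxOffset)
  m <- as.data.frame(matureArms(registry, ownOnly = TRUE))
  p <- as.data.frame(precursors(registry, ownOnly = TRUE))
  w <- data.table::as.data.table(.armWindows(m, p, maxOffset))
  parts <- list()
  maxLen <- max(nchar(w$seq))
  for (pos in seq_len(maxLen)) {
    sub <- w[nchar(seq) >= pos]
    if (!nrow(sub)) next
    orig <- substr(sub$seq, pos, pos)
    for (b in BASES) {
      keep <- orig != b
      if (!any(keep)) next
      v <- sub[keep]
      parts[[length(parts) + 1L]] <- data.table::data.table(
        seq = .substituteAt(v$seq, pos, b), matureId = v$matureId,
        off5 = v$off5, off3 = v$off3,
        position = pos + v$off5, from = orig[keep], to = b)
    }
  }
  dt <- rbindlist(parts)
  dt <- dt[!seq %in% exact$seq]
  dt[, totOff := abs(off5) + abs(off3)]
  setorderv(dt, c("seq", "totOff", "matureId", "position"))
  unique(dt, by = "seq")
}

# Split tag indices by width, dropping tags with non-ACGT symbols (which
# can never match an unambiguous reference exactly).
.cleanWidthGroups <- function(tags) {
  ok <- which(!stri_detect_regex(tags, "[^ACGT]"))
  split(ok, nchar(tags[ok]))
}

#' Match tags against the ncRNA contaminant set
#'
#' A tag hits if and only if it is an exact substring of any ncRNA
#' reference sequence (sense orientation).
#'
#' @param tags character vector of tag sequences.
#' @param ncrna a `DNAStringSet` with `mcols()$class` / `mcols()$db`, as
#'   in a [ReferenceBundle].
#' @return A data.frame aligned with `tags`: `hit`, `name`, `class`, `db`.
#' @export
matchNcRNA <- function(tags, ncrna) {
  out <- data.frame(hit = logical(length(tags)), name = NA_character_,
                    class = NA_character_, db = NA_character_,
                    stringsAsFactors = FALSE)
  if (!length(tags) || !length(ncrna)) return(out)
  groups <- .cleanWidthGroups(tags)
  # GenBank-style classes are searched before Rfam-style classes
  ord <- order(S4Vectors::mcols(ncrna)$db != "genbank")
  nc <- ncrna[ord]
  for (idx in groups) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(tags[idx])))
    for (j in seq_along(nc)) {
      hits <- Biostrings::vwhichPDict(pd, nc[j])[[1]]
      hits <- idx[unique(hits)]
      newHits <- hits[!out$hit[hits]]
      if (length(newHits)) {
        out$hit[newHits] <- TRUE
        out$name[newHits] <- names(nc)[j]
        out$class[newHits] <- S4Vectors::mcols(nc)$class[j]
        out$db[newHits] <- S4Vectors::mcols(nc)$db[j]
      }
    }
  }
  out
}

#' Match tags to known miRNAs with end-shift tolerance
#'
#' A tag is a known-miRNA hit iff it aligns inside an own-species
#' precursor with zero mismatches and both ends within +/-2 nt of the
#' annotated mature-arm ends. Ties are broken by smaller
#' `|off5| + |off3|`, then lexicographic mature id.
#'
#' @param tags character vector of tag sequences.
#' @param registry a [MiRNARegistry].
#' @param maxOffset end-shift window (nt).
#' @return A data.frame aligned with `tags`: `matureId`, `off5`, `off3`
#'   (NA when unmatched).
#' @export
matchKnownMiRNA <- function(tags, registry, maxOffset = 2L) {
  dict <- .knownDict(registry, maxOffset)
  q <- data.table::data.table(seq = tags, ord = seq_along(tags))
  hit <- dict[q, on = "seq"]
  setorder(hit, ord)
  data.frame(matureId = hit$matureId, off5 = hit$off5, off3 = hit$off3,
             stringsAsFactors = FALSE)
}

#' Detect single-base edited / SNP variants of known miRNAs
#'
#' A tag is an edited hit iff it aligns as in [matchKnownMiRNA()] but with
#' exactly one mismatch. The mismatch position is reported in mature-arm
#' coordinates (position 1 = annotated mature 5' end; positions outside
#' `1..length` lie in the templated end extension).
#'
#' @inheritParams matchKnownMiRNA
#' @return A data.frame aligned with `tags`: `matureId`, `off5`, `off3`,
#'   `position`, `from`, `to`.
#' @export
detectEdited <- function(tags, registry, maxOffset = 2L) {
  dict <- .editDict(registry, maxOffset)
  q <- data.table::data.table(seq = tags, ord = seq_along(tags))
  hit <- dict[q, on = "seq"]
  setorder(hit, ord)
  data.frame(matureId = hit$matureId, off5 = hit$off5, off3 = hit$off3,
             position = hit$position, from = hit$from, to = hit$to,
             stringsAsFactors = FALSE)
}

#' Match tags to foreign-species miRNA homologs
#'
#' A tag is a homolog hit iff it aligns to a foreign-species mature arm
#' with at most `maxMismatch` mismatches and both ends within +/-2 nt
#' (end shifts templated on the foreign precursor). The best hit has the
#' fewest mismatches, then the smallest total |offset|, then the
#' lexicographically smallest mature id. Foreign arms with identical
#' mature sequences collapse to one homolog entity, reported without the
#' species prefix.
#'
#' @inheritParams matchKnownMiRNA
#' @param maxMismatch mismatch tolerance.
#' @return A data.frame aligned with `tags`: `entity`, `matureId`,
#'   `mismatches`, `off5`, `off3`.
#' @export
matchHomolog <- function(tags, registry, maxMismatch = 2L, maxOffset = 2L) {
  out <- data.frame(entity = rep(NA_character_, length(tags)),
                    matureId = NA_character_, mismatches = NA_integer_,
                    off5 = NA_integer_, off3 = NA_integer_,
                    stringsAsFactors = FALSE)
  m <- as.data.frame(matureArms(registry))
  fm <- m[!m$own, , drop = FALSE]
  if (!nrow(fm) || !length(tags)) return(out)
  p <- as.data.frame(precursors(registry))
  fp <- p[!p$own, , drop = FALSE]
  ent <- .homologEntities(registry)
  entOf <- setNames(rep(ent$name, lengths(strsplit(ent$memberIds, ","))),
                    unlist(strsplit(ent$memberIds, ",")))
  w <- .armWindows(fm, fp, maxOffset)
  w$totOff <- abs(w$off5) + abs(w$off3)
  w <- w[order(w$totOff, w$matureId), , drop = FALSE]
  groups <- .cleanWidthGroups(tags)
  for (idx in groups) {
    width <- nchar(tags[idx[1]])
    ww <- w[nchar(w$seq) == width, , drop = FALSE]
    if (!nrow(ww)) next
    tagMat <- matrix(unlist(strsplit(tags[idx], "", fixed = TRUE),
                            use.names = FALSE), nrow = width)
    bestMM <- rep(maxMismatch + 1L, length(idx))
    bestJ <- rep(NA_integer_, length(idx))
    for (j in seq_len(nrow(ww))) {
      ref <- strsplit(ww$seq[j], "", fixed = TRUE)[[1]]
      mm <- colSums(tagMat != ref)
      # windows are pre-sorted by (totOff, matureId), so strictly fewer
      # mismatches is the only way to displace an earlier hit
      upd <- which(mm <= maxMismatch & mm < bestMM)
      if (length(upd)) {
        bestMM[upd] <- mm[upd]
        bestJ[upd] <- j
      }
    }
    got <- which(!is.na(bestJ))
    if (length(got)) {
      j <- bestJ[got]
      gi <- idx[got]
      out$entity[gi] <- unname(entOf[ww$matureId[j]])
      out$matureId[gi] <- ww$matureId[j]
      out$mismatches[gi] <- bestMM[got]
      out$off5[gi] <- ww$off5[j]
      out$off3[gi] <- ww$off3[j]
    }
  }
  out
}

#' Map tags to exact genomic loci
#'
#' All exact full-length occurrences on both strands, in deterministic
#' (chrom, pos, strand) order.
#'
#' @param tags character vector of tag sequences.
#' @param genome a `DNAStringSet` of chromosomes.
#' @return A data.frame with `tag` (index into `tags`), `sequence`,
#'   `chrom`, `pos` (1-based start on the plus strand) and `strand`.
#' @export
mapToGenome <- function(tags, genome) {
  empty <- data.frame(tag = integer(0), sequence = character(0),
                      chrom = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (!length(tags)) return(empty)
  groups <- .cleanWidthGroups(tags)
  rows <- list()
  for (idx in groups) {
    fwd <- Biostrings::DNAStringSet(unname(tags[idx]))
    rev <- Biostrings::reverseComplement(fwd)
    for (strand in c("+", "-")) {
      pd <- Biostrings::PDict(if (strand == "+") fwd else rev)
      for (ch in names(genome)) {
        mi <- Biostrings::matchPDict(pd, genome[[ch]])
        starts <- Biostrings::startIndex(mi)
        nhit <- lengths(starts)
        if (!sum(nhit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          tag = rep(idx, nhit),
          chrom = ch,
          pos = unlist(starts, use.names = FALSE),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$sequence <- tags[out$tag]
  out <- out[order(out$tag, out$chrom, out$pos, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("tag", "sequence", "chrom", "pos", "strand")]
}

#' Classify every tag into exactly one annotation category
#'
#' Applies the priority hierarchy: ncRNA (GenBank-style before
#' Rfam-style) > known miRNA (including single-mismatch edited variants)
#' > cross-species homolog > repeat > exon > novel-miRNA candidate >
#' intron > unannotated. Feature overlap requires at least one exact
#' genomic locus intersecting the feature interval; gene regions are
#' approximated by per-gene exon spans extended by `geneFlank`.
#' Novel-miRNA candidates are genome-mapped tags free of any feature or
#' gene-region overlap; they feed hairpin excision.
#'
#' @param tags a [TagSet] or character vector of tag sequences.
#' @param bundle a [ReferenceBundle].
#' @param geneFlank flank (bp) around each gene's exon span used for the
#'   intron category.
#' @return A data.frame with one row per tag: `sequence`, `category`,
#'   `assignedMirna` (mature id or homolog entity), `homologOf`, `off5`,
#'   `off3`, `mismatches`, `editPosition`, `editFrom`, `editTo`, `nLoci`,
#'   `mapped`. The genomic loci table is attached as
#'   `attr(x, "loci")`.
#' @export
classifyTags <- function(tags, bundle, geneFlank = 2000L) {
  seqs <- if (is(tags, "TagSet")) tagSequences(tags) else tags
  n <- length(seqs)
  cat <- rep(NA_character_, n)
  out <- data.frame(
    sequence = seqs, category = NA_character_,
    assignedMirna = NA_character_, homologOf = NA_character_,
    off5 = NA_integer_, off3 = NA_integer_, mismatches = NA_integer_,
    editPosition = NA_integer_, editFrom = NA_character_,
    editTo = NA_character_, nLoci = 0L, mapped = FALSE,
    stringsAsFactors = FALSE)

  nc <- matchNcRNA(seqs, bundle@ncrna)
  cat[nc$hit] <- "ncRNA"

  open <- which(is.na(cat))
  if (length(open)) {
    kn <- matchKnownMiRNA(seqs[open], bundle@registry)
    hit <- which(!is.na(kn$matureId))
    i <- open[hit]
    cat[i] <- "known-miRNA"
    out$assignedMirna[i] <- kn$matureId[hit]
    out$off5[i] <- kn$off5[hit]
    out$off3[i] <- kn$off3[hit]
    out$mismatches[i] <- 0L
  }
  open <- which(is.na(cat))
  if (length(open)) {
    ed <- detectEdited(seqs[open], bundle@registry)
    hit <- which(!is.na(ed$matureId))
    i <- open[hit]
    cat[i] <- "edited-miRNA"
    out$assignedMirna[i] <- ed$matureId[hit]
    out$off5[i] <- ed$off5[hit]
    out$off3[i] <- ed$off3[hit]
    out$mismatches[i] <- 1L
    out$editPosition[i] <- ed$position[hit]
    out$editFrom[i] <- ed$from[hit]
    out$editTo[i] <- ed$to[hit]
  }
  open <- which(is.na(cat))
  if (length(open)) {
    hm <- matchHomolog(seqs[open], bundle@registry)
    hit <- which(!is.na(hm$entity))
    i <- open[hit]
    cat[i] <- "homolog-miRNA"
    out$assignedMirna[i] <- hm$entity[hit]
    out$homologOf[i] <- hm$matureId[hit]
    out$off5[i] <- hm$off5[hit]
    out$off3[i] <- hm$off3[hit]
    out$mismatches[i] <- hm$mismatches[hit]
  }

  loci <- mapToGenome(seqs, bundle@genome)
  nl <- tabulate(loci$tag, nbins = n)
  out$nLoci <- nl
  out$mapped <- nl > 0L

  open <- which(is.na(cat))
  if (length(open) && nrow(loci)) {
    sub <- loci[loci$tag %in% open, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      sub$chrom,
      IRanges::IRanges(sub$pos, sub$pos + nchar(sub$sequence) - 1L))
    feat <- bundle@features
    cls <- S4Vectors::mcols(feat)$class
    ovRepeat <- GenomicRanges::countOverlaps(
      gr, feat[cls == "repeat"], ignore.strand = TRUE) > 0L
    ovExon <- GenomicRanges::countOverlaps(
      gr, feat[cls == "exon"], ignore.strand = TRUE) > 0L
    ex <- feat[cls == "exon"]
    genes <- S4Vectors::split(ex, S4Vectors::mcols(ex)$gene)
    geneSpan <- unlist(range(genes, ignore.strand = TRUE))
    geneSpan <- GenomicRanges::resize(geneSpan,
                                      GenomicRanges::width(geneSpan) + 2L * geneFlank,
                                      fix = "center")
    ovGene <- GenomicRanges::countOverlaps(gr, geneSpan,
                                           ignore.strand = TRUE) > 0L
    hasRep <- tapply(ovRepeat, sub$tag, any)
    hasEx <- tapply(ovExon, sub$tag, any)
    hasGene <- tapply(ovGene, sub$tag, any)
    ids <- as.integer(names(hasRep))
    tagCat <- ifelse(hasRep, "repeat",
                     ifelse(hasEx, "exon",
                            ifelse(!hasGene, "novel-candidate", "intron")))
    cat[ids] <- tagCat
  }
  cat[is.na(cat)] <- "unannotated"
  out$category <- cat
  attr(out, "loci") <- loci
  out
}

#' Category counts of an annotation run
#'
#' @param annot a data.frame from [classifyTags()].
#' @param tags the matching [TagSet] (for read-weighted counts).
#' @return A data.frame per category: distinct tags, total reads, and
#'   per-library read counts.
#' @export
categorySummary <- function(annot, tags) {
  cnt <- tagCounts(tags)
  cats <- c("ncRNA", "known-miRNA", "edited-miRNA", "homolog-miRNA",
            "repeat", "exon", "novel-candidate", "intron", "unannotated")
  rows <- lapply(cats, function(cc) {
    i <- annot$category == cc
    lib <- colSums(cnt[i, , drop = FALSE])
    cbind(data.frame(category = cc, tags = sum(i),
                     reads = sum(cnt[i, , drop = FALSE]),
                     stringsAsFactors = FALSE),
          as.data.frame(t(lib)))
  })
  do.call(rbind, rows)
}
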