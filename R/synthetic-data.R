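#' Generator configuration for the synthetic reference bundle
#'
#' Returns the default parameters of the synthetic reference generator. The
#' defaults emulate the study design the pipeline targets: ~300 own-species
#' miRNA genes of which 50 form a dense cluster inside a 1 Mb window of one
#' chromosome (a DLK1-DIO3-like locus), a foreign-species homolog section,
#' ncRNA contaminants, repeat and exon annotation, 3'UTRs with planted
#' target sites, plantable novel hairpins and decoy read loci.
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param clusterChrom,clusterStart,clusterSpan location of the planted
#'   miRNA cluster; all cluster genes fall within
#'   `[clusterStart, clusterStart + clusterSpan]`.
#' @param nMirna total own-species precursors, including `nCluster`.
#' @param nCluster cluster member count.
#' @param secondArmFrac fraction of non-cluster precursors carrying both a
#'   -5p and a -3p arm.
#' @param nForeign foreign-species homolog donors (each derived from an
#'   own-species mature arm by exactly two substitutions).
#' @param nForeignIdenticalPairs foreign donors duplicated under a second
#'   species id with an identical sequence (collapsed to one homolog entity
#'   downstream).
#' @param nForeignAdd3 foreign entries built as an own-species mature arm
#'   plus three non-templated 3' bases (3'-modification-style homologs).
#' @param foreignSpecies species prefixes to draw foreign ids from.
#' @param ncrnaCounts named counts of contaminant classes.
#' @param nRepeats,repeatWidth repeat annotation intervals.
#' @param nGenes,exonsPerGene,exonWidth,intronWidth,geneFlank exon/gene
#'   model used for the feature annotation (gene region = exon span plus
#'   `geneFlank` when classifying intronic tags).
#' @param utrWidth 3'UTR length range; `nTargetGenes` UTRs receive a
#'   planted perfect-complement target site.
#' @param nTargetMirnas miRNAs designated as target-site owners (these are
#'   guaranteed a >100 RPM differential-expression truth).
#' @param nGeneSets,geneSetSize gene-set (GMT) model.
#' @param nNovel planted novel hairpins; the first one is planted at two
#'   genomic copies. `novelLoop`/`novelFlank` size the hairpin loop and the
#'   flanks around the duplex arms.
#' @param nDecoy,decoyWidth decoy loci that receive scattered reads with no
#'   hairpin signal.
#' @param matureLength,precursorLength sampling ranges (nt).
#' @param speciesPrefix own-species id prefix.
#' @param stages stage labels used for the mRNA fold-change table.
#' @return A named list of generator parameters.
#' @export
referenceConfig <- function(
    chromLengths = c(chr1 = 4000000L, chr2 = 4000000L, chr3 = 4000000L,
                     chr4 = 4000000L, chr5 = 4000000L, chr21 = 3200000L),
    clusterChrom = "chr21", clusterStart = 1000000L, clusterSpan = 1000000L,
    nMirna = 300L, nCluster = 50L, secondArmFrac = 0.15,
    nForeign = 60L, nForeignIdenticalPairs = 3L, nForeignAdd3 = 2L,
    foreignSpecies = c("mmu", "hsa", "bta", "ssc", "oar"),
    ncrnaCounts = c(rRNA = 3L, tRNA = 12L, snRNA = 5L, snoRNA = 6L),
    nRepeats = 120L, repeatWidth = c(200L, 1500L),
    nGenes = 120L, exonsPerGene = c(2L, 4L), exonWidth = c(150L, 400L),
    intronWidth = c(300L, 1500L), geneFlank = 2000L,
    utrWidth = c(300L, 600L), nTargetGenes = 40L, nTargetMirnas = 12L,
    nGeneSets = 12L, geneSetSize = c(8L, 25L),
    nNovel = 10L, novelLoop = 10L, novelFlank = 8L,
    nDecoy = 6L, decoyWidth = 250L,
    matureLength = c(20L, 24L), precursorLength = c(70L, 90L),
    speciesPrefix = "chi",
    stages = c("E45", "E60", "E105", "B3")) {
  cfg <- as.list(environment())
  if (cfg$nCluster > cfg$nMirna)
    stop("nCluster cannot exceed nMirna")
  cfg
}

#' Study design constructor
#'
#' @param stages ordered stage labels (temporal order).
#' @param replicates libraries per stage.
#' @param readsPerLibrary raw single-end reads simulated per library.
#' @param adapter3,adapter5 adapter sequences.
#' @param readLength read length (nt).
#' @return A [StudyDesign] object.
#' @examples
#' design <- studyDesign(readsPerLibrary = 1000L)
#' libraryNames(design)
#' @export
studyDesign <- function(stages = c("E45", "E60", "E105", "B3"),
                        replicates = 2L, readsPerLibrary = 200000L,
                        adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                        adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                        readLength = 50L) {
  new("StudyDesign", stages = stages, replicates = as.integer(replicates),
      readsPerLibrary = as.integer(readsPerLibrary),
      adapter3 = adapter3, adapter5 = adapter5,
      readLength = as.integer(readLength))
}

# Interval allocator: rejection-samples non-overlapping loci.
.allocLoci <- function(occ, chromLengths, widths, chrom = NULL,
                       gap = 60L, maxTries = 5000L) {
  n <- length(widths)
  out <- data.frame(chrom = character(n), start = integer(n),
                    end = integer(n), stringsAsFactors = FALSE)
  chrNames <- names(chromLengths)
  for (k in seq_len(n)) {
    w <- widths[k]
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      cn <- if (is.null(chrom)) {
        sample(chrNames, 1L, prob = chromLengths)
      } else chrom
      if (chromLengths[[cn]] < w + 2L * gap)
        stop(sprintf("chromosome %s (%d bp) too short to host a %d bp feature",
                     cn, chromLengths[[cn]], w))
      st <- sample.int(chromLengths[[cn]] - w - gap, 1L) + gap %/% 2L
      cand <- GenomicRanges::GRanges(cn, IRanges::IRanges(st - gap, st + w - 1L + gap))
      if (length(occ) == 0L ||
          length(suppressWarnings(
            GenomicRanges::findOverlaps(cand, occ))) == 0L) {
        out$chrom[k] <- cn; out$start[k] <- st; out$end[k] <- st + w - 1L
        occ <- suppressWarnings(
          c(occ, GenomicRanges::GRanges(cn, IRanges::IRanges(st, st + w - 1L))))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place a %d bp feature: genome too crowded (deficit on %s)",
                   w, if (is.null(chrom)) "all chromosomes" else chrom))
  }
  list(loci = out, occupied = occ)
}

# Write a sequence (plus-strand representation) into a chromosome string.
.plantSequence <- function(genome, chrom, start, seq, strand) {
  if (strand == "-") seq <- .revcomp(seq)
  stri_sub(genome[[chrom]], start, start + nchar(seq) - 1L) <- seq
  genome
}

#' Build a synthetic reference bundle
#'
#' Generates a deterministic, self-consistent reference set: genome, miRNA
#' registry (own-species precursors with genomic coordinates plus
#' foreign-species homolog donors), ncRNA contaminants, repeat/exon
#' annotation, 3'UTRs with planted target sites, gene sets and an mRNA
#' fold-change table. Novel hairpins and decoy loci are planted into the
#' genome and recorded in the bundle's `planted` table.
#'
#' Foreign homolog donors are constructed from own-species mature arms by
#' exactly two substitutions (verified to stay at Hamming distance >= 2
#' from every own-species precursor window, so they are recovered as
#' homologs and not as edited miRNAs), or as an own-species arm plus three
#' non-templated 3' bases.
#'
#' @param config a list from [referenceConfig()].
#' @param seed integer seed; identical `(config, seed)` give byte-identical
#'   output.
#' @return A [ReferenceBundle].
#' @examples
#' cfg <- referenceConfig(nMirna = 30L, nCluster = 12L, nForeign = 6L,
#'                        nRepeats = 20L, nGenes = 20L, nNovel = 2L,
#'                        chromLengths = c(chr1 = 300000L, chr21 = 2200000L))
#' bundle <- buildReference(cfg, seed = 7L)
#' bundle
#' @export
buildReference <- function(config = referenceConfig(), seed = 1L) {
  set.seed(.subSeed(seed, 1L))
  cfg <- config
  chrLen <- cfg$chromLengths
  if (cfg$clusterStart + cfg$clusterSpan > chrLen[[cfg$clusterChrom]])
    stop(sprintf("cluster chromosome %s too short: needs %d bp, has %d bp",
                 cfg$clusterChrom, cfg$clusterStart + cfg$clusterSpan,
                 chrLen[[cfg$clusterChrom]]))

  genome <- lapply(chrLen, .randChromosome)

  occ <- GenomicRanges::GRanges()
  nOwn <- cfg$nMirna
  plen <- sample(cfg$precursorLength[1]:cfg$precursorLength[2], nOwn, TRUE)

  # Cluster members sit on a jittered grid so that adjacent gaps stay well
  # below typical cluster-detection windows for every seed.
  nC <- cfg$nCluster
  step <- floor((cfg$clusterSpan - 30000) / max(nC, 1L))
  cstart <- as.integer(cfg$clusterStart + (seq_len(nC) - 1L) * step +
                       sample.int(max(step %/% 3L, 1L), nC, TRUE))
  cl <- data.frame(chrom = cfg$clusterChrom, start = cstart,
                   end = cstart + plen[seq_len(nC)] - 1L)
  occ <- c(occ, GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(cl$start, cl$end)))

  scatterChroms <- setdiff(names(chrLen), cfg$clusterChrom)
  al <- .allocLoci(occ, chrLen[scatterChroms], plen[(nC + 1L):nOwn])
  occ <- al$occupied
  preLoci <- rbind(cl, al$loci)
  preLoci$strand <- sample(c("+", "-"), nOwn, TRUE)

  # precursor + mature arm sequences ------------------------------------
  px <- cfg$speciesPrefix
  preId <- sprintf("%s-mir-%d", px, seq_len(nOwn))
  preSeq <- stri_rand_strings(nOwn, plen, "[ACGT]")
  mat <- list()
  arm1 <- sample(c("5p", "3p"), nOwn, TRUE)
  secondArm <- rep(FALSE, nOwn)
  idx2 <- which(seq_len(nOwn) > nC)
  secondArm[sample(idx2, round(cfg$secondArmFrac * length(idx2)))] <- TRUE
  # mature lengths peak at 22 nt, the canonical miRNA length
  lenRange <- cfg$matureLength[1]:cfg$matureLength[2]
  lenWeight <- stats::dnorm(lenRange, 22, 1.2)
  for (i in seq_len(nOwn)) {
    arms <- if (secondArm[i]) c("5p", "3p") else arm1[i]
    for (a in arms) {
      mlen <- sample(lenRange, 1L, prob = lenWeight)
      off <- if (a == "5p") sample(4:8, 1L)
             else plen[i] - mlen - sample(3:7, 1L) + 1L
      mat[[length(mat) + 1L]] <- data.frame(
        id = sprintf("%s-miR-%d-%s", px, i, a),
        sequence = substr(preSeq[i], off, off + mlen - 1L),
        precursorId = preId[i], offset = off,
        species = px, own = TRUE, stringsAsFactors = FALSE)
    }
  }
  matures <- do.call(rbind, mat)

  for (i in seq_len(nOwn))
    genome <- .plantSequence(genome, preLoci$chrom[i], preLoci$start[i],
                             preSeq[i], preLoci$strand[i])

  precursorsDF <- data.frame(
    id = preId, sequence = preSeq, chrom = preLoci$chrom,
    start = preLoci$start, end = preLoci$end, strand = preLoci$strand,
    species = px, own = TRUE, stringsAsFactors = FALSE)

  # foreign homolog section ----------------------------------------------
  win <- .armWindows(matures, precursorsDF)
  ownWindows <- split(win$seq, nchar(win$seq))
  .minHammingToOwn <- function(s) {
    w <- ownWindows[[as.character(nchar(s))]]
    if (is.null(w) || !length(w)) return(Inf)
    min(.hammingToRef(w, s))
  }

  fPre <- list(); fMat <- list()
  donors <- matures[sample(nrow(matures), cfg$nForeign), , drop = FALSE]
  fk <- 0L
  for (d in seq_len(cfg$nForeign)) {
    mseq <- donors$sequence[d]
    pre <- precursorsDF[match(donors$precursorId[d], preId), ]
    repeat {
      pos <- sample(nchar(mseq), 2L)
      fs <- mseq
      for (p in pos) {
        cur <- substr(fs, p, p)
        substr(fs, p, p) <- sample(setdiff(BASES, cur), 1L)
      }
      if (.minHammingToOwn(fs) >= 2) break
    }
    fk <- fk + 1L
    fpSeq <- pre$sequence
    substr(fpSeq, donors$offset[d], donors$offset[d] + nchar(fs) - 1L) <- fs
    armSuffix <- sub(".*-", "", donors$id[d])
    nSpecies <- if (d <= cfg$nForeignIdenticalPairs) 2L else 1L
    spp <- sample(cfg$foreignSpecies, nSpecies)
    for (sp in spp) {
      fPre[[length(fPre) + 1L]] <- data.frame(
        id = sprintf("%s-mir-h%d", sp, fk), sequence = fpSeq,
        chrom = NA_character_, start = NA_integer_, end = NA_integer_,
        strand = NA_character_, species = sp, own = FALSE,
        stringsAsFactors = FALSE)
      fMat[[length(fMat) + 1L]] <- data.frame(
        id = sprintf("%s-miR-h%d-%s", sp, fk, armSuffix), sequence = fs,
        precursorId = sprintf("%s-mir-h%d", sp, fk),
        offset = donors$offset[d], species = sp, own = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  # 3'-addition style homolog entries (own mature + 3 non-templated bases)
  addPool <- matures[nchar(matures$sequence) <= 22L, , drop = FALSE]
  addDonors <- addPool[sample(nrow(addPool), cfg$nForeignAdd3), , drop = FALSE]
  for (d in seq_len(nrow(addDonors))) {
    pre <- precursorsDF[match(addDonors$precursorId[d], preId), ]
    mEnd <- addDonors$offset[d] + nchar(addDonors$sequence[d]) - 1L
    templated <- substr(pre$sequence, mEnd + 1L, mEnd + 3L)
    repeat {
      add3 <- .randSeq(1L, 3L)
      if (add3 != templated) break
    }
    fs <- paste0(addDonors$sequence[d], add3)
    fk <- fk + 1L
    fpSeq <- paste0(substr(pre$sequence, 1L, mEnd), add3,
                    substr(pre$sequence, mEnd + 1L, nchar(pre$sequence)))
    sp <- sample(cfg$foreignSpecies, 1L)
    armSuffix <- sub(".*-", "", addDonors$id[d])
    fPre[[length(fPre) + 1L]] <- data.frame(
      id = sprintf("%s-mir-h%d", sp, fk), sequence = fpSeq,
      chrom = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_character_, species = sp, own = FALSE,
      stringsAsFactors = FALSE)
    fMat[[length(fMat) + 1L]] <- data.frame(
      id = sprintf("%s-miR-h%d-%s", sp, fk, armSuffix), sequence = fs,
      precursorId = sprintf("%s-mir-h%d", sp, fk),
      offset = addDonors$offset[d], species = sp, own = FALSE,
      stringsAsFactors = FALSE)
  }
  if (cfg$nForeign + cfg$nForeignAdd3 > 0L) {
    precursorsDF <- rbind(precursorsDF, do.call(rbind, fPre))
    matures <- rbind(matures, do.call(rbind, fMat))
  }

  registry <- new("MiRNARegistry",
                  precursors = S4Vectors::DataFrame(precursorsDF),
                  matures = S4Vectors::DataFrame(matures))

  # ncRNA contaminants ----------------------------------------------------
  lenModel <- list(rRNA = c(800L, 1600L), tRNA = c(70L, 90L),
                   snRNA = c(120L, 200L), snoRNA = c(80L, 150L))
  ncl <- list()
  for (cls in names(cfg$ncrnaCounts)) {
    k <- cfg$ncrnaCounts[[cls]]
    if (k == 0L) next
    lens <- sample(lenModel[[cls]][1]:lenModel[[cls]][2], k, TRUE)
    ncl[[cls]] <- data.frame(
      name = sprintf("%s-%d", cls, seq_len(k)),
      sequence = vapply(lens, function(w) .randSeq(1L, w), character(1)),
      class = cls,
      db = ifelse(cls %in% c("rRNA", "tRNA"), "genbank", "rfam"),
      stringsAsFactors = FALSE)
  }
  ncdf <- do.call(rbind, ncl)
  ncrna <- Biostrings::DNAStringSet(setNames(ncdf$sequence, ncdf$name))
  S4Vectors::mcols(ncrna)$class <- ncdf$class
  S4Vectors::mcols(ncrna)$db <- ncdf$db

  # repeats and genes ------------------------------------------------------
  rw <- sample(cfg$repeatWidth[1]:cfg$repeatWidth[2], cfg$nRepeats, TRUE)
  al <- .allocLoci(occ, chrLen, rw)
  occ <- al$occupied
  feat <- data.frame(chrom = al$loci$chrom, start = al$loci$start,
                     end = al$loci$end, strand = "+", class = "repeat",
                     gene = NA_character_, stringsAsFactors = FALSE)
  geneIds <- sprintf("g%03d", seq_len(cfg$nGenes))
  exonRows <- list()
  for (g in seq_len(cfg$nGenes)) {
    nEx <- sample(cfg$exonsPerGene[1]:cfg$exonsPerGene[2], 1L)
    ew <- sample(cfg$exonWidth[1]:cfg$exonWidth[2], nEx, TRUE)
    iw <- if (nEx > 1L) sample(cfg$intronWidth[1]:cfg$intronWidth[2], nEx - 1L, TRUE) else integer(0)
    span <- sum(ew) + sum(iw)
    al <- .allocLoci(occ, chrLen, span)
    occ <- al$occupied
    st <- al$loci$start[1]
    strand <- sample(c("+", "-"), 1L)
    pos <- st
    for (e in seq_len(nEx)) {
      exonRows[[length(exonRows) + 1L]] <- data.frame(
        chrom = al$loci$chrom[1], start = pos, end = pos + ew[e] - 1L,
        strand = strand, class = "exon", gene = geneIds[g],
        stringsAsFactors = FALSE)
      pos <- pos + ew[e] + if (e < nEx) iw[e] else 0L
    }
  }
  feat <- rbind(feat, do.call(rbind, exonRows))
  features <- GenomicRanges::GRanges(
    feat$chrom, IRanges::IRanges(feat$start, feat$end), strand = feat$strand)
  S4Vectors::mcols(features)$class <- feat$class
  S4Vectors::mcols(features)$gene <- feat$gene

  # planted novel hairpins and decoy loci ----------------------------------
  planted <- list()
  novelSeqs <- list()
  for (k in seq_len(cfg$nNovel)) {
    mlen <- sample(21:22, 1L)
    mseq <- .randSeq(1L, mlen)
    # imperfect stem: three interior substitutions keep the duplex strong
    # (~18 of 22 pairs) while making the two arms distinct sequences, as
    # in real hairpins
    star <- .revcomp(mseq)
    for (pos in sample(seq(4L, mlen - 3L), 3L)) {
      cur <- substr(star, pos, pos)
      substr(star, pos, pos) <- sample(setdiff(BASES, cur), 1L)
    }
    loop <- .randSeq(1L, cfg$novelLoop)
    # complementary lower stem: the flanks pair with each other, extending
    # the duplex below the mature/star arms as in genuine pri-miRNAs
    fl5 <- .randSeq(1L, cfg$novelFlank)
    fl3 <- .revcomp(fl5)
    pre <- paste0(fl5, mseq, loop, star, fl3)
    novelSeqs[[k]] <- list(mature = mseq, star = star, pre = pre,
                           matureOff = cfg$novelFlank + 1L,
                           starOff = cfg$novelFlank + mlen + cfg$novelLoop + 1L)
  }
  nLoci <- cfg$nNovel + 1L  # hairpin 1 planted twice
  widths <- vapply(c(1L, seq_len(cfg$nNovel)), function(k)
    nchar(novelSeqs[[k]]$pre), integer(1))
  # planted novel/decoy loci keep clear of gene flanks so their reads are
  # intergenic, not intronic
  al <- .allocLoci(occ, chrLen[scatterChroms], widths,
                   gap = cfg$geneFlank + 200L)
  occ <- al$occupied
  hpIdx <- c(1L, seq_len(cfg$nNovel))
  for (j in seq_len(nLoci)) {
    k <- hpIdx[j]
    hp <- novelSeqs[[k]]
    genome <- .plantSequence(genome, al$loci$chrom[j], al$loci$start[j],
                             hp$pre, "+")
    planted[[length(planted) + 1L]] <- data.frame(
      kind = "novel", name = sprintf("novel-%d", k),
      chrom = al$loci$chrom[j], start = al$loci$start[j],
      end = al$loci$end[j], strand = "+",
      matureSeq = hp$mature, starSeq = hp$star, precursorSeq = hp$pre,
      gene = NA_character_, matureId = NA_character_,
      direction = NA_integer_, transition = NA_integer_,
      stringsAsFactors = FALSE)
  }
  al <- .allocLoci(occ, chrLen, rep(cfg$decoyWidth, cfg$nDecoy),
                   gap = cfg$geneFlank + 200L)
  occ <- al$occupied
  for (j in seq_len(cfg$nDecoy)) {
    planted[[length(planted) + 1L]] <- data.frame(
      kind = "decoy", name = sprintf("decoy-%d", j),
      chrom = al$loci$chrom[j], start = al$loci$start[j],
      end = al$loci$end[j], strand = "+",
      matureSeq = NA_character_, starSeq = NA_character_,
      precursorSeq = NA_character_, gene = NA_character_,
      matureId = NA_character_, direction = NA_integer_,
      transition = NA_integer_, stringsAsFactors = FALSE)
  }

  # 3'UTRs, planted target sites, gene sets, mRNA fold changes -------------
  uw <- sample(cfg$utrWidth[1]:cfg$utrWidth[2], cfg$nGenes, TRUE)
  utrSeq <- vapply(uw, function(w) .randSeq(1L, w), character(1))
  ownMat <- matures[matures$own, , drop = FALSE]
  nonCluster <- ownMat[!(ownMat$precursorId %in% preId[seq_len(nC)]) &
                         nchar(ownMat$sequence) >= 21L, , drop = FALSE]
  nTM <- min(cfg$nTargetMirnas, nrow(nonCluster))
  nTG <- min(cfg$nTargetGenes, cfg$nGenes)
  tm <- sample(nrow(nonCluster), nTM)
  targetMirnas <- nonCluster$id[tm]
  targetDir <- sample(rep(c(-1L, 1L), length.out = nTM))
  targetTrans <- sample.int(length(cfg$stages) - 1L, nTM, TRUE)
  targetGenes <- sample(geneIds, nTG)
  geneOwner <- sample(seq_len(nTM), nTG, TRUE)
  for (j in seq_len(nTG)) {
    g <- match(targetGenes[j], geneIds)
    mseq <- ownMat$sequence[match(targetMirnas[geneOwner[j]], ownMat$id)]
    site <- .revcomp(mseq)
    pos <- sample(seq(20L, uw[g] - nchar(site) - 20L), 1L)
    substr(utrSeq[g], pos, pos + nchar(site) - 1L) <- site
    planted[[length(planted) + 1L]] <- data.frame(
      kind = "target", name = sprintf("site-%d", j),
      chrom = NA_character_, start = pos, end = pos + nchar(site) - 1L,
      strand = NA_character_, matureSeq = mseq, starSeq = NA_character_,
      precursorSeq = NA_character_, gene = targetGenes[j],
      matureId = targetMirnas[geneOwner[j]],
      direction = targetDir[geneOwner[j]],
      transition = targetTrans[geneOwner[j]], stringsAsFactors = FALSE)
  }
  utrs <- Biostrings::DNAStringSet(setNames(utrSeq, geneIds))

  gs <- list()
  setSizes <- pmin(sample(cfg$geneSetSize[1]:cfg$geneSetSize[2],
                          cfg$nGeneSets, TRUE), cfg$nGenes)
  nCore <- min(length(targetGenes), max(setSizes[1] - 4L, 4L))
  gs[["target_program"]] <- unique(c(sample(targetGenes, nCore),
                                     sample(geneIds, 4L)))
  for (s in 2:cfg$nGeneSets)
    gs[[sprintf("set_%02d", s)]] <- sample(geneIds, setSizes[s])

  comps <- .comparisonLabels(cfg$stages)
  mfc <- expand.grid(gene = geneIds, comparison = comps,
                     stringsAsFactors = FALSE)
  mfc$log2fc <- round(stats::rnorm(nrow(mfc), 0, 0.8), 3)
  # targeted genes respond opposite to their miRNA in the comparisons the
  # miRNA changes in; a quarter are planted with the same sign to exercise
  # the anti-correlation filter.
  sameSign <- runif(nTG) < 0.25
  for (j in seq_len(nTG)) {
    t0 <- targetTrans[geneOwner[j]]
    dir <- targetDir[geneOwner[j]]
    stagesL <- cfg$stages
    for (a in seq_len(t0)) for (b in (t0 + 1L):length(stagesL)) {
      lab <- sprintf("%s_vs_%s", stagesL[a], stagesL[b])
      sgn <- if (sameSign[j]) dir else -dir
      mfc$log2fc[mfc$gene == targetGenes[j] & mfc$comparison == lab] <-
        round(sgn * runif(1L, 0.8, 2.5), 3)
    }
  }

  genomeSet <- Biostrings::DNAStringSet(unlist(genome))
  new("ReferenceBundle", genome = genomeSet, registry = registry,
      ncrna = ncrna, features = features, utrs = utrs, geneSets = gs,
      mrnaFC = mfc, planted = do.call(rbind, planted))
}

.comparisonLabels <- function(stages) {
  n <- length(stages)
  out <- character(0)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    out <- c(out, sprintf("%s_vs_%s", stages[a], stages[b]))
  out
}

# All (off5, off3) end-shift windows of every mature arm inside its
# precursor, vectorized; the backbone of the tolerant matchers.
.armWindows <- function(matures, precursors, maxOffset = 2L) {
  pidx <- match(matures$precursorId, precursors$id)
  off <- expand.grid(off5 = -maxOffset:maxOffset, off3 = -maxOffset:maxOffset)
  k <- nrow(off)
  n <- nrow(matures)
  i <- rep(seq_len(n), each = k)
  o5 <- rep(off$off5, n)
  o3 <- rep(off$off3, n)
  pre <- precursors$sequence[pidx][i]
  st <- matures$offset[i] + o5
  en <- matures$offset[i] + nchar(matures$sequence)[i] - 1L + o3
  ok <- st >= 1L & en <= nchar(pre) & (en - st + 1L) >= 16L
  data.frame(seq = stri_sub(pre[ok], st[ok], en[ok]),
             matureId = matures$id[i][ok], off5 = o5[ok], off3 = o3[ok],
             stringsAsFactors = FALSE)
}
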