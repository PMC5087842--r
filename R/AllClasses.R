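#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MiRNARegistry: precursor and mature-arm reference
#'
#' Container for a miRBase-like reference of miRNA precursors and their
#' mature -5p/-3p arms, split into an own-species section (with genomic
#' coordinates) and a foreign-species section used for homolog matching.
#'
#' @slot precursors [S4Vectors::DataFrame] with columns `id`, `sequence`,
#'   `chrom`, `start`, `end`, `strand`, `species`, `own`. Coordinates are
#'   1-based inclusive; foreign precursors carry `NA` coordinates.
#' @slot matures [S4Vectors::DataFrame] with columns `id` (carrying a
#'   -5p/-3p suffix), `sequence`, `precursorId`, `offset` (1-based start of
#'   the mature arm within its precursor), `species`, `own`.
#'
#' @export
setClass("MiRNARegistry",
  representation(precursors = "DataFrame", matures = "DataFrame"))

setValidity("MiRNARegistry", function(object) {
  p <- object@precursors
  m <- object@matures
  need_p <- c("id", "sequence", "chrom", "start", "end", "strand", "species", "own")
  need_m <- c("id", "sequence", "precursorId", "offset", "species", "own")
  if (!all(need_p %in% colnames(p))) return("precursor columns incomplete")
  if (!all(need_m %in% colnames(m))) return("mature columns incomplete")
  if (anyDuplicated(p$id)) return("duplicated precursor ids")
  idx <- match(m$precursorId, p$id)
  if (anyNA(idx)) return("mature arm references unknown precursor")
  wid <- nchar(m$sequence)
  if (any(wid < 19L | wid > 25L)) return("mature arm length outside 19-25 nt")
  sub <- substr(p$sequence[idx], m$offset, m$offset + wid - 1L)
  if (!all(sub == m$sequence))
    return("mature arm does not equal its precursor substring at the stated offset")
  TRUE
})

#' ReferenceBundle: self-consistent toy reference set
#'
#' Bundles every reference input of the pipeline: genome, miRNA registry,
#' non-coding RNA contaminants, repeat/exon feature annotation, 3'UTRs,
#' gene sets and an mRNA fold-change table.
#'
#' @slot genome [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot registry [MiRNARegistry].
#' @slot ncrna [Biostrings::DNAStringSet]; `mcols(ncrna)$class` holds the
#'   contaminant class (rRNA/tRNA/snRNA/snoRNA) and `mcols(ncrna)$db` the
#'   database style tier ("genbank" or "rfam").
#' @slot features [GenomicRanges::GRanges] with `mcols()$class` in
#'   `repeat`/`exon`; gene regions are approximated downstream from exon
#'   spans plus a flank.
#' @slot utrs [Biostrings::DNAStringSet] of 3'UTRs named by gene id.
#' @slot geneSets named `list` of character vectors of gene ids.
#' @slot mrnaFC `data.frame` with columns `gene`, `comparison`, `log2fc`.
#' @slot planted generator bookkeeping `data.frame`: loci and sequences of
#'   planted novel hairpins and decoy read loci, plus the designated target
#'   miRNA/gene pairs, consumed when the matching [TruthTable] is built.
#'
#' @export
setClass("ReferenceBundle",
  representation(genome = "DNAStringSet", registry = "MiRNARegistry",
                 ncrna = "DNAStringSet", features = "GRanges",
                 utrs = "DNAStringSet", geneSets = "list",
                 mrnaFC = "data.frame", planted = "data.frame"))

setValidity("ReferenceBundle", function(object) {
  p <- object@registry@precursors
  own <- p[p$own, , drop = FALSE]
  if (nrow(own)) {
    chrlen <- Biostrings::width(object@genome)
    names(chrlen) <- names(object@genome)
    if (!all(own$chrom %in% names(chrlen)))
      return("registry chromosome not present in genome")
    if (any(own$start < 1L) || any(own$end > chrlen[own$chrom]))
      return("registry coordinates outside genome bounds")
    gseq <- as.character(Biostrings::subseq(
      object@genome[own$chrom], start = own$start, end = own$end))
    minus <- own$strand == "-"
    if (any(minus))
      gseq[minus] <- .revcomp(gseq[minus])
    if (!all(gseq == own$sequence))
      return("precursor sequence does not match its genomic substring")
  }
  TRUE
})

#' StudyDesign: stages, replication and read model
#'
#' @slot stages ordered character vector of stage labels.
#' @slot replicates integer, libraries per stage.
#' @slot readsPerLibrary integer.
#' @slot adapter3,adapter5 adapter sequences ligated during library prep.
#' @slot readLength integer, single-end read length in nt.
#'
#' @export
setClass("StudyDesign",
  representation(stages = "character", replicates = "integer",
                 readsPerLibrary = "integer", adapter3 = "character",
                 adapter5 = "character", readLength = "integer"))

setValidity("StudyDesign", function(object) {
  if (length(object@stages) < 2L) return("need at least two stages")
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (object@readLength < 20L) return("read length too short for the read model")
  TRUE
})

#' TruthTable: planted parameters of the synthetic generator
#'
#' Holds every planted truth of a simulation run and is the oracle for
#' recovery testing: per-stage expected abundances, per-library expected
#' read proportions (after replicate-level biological noise), the isomiR
#' offset distributions, planted editing events, planted differential
#' expression, planted novel hairpins, and contaminant class fractions.
#'
#' @slot stageRPM numeric matrix, miRNA x stage, expected RPM (per million
#'   genome-mapped reads).
#' @slot proportions numeric matrix, miRNA x library: expected proportion of
#'   the library's raw reads attributable to the miRNA (isomiRs and edits
#'   included), the reference for binomial recovery bounds.
#' @slot isomir list with named probability vectors `p5` and `p3` over
#'   offsets -2..2.
#' @slot edits data.frame: `matureId`, `position` (mature coordinates),
#'   `from`, `to`, `rate`.
#' @slot de data.frame of planted differential expression:
#'   `matureId`, `comparison`, `log2fc` (|log2fc| >= 1).
#' @slot novel data.frame of planted hairpins: `name`, `chrom`, `start`,
#'   `end`, `strand`, `matureSeq`, `starSeq`, `precursorSeq`, `readShare`.
#' @slot fractions named numeric read-class fractions, summing to 1.
#' @slot mappedFraction per-library expected fraction of raw reads that map
#'   to the genome (the RPM denominator model).
#' @slot sentinel id of the constant high-abundance control miRNA.
#'
#' @export
setClass("TruthTable",
  representation(stageRPM = "matrix", proportions = "matrix",
                 isomir = "list", edits = "data.frame", de = "data.frame",
                 novel = "data.frame", fractions = "numeric",
                 mappedFraction = "numeric", sentinel = "character"))

setValidity("TruthTable", function(object) {
  for (nm in c("p5", "p3")) {
    p <- object@isomir[[nm]]
    if (is.null(p)) return(sprintf("missing isomiR distribution '%s'", nm))
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
      return(sprintf("isomiR distribution '%s' is not a probability vector", nm))
  }
  if (nrow(object@de) && any(abs(object@de$log2fc) < 1))
    return("planted DE log2 fold change magnitude below 1")
  if (length(object@fractions) &&
      abs(sum(object@fractions) - 1) > 1e-8)
    return("read-class fractions do not sum to 1")
  if (any(object@proportions < 0)) return("negative expected proportion")
  TRUE
})

#' TagSet: collapsed unique read tags with per-library counts
#'
#' @slot sequences character vector of distinct trimmed inserts.
#' @slot counts integer matrix, tags x libraries.
#'
#' @export
setClass("TagSet",
  representation(sequences = "character", counts = "matrix"))

setValidity("TagSet", function(object) {
  if (length(object@sequences) != nrow(object@counts))
    return("sequence/count length mismatch")
  if (anyDuplicated(object@sequences)) return("duplicated tag sequence")
  if (any(object@counts < 0)) return("negative tag count")
  if (length(object@sequences) && any(rowSums(object@counts) < 1))
    return("tag with zero total count")
  TRUE
})

#' MiRNAExperiment: miRNA x library expression container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the raw
#' count and RPM assays for known miRNAs, homolog entities and novel
#' miRNAs. `colData()` records the library label, stage and the per-library
#' mapped-read denominator used for RPM; `rowData()` records the row type
#' (`known`, `homolog`, `novel`) and genomic coordinates where available.
#'
#' @export
setClass("MiRNAExperiment", contains = "SummarizedExperiment")

setValidity("MiRNAExperiment", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "rpm") %in% a))
    return("assays 'counts' and 'rpm' are required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("stage", "mappedReads") %in% colnames(cd)))
    return("colData must contain 'stage' and 'mappedReads'")
  if (any(cd$mappedReads <= 0)) return("mapped-read denominators must be > 0")
  cnt <- SummarizedExperiment::assay(object, "counts")
  rpm <- SummarizedExperiment::assay(object, "rpm")
  expect <- sweep(cnt, 2, 1e6 / cd$mappedReads, "*")
  if (nrow(cnt) && max(abs(rpm - expect)) > 1e-6)
    return("rpm assay inconsistent with counts and mapped-read denominators")
  TRUE
})
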