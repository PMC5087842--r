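#' Read and write pipeline files
#'
#' Thin wrappers around Biostrings / rtracklayer / data.table for the
#' standard formats the pipeline consumes and emits: gzipped FASTQ
#' (Phred+33), FASTA, GFF3 (1-based inclusive, strand-aware), GMT gene
#' sets and TSV tables.
#'
#' @param sequences,qualities character vectors of equal length.
#' @param path file path; `.gz` suffix triggers compression for FASTQ.
#' @param idPrefix read-id prefix for written FASTQ.
#' @return `readFastq()` returns a list with `sequences` and `qualities`;
#'   the writers return the path invisibly.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeFastq <- function(sequences, qualities, path, idPrefix = "read") {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- sprintf("%s_%d", idPrefix, seq_along(sequences))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qualities),
    compress = endsWith(path, ".gz"))
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(sequences = as.character(x),
       qualities = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a reference bundle to standard files
#'
#' Emits genome FASTA, precursor/mature FASTA plus a GFF3 of own-species
#' precursor coordinates, ncRNA FASTA, feature GFF3, 3'UTR FASTA, GMT
#' gene sets and the mRNA fold-change TSV.
#'
#' @param bundle a [ReferenceBundle].
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writeReferenceBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle@genome, file.path(dir, "genome.fa"))
  p <- as.data.frame(precursors(bundle@registry))
  m <- as.data.frame(matureArms(bundle@registry))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(p$sequence, p$id)),
    file.path(dir, "precursors.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(m$sequence, m$id)),
    file.path(dir, "matures.fa"))
  own <- p[p$own, , drop = FALSE]
  gr <- GenomicRanges::GRanges(own$chrom,
                               IRanges::IRanges(own$start, own$end),
                               strand = own$strand)
  S4Vectors::mcols(gr)$type <- "miRNA_primary_transcript"
  S4Vectors::mcols(gr)$ID <- own$id
  rtracklayer::export(gr, file.path(dir, "registry.gff3"), format = "gff3")
  Biostrings::writeXStringSet(bundle@ncrna, file.path(dir, "ncrna.fa"))
  fg <- bundle@features
  S4Vectors::mcols(fg)$type <- S4Vectors::mcols(fg)$class
  rtracklayer::export(fg, file.path(dir, "features.gff3"), format = "gff3")
  Biostrings::writeXStringSet(bundle@utrs, file.path(dir, "utrs.fa"))
  writeGmt(bundle@geneSets, file.path(dir, "gene_sets.gmt"))
  data.table::fwrite(bundle@mrnaFC, file.path(dir, "mrna_fc.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname pipeline-io
#' @param geneSets named list of character vectors.
#' @export
writeGmt <- function(geneSets, path) {
  lines <- vapply(names(geneSets), function(nm)
    paste(c(nm, "synthetic", geneSets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[`, character(1), 1L))
}

#' Write the truth tables of a simulation run
#'
#' @param truth a [TruthTable].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
writeTruthTable <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  fw(data.frame(id = rownames(truth@stageRPM), truth@stageRPM,
                check.names = FALSE), "truth_stage_rpm.tsv")
  fw(data.frame(id = rownames(truth@proportions), truth@proportions,
                check.names = FALSE), "truth_proportions.tsv")
  fw(truth@edits, "truth_edits.tsv")
  fw(truth@de, "truth_de.tsv")
  fw(truth@novel, "truth_novel.tsv")
  fw(data.frame(class = names(truth@fractions),
                fraction = unname(truth@fractions)), "truth_fractions.tsv")
  invisible(dir)
}
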