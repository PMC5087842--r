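#' @include AllClasses.R
NULL

#' Accessors for pipeline containers
#'
#' Small accessor family for the package's S4 containers: the registry's
#' precursor and mature tables, the tag sequences and counts of a
#' [TagSet], and the RPM assay / mapped-read denominators of a
#' [MiRNAExperiment].
#'
#' @param x an object of the documented class.
#' @param ownOnly logical; restrict registry tables to the own-species
#'   section.
#' @return A `DataFrame`, matrix or vector as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("precursors", function(x, ownOnly = FALSE) standardGeneric("precursors"))

#' @rdname accessors
#' @export
setGeneric("matureArms", function(x, ownOnly = FALSE) standardGeneric("matureArms"))

#' @rdname accessors
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))

#' @rdname accessors
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname accessors
#' @export
setGeneric("rpm", function(x) standardGeneric("rpm"))

#' @rdname accessors
#' @export
setGeneric("mappedReads", function(x) standardGeneric("mappedReads"))

#' @rdname accessors
#' @export
setGeneric("libraryNames", function(x) standardGeneric("libraryNames"))

#' @rdname accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @rdname accessors
#' @export
setMethod("precursors", "MiRNARegistry", function(x, ownOnly = FALSE) {
  p <- x@precursors
  if (ownOnly) p[p$own, , drop = FALSE] else p
})

#' @rdname accessors
#' @export
setMethod("matureArms", "MiRNARegistry", function(x, ownOnly = FALSE) {
  m <- x@matures
  if (ownOnly) m[m$own, , drop = FALSE] else m
})

#' @rdname accessors
#' @export
setMethod("precursors", "ReferenceBundle", function(x, ownOnly = FALSE)
  precursors(x@registry, ownOnly))

#' @rdname accessors
#' @export
setMethod("matureArms", "ReferenceBundle", function(x, ownOnly = FALSE)
  matureArms(x@registry, ownOnly))

#' @rdname accessors
#' @export
setMethod("tagSequences", "TagSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("tagCounts", "TagSet", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("libraryNames", "TagSet", function(x) colnames(x@counts))

#' @rdname accessors
#' @export
setMethod("libraryNames", "StudyDesign", function(x) {
  as.vector(t(outer(x@stages, seq_len(x@replicates), paste, sep = "-")))
})

#' @rdname accessors
#' @export
setMethod("stages", "StudyDesign", function(x) x@stages)

#' @rdname accessors
#' @export
setMethod("rpm", "MiRNAExperiment", function(x)
  SummarizedExperiment::assay(x, "rpm"))

#' @rdname accessors
#' @export
setMethod("mappedReads", "MiRNAExperiment", function(x)
  SummarizedExperiment::colData(x)$mappedReads)

#' @rdname accessors
#' @export
setMethod("stages", "MiRNAExperiment", function(x)
  as.character(SummarizedExperiment::colData(x)$stage))

setMethod("show", "MiRNARegistry", function(object) {
  p <- object@precursors
  m <- object@matures
  cat("MiRNARegistry:", sum(p$own), "own-species precursors (",
      sum(m$own), "mature arms ),", sum(!p$own),
      "foreign precursors (", sum(!m$own), "mature arms )\n")
})

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle\n")
  cat("  genome    :", length(object@genome), "chromosomes,",
      sum(Biostrings::width(object@genome)), "bp\n")
  show(object@registry)
  cat("  ncRNA     :", length(object@ncrna), "sequences\n")
  cat("  features  :", length(object@features), "intervals\n")
  cat("  3'UTRs    :", length(object@utrs), "genes;",
      length(object@geneSets), "gene sets\n")
})

setMethod("show", "TagSet", function(object) {
  cat("TagSet:", length(object@sequences), "unique tags,",
      sum(object@counts), "reads across", ncol(object@counts), "libraries\n")
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", paste(object@stages, collapse = " -> "),
      "x", object@replicates, "replicates;",
      object@readsPerLibrary, "reads/library,",
      object@readLength, "nt reads\n")
})

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable:", nrow(object@stageRPM), "planted miRNAs,",
      nrow(object@edits), "edit events,",
      nrow(object@de), "planted DE entries,",
      nrow(object@novel), "planted novel hairpins\n")
})
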