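#' QC parameters for raw small-RNA reads
#'
#' Defaults implement the cleaning rules of the pipeline: at most one
#' unknown (N) base, at most one base below Phred 20, rejection of reads
#' carrying the 5' adapter or lacking the 3' adapter, of empty inserts
#' (adapter dimers), of poly(A) inserts, and of inserts shorter than 16 nt
#' (or beyond the upper insert bound implied by the library gel cut).
#'
#' @param maxN maximum N bases tolerated.
#' @param qualityThreshold Phred score below which a base counts as
#'   low-quality.
#' @param maxLowQualityBases maximum tolerated low-quality bases.
#' @param minInsertLength,maxInsertLength retained insert length range (nt).
#' @param adapter3,adapter5 adapter sequences.
#' @param polyAFraction insert A fraction at or above which a read is
#'   rejected as poly(A).
#' @param adapterMatchMin minimum adapter prefix (nt) for detection: the 3'
#'   adapter is located by the leftmost exact match of this prefix, the 5'
#'   adapter by a read-start prefix match.
#' @return A named list of validated parameters.
#' @export
qcParams <- function(maxN = 1L, qualityThreshold = 20L,
                     maxLowQualityBases = 1L, minInsertLength = 16L,
                     maxInsertLength = 35L,
                     adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                     adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                     polyAFraction = 0.9, adapterMatchMin = 8L) {
  stopifnot(minInsertLength >= 1L, maxN >= 0L, qualityThreshold >= 0L,
            maxLowQualityBases >= 0L, maxInsertLength >= minInsertLength,
            polyAFraction > 0, polyAFraction <= 1,
            adapterMatchMin >= 4L, nchar(adapter3) >= adapterMatchMin)
  as.list(environment())
}

QC_REASONS <- c("too-many-N", "low-quality", "has-5'-adapter",
                "no-3'-adapter", "no-insert", "polyA", "too-short")

#' Filter raw reads by the cleaning rules
#'
#' Applies the rejection rules in fixed order (`too-many-N`,
#' `low-quality`, `has-5'-adapter`, `no-3'-adapter`, `no-insert`, `polyA`,
#' `too-short`); a read is tagged with the first rule it violates. Kept
#' reads are returned as 3'-adapter-trimmed inserts.
#'
#' @param sequences,qualities character vectors (Phred+33 qualities) of
#'   equal lengths per record.
#' @param params a list from [qcParams()].
#' @return A data.frame with one row per read: `insert` (NA when
#'   rejected), `reason` (NA when kept) and `keep`.
#' @examples
#' p <- qcParams()
#' filterReads(paste0("ACGTACGTACGTACGTACGTAC", p$adapter3),
#'             strrep("I", 43), p)$keep
#' @export
filterReads <- function(sequences, qualities, params = qcParams()) {
  n <- length(sequences)
  if (length(qualities) != n)
    stop("sequence/quality vector length mismatch")
  bad <- which(nchar(sequences) != nchar(qualities))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d: sequence/quality length mismatch",
                 bad[1]))
  reason <- rep(NA_character_, n)
  mark <- function(cond, lab) {
    idx <- which(cond & is.na(reason))
    reason[idx] <<- lab
    invisible()
  }
  mark(stri_count_fixed(sequences, "N") > params$maxN, "too-many-N")
  lowClass <- sprintf("[\\x21-\\x%02x]", 32L + params$qualityThreshold)
  mark(stri_count_charclass(qualities, lowClass) > params$maxLowQualityBases,
       "low-quality")
  a5 <- substr(params$adapter5, 1L, params$adapterMatchMin)
  mark(startsWith(sequences, a5), "has-5'-adapter")
  a3 <- substr(params$adapter3, 1L, params$adapterMatchMin)
  pos <- stri_locate_first_fixed(sequences, a3)[, 1L]
  mark(is.na(pos), "no-3'-adapter")
  insert <- substr(sequences, 1L, ifelse(is.na(pos), 0L, pos - 1L))
  mark(!is.na(pos) & pos == 1L, "no-insert")
  ilen <- nchar(insert)
  fracA <- ifelse(ilen > 0L, stri_count_fixed(insert, "A") / ilen, 0)
  mark(fracA >= params$polyAFraction, "polyA")
  mark(ilen < params$minInsertLength | ilen > params$maxInsertLength,
       "too-short")
  keep <- is.na(reason)
  data.frame(insert = ifelse(keep, insert, NA_character_),
             reason = reason, keep = keep, stringsAsFactors = FALSE)
}

#' Summarize a QC run
#'
#' @param filtered a data.frame from [filterReads()].
#' @return A data.frame of read counts per outcome (kept first, then each
#'   rejection reason), with the conservation identity
#'   `total = kept + sum(rejected)`.
#' @export
qcSummary <- function(filtered) {
  counts <- c(kept = sum(filtered$keep),
              vapply(QC_REASONS, function(r)
                sum(!is.na(filtered$reason) & filtered$reason == r),
                integer(1)))
  data.frame(outcome = names(counts), reads = unname(counts),
             stringsAsFactors = FALSE)
}

#' Collapse clean inserts to unique tags
#'
#' One tag per distinct insert sequence, with per-library counts. The
#' result is ordered lexicographically by sequence, so collapsing is
#' invariant to the order of the input reads.
#'
#' @param insertsByLibrary named list; one character vector of clean
#'   inserts per library.
#' @return A [TagSet].
#' @examples
#' collapseReads(list(A = c("ACGTACGTACGTACGTA", "ACGTACGTACGTACGTA"),
#'                    B = "TTTTACGTACGTACGTA"))
#' @export
collapseReads <- function(insertsByLibrary) {
  stopifnot(is.list(insertsByLibrary), !is.null(names(insertsByLibrary)))
  libs <- names(insertsByLibrary)
  dts <- lapply(libs, function(l) {
    x <- insertsByLibrary[[l]]
    if (!length(x))
      return(data.table::data.table(seq = character(0), lib = character(0)))
    data.table::data.table(seq = x, lib = l)
  })
  dt <- data.table::rbindlist(dts)
  if (!nrow(dt)) {
    m <- matrix(0L, 0, length(libs), dimnames = list(NULL, libs))
    return(new("TagSet", sequences = character(0), counts = m))
  }
  agg <- dt[, .N, by = c("seq", "lib")]
  wide <- data.table::dcast(agg, seq ~ lib, value.var = "N", fill = 0L)
  data.table::setorder(wide, seq)
  seqs <- wide$seq
  m <- as.matrix(wide[, -1, drop = FALSE])
  missing <- setdiff(libs, colnames(m))
  if (length(missing)) {
    m <- cbind(m, matrix(0L, nrow(m), length(missing),
                         dimnames = list(NULL, missing)))
  }
  m <- m[, libs, drop = FALSE]
  rownames(m) <- seqs
  new("TagSet", sequences = seqs, counts = m)
}

#' Length distribution of clean reads
#'
#' Histogram of insert lengths weighted by read counts (not by distinct
#' tags); fractions sum to one.
#'
#' @param tags a [TagSet].
#' @param library optional library label; default pools all libraries.
#' @return A data.frame with `length`, `reads` and `fraction`.
#' @export
lengthDistribution <- function(tags, library = NULL) {
  cnt <- tagCounts(tags)
  w <- if (is.null(library)) rowSums(cnt) else {
    stopifnot(library %in% colnames(cnt))
    cnt[, library]
  }
  len <- nchar(tagSequences(tags))
  tb <- tapply(w, len, sum)
  out <- data.frame(length = as.integer(names(tb)), reads = as.numeric(tb))
  out <- out[out$reads > 0, , drop = FALSE]
  out$fraction <- out$reads / sum(out$reads)
  rownames(out) <- NULL
  out
}
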