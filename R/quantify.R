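#' Build the miRNA x library expression matrix
#'
#' Aggregates tag counts per assigned mature miRNA (isomiRs within +/-2 nt
#' and single-mismatch edited variants are counted under their mature id)
#' and per homolog entity, and normalizes to reads per million
#' genome-mapped reads (RPM). The RPM denominator is the per-library
#' count of clean reads whose tag maps exactly to the genome; it is
#' recorded in `colData()` for auditability.
#'
#' @param annot annotation data.frame from [classifyTags()].
#' @param tags the matching [TagSet].
#' @param design a [StudyDesign] (stage assignment of libraries).
#' @param registry optional [MiRNARegistry] used to attach genomic
#'   coordinates and to include zero-count registry miRNAs as rows.
#' @return A [MiRNAExperiment] with assays `counts` and `rpm`.
#' @export
buildExpressionMatrix <- function(annot, tags, design, registry = NULL) {
  cnt <- tagCounts(tags)
  libs <- colnames(cnt)
  denom <- colSums(cnt[annot$mapped, , drop = FALSE])
  if (any(denom == 0))
    stop(sprintf("zero mapped-read denominator in library %s",
                 paste(libs[denom == 0], collapse = ", ")))

  isMir <- annot$category %in% c("known-miRNA", "edited-miRNA", "homolog-miRNA")
  ids <- annot$assignedMirna[isMir]
  agg <- rowsum(cnt[isMir, , drop = FALSE], ids)

  type <- ifelse(rownames(agg) %in%
                   unique(annot$assignedMirna[annot$category == "homolog-miRNA"]),
                 "homolog", "known")
  if (!is.null(registry)) {
    ownIds <- matureArms(registry, ownOnly = TRUE)$id
    missing <- setdiff(ownIds, rownames(agg))
    if (length(missing)) {
      agg <- rbind(agg, matrix(0L, length(missing), ncol(agg),
                               dimnames = list(missing, colnames(agg))))
      type <- c(type, rep("known", length(missing)))
    }
  }
  ord <- order(rownames(agg))
  agg <- agg[ord, , drop = FALSE]
  type <- type[ord]

  rowData <- S4Vectors::DataFrame(id = rownames(agg), type = type)
  if (!is.null(registry)) {
    coords <- .matureCoordinates(registry)
    idx <- match(rownames(agg), coords$matureId)
    rowData$chrom <- coords$chrom[idx]
    rowData$start <- coords$start[idx]
    rowData$end <- coords$end[idx]
    rowData$strand <- coords$strand[idx]
  }

  stageOf <- setNames(rep(stages(design), each = design@replicates),
                      libraryNames(design))
  rpmAssay <- sweep(agg, 2, 1e6 / denom, "*")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = agg, rpm = rpmAssay),
    rowData = rowData,
    colData = S4Vectors::DataFrame(
      library = libs, stage = unname(stageOf[libs]),
      mappedReads = unname(denom), row.names = libs))
  new("MiRNAExperiment", se)
}

# Genomic coordinates of own-species mature arms, strand-aware.
.matureCoordinates <- function(registry) {
  m <- as.data.frame(matureArms(registry, ownOnly = TRUE))
  p <- as.data.frame(precursors(registry, ownOnly = TRUE))
  i <- match(m$precursorId, p$id)
  mlen <- nchar(m$sequence)
  plus <- p$strand[i] == "+"
  start <- ifelse(plus, p$start[i] + m$offset - 1L,
                  p$end[i] - m$offset - mlen + 2L)
  data.frame(matureId = m$id, chrom = p$chrom[i], start = start,
             end = start + mlen - 1L, strand = p$strand[i],
             stringsAsFactors = FALSE)
}

#' Retention filter and abundance tiers
#'
#' The overall average is the unweighted mean of per-library RPM. A miRNA
#' is retained if its overall average exceeds 1 RPM; tiers are
#' low (< 100), moderate (>= 100 and < 1000) and high (>= 1000).
#'
#' @param x a [MiRNAExperiment].
#' @return A data.frame: `id`, `type`, `overallRPM`, `retained`, `tier`,
#'   `over10k`.
#' @export
filterAndTier <- function(x) {
  r <- rpm(x)
  avg <- rowMeans(r)
  data.frame(
    id = rownames(r),
    type = SummarizedExperiment::rowData(x)$type,
    overallRPM = avg,
    retained = avg > 1,
    tier = cut(avg, c(-Inf, 100, 1000, Inf),
               labels = c("low", "moderate", "high"), right = FALSE),
    over10k = avg > 10000,
    stringsAsFactors = FALSE)
}

#' Tier bookkeeping summary
#'
#' @param tiers a data.frame from [filterAndTier()], typically restricted
#'   to retained known miRNAs.
#' @return A one-row data.frame: counts and percentages per tier and for
#'   the >10,000 RPM set.
#' @export
tierSummary <- function(tiers) {
  n <- nrow(tiers)
  data.frame(
    n = n,
    low = sum(tiers$tier == "low"), moderate = sum(tiers$tier == "moderate"),
    high = sum(tiers$tier == "high"), over10k = sum(tiers$over10k),
    pctLow = round(100 * sum(tiers$tier == "low") / n, 2),
    pctModerate = round(100 * sum(tiers$tier == "moderate") / n, 2),
    pctHigh = round(100 * sum(tiers$tier == "high") / n, 2),
    pctOver10k = round(100 * sum(tiers$over10k) / n, 2))
}

#' Stage-mean abundance summary and top-N report
#'
#' Computes per-stage mean RPM (mean over replicate libraries), the
#' overall average (mean of per-library RPM, which equals the mean of
#' stage means under equal replication), and the percent of total
#' computed over retained known miRNAs.
#'
#' @param x a [MiRNAExperiment].
#' @param tiers a data.frame from [filterAndTier()].
#' @param topN rows of the descending top-abundance report.
#' @return A data.frame sorted by descending overall average: stage mean
#'   columns, `overallRPM`, `pctTotal` and `topN` flag.
#' @export
summarizeAbundance <- function(x, tiers, topN = 19L) {
  r <- rpm(x)
  stage <- stages(x)
  stageLevels <- unique(stage)
  sm <- vapply(stageLevels, function(s)
    rowMeans(r[, stage == s, drop = FALSE]), numeric(nrow(r)))
  overall <- rowMeans(r)
  known <- SummarizedExperiment::rowData(x)$type == "known"
  retained <- tiers$retained[match(rownames(r), tiers$id)]
  denom <- sum(overall[known & retained])
  pct <- ifelse(known & retained, 100 * overall / denom, NA_real_)
  out <- data.frame(id = rownames(r), sm, overallRPM = overall,
                    pctTotal = pct, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$overallRPM), , drop = FALSE]
  out$topN <- seq_len(nrow(out)) <= topN
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations between libraries
#'
#' Computed on the RPM vectors of retained known miRNAs; symmetric with a
#' unit diagonal. Zero-variance libraries give NA with a warning.
#'
#' @param x a [MiRNAExperiment].
#' @param tiers a data.frame from [filterAndTier()]; when supplied, only
#'   retained known miRNAs enter.
#' @return The library x library correlation matrix.
#' @export
pairwiseCorrelation <- function(x, tiers = NULL) {
  r <- rpm(x)
  if (!is.null(tiers)) {
    keep <- tiers$id[tiers$retained & tiers$type == "known"]
    r <- r[rownames(r) %in% keep, , drop = FALSE]
  }
  sds <- apply(r, 2, stats::sd)
  if (any(sds == 0))
    warning(sprintf("zero-variance library: %s",
                    paste(colnames(r)[sds == 0], collapse = ", ")))
  cor(r)
}

#' Detect genomic miRNA clusters
#'
#' A cluster is a maximal run of same-chromosome miRNA genes, ordered by
#' position, in which every adjacent gap (distance between consecutive
#' gene intervals) is at most `window`. Only miRNAs above `minRPM`
#' overall average are considered; clusters with fewer than `minSize`
#' members are dropped. Detection is invariant to input order and to
#' coordinate translation.
#'
#' @param registry a [MiRNARegistry].
#' @param tiers a data.frame from [filterAndTier()] (used for the
#'   abundance filter); `NULL` disables the filter.
#' @param window maximum adjacent gap (bp).
#' @param minSize minimum cluster size.
#' @param minRPM overall-average RPM threshold.
#' @return A data.frame per cluster: `chrom`, `start`, `end`, `n`,
#'   `members` (comma-separated mature ids).
#' @export
detectGenomicClusters <- function(registry, tiers = NULL, window = 100000L,
                                  minSize = 3L, minRPM = 100) {
  co <- .matureCoordinates(registry)
  if (!is.null(tiers)) {
    keep <- tiers$id[tiers$overallRPM > minRPM]
    co <- co[co$matureId %in% keep, , drop = FALSE]
  }
  if (!nrow(co)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  co <- co[order(co$chrom, co$start, co$matureId), , drop = FALSE]
  newRun <- c(TRUE, co$chrom[-1] != co$chrom[-nrow(co)] |
                co$start[-1] - co$end[-nrow(co)] - 1L > window)
  run <- cumsum(newRun)
  out <- do.call(rbind, lapply(split(co, run), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               n = nrow(g), members = paste(g$matureId, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n >= minSize, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Hierarchical ordering of expression rows
#'
#' Agglomerative clustering (correlation distance, average linkage) of
#' per-stage RPM rows; rows are pre-sorted by id so ties break
#' deterministically. The two top-level groups are the children of the
#' dendrogram root.
#'
#' @param mat numeric matrix (miRNA x stage); rows with zero variance are
#'   assigned a zero correlation against all others.
#' @return A list: `order` (leaf ids in dendrogram order), `groups`
#'   (named integer vector, 1 or 2, from cutting the root).
#' @export
hierarchicalOrder <- function(mat) {
  stopifnot(nrow(mat) >= 2L)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  cc <- suppressWarnings(cor(t(mat)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  hc <- hclust(as.dist(1 - cc), method = "average")
  groups <- cutree(hc, k = 2L)
  list(order = rownames(mat)[hc$order], groups = groups, hclust = hc)
}
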