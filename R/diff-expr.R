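#' Upper-quartile scale factors
#'
#' The factor of a library is the 75th percentile of its nonzero raw
#' counts, rescaled so the geometric mean of all factors equals one. The
#' effective library size is the mapped-read denominator multiplied by
#' the factor.
#'
#' @param counts integer matrix (features x libraries).
#' @return Named numeric vector of scale factors.
#' @examples
#' m <- cbind(A = c(10L, 20L, 30L, 0L), B = c(20L, 40L, 60L, 0L))
#' uqFactors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
uqFactors <- function(counts) {
  zero <- colSums(counts > 0) == 0
  if (any(zero))
    stop(sprintf("library %s has no nonzero counts",
                 paste(colnames(counts)[zero], collapse = ", ")))
  uq <- apply(counts, 2, function(x)
    quantile(x[x > 0], 0.75, names = FALSE, type = 7))
  uq / exp(mean(log(uq)))
}

# Scale counts to a common effective library size (geometric mean),
# rounding half away from zero.
.scaleToCommon <- function(counts, effSizes) {
  common <- exp(mean(log(effSizes)))
  scaled <- sweep(counts, 2, common / effSizes, "*")
  floor(abs(scaled) + 0.5) * sign(scaled)
}

# Conditional (on the within-group sum) NB log-likelihood of one group of
# equal-mean libraries, as a function of dispersion phi = 1/r. The
# conditional distribution is free of the mean.
.condLogLik <- function(countsMat, phi) {
  if (phi <= 0) return(NA_real_)
  r <- 1 / phi
  nlib <- ncol(countsMat)
  s <- rowSums(countsMat)
  ll <- rowSums(lgamma(countsMat + r)) - nlib * lgamma(r) +
    lgamma(nlib * r) - lgamma(s + nlib * r) +
    lgamma(s + 1) - rowSums(lgamma(countsMat + 1))
  sum(ll)
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional (qCML-style) NB log-likelihood, summed over
#' features and replicate groups, after quantile-scaling counts to a
#' common effective library size. The search is bounded to [0, 5] with
#' tolerance 1e-6; identical replicates drive the estimate to the lower
#' bound (the Poisson limit).
#'
#' @param counts integer matrix (features x libraries).
#' @param groups factor/character of group labels per library.
#' @param effSizes effective library sizes (defaults to column sums).
#' @return A list: `phi`, `method`.
#' @export
estimateCommonDispersion <- function(counts, groups,
                                     effSizes = colSums(counts)) {
  groups <- as.character(groups)
  reps <- names(which(table(groups) >= 2L))
  if (!length(reps))
    stop("no group has replicates; supply a dispersion directly")
  scaled <- .scaleToCommon(counts, effSizes)
  mats <- lapply(reps, function(g) scaled[, groups == g, drop = FALSE])
  obj <- function(phi) sum(vapply(mats, .condLogLik, numeric(1), phi = phi))
  opt <- optimize(obj, c(1e-6, 5), maximum = TRUE, tol = 1e-6)
  phi <- opt$maximum
  if (obj(1e-6) >= opt$objective) phi <- 0
  list(phi = phi, method = "qCML-common")
}

# Conditional two-sided NB exact test for one feature with equal
# effective library sizes: given pooled total t over nA + nB libraries,
# sums the probabilities of all group-A totals as or less likely than the
# observed one. phi = 0 reduces to the binomial split.
.exactTestOne <- function(a, b, nA, nB, phi) {
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    lp <- dbinom(k, t, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi
    rB <- nB / phi
    lp <- lgamma(k + rA) - lgamma(k + 1) +
      lgamma(t - k + rB) - lgamma(t - k + 1)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  pObs <- lp[a + 1]
  sum(exp(lp[lp <= pObs + 1e-12]))
}

#' Negative-binomial exact test for a two-group comparison
#'
#' Counts are quantile-scaled to equal effective library sizes, pooled
#' within groups and tested conditionally on the pooled total under a
#' common-dispersion NB model. The log2 fold change uses 0.5
#' pseudo-counts on the scaled group means, with positive values meaning
#' higher counts in group B.
#'
#' @param countsA,countsB integer matrices (features x replicates).
#' @param phi common NB dispersion (>= 0; 0 is the Poisson/binomial
#'   limit).
#' @param effSizesA,effSizesB effective library sizes.
#' @return A data.frame: `log2fc`, `pvalue`.
#' @export
nbExactTest <- function(countsA, countsB, phi,
                        effSizesA = colSums(countsA),
                        effSizesB = colSums(countsB)) {
  if (phi < 0) stop("dispersion phi must be non-negative")
  countsA <- as.matrix(countsA)
  countsB <- as.matrix(countsB)
  stopifnot(nrow(countsA) == nrow(countsB))
  all <- .scaleToCommon(cbind(countsA, countsB),
                        c(effSizesA, effSizesB))
  nA <- ncol(countsA)
  nB <- ncol(countsB)
  sA <- all[, seq_len(nA), drop = FALSE]
  sB <- all[, nA + seq_len(nB), drop = FALSE]
  a <- rowSums(sA)
  b <- rowSums(sB)
  p <- vapply(seq_along(a), function(i)
    .exactTestOne(a[i], b[i], nA, nB, phi), numeric(1))
  log2fc <- log2((rowMeans(sB) + 0.5) / (rowMeans(sA) + 0.5))
  data.frame(log2fc = log2fc, pvalue = pmin(p, 1),
             row.names = rownames(countsA))
}

#' Call differential expression across stage comparisons
#'
#' Runs the UQ-scaled NB exact test for every pairwise stage comparison
#' (direction convention: log2FC > 0 means higher in the later stage),
#' applies Benjamini-Hochberg FDR within each comparison, and calls a
#' miRNA differentially expressed when `|log2FC| >= fcThreshold` and
#' `FDR <= fdrThreshold`.
#'
#' @param x a [MiRNAExperiment].
#' @param tiers a data.frame from [filterAndTier()]; only retained miRNAs
#'   are tested.
#' @param comparisons character vector like `"E45_vs_B3"`; default all
#'   stage pairs in design order.
#' @param phi common dispersion; `NULL` estimates it with
#'   [estimateCommonDispersion()] across all stages.
#' @param fcThreshold,fdrThreshold call thresholds.
#' @param typeFilter row types to test (default known miRNAs, the focus
#'   of downstream reporting).
#' @return A data.frame: `id`, `comparison`, `log2fc`, `pvalue`, `fdr`,
#'   `call` (`up`, `down`, `ns`), with the dispersion in
#'   `attr(x, "phi")`.
#' @export
callDE <- function(x, tiers, comparisons = NULL, phi = NULL,
                   fcThreshold = 1, fdrThreshold = 0.05,
                   typeFilter = c("known")) {
  stage <- stages(x)
  stageLevels <- unique(stage)
  if (is.null(comparisons))
    comparisons <- .comparisonLabels(stageLevels)
  keep <- tiers$retained & tiers$type %in% typeFilter
  ids <- tiers$id[keep]
  cnt <- SummarizedExperiment::assay(x, "counts")[ids, , drop = FALSE]
  uq <- uqFactors(cnt)
  eff <- mappedReads(x) * uq
  names(eff) <- colnames(cnt)
  if (is.null(phi))
    phi <- estimateCommonDispersion(cnt, stage, eff)$phi
  out <- list()
  for (cmp in comparisons) {
    ab <- strsplit(cmp, "_vs_")[[1]]
    if (!all(ab %in% stageLevels))
      stop(sprintf("unknown stage label in comparison %s", cmp))
    iA <- which(stage == ab[1])
    iB <- which(stage == ab[2])
    res <- nbExactTest(cnt[, iA, drop = FALSE], cnt[, iB, drop = FALSE],
                       phi, eff[iA], eff[iB])
    fdr <- p.adjust(res$pvalue, "BH")
    call <- ifelse(abs(res$log2fc) >= fcThreshold & fdr <= fdrThreshold,
                   ifelse(res$log2fc > 0, "up", "down"), "ns")
    out[[cmp]] <- data.frame(id = ids, comparison = cmp,
                             log2fc = res$log2fc, pvalue = res$pvalue,
                             fdr = fdr, call = call,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "phi") <- phi
  res
}

#' Common / unique DE partition across comparisons
#'
#' Set-algebra report of up- and down-regulated miRNAs across a group of
#' comparisons (a Venn-diagram analogue).
#'
#' @param de a data.frame from [callDE()].
#' @param comparisons comparisons to partition over (default: all in
#'   `de`).
#' @return A list with `up` and `down`, each containing `common` (ids
#'   called in every comparison), `perComparison` counts and `unique`
#'   counts (ids exclusive to one comparison).
#' @export
vennPartition <- function(de, comparisons = unique(de$comparison)) {
  part <- function(dir) {
    sets <- lapply(comparisons, function(cmp)
      de$id[de$comparison == cmp & de$call == dir])
    names(sets) <- comparisons
    common <- Reduce(intersect, sets)
    uniq <- vapply(comparisons, function(cmp) {
      others <- unlist(sets[setdiff(comparisons, cmp)])
      length(setdiff(sets[[cmp]], others))
    }, integer(1))
    list(common = common, nCommon = length(common),
         perComparison = lengths(sets), unique = uniq)
  }
  list(up = part("up"), down = part("down"))
}
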