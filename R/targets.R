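#' Canonical seed-match sites in a 3'UTR
#'
#' Scans a UTR (sense orientation) for reverse-complement matches to the
#' miRNA seed: positions 2-8 (7mer-m8), positions 2-7 followed by a
#' genomic A opposite position 1 (7mer-A1), or both (8mer). All
#' occurrences are reported; a position matching the 8mer definition is
#' reported once, as 8mer.
#'
#' @param mirna miRNA sequence (>= 8 nt, 5'->3').
#' @param utr UTR sequence (5'->3').
#' @return A data.frame: `position` (1-based site start in the UTR) and
#'   `class` (`8mer`, `7mer-m8`, `7mer-A1`).
#' @export
findSeedSites <- function(mirna, utr) {
  stopifnot(nchar(mirna) >= 8L)
  m8 <- .revcomp(substr(mirna, 2L, 8L))   # 7 nt
  m7 <- .revcomp(substr(mirna, 2L, 7L))   # 6 nt
  hit <- function(pat) {
    if (nchar(utr) < nchar(pat)) return(integer(0))
    unlist(gregexpr(pat, utr, fixed = TRUE))
  }
  p8 <- hit(m8); p8 <- p8[p8 > 0]
  rows <- list()
  for (p in p8) {
    nxt <- substr(utr, p + 7L, p + 7L)
    cls <- if (nxt == "A") "8mer" else "7mer-m8"
    rows[[length(rows) + 1L]] <- data.frame(position = p, class = cls,
                                            stringsAsFactors = FALSE)
  }
  p7 <- hit(paste0(m7, "A")); p7 <- p7[p7 > 0]
  # drop 7mer-A1 positions already covered by an m8 match at p-1
  for (p in p7) {
    if ((p - 1L) %in% p8) next
    rows[[length(rows) + 1L]] <- data.frame(position = p, class = "7mer-A1",
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(position = integer(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}

#' Weighted local complementarity score
#'
#' Smith-Waterman-style local alignment of the miRNA against a UTR
#' window scored by complementarity (+5 Watson-Crick, +1 G:U wobble, -3
#' mismatch, gap open -8, gap extend -2), with miRNA seed positions 2-8
#' weighted x2.
#'
#' @param mirna miRNA sequence.
#' @param window UTR window sequence.
#' @return The maximal local alignment score.
#' @export
scoreComplementarity <- function(mirna, window) {
  if (!nchar(window) || !nchar(mirna)) return(0)
  align_complement_cpp(mirna, window)
}

#' Minimum duplex hybridization energy
#'
#' Minimum-energy intermolecular duplex between miRNA and UTR window
#' (antiparallel, no intramolecular pairs) under the same stacking
#' energy table as [foldHairpin()]; loops/bulges up to `maxLoop`
#' unpaired bases cost a flat penalty.
#'
#' @param mirna,window sequences (<= 80 nt each).
#' @param maxLoop maximum unpaired bases per internal loop.
#' @return Duplex energy in kcal/mol (<= 0).
#' @examples
#' duplexEnergy(strrep("G", 22), strrep("C", 22))  # -63
#' @export
duplexEnergy <- function(mirna, window, maxLoop = 8L) {
  stopifnot(nchar(mirna) <= 80L, nchar(window) <= 80L)
  duplex_energy_cpp(mirna, window, 2.0, as.integer(maxLoop))
}

#' Predict target genes by three-method intersection
#'
#' Runs the three archetypal site finders on identical inputs — seed
#' scan, weighted complementarity alignment (threshold
#' `alignThreshold`), duplex energy (threshold `energyThreshold`,
#' evaluated on sliding windows) — and retains a (miRNA, gene) pair iff
#' all three predict it.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param utrs named character vector (or `DNAStringSet`) of 3'UTRs.
#' @param alignThreshold minimum complementarity score.
#' @param energyThreshold maximum duplex energy (kcal/mol).
#' @param windowSize,windowStep sliding-window scan for the duplex
#'   method.
#' @return A list: `pairs` (data.frame `mirna`, `gene` of final
#'   targets), `perMethod` (list of per-method data.frames), `sites`
#'   (seed sites of final pairs).
#' @export
predictTargets <- function(mirnas, utrs, alignThreshold = 140,
                           energyThreshold = -15, windowSize = 30L,
                           windowStep = 5L) {
  utrSeq <- if (is.character(utrs)) utrs else
    setNames(as.character(utrs), names(utrs))
  genes <- names(utrSeq)
  stopifnot(!is.null(genes), !is.null(names(mirnas)))
  seedHits <- list(); alignHits <- list(); duplexHits <- list()
  sites <- list()
  for (mi in names(mirnas)) {
    ms <- mirnas[[mi]]
    for (g in genes) {
      us <- utrSeq[[g]]
      ss <- findSeedSites(ms, us)
      if (nrow(ss)) {
        seedHits[[length(seedHits) + 1L]] <- data.frame(
          mirna = mi, gene = g, stringsAsFactors = FALSE)
        sites[[length(sites) + 1L]] <- cbind(
          data.frame(mirna = mi, gene = g, stringsAsFactors = FALSE), ss)
      }
      if (align_complement_cpp(ms, us) >= alignThreshold)
        alignHits[[length(alignHits) + 1L]] <- data.frame(
          mirna = mi, gene = g, stringsAsFactors = FALSE)
      starts <- unique(c(seq(1L, max(nchar(us) - windowSize + 1L, 1L),
                             by = windowStep)))
      emin <- 0
      for (st in starts) {
        e <- duplex_energy_cpp(ms, substr(us, st, st + windowSize - 1L))
        if (e < emin) emin <- e
        if (emin <= energyThreshold) break
      }
      if (emin <= energyThreshold)
        duplexHits[[length(duplexHits) + 1L]] <- data.frame(
          mirna = mi, gene = g, stringsAsFactors = FALSE)
    }
  }
  tab <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(mirna = character(0), gene = character(0),
               stringsAsFactors = FALSE)
  perMethod <- list(seed = tab(seedHits), alignment = tab(alignHits),
                    duplex = tab(duplexHits))
  pairs <- intersectTargets(perMethod)
  siteTab <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna = character(0), gene = character(0),
               position = integer(0), class = character(0))
  key <- paste(pairs$mirna, pairs$gene)
  siteTab <- siteTab[paste(siteTab$mirna, siteTab$gene) %in% key, ,
                     drop = FALSE]
  list(pairs = pairs, perMethod = perMethod, sites = siteTab)
}

#' Intersect per-method target predictions
#'
#' @param perMethod list of data.frames with columns `mirna`, `gene`.
#' @return A data.frame of pairs predicted by every method.
#' @export
intersectTargets <- function(perMethod) {
  keys <- lapply(perMethod, function(d) unique(paste(d$mirna, d$gene)))
  common <- Reduce(intersect, keys)
  if (!length(common)) {
    return(data.frame(mirna = character(0), gene = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(common, " ", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[`, character(1), 1L),
                    gene = vapply(parts, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  out[order(out$mirna, out$gene), , drop = FALSE]
}

#' Filter target pairs by opposite expression change
#'
#' Restricts to miRNAs that are differentially expressed in the
#' comparison with an overall average above `minRPM`, and keeps a
#' (miRNA, gene) pair iff the mRNA log2 fold change is nonzero with the
#' opposite sign to the miRNA's. Pairs whose gene is missing from the
#' mRNA table are dropped and counted.
#'
#' @param targets data.frame with `mirna`, `gene` (gene-level pairs).
#' @param de data.frame from [callDE()].
#' @param mrnaFC data.frame `gene`, `comparison`, `log2fc`.
#' @param comparison comparison label.
#' @param tiers data.frame from [filterAndTier()].
#' @param minRPM abundance focus threshold.
#' @return The retained pairs with `mirnaLog2fc` and `mrnaLog2fc`;
#'   dropped-gene count in `attr(x, "missingGenes")`.
#' @export
anticorrelationFilter <- function(targets, de, mrnaFC, comparison, tiers,
                                  minRPM = 100) {
  deCmp <- de[de$comparison == comparison & de$call != "ns", , drop = FALSE]
  focus <- tiers$id[tiers$overallRPM > minRPM]
  deCmp <- deCmp[deCmp$id %in% focus, , drop = FALSE]
  t <- targets[targets$mirna %in% deCmp$id, , drop = FALSE]
  t$mirnaLog2fc <- deCmp$log2fc[match(t$mirna, deCmp$id)]
  fc <- mrnaFC[mrnaFC$comparison == comparison, , drop = FALSE]
  t$mrnaLog2fc <- fc$log2fc[match(t$gene, fc$gene)]
  missing <- sum(is.na(t$mrnaLog2fc))
  t <- t[!is.na(t$mrnaLog2fc), , drop = FALSE]
  keep <- t$mrnaLog2fc != 0 & sign(t$mrnaLog2fc) == -sign(t$mirnaLog2fc)
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missingGenes") <- missing
  out
}

#' Gene-set enrichment by hypergeometric or EASE test
#'
#' Upper-tail hypergeometric p-value per gene set against a supplied
#' background; in EASE mode the overlap is decremented by one (floored
#' at zero) before the test. BH FDR across sets.
#'
#' @param genes character vector (the gene list; intersected with the
#'   background).
#' @param background character vector of background gene ids.
#' @param geneSets named list of character vectors.
#' @param mode `"hypergeometric"` or `"EASE"`.
#' @param alpha reporting threshold on the raw p-value.
#' @return A data.frame per set: `set`, `k` (overlap), `n` (list size),
#'   `K` (set size in background), `N` (background size), `pvalue`,
#'   `fdr`, `significant`.
#' @examples
#' enrichGeneSets(letters[1:5], letters[1:20], list(s = letters[1:5]))
#' @export
enrichGeneSets <- function(genes, background, geneSets,
                           mode = c("hypergeometric", "EASE"),
                           alpha = 0.05) {
  mode <- match.arg(mode)
  background <- unique(background)
  if (!length(background)) stop("empty background")
  genes <- unique(intersect(genes, background))
  N <- length(background)
  n <- length(genes)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], background)
    K <- length(set)
    k <- length(intersect(genes, set))
    kTest <- if (mode == "EASE") max(k - 1L, 0L) else k
    p <- phyper(kTest - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$pvalue, "BH")
  out$significant <- out$pvalue < alpha
  out[order(out$pvalue), , drop = FALSE]
}
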