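# Collapse foreign-species mature arms with identical sequences into one
# homolog entity, named in the prefix-free style used for reporting
# (e.g. "mmu-miR-h7-5p" -> "miR-h7-5p").
.homologEntities <- function(registry) {
  fm <- as.data.frame(matureArms(registry))
  fm <- fm[!fm$own, , drop = FALSE]
  if (!nrow(fm)) {
    return(data.frame(name = character(0), sequence = character(0),
                      memberIds = character(0), stringsAsFactors = FALSE))
  }
  fm <- fm[order(fm$id), , drop = FALSE]
  sp <- split(fm$id, fm$sequence)
  data.frame(
    name = vapply(sp, function(ids) sub("^[a-z]{3}-", "", sort(ids)[1]),
                  character(1)),
    sequence = names(sp),
    memberIds = vapply(sp, function(ids) paste(sort(ids), collapse = ","),
                       character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

.defaultFractions <- function() {
  c(mirna = 0.62, homolog = 0.04, ncrna = 0.10, "repeat" = 0.03,
    exon = 0.03, novel = 0.02, decoy = 0.01, background = 0.04,
    adapterDimer = 0.04, lowQuality = 0.03, polyA = 0.02,
    adapter5 = 0.01, nBases = 0.01)
}

#' Build the planted truth table for a simulation run
#'
#' Assigns every registry miRNA a stage-structured expected abundance and
#' records all planted, recoverable truths: a constant ~10,000 RPM sentinel
#' miRNA, two co-expressed programs inside the genomic cluster,
#' fold-change differential expression at designated stage transitions
#' (including all planted target-site miRNAs), single-base editing events,
#' isomiR end-offset distributions, novel hairpin read shares and the
#' contaminant class fractions. Replicate-level biological variability is
#' drawn here as per-library gamma multipliers (squared coefficient of
#' variation `phi`), so the stored per-library read proportions are the
#' exact binomial expectations of the simulated counts.
#'
#' @param bundle a [ReferenceBundle].
#' @param design a [StudyDesign].
#' @param seed integer seed.
#' @param config the [referenceConfig()] used to build `bundle`.
#' @param phi squared biological coefficient of variation between replicate
#'   libraries (gamma-distributed expression multipliers); 0 disables
#'   replicate noise.
#' @param fractions named read-class fractions (must sum to 1).
#' @param nDE,deFold number of designed differentially expressed miRNAs and
#'   their fold change between consecutive designated stages.
#' @param nEdits,editRate planted single-base editing events and the
#'   per-read editing rate.
#' @param nLow miRNAs planted below the 1 RPM retention threshold.
#' @return A [TruthTable].
#' @export
buildTruthTable <- function(bundle, design, seed = 1L,
                            config = referenceConfig(), phi = 0.1,
                            fractions = .defaultFractions(),
                            nDE = 60L, deFold = 4, nEdits = 10L,
                            editRate = 0.15, nLow = 8L) {
  set.seed(.subSeed(seed, 2L))
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  stagesL <- stages(design)
  S <- length(stagesL)
  libs <- libraryNames(design)
  stageOf <- rep(stagesL, each = design@replicates)

  mat <- as.data.frame(matureArms(bundle@registry))
  own <- mat[mat$own, , drop = FALSE]
  pre <- as.data.frame(precursors(bundle@registry))
  preOwn <- pre[pre$own, , drop = FALSE]
  M <- nrow(own)

  clusterPre <- preOwn$id[preOwn$chrom == config$clusterChrom &
                          preOwn$start >= config$clusterStart &
                          preOwn$end <= config$clusterStart + config$clusterSpan]
  isCluster <- own$precursorId %in% clusterPre

  planted <- bundle@planted
  targetRows <- unique(planted[planted$kind == "target",
                               c("matureId", "direction", "transition")])
  targetIds <- targetRows$matureId

  sentinel <- own$id[which(!isCluster & !(own$id %in% targetIds))[1]]
  pool <- setdiff(own$id[!isCluster], c(sentinel, targetIds))
  nExtra <- max(nDE - length(targetIds), 0L)
  deExtra <- sample(pool, min(nExtra, length(pool)))
  deIds <- c(targetIds, deExtra)
  # balance up/down within each transition so the per-stage expression
  # totals stay level and planted fold changes are not attenuated by the
  # compositional normalizer
  grid <- expand.grid(dir = c(1L, -1L), trans = seq_len(S - 1L))
  slots <- grid[rep(seq_len(nrow(grid)),
                    length.out = length(deExtra)), , drop = FALSE]
  slots <- slots[sample(nrow(slots)), , drop = FALSE]
  deDir <- c(targetRows$direction, slots$dir)
  deTrans <- c(targetRows$transition, slots$trans)
  pool <- setdiff(pool, deExtra)
  editIds <- sample(pool, min(nEdits, length(pool)))
  pool <- setdiff(pool, editIds)
  lowIds <- sample(pool, min(nLow, length(pool)))
  nullIds <- setdiff(pool, lowIds)

  # stage-level expression (RPM-scale levels, normalized later) -----------
  level <- matrix(0, M, S, dimnames = list(own$id, stagesL))
  level[nullIds, ] <- pmin(pmax(rlnorm(length(nullIds), log(500), 1.6),
                                1.5), 40000)
  level[lowIds, ] <- 0.4
  level[editIds, ] <- runif(length(editIds), 200, 2000)
  for (k in seq_along(deIds)) {
    base <- 10^runif(1L, log10(500), log10(3000))
    prof <- rep(base, S)
    later <- (deTrans[k] + 1L):S
    prof[later] <- if (deDir[k] > 0) base * deFold else base / deFold
    level[deIds[k], ] <- prof
  }
  clIdx <- which(isCluster)
  if (length(clIdx)) {
    shapeA <- if (S == 4L) c(1, 1.7, 2.6, 0.9) else seq(1, 2.5, length.out = S)
    shapeB <- if (S == 4L) c(2.2, 1.5, 0.9, 0.45) else seq(2.5, 1, length.out = S)
    half <- ceiling(length(clIdx) / 2)
    for (j in seq_along(clIdx)) {
      base <- 10^runif(1L, log10(250), log10(8000))
      shape <- if (j <= half) shapeA else shapeB
      level[clIdx[j], ] <- base * shape * exp(rnorm(S, 0, 0.08))
    }
  }
  level[sentinel, ] <- 0  # handled as a fixed absolute share

  ent <- .homologEntities(bundle@registry)
  H <- nrow(ent)
  hLevel <- matrix(rep(pmin(rlnorm(H, log(40), 1.2), 2000), S), H, S,
                   dimnames = list(ent$name, stagesL))
  if (H >= 3L) {
    hi <- sample(H, 3L)
    hLevel[hi, ] <- runif(3L, 1200, 3000)
  }

  # editing events ---------------------------------------------------------
  win <- .armWindows(own, preOwn)
  winByLen <- split(win$seq, nchar(win$seq))
  edits <- list()
  for (id in editIds) {
    mseq <- own$sequence[match(id, own$id)]
    repeat {
      pos <- sample(3:(nchar(mseq) - 3L), 1L)
      from <- substr(mseq, pos, pos)
      to <- sample(setdiff(BASES, from), 1L)
      eseq <- mseq
      substr(eseq, pos, pos) <- to
      w <- winByLen[[as.character(nchar(eseq))]]
      if (is.null(w) || min(.hammingToRef(w, eseq)) >= 1L) break
    }
    edits[[length(edits) + 1L]] <- data.frame(
      matureId = id, position = pos, from = from, to = to, rate = editRate,
      stringsAsFactors = FALSE)
  }
  edits <- if (length(edits)) do.call(rbind, edits) else
    data.frame(matureId = character(0), position = integer(0),
               from = character(0), to = character(0), rate = numeric(0))
  rate <- setNames(rep(0, M), own$id)
  rate[edits$matureId] <- edits$rate

  # per-library proportions with gamma replicate noise ---------------------
  L <- length(libs)
  gam <- function(n) if (phi > 0) rgamma(n, shape = 1 / phi, rate = 1 / phi) else rep(1, n)
  gOwn <- matrix(gam(M * L), M, L, dimnames = list(own$id, libs))
  gHom <- matrix(gam(max(H, 1L) * L), max(H, 1L), L)
  lv <- level[, match(stageOf, stagesL), drop = FALSE] * gOwn
  wOwn <- sweep(lv, 2, colSums(lv), "/")
  hv <- hLevel[, match(stageOf, stagesL), drop = FALSE] * gHom[seq_len(H), , drop = FALSE]
  wHom <- if (H) sweep(hv, 2, colSums(hv), "/") else hv

  mappedOther <- sum(fractions[c("repeat", "exon", "novel", "decoy", "background")])
  frMir <- fractions[["mirna"]]
  pS <- 0.0075
  for (it in 1:4) {
    pOwn <- (frMir - pS) * wOwn
    fMap <- pS + colSums(pOwn * (1 - rate[own$id])) + mappedOther
    pS <- 10000 * mean(fMap) / 1e6
  }
  pOwn <- (frMir - pS) * wOwn
  pOwn[sentinel, ] <- pS
  fMap <- colSums(pOwn * (1 - rate[own$id])) + mappedOther
  pHom <- fractions[["homolog"]] * wHom
  proportions <- rbind(pOwn, pHom)
  dimnames(proportions) <- list(c(own$id, ent$name), libs)
  names(fMap) <- libs

  # stage-level expected RPM (no replicate noise) --------------------------
  wBar <- sweep(level, 2, colSums(level), "/")
  pBar <- (frMir - pS) * wBar
  pBar[sentinel, ] <- pS
  fBar <- colSums(pBar * (1 - rate[own$id])) + mappedOther
  rpmOwn <- sweep(pBar, 2, fBar, "/") * 1e6
  wHBar <- if (H) sweep(hLevel, 2, colSums(hLevel), "/") else hLevel
  rpmHom <- if (H) sweep(fractions[["homolog"]] * wHBar, 2, fBar, "/") * 1e6 else wHBar
  stageRPM <- rbind(rpmOwn, rpmHom)

  # derived DE truth --------------------------------------------------------
  comps <- .comparisonLabels(stagesL)
  deRows <- list()
  for (cmp in comps) {
    ab <- strsplit(cmp, "_vs_")[[1]]
    lfc <- log2(stageRPM[, ab[2]] / stageRPM[, ab[1]])
    keep <- which(is.finite(lfc) & abs(lfc) >= 1)
    if (!length(keep)) next
    ids <- rownames(stageRPM)[keep]
    src <- ifelse(ids %in% deIds, "designed",
                  ifelse(ids %in% own$id[isCluster], "cluster", "other"))
    deRows[[cmp]] <- data.frame(matureId = ids, comparison = cmp,
                                log2fc = unname(lfc[keep]), source = src,
                                stringsAsFactors = FALSE)
  }
  de <- if (length(deRows)) do.call(rbind, c(deRows, make.row.names = FALSE)) else
    data.frame(matureId = character(0), comparison = character(0),
               log2fc = numeric(0), source = character(0))

  novel <- planted[planted$kind == "novel", , drop = FALSE]
  if (nrow(novel)) {
    shares <- table(novel$name)
    shares <- shares / sum(shares)
    novel$readShare <- as.numeric(shares[novel$name] / as.numeric(table(novel$name)[novel$name]))
    # readShare is per locus; a duplicated hairpin splits its name share
    # evenly over its genomic copies at read-generation time.
  } else novel$readShare <- numeric(0)

  new("TruthTable",
      stageRPM = stageRPM, proportions = proportions,
      isomir = list(p5 = c(`-2` = 0.05, `-1` = 0.15, `0` = 0.6,
                           `1` = 0.15, `2` = 0.05),
                    p3 = c(`-2` = 0.05, `-1` = 0.15, `0` = 0.6,
                           `1` = 0.15, `2` = 0.05)),
      edits = edits, de = de,
      novel = novel[, c("name", "chrom", "start", "end", "strand",
                        "matureSeq", "starSeq", "precursorSeq", "readShare")],
      fractions = fractions, mappedFraction = unname(fMap),
      sentinel = sentinel)
}
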