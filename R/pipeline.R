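#' Run the full miRNAome pipeline
#'
#' Executes every analysis stage on raw reads (simulated in-memory or
#' read from FASTQ): QC filtering, tag collapsing, hierarchical
#' annotation, expression quantification with tiers, descriptive
#' summaries (stage means, correlations, genomic clusters, heatmap
#' ordering), pairwise differential expression, temporal model-profile
#' clustering of DE miRNAs, novel-miRNA discovery and (optionally)
#' target prediction with anti-correlation filtering and gene-set
#' enrichment.
#'
#' @param bundle a [ReferenceBundle].
#' @param design a [StudyDesign].
#' @param reads named list (per library) of lists with `sequences` and
#'   `qualities`; `NULL` simulates them from `truth`.
#' @param truth a [TruthTable]; required when `reads` is `NULL`.
#' @param seed integer seed for simulation and shuffle p-values.
#' @param params QC parameters; adapters default to the design's.
#' @param clusterWindow,clusterMinSize,clusterMinRPM genomic-cluster
#'   detection settings.
#' @param runTargets logical; run the target-prediction stage.
#' @param novelShuffles shuffle count for novel candidate p-values.
#' @param phi common NB dispersion; `NULL` estimates it from replicates.
#' @return A list with elements `qc`, `tags`, `annotation`,
#'   `categorySummary`, `experiment`, `tiers`, `abundance`,
#'   `correlations`, `clusters`, `heatmap`, `de`, `venn`, `profiles`,
#'   `novel`, `targets`, `classCounts`.
#' @export
runPipeline <- function(bundle, design, reads = NULL, truth = NULL,
                        seed = 1L, params = NULL,
                        clusterWindow = 100000L, clusterMinSize = 3L,
                        clusterMinRPM = 100, runTargets = TRUE,
                        novelShuffles = 100L, phi = NULL) {
  if (is.null(params))
    params <- qcParams(adapter3 = design@adapter3,
                       adapter5 = design@adapter5)
  classCounts <- NULL
  if (is.null(reads)) {
    stopifnot(!is.null(truth))
    sim <- simulateLibraries(bundle, design, truth, seed)
    reads <- sim$libraries
    classCounts <- sim$classCounts
  }
  libs <- names(reads)

  qc <- vector("list", length(libs))
  names(qc) <- libs
  inserts <- vector("list", length(libs))
  names(inserts) <- libs
  for (l in libs) {
    f <- filterReads(reads[[l]]$sequences, reads[[l]]$qualities, params)
    qc[[l]] <- qcSummary(f)
    inserts[[l]] <- f$insert[f$keep]
  }
  tags <- collapseReads(inserts)

  annot <- classifyTags(tags, bundle)
  catSum <- categorySummary(annot, tags)

  x <- buildExpressionMatrix(annot, tags, design, bundle@registry)
  tiers <- filterAndTier(x)
  abundance <- summarizeAbundance(x, tiers)
  correlations <- pairwiseCorrelation(x, tiers)
  clusters <- detectGenomicClusters(bundle@registry, tiers,
                                    window = clusterWindow,
                                    minSize = clusterMinSize,
                                    minRPM = clusterMinRPM)
  heatmap <- NULL
  if (nrow(clusters)) {
    big <- clusters[which.max(clusters$n), ]
    members <- strsplit(big$members, ",")[[1]]
    traj <- stageTrajectories(x, intersect(members, rownames(x)))
    if (nrow(traj) >= 2L) heatmap <- hierarchicalOrder(traj)
  }

  de <- callDE(x, tiers, phi = phi)
  stageLevels <- stages(design)
  prenatal <- .comparisonLabels(stageLevels[-length(stageLevels)])
  vsNeonatal <- sprintf("%s_vs_%s", stageLevels[-length(stageLevels)],
                        stageLevels[length(stageLevels)])
  venn <- list(prenatal = vennPartition(de, prenatal),
               neonatal = vennPartition(de, vsNeonatal))

  deIds <- sort(unique(de$id[de$call != "ns"]))
  profiles <- NULL
  if (length(deIds) >= 2L) {
    prof <- enumerateProfiles(length(stageLevels), 1L, 30L)
    traj <- stageTrajectories(x, deIds)
    profiles <- list(profiles = prof,
                     assignments = assignProfiles(traj, prof),
                     significance = profileSignificance(traj, prof))
  }

  novel <- findNovelMiRNAs(annot, tags, bundle@genome,
                           shuffles = novelShuffles, seed = seed)

  targets <- NULL
  if (runTargets) {
    focus <- intersect(deIds, tiers$id[tiers$overallRPM > clusterMinRPM &
                                         tiers$type == "known"])
    if (length(focus)) {
      mseqs <- setNames(
        matureArms(bundle@registry, ownOnly = TRUE)$sequence,
        matureArms(bundle@registry, ownOnly = TRUE)$id)[focus]
      pred <- predictTargets(mseqs, bundle@utrs)
      filtered <- list()
      for (cmp in unique(de$comparison)) {
        filtered[[cmp]] <- anticorrelationFilter(
          pred$pairs, de, bundle@mrnaFC, cmp, tiers)
      }
      allGenes <- sort(unique(unlist(lapply(filtered, function(d) d$gene))))
      enrichment <- enrichGeneSets(allGenes, names(bundle@utrs),
                                   bundle@geneSets)
      targets <- list(predicted = pred, filtered = filtered,
                      enrichment = enrichment)
    }
  }

  list(qc = qc, tags = tags, annotation = annot, categorySummary = catSum,
       experiment = x, tiers = tiers, abundance = abundance,
       correlations = correlations, clusters = clusters, heatmap = heatmap,
       de = de, venn = venn, profiles = profiles, novel = novel,
       targets = targets, classCounts = classCounts)
}
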