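#' Enumerate model profiles for short time series
#'
#' Generates all integer template trajectories of length `T` that start
#' at 0 with successive differences in `[-c, c]` — `(2c+1)^(T-1)`
#' candidates. When more than `m` exist, `m` maximally distinct profiles
#' are kept by greedy max-min Euclidean selection seeded from the flat
#' profile (ties by lower profile id).
#'
#' @param T number of stages (>= 2).
#' @param c maximum unit change between consecutive stages.
#' @param m maximum number of profiles retained.
#' @return A data.frame with `id` (0-based enumeration order) and one
#'   `v1..vT` column per stage.
#' @examples
#' nrow(enumerateProfiles(4, 1, 30))  # all 27 kept
#' @export
enumerateProfiles <- function(T, c = 1L, m = 30L) {
  stopifnot(T >= 2L, c >= 1L, m >= 1L)
  steps <- expand.grid(rep(list(seq(-c, c)), T - 1L))
  cs <- apply(steps, 1L, cumsum)
  cs <- if (is.null(dim(cs))) matrix(cs, ncol = 1L) else t(cs)
  vals <- cbind(0L, cs)
  colnames(vals) <- paste0("v", seq_len(T))
  ord <- do.call(order, as.data.frame(vals))
  vals <- vals[ord, , drop = FALSE]
  prof <- data.frame(id = seq_len(nrow(vals)) - 1L, vals)
  if (nrow(prof) <= m) return(prof)
  flat <- which(rowSums(abs(vals)) == 0)[1]
  chosen <- flat
  d <- as.matrix(dist(vals))
  while (length(chosen) < m) {
    minD <- apply(d[, chosen, drop = FALSE], 1L, min)
    minD[chosen] <- -Inf
    chosen <- c(chosen, which.max(minD))
  }
  out <- prof[sort(chosen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign miRNA trajectories to model profiles
#'
#' Each trajectory (stage means of log2(RPM + 1)) is assigned to the
#' profile maximizing the Pearson correlation; flat trajectories, for
#' which r is undefined, go to the flat profile. Ties break by lower
#' profile id. Assignment is invariant to positive affine transforms of
#' a trajectory.
#'
#' @param trajectories numeric matrix (miRNA x stage).
#' @param profiles a data.frame from [enumerateProfiles()].
#' @return A data.frame: `id`, `profile`, `correlation`.
#' @export
assignProfiles <- function(trajectories, profiles) {
  pv <- as.matrix(profiles[, -1, drop = FALSE])
  stopifnot(ncol(trajectories) == ncol(pv))
  flatProfile <- profiles$id[rowSums(abs(pv)) == 0][1]
  tSd <- apply(trajectories, 1L, stats::sd)
  pSd <- apply(pv, 1L, stats::sd)
  cc <- suppressWarnings(cor(t(trajectories), t(pv)))
  cc[, pSd == 0] <- -Inf
  best <- apply(cc, 1L, which.max)
  r <- cc[cbind(seq_len(nrow(cc)), best)]
  prof <- profiles$id[best]
  flat <- tSd == 0
  if (any(flat)) {
    prof[flat] <- flatProfile
    r[flat] <- NA_real_
  }
  data.frame(id = rownames(trajectories), profile = prof, correlation = r,
             stringsAsFactors = FALSE)
}

#' Permutation significance of profile assignment counts
#'
#' The expected count of each profile is estimated by re-assigning every
#' trajectory under all `T!` stage-order permutations and averaging. The
#' p-value is the upper-tail binomial probability of observing at least
#' the actual count given `n` trials with success probability
#' `expected / n`, Bonferroni-corrected over the retained profiles;
#' profiles are significant at corrected p < `alpha`.
#'
#' @param trajectories numeric matrix (miRNA x stage).
#' @param profiles a data.frame from [enumerateProfiles()].
#' @param alpha significance level after correction.
#' @return A data.frame per profile: `profile`, `count`, `expected`,
#'   `pvalue`, `corrected`, `significant`.
#' @export
profileSignificance <- function(trajectories, profiles, alpha = 0.05) {
  n <- nrow(trajectories)
  if (n == 0L) {
    return(data.frame(profile = integer(0), count = integer(0),
                      expected = numeric(0), pvalue = numeric(0),
                      corrected = numeric(0), significant = logical(0)))
  }
  T <- ncol(trajectories)
  perms <- .permutations(T)
  obs <- assignProfiles(trajectories, profiles)
  counts <- table(factor(obs$profile, levels = profiles$id))
  expCounts <- rep(0, nrow(profiles))
  for (k in seq_len(nrow(perms))) {
    pa <- assignProfiles(trajectories[, perms[k, ], drop = FALSE], profiles)
    expCounts <- expCounts +
      as.numeric(table(factor(pa$profile, levels = profiles$id)))
  }
  expCounts <- expCounts / nrow(perms)
  p <- pbinom(as.numeric(counts) - 1L, n, pmin(expCounts / n, 1),
              lower.tail = FALSE)
  corrected <- pmin(p * nrow(profiles), 1)
  data.frame(profile = profiles$id, count = as.integer(counts),
             expected = expCounts, pvalue = p, corrected = corrected,
             significant = corrected < alpha)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Stage-mean log2 trajectories of a MiRNAExperiment
#'
#' @param x a [MiRNAExperiment].
#' @param ids rows to include (default all).
#' @return Matrix of per-stage means of log2(RPM + 1).
#' @export
stageTrajectories <- function(x, ids = rownames(x)) {
  r <- log2(rpm(x)[ids, , drop = FALSE] + 1)
  stage <- stages(x)
  stageLevels <- unique(stage)
  out <- vapply(stageLevels, function(s)
    rowMeans(r[, stage == s, drop = FALSE]), numeric(length(ids)))
  if (length(ids) == 1L) out <- matrix(out, 1L, dimnames = list(ids, stageLevels))
  out
}
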