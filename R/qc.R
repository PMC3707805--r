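# Marker and individual cleaning chain: Tukey IBS outlier/relatedness
# screening within subpopulations, per-subpopulation missingness filter,
# exact Hardy-Weinberg filter with Bonferroni correction, and greedy
# Kendall tau-b LD pruning. Stage order is fixed:
# individual outliers -> missingness -> HWE -> LD.

.siteMembers <- function(gm, sites) {
  a <- siteAssignment(sites)
  ids <- individualIds(gm)
  bad <- setdiff(ids, names(a))
  if (length(bad)) stop("individual(s) without site assignment: ",
                        paste(head(bad, 5L), collapse = ", "))
  split(ids, a[ids])
}

#' Tukey IBS screening for genetic outliers and related pairs
#'
#' Within each subpopulation, all pairwise IBS distances are pooled. An
#' individual is flagged as a genetic outlier when the median of its
#' distances to the other members exceeds Q3 + k IQR of the pool; a pair is
#' flagged as related when its distance falls below Q1 - k IQR, in which
#' case the member with the higher missing-genotype rate (ties: the
#' lexicographically larger id) is excluded. Subpopulations with fewer than
#' 3 members are skipped with a message.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param sites a \linkS4class{SiteTable} assigning every individual
#' @param k Tukey multiplier (1.5 by default)
#' @return data.frame with columns \code{id}, \code{reason}
#'   (\code{"outlier"} or \code{"related"}) and \code{site}; zero rows when
#'   nothing is flagged.
#' @export
tukeyIbsOutliers <- function(gm, sites, k = 1.5) {
  members <- .siteMembers(gm, sites)
  g <- genotypeCalls(gm)
  missRate <- colMeans(is.na(g))
  out <- list()
  for (site in names(members)) {
    ids <- members[[site]]
    if (length(ids) < 3L) {
      message("subpopulation ", site, " has < 3 individuals; Tukey screen skipped")
      next
    }
    d <- pairValues(ibsDistance(gm[, ids]))
    pool <- d[upper.tri(d)]
    q <- quantile(pool, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2L] - q[1L]
    hi <- q[2L] + k * iqr
    lo <- q[1L] - k * iqr
    med <- apply(d + diag(NA_real_, length(ids)), 1L, median, na.rm = TRUE)
    for (id in ids[med > hi])
      out[[length(out) + 1L]] <- data.frame(id = id, reason = "outlier",
                                            site = site)
    rel <- which(d < lo & upper.tri(d), arr.ind = TRUE)
    if (nrow(rel)) {
      for (r in seq_len(nrow(rel))) {
        a <- ids[rel[r, 1L]]; b <- ids[rel[r, 2L]]
        drop <- if (missRate[a] > missRate[b]) a
                else if (missRate[b] > missRate[a]) b
                else max(a, b)
        out[[length(out) + 1L]] <- data.frame(id = drop, reason = "related",
                                              site = site)
      }
    }
  }
  if (!length(out))
    return(data.frame(id = character(), reason = character(),
                      site = character()))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Per-subpopulation missingness filter
#'
#' A SNP is removed when its missing-genotype rate is strictly greater than
#' \code{maxRate} in at least one subpopulation.
#'
#' @inheritParams tukeyIbsOutliers
#' @param maxRate maximum tolerated per-subpopulation missing rate (0.10)
#' @return character vector of kept SNP ids.
#' @export
missingnessFilter <- function(gm, sites, maxRate = 0.10) {
  members <- .siteMembers(gm, sites)
  g <- genotypeCalls(gm)
  bad <- rep(FALSE, nrow(g))
  for (ids in members) {
    rate <- rowMeans(is.na(g[, ids, drop = FALSE]))
    bad <- bad | rate > maxRate
  }
  markerMap(gm)$id[!bad]
}

#' Exact Hardy-Weinberg test probability
#'
#' Conditional exact test: the probability of each possible heterozygote
#' count given the observed allele counts is enumerated, and the p-value is
#' the total probability of outcomes no more likely than the observed one.
#' Monomorphic samples return 1.
#'
#' @param nAA,nAB,nBB genotype counts
#' @return exact two-sided p-value in (0, 1].
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n == 0L) return(1)
  nA <- 2L * nAA + nAB
  nB <- 2L * nBB + nAB
  if (nA == 0L || nB == 0L) return(1)
  hets <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  pObs <- p[match(nAB, hets)]
  sum(p[p <= pObs * (1 + 1e-12)])
}

#' Per-subpopulation exact HWE filter
#'
#' Tests every SNP in every subpopulation with the conditional exact test;
#' a SNP is removed when any subpopulation shows
#' p < alpha / (n_snps x n_subpops) (Bonferroni).
#'
#' @inheritParams tukeyIbsOutliers
#' @param alpha family-wise significance level (0.05)
#' @param correction multiple-testing correction; only \code{"bonferroni"}
#' @return character vector of kept SNP ids.
#' @export
hweFilter <- function(gm, sites, alpha = 0.05,
                      correction = c("bonferroni")) {
  correction <- match.arg(correction)
  members <- .siteMembers(gm, sites)
  g <- genotypeCalls(gm)
  thr <- alpha / (nrow(g) * length(members))
  bad <- rep(FALSE, nrow(g))
  memo <- new.env(parent = emptyenv())
  for (ids in members) {
    sub <- g[, ids, drop = FALSE]
    nAA <- rowSums(sub == 0L, na.rm = TRUE)
    nAB <- rowSums(sub == 1L, na.rm = TRUE)
    nBB <- rowSums(sub == 2L, na.rm = TRUE)
    for (s in which(!bad)) {
      key <- paste(nAA[s], nAB[s], nBB[s])
      p <- memo[[key]]
      if (is.null(p)) {
        p <- hweExactTest(nAA[s], nAB[s], nBB[s])
        memo[[key]] <- p
      }
      if (p < thr) bad[s] <- TRUE
    }
  }
  markerMap(gm)$id[!bad]
}

#' Kendall's tau-b between two genotype vectors
#'
#' Computed from the 3x3 genotype contingency table with tie correction,
#' in O(n). Pairs with a missing value in either vector are dropped;
#' if no pairs remain or either vector is constant the statistic is
#' undefined and \code{NA} is returned.
#'
#' @param x,y integer dosage vectors of equal length (0/1/2/NA)
#' @return tau-b in [-1, 1], or \code{NA}.
#' @export
kendallTauB <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  nr <- nrow(tab); nc <- ncol(tab)
  if (nr < 2L || nc < 2L) return(NA_real_)
  conc <- disc <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nij <- tab[i, j]
    if (nij == 0) next
    if (i < nr && j < nc)
      conc <- conc + nij * sum(tab[(i + 1):nr, (j + 1):nc])
    if (i < nr && j > 1L)
      disc <- disc + nij * sum(tab[(i + 1):nr, 1:(j - 1)])
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(rowSums(tab) * (rowSums(tab) - 1) / 2)
  n2 <- sum(colSums(tab) * (colSums(tab) - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

#' Greedy LD pruning by Kendall's tau-b
#'
#' Scans markers in map order (chromosome, position). A marker is kept iff
#' |tau-b| with every already-kept marker within \code{windowBp} on the
#' same chromosome is strictly below \code{tauMax}. Undefined tau
#' (monomorphic comparisons) does not block a marker.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param windowBp comparison window in bp (500 kb)
#' @param tauMax exclusion threshold on |tau-b| (0.5)
#' @return character vector of kept SNP ids, in map order.
#' @export
ldPrune <- function(gm, windowBp = 500000L, tauMax = 0.5) {
  map <- markerMap(gm)
  g <- genotypeCalls(gm)
  kept <- logical(nrow(map))
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)      # already position-sorted
    keptPos <- integer(0)
    keptIdx <- integer(0)
    for (s in idx) {
      lo <- map$position[s] - windowBp
      first <- findInterval(lo, keptPos) + 1L
      inWin <- if (first <= length(keptIdx))
        keptIdx[first:length(keptIdx)] else integer(0)
      # window is symmetric, but earlier markers are all upstream
      ok <- TRUE
      for (t in inWin) {
        if (map$position[s] - map$position[t] >= windowBp) next
        tau <- kendallTauB(g[s, ], g[t, ])
        if (!is.na(tau) && abs(tau) >= tauMax) { ok <- FALSE; break }
      }
      if (ok) {
        kept[s] <- TRUE
        keptPos <- c(keptPos, map$position[s])
        keptIdx <- c(keptIdx, s)
      }
    }
  }
  map$id[kept]
}

#' Run the full QC chain
#'
#' Applies, in fixed order: Tukey IBS individual screening, the
#' per-subpopulation missingness filter, the exact HWE filter, and LD
#' pruning; returns the cleaned matrix together with a report of what was
#' excluded at each stage.
#'
#' @inheritParams tukeyIbsOutliers
#' @param maxMissing per-subpopulation missing-rate ceiling (0.10)
#' @param hweAlpha family-wise alpha for the HWE filter (0.05)
#' @param ldWindowBp LD window (500 kb); set \code{NULL} to skip pruning
#' @param ldTauMax LD threshold on |tau-b| (0.5)
#' @return list with \code{genotypes} (cleaned
#'   \linkS4class{GenotypeMatrix}), \code{excludedIndividuals},
#'   \code{excludedSnps} (data.frames with id + reason) and \code{counts}
#'   (per-stage bookkeeping).
#' @export
runQc <- function(gm, sites, k = 1.5, maxMissing = 0.10, hweAlpha = 0.05,
                  ldWindowBp = 500000L, ldTauMax = 0.5) {
  counts <- list(individualsIn = nIndividuals(gm), snpsIn = nMarkers(gm))
  flags <- tukeyIbsOutliers(gm, sites, k = k)
  keepInd <- setdiff(individualIds(gm), flags$id)
  gm1 <- gm[, keepInd]
  counts$individualsExcluded <- nrow(flags)

  keptMiss <- missingnessFilter(gm1, sites, maxRate = maxMissing)
  excl <- list()
  dropMiss <- setdiff(markerMap(gm1)$id, keptMiss)
  if (length(dropMiss))
    excl$miss <- data.frame(id = dropMiss, reason = "missingness")
  gm2 <- gm1[keptMiss, ]
  counts$snpsAfterMissingness <- nMarkers(gm2)

  keptHwe <- hweFilter(gm2, sites, alpha = hweAlpha)
  dropHwe <- setdiff(markerMap(gm2)$id, keptHwe)
  if (length(dropHwe))
    excl$hwe <- data.frame(id = dropHwe, reason = "hwe")
  gm3 <- gm2[keptHwe, ]
  counts$snpsAfterHwe <- nMarkers(gm3)

  if (!is.null(ldWindowBp)) {
    keptLd <- ldPrune(gm3, windowBp = ldWindowBp, tauMax = ldTauMax)
    dropLd <- setdiff(markerMap(gm3)$id, keptLd)
    if (length(dropLd))
      excl$ld <- data.frame(id = dropLd, reason = "ld")
    gm4 <- gm3[keptLd, ]
  } else gm4 <- gm3
  counts$snpsOut <- nMarkers(gm4)
  counts$individualsOut <- nIndividuals(gm4)

  excludedSnps <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(), reason = character())
  rownames(excludedSnps) <- NULL
  list(genotypes = gm4,
       excludedIndividuals = flags,
       excludedSnps = excludedSnps,
       counts = counts)
}
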