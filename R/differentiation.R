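# Weir-Cockerham Fst (per SNP and combined pairwise) and AMOVA under an
# external grouping of subpopulations.

# Variance components a (among populations), b (among individuals within
# populations), c (within individuals) of the Weir-Cockerham theta
# estimator, vectorized over SNPs. Inputs are pop x snp matrices of
# genotype counts. Returns per-SNP a, b, c; SNPs informative in fewer
# than 2 populations yield NA.
.wcComponents <- function(nAA, nAB, nBB) {
  ni <- nAA + nAB + nBB                     # pop x snp sample sizes
  use <- ni > 0
  r <- colSums(use)
  niz <- ifelse(use, ni, 0)
  pi <- ifelse(use, (2 * nAA + nAB) / (2 * pmax(ni, 1L)), 0)
  hi <- ifelse(use, nAB / pmax(ni, 1L), 0)
  nTot <- colSums(niz)
  nbar <- nTot / r
  nc <- (nTot - colSums(niz^2) / nTot) / (r - 1)
  pbar <- colSums(niz * pi) / nTot
  s2 <- colSums(niz * (pi - rep(pbar, each = nrow(ni)))^2) /
    ((r - 1) * nbar)
  hbar <- colSums(niz * hi) / nTot
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  badSnp <- r < 2 | nbar <= 1 | nc <= 0
  a[badSnp] <- b[badSnp] <- cc[badSnp] <- NA_real_
  list(a = a, b = b, c = cc)
}

.genotypeCountsByPop <- function(gm, sites, pops) {
  members <- .siteMembers(gm, sites)
  members <- members[intersect(pops, names(members))]
  g <- genotypeCalls(gm)
  count <- function(code) do.call(rbind, lapply(members, function(ids)
    rowSums(g[, ids, drop = FALSE] == code, na.rm = TRUE)))
  list(nAA = count(0L), nAB = count(1L), nBB = count(2L),
       pops = names(members))
}

#' Weir-Cockerham Fst: per SNP and combined between subpopulation pairs
#'
#' Per-SNP theta is estimated over all included subpopulations by the
#' Weir-Cockerham variance-components estimator (negative estimates kept).
#' The combined Fst between each pair of subpopulations is the ratio of
#' summed numerator components to summed total components across SNPs
#' (SNPs monomorphic in both members contribute nothing); negative
#' combined values are clamped to 0 in the pairwise matrix only. Pairwise
#' values are computed only for subpopulations meeting the size floor.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param sites a \linkS4class{SiteTable}
#' @param pops subset of site codes to include (default all assigned)
#' @param minSize pairwise size floor: subpopulations with at least this
#'   many individuals enter the pairwise matrix (default 10)
#' @return list with \code{perSnpTheta} (named per-SNP estimates over
#'   \code{pops}), \code{pairwise} (\linkS4class{PairMatrix} of kind
#'   \code{"fst"} over the floored subpopulations), \code{clampedCount}
#'   (negative pairwise values set to 0) and \code{pairwisePops}.
#' @export
wcFst <- function(gm, sites, pops = NULL, minSize = 10L) {
  members <- .siteMembers(gm, sites)
  if (is.null(pops)) pops <- names(members)
  stopifnot(length(pops) >= 2L)
  cnt <- .genotypeCountsByPop(gm, sites, pops)
  comp <- .wcComponents(cnt$nAA, cnt$nAB, cnt$nBB)
  tot <- comp$a + comp$b + comp$c
  theta <- ifelse(is.na(tot) | tot == 0, NA_real_, comp$a / tot)
  names(theta) <- markerMap(gm)$id

  sizes <- vapply(members[cnt$pops], length, integer(1))
  big <- cnt$pops[sizes >= minSize]
  fst <- matrix(0, length(big), length(big), dimnames = list(big, big))
  clamped <- 0L
  if (length(big) >= 2L) {
    for (i in seq_len(length(big) - 1L)) for (j in (i + 1L):length(big)) {
      sel <- match(c(big[i], big[j]), cnt$pops)
      pc <- .wcComponents(cnt$nAA[sel, , drop = FALSE],
                          cnt$nAB[sel, , drop = FALSE],
                          cnt$nBB[sel, , drop = FALSE])
      ptot <- pc$a + pc$b + pc$c
      ok <- !is.na(ptot) & ptot != 0
      val <- if (any(ok)) sum(pc$a[ok]) / sum(ptot[ok]) else 0
      if (val < 0) { val <- 0; clamped <- clamped + 1L }
      fst[i, j] <- fst[j, i] <- val
    }
  }
  list(perSnpTheta = theta,
       pairwise = PairMatrix(fst, "fst", big),
       clampedCount = clamped,
       pairwisePops = big)
}

#' Analysis of molecular variance (AMOVA) under a site grouping
#'
#' Partitions genetic variance into among-group, among-subpopulation-
#' within-group, and within-subpopulation components from squared
#' Euclidean distances on genotype dosages (missing calls handled by
#' rescaling over jointly typed SNPs). Significance of the among-group
#' component is assessed by permuting sites among groups; of the
#' among-subpopulation component by permuting individuals among
#' subpopulations within their group.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param sites a \linkS4class{SiteTable}
#' @param groups named character vector: site code -> group label; every
#'   assigned site must be present
#' @param nPerm permutations per tested level (default 1000)
#' @param seed RNG seed
#' @return list with \code{components} (named variance components),
#'   \code{percent} (percentage of total per level; negative components
#'   are reported as-is and flagged), \code{phi} (phi-statistics),
#'   \code{p} (permutation p per tested level), \code{negativeComponents}
#'   flag and \code{degenerateGroups} flag (some group has a single site).
#' @export
amova <- function(gm, sites, groups, nPerm = 1000L, seed = 1L) {
  members <- .siteMembers(gm, sites)
  popOf <- siteAssignment(sites)[individualIds(gm)]
  missingGroups <- setdiff(unique(popOf), names(groups))
  if (length(missingGroups))
    stop("site(s) without group: ", paste(missingGroups, collapse = ", "))
  D <- pairValues(d2Distance(gm)) * nMarkers(gm)  # squared Euclidean scale
  if (anyNA(D)) stop("pairs with no jointly typed SNPs; run QC first")

  calc <- function(popOf, groupOfPop) {
    grpOf <- groupOfPop[popOf]
    N <- length(popOf)
    ssOf <- function(idx) if (length(idx) < 2L) 0 else
      sum(D[idx, idx]) / (2 * length(idx))
    ssTotal <- ssOf(seq_len(N))
    popsIdx <- split(seq_len(N), popOf)
    grpIdx <- split(seq_len(N), grpOf)
    ssWP <- sum(vapply(popsIdx, ssOf, numeric(1)))
    ssWG <- sum(vapply(grpIdx, ssOf, numeric(1)))
    ssAP <- ssWG - ssWP
    ssAG <- ssTotal - ssWG
    P <- length(popsIdx); G <- length(grpIdx)
    dfA <- G - 1; dfB <- P - G; dfC <- N - P
    np <- vapply(popsIdx, length, integer(1))
    grpOfPopNames <- groupOfPop[names(popsIdx)]
    Sg <- vapply(split(np, grpOfPopNames), function(x) sum(x^2), numeric(1))
    Ng <- vapply(grpIdx, length, integer(1))
    Ng <- Ng[names(Sg)]
    nPrime <- (N - sum(Sg / Ng)) / max(dfB, 1)
    nDbl <- (sum(Sg / Ng) - sum(np^2) / N) / max(dfA, 1)
    nTrpl <- (N - sum(Ng^2) / N) / max(dfA, 1)
    sigC <- if (dfC > 0) ssWP / dfC else 0
    sigB <- if (dfB > 0 && nPrime > 0) (ssAP / dfB - sigC) / nPrime else 0
    sigA <- if (dfA > 0 && nTrpl > 0)
      (ssAG / dfA - sigC - nDbl * sigB) / nTrpl else 0
    c(a = sigA, b = sigB, c = sigC)
  }

  groupOfPop <- groups[names(members)]
  obs <- calc(popOf, groupOfPop)
  tot <- sum(obs)
  percent <- if (abs(tot) < 1e-300) c(a = 0, b = 0, c = 0) else
    100 * obs / tot
  phi <- c(phiCT = if (abs(tot) > 1e-300) obs[["a"]] / tot else 0,
           phiSC = if (abs(sum(obs[c("b", "c")])) > 1e-300)
             obs[["b"]] / sum(obs[c("b", "c")]) else 0,
           phiST = if (abs(tot) > 1e-300) sum(obs[c("a", "b")]) / tot else 0)

  degenerate <- any(table(groupOfPop) < 2L)
  pA <- pB <- NA_real_
  if (nPerm > 0L) {
    permA <- permB <- numeric(nPerm)
    .withSeed(.childSeed(seed, "amova"), {
      popNames <- names(groupOfPop)
      for (b in seq_len(nPerm)) {
        gPerm <- setNames(sample(unname(groupOfPop)), popNames)
        permA[b] <- calc(popOf, gPerm)[["a"]]
        # individuals among pops within groups
        popPerm <- popOf
        for (g in unique(unname(groupOfPop))) {
          idx <- which(groupOfPop[popOf] == g)
          popPerm[idx] <- sample(popOf[idx])
        }
        permB[b] <- calc(popPerm, groupOfPop)[["b"]]
      }
    })
    pA <- .permP(obs[["a"]], permA, "greater")
    pB <- .permP(obs[["b"]], permB, "greater")
  }
  list(components = obs, percent = percent, phi = phi,
       p = c(amongGroups = pA, amongPopsWithinGroups = pB,
             withinPops = NA_real_),
       negativeComponents = any(obs < 0),
       degenerateGroups = degenerate)
}
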