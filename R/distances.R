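# Pairwise relationship matrices: IBS distance, mean squared dosage
# difference (D2), the covariance derived from D2 by double centering, and
# normalized IBD segment sharing.

# Indicator decomposition of the dosage matrix; all pairwise accumulations
# reduce to a handful of crossproducts, so no per-pair loops.
.dosageIndicators <- function(gm) {
  g <- t(genotypeCalls(gm))          # individuals x markers
  x0 <- (!is.na(g) & g == 0L) * 1
  x1 <- (!is.na(g) & g == 1L) * 1
  x2 <- (!is.na(g) & g == 2L) * 1
  list(x0 = x0, x1 = x1, x2 = x2, m = x0 + x1 + x2)
}

.pairAccumulate <- function(ind) {
  hom <- tcrossprod(ind$x0, ind$x2)
  cross02 <- hom + t(hom)
  a <- tcrossprod(ind$x1, ind$x0 + ind$x2)
  adjacent <- a + t(a)
  list(cross02 = cross02, adjacent = adjacent,
       nJoint = tcrossprod(ind$m))
}

#' Identity-by-state distance between individuals
#'
#' For each pair, the IBS distance is one minus the mean proportion of
#' shared alleles over jointly typed SNPs. Allele sharing per SNP follows
#' the allele-count overlap convention: opposite homozygotes share 0
#' alleles, a homozygote and a heterozygote share 1, identical genotypes
#' (including het-het) share 2 — i.e. shared = 2 - |g_i - g_j|.
#'
#' @param gm a \linkS4class{GenotypeMatrix} with at least 2 individuals
#' @return A \linkS4class{PairMatrix} of kind \code{"distance"}; pairs with
#'   zero jointly typed SNPs get \code{NA} (with a message).
#' @export
ibsDistance <- function(gm) {
  stopifnot(nIndividuals(gm) >= 2L)
  acc <- .pairAccumulate(.dosageIndicators(gm))
  num <- 2 * acc$cross02 + acc$adjacent       # sum |g_i - g_j|
  d <- num / (2 * acc$nJoint)
  if (any(acc$nJoint == 0 & upper.tri(acc$nJoint))) {
    message("pair(s) with no jointly typed SNPs: distance set to NA")
    d[acc$nJoint == 0] <- NA
  }
  diag(d) <- 0
  PairMatrix(d, "distance", individualIds(gm))
}

#' Mean squared dosage difference between individuals
#'
#' \eqn{d^2_{ij} = \sum_s (G_{is} - G_{js})^2 / n_{ij}} where the sum and
#' the count \eqn{n_{ij}} run over SNPs jointly typed in both individuals.
#' This is the squared-distance input for \code{\link{covarianceFromD2}}.
#'
#' @inheritParams ibsDistance
#' @return A \linkS4class{PairMatrix} of kind \code{"distance"} holding the
#'   squared quantities (diagonal 0; \code{NA} for never-jointly-typed pairs).
#' @export
d2Distance <- function(gm) {
  stopifnot(nIndividuals(gm) >= 2L)
  acc <- .pairAccumulate(.dosageIndicators(gm))
  num <- 4 * acc$cross02 + acc$adjacent       # sum (g_i - g_j)^2
  d <- num / acc$nJoint
  if (any(acc$nJoint == 0 & upper.tri(acc$nJoint))) {
    message("pair(s) with no jointly typed SNPs: distance set to NA")
    d[acc$nJoint == 0] <- NA
  }
  diag(d) <- 0
  PairMatrix(d, "distance", individualIds(gm))
}

#' Genetic covariance from squared distances by double centering
#'
#' \eqn{c_{ij} = -\tfrac12 (d^2_{ij} - \bar d^2_{i.} - \bar d^2_{.j} +
#' \bar d^2_{..})}. For complete data this equals the centered genotype
#' Gram matrix divided by the SNP count; every row of the result sums to
#' zero.
#'
#' @param d2 a square symmetric zero-diagonal \linkS4class{PairMatrix} of
#'   squared distances (e.g. from \code{\link{d2Distance}})
#' @return A \linkS4class{PairMatrix} of kind \code{"covariance"}.
#' @export
covarianceFromD2 <- function(d2) {
  stopifnot(is(d2, "PairMatrix"))
  v <- pairValues(d2)
  if (anyNA(v)) stop("squared-distance matrix has NA cells; run QC first")
  rm <- rowMeans(v)
  cc <- -0.5 * (v - outer(rm, rep(1, length(rm))) -
                  outer(rep(1, length(rm)), rm) + mean(v))
  PairMatrix((cc + t(cc)) / 2, "covariance", pairLabels(d2))
}

#' Normalized IBD segment sharing (Gusev weighting)
#'
#' Each chromosome is partitioned into elementary intervals at the union of
#' all segment endpoints. An interval of length \eqn{l_s} covered by
#' \eqn{\pi_s} pairs gets weight \eqn{F(s) = l_s / \pi_s} (0 when
#' uncovered), so genome regions shared by many pairs count less. The
#' total \eqn{W_{tot} = \sum_s F(s)} is the maximum attainable sharing, and
#' each pair's sharing \eqn{W_{ij}} is the sum of \eqn{F} over the
#' intervals its segments cover, divided by \eqn{W_{tot}}; the associated
#' distance is \eqn{1 - W_{ij}}.
#'
#' @param segments an \linkS4class{IBDSegmentTable}
#' @param gm the \linkS4class{GenotypeMatrix} the segments refer to
#'   (individual ids and chromosome spans are validated against it)
#' @return list with \code{W} (named symmetric matrix of sharing values),
#'   \code{wTot}, \code{intervals} (data.frame of elementary intervals with
#'   lengths, pair counts and F), and \code{distance} (a
#'   \linkS4class{PairMatrix} of \eqn{1 - W_{ij}}).
#' @export
ibdSharing <- function(segments, gm) {
  stopifnot(is(segments, "IBDSegmentTable"), is(gm, "GenotypeMatrix"))
  seg <- ibdSegments(segments)
  ids <- individualIds(gm)
  map <- markerMap(gm)
  if (nrow(seg)) {
    bad <- setdiff(unique(c(seg$id_a, seg$id_b)), ids)
    if (length(bad)) stop("segment individual(s) not in genotype matrix: ",
                          paste(bad, collapse = ", "))
    for (ch in unique(seg$chromosome)) {
      pos <- map$position[map$chromosome == ch]
      if (!length(pos)) stop("segment chromosome not in marker map: ", ch)
      s <- seg[seg$chromosome == ch, ]
      if (any(s$start_bp < min(pos)) || any(s$end_bp > max(pos)))
        stop("segment outside marker span on chromosome ", ch)
    }
  }
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(seg) == 0L) {
    dval <- matrix(1, n, n, dimnames = list(ids, ids)); diag(dval) <- 0
    return(list(W = W, wTot = 0,
                intervals = data.frame(chromosome = character(),
                                       start_bp = integer(),
                                       end_bp = integer(),
                                       n_pairs = integer(), F = numeric()),
                distance = PairMatrix(dval, "distance", ids)))
  }
  pairKey <- paste(pmin(seg$id_a, seg$id_b), pmax(seg$id_a, seg$id_b),
                   sep = "\r")
  intervals <- list()
  pairF <- new.env(parent = emptyenv())
  for (ch in unique(seg$chromosome)) {
    sel <- seg$chromosome == ch
    s <- seg[sel, ]
    keys <- pairKey[sel]
    cuts <- sort(unique(c(s$start_bp, s$end_bp)))
    lo <- cuts[-length(cuts)]
    hi <- cuts[-1L]
    len <- hi - lo
    # coverage per elementary interval per pair (a pair counted once even
    # with overlapping duplicate records)
    covers <- vapply(seq_along(lo), function(k) {
      hit <- s$start_bp <= lo[k] & s$end_bp >= hi[k]
      length(unique(keys[hit]))
    }, integer(1))
    Fv <- ifelse(covers > 0, len / pmax(covers, 1L), 0)
    intervals[[ch]] <- data.frame(chromosome = ch, start_bp = lo,
                                  end_bp = hi, n_pairs = covers, F = Fv)
    for (key in unique(keys)) {
      hit <- keys == key
      covered <- vapply(seq_along(lo), function(k)
        any(s$start_bp[hit] <= lo[k] & s$end_bp[hit] >= hi[k]), logical(1))
      prev <- mget(key, envir = pairF, ifnotfound = 0)[[1L]]
      assign(key, prev + sum(Fv[covered]), envir = pairF)
    }
  }
  intervals <- do.call(rbind, intervals)
  rownames(intervals) <- NULL
  wTot <- sum(intervals$F)
  if (wTot > 0) {
    for (key in ls(pairF)) {
      pr <- strsplit(key, "\r", fixed = TRUE)[[1L]]
      W[pr[1L], pr[2L]] <- W[pr[2L], pr[1L]] <- get(key, envir = pairF) / wTot
    }
  }
  dval <- 1 - W
  diag(dval) <- 0
  list(W = W, wTot = wTot, intervals = intervals,
       distance = PairMatrix(dval, "distance", ids))
}
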