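# Spatial hypothesis tests: geodesic distances, the distance-class spatial
# autocorrelogram on the individual genetic covariance matrix with
# label-permutation significance and a combined P, the Mantel test, and the
# bearing correlogram that orients a cline.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix between sites
#'
#' Haversine distances on a spherical earth of radius 6371.0088 km.
#'
#' @param sites a \linkS4class{SiteTable}
#' @return A \linkS4class{PairMatrix} of kind \code{"geographic"} in km.
#' @export
geodesicDistance <- function(sites) {
  s <- siteCoords(sites)
  p <- cbind(s$lon, s$lat)
  d <- geosphere::distm(p, fun = function(a, b)
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM * 1000)) / 1000
  d <- (d + t(d)) / 2
  diag(d) <- 0
  PairMatrix(d, "geographic", s$site)
}

# Initial bearings (degrees clockwise from north) between sites, upper
# triangle orientation i -> j.
.siteBearings <- function(sites) {
  s <- siteCoords(sites)
  p <- cbind(s$lon, s$lat)
  n <- nrow(p)
  b <- matrix(0, n, n, dimnames = list(s$site, s$site))
  for (i in seq_len(n - 1L)) {
    bb <- geosphere::bearing(p[i, , drop = FALSE],
                             p[(i + 1L):n, , drop = FALSE])
    b[i, (i + 1L):n] <- bb
    b[(i + 1L):n, i] <- bb + 180
  }
  b %% 360
}

#' Spatial autocorrelogram of genetic covariance by distance class
#'
#' Pairwise geographic distances (inherited from the site of each
#' individual; 0 within a site) are split into distance classes, by default
#' equal-count (quantile) bins. For class h the autocorrelation is the mean
#' codeviation over the (ordered) pairs in the class divided by the mean
#' self-codeviation of the individuals incident to the class,
#' \eqn{r_h = \overline{c_{ij}}^{(h)} / \overline{c_{ii}}^{(h)}}, whose
#' expectation under no spatial structure is \eqn{-1/(N-1)}.
#' The null distribution permutes individuals
#' among subpopulations (site sample sizes preserved). Per-class two-sided
#' p-values and a combined P (Fisher's combination, itself calibrated
#' against the permutation null) are reported.
#'
#' @param C individual-level covariance \linkS4class{PairMatrix}
#' @param geo site-level geographic \linkS4class{PairMatrix} (km)
#' @param assignment named character vector individual -> site
#' @param nClasses number of distance classes (24)
#' @param nPerm permutations (1000)
#' @param seed RNG seed
#' @param binning \code{"quantile"} (equal-count, default) or
#'   \code{"width"} (equal-width)
#' @return list with \code{classes} (data.frame: bounds, nPairs, r, p,
#'   and the permutation SD of r per class), \code{combinedP},
#'   \code{nPerm}, \code{seed}, \code{binning}.
#' @export
spatialAutocorrelogram <- function(C, geo, assignment, nClasses = 24L,
                                   nPerm = 1000L, seed = 1L,
                                   binning = c("quantile", "width")) {
  binning <- match.arg(binning)
  stopifnot(is(C, "PairMatrix"), is(geo, "PairMatrix"))
  ids <- pairLabels(C)
  siteOf <- assignment[ids]
  if (anyNA(siteOf)) stop("unassigned individual(s) in covariance matrix")
  gsite <- pairValues(geo)
  cv <- pairValues(C)
  siteNames <- pairLabels(geo)
  stopifnot(all(siteOf %in% siteNames))

  sizes <- table(factor(siteOf, levels = siteNames))
  nPairsSite <- outer(sizes, sizes)
  diag(nPairsSite) <- sizes * (sizes - 1) / 2
  pairDist <- rep(gsite[upper.tri(gsite, diag = TRUE)],
                  nPairsSite[upper.tri(nPairsSite, diag = TRUE)])
  breaks <- if (binning == "quantile")
    unique(quantile(pairDist, probs = seq(0, 1, length.out = nClasses + 1),
                    names = FALSE))
  else seq(min(pairDist), max(pairDist), length.out = nClasses + 1)
  if (length(breaks) < 2L)             # degenerate: all distances equal
    breaks <- c(breaks[1L] - 1e-9, breaks[1L] + 1e-9)
  nCl <- length(breaks) - 1L
  classOfSitePair <- matrix(cut(gsite, breaks, labels = FALSE,
                                include.lowest = TRUE),
                            nrow(gsite), dimnames = dimnames(gsite))

  nSites <- length(siteNames)
  rStat <- function(siteVec) {
    f <- factor(siteVec, levels = siteNames)
    sumBySite <- function(m) {
      out <- rowsum(m, f)
      full <- matrix(0, nSites, ncol(m))
      full[match(rownames(out), siteNames), ] <- out
      full
    }
    agg <- sumBySite(t(sumBySite(cv)))
    diagBySite <- sumBySite(cbind(diag(cv)))[, 1L]
    nBySite <- as.integer(table(f))
    num <- den <- numeric(nCl)
    for (h in seq_len(nCl)) {
      sel <- classOfSitePair == h
      sel[lower.tri(sel)] <- FALSE
      idx <- which(sel, arr.ind = TRUE)
      if (!nrow(idx)) { num[h] <- NA; den[h] <- NA; next }
      tot <- 0
      nPairsOrdered <- 0
      incident <- rep(FALSE, length(siteNames))
      for (r in seq_len(nrow(idx))) {
        s <- idx[r, 1L]; t <- idx[r, 2L]
        if (s == t) {
          if (nBySite[s] >= 2L) {
            tot <- tot + (agg[s, s] - diagBySite[s])
            nPairsOrdered <- nPairsOrdered + nBySite[s] * (nBySite[s] - 1L)
            incident[s] <- TRUE
          }
        } else if (nBySite[s] > 0L && nBySite[t] > 0L) {
          tot <- tot + agg[s, t] + agg[t, s]
          nPairsOrdered <- nPairsOrdered + 2L * nBySite[s] * nBySite[t]
          incident[s] <- incident[t] <- TRUE
        }
      }
      # mean codeviation per pair over mean self-codeviation per incident
      # individual: null expectation -1/(N-1), matching the field estimator
      if (nPairsOrdered == 0) { num[h] <- NA; den[h] <- NA; next }
      num[h] <- tot / nPairsOrdered
      den[h] <- sum(diagBySite[incident]) / sum(nBySite[incident])
    }
    num / den
  }

  rObs <- rStat(siteOf)
  perms <- matrix(NA_real_, nPerm, nCl)
  .withSeed(.childSeed(seed, "autocorrelogram"), {
    for (b in seq_len(nPerm)) perms[b, ] <- rStat(sample(siteOf))
  })
  pClass <- vapply(seq_len(nCl), function(h) {
    if (is.na(rObs[h])) return(NA_real_)
    .permP(rObs[h], perms[, h][!is.na(perms[, h])], "two")
  }, numeric(1))
  permSd <- apply(perms, 2L, sd, na.rm = TRUE)

  # combined P: Fisher statistic over per-class pseudo p-values, compared
  # against the same statistic computed on each permutation replicate
  all <- rbind(rObs, perms)
  fisherX <- function(rowIdx) {
    x <- 0
    for (h in seq_len(nCl)) {
      col <- all[, h]
      if (is.na(col[rowIdx])) next
      colOk <- col[!is.na(col)]
      pg <- sum(colOk >= col[rowIdx]) / length(colOk)
      pl <- sum(colOk <= col[rowIdx]) / length(colOk)
      x <- x - 2 * log(min(1, 2 * min(pg, pl)))
    }
    x
  }
  xAll <- vapply(seq_len(nPerm + 1L), fisherX, numeric(1))
  combinedP <- (1 + sum(xAll[-1L] >= xAll[1L])) / (nPerm + 1)

  nPairsClass <- vapply(seq_len(nCl), function(h) {
    sel <- classOfSitePair == h
    sel[lower.tri(sel)] <- FALSE
    sum(nPairsSite[sel])
  }, numeric(1))
  list(classes = data.frame(lower = breaks[-length(breaks)],
                            upper = breaks[-1L],
                            nPairs = nPairsClass, r = rObs, p = pClass,
                            permSd = if (nPerm > 0L) permSd else NA_real_),
       combinedP = combinedP, nPerm = nPerm, seed = seed, binning = binning)
}

#' Mantel test between two pairwise matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with one-sided
#' significance by jointly permuting the rows and columns of the second
#' matrix (wraps \code{vegan::mantel}).
#'
#' @param d1,d2 \linkS4class{PairMatrix} objects with the same labels
#' @param nPerm permutations (1000)
#' @param seed RNG seed
#' @return list with \code{r}, \code{p}, \code{nPerm}.
#' @export
mantelTest <- function(d1, d2, nPerm = 1000L, seed = 1L) {
  stopifnot(is(d1, "PairMatrix"), is(d2, "PairMatrix"))
  v1 <- pairValues(d1)
  v2 <- pairValues(d2)[pairLabels(d1), pairLabels(d1)]
  if (sd(.upperTri(v1)) == 0 || sd(.upperTri(v2)) == 0)
    stop("constant matrix: Mantel correlation undefined")
  fit <- .withSeed(.childSeed(seed, "mantel"),
                   vegan::mantel(as.dist(v1), as.dist(v2),
                                 permutations = nPerm))
  list(r = unname(fit$statistic), p = fit$signif, nPerm = nPerm)
}

#' Bearing correlogram: compass orientation of a genetic gradient
#'
#' For each angle on a grid over [0, 180), the geographic distance matrix
#' is weighted by the squared cosine of the difference between each pair's
#' initial bearing and the angle, \eqn{g_{ij}(\theta) = d_{ij}
#' \cos^2(\alpha_{ij} - \theta)}, and the Mantel correlation between the
#' genetic matrix and \eqn{g(\theta)} is computed. The profile is
#' 180-degree periodic; the reported argmax is the angle of maximal
#' correlation. One permutation set (joint row/column shuffles of the
#' genetic matrix) is shared across angles.
#'
#' @param dgen genetic \linkS4class{PairMatrix} over sites (e.g. pairwise
#'   Fst)
#' @param sites a \linkS4class{SiteTable} covering the labels of
#'   \code{dgen}
#' @param stepDeg grid resolution in degrees (1)
#' @param nPerm permutations (999); 0 skips p-values
#' @param seed RNG seed
#' @return list with \code{angles}, \code{r}, \code{p}, \code{argmax}
#'   (degrees in [0, 180)), \code{rMax}, \code{nPerm}, \code{seed}.
#' @export
bearingCorrelogram <- function(dgen, sites, stepDeg = 1L, nPerm = 999L,
                               seed = 1L) {
  stopifnot(is(dgen, "PairMatrix"))
  labels <- pairLabels(dgen)
  if (length(labels) < 4L) stop("bearing correlogram needs >= 4 sites")
  sc <- siteCoords(sites)
  stopifnot(all(labels %in% sc$site))
  sub <- SiteTable(sc[match(labels, sc$site), ])
  geo <- pairValues(geodesicDistance(sub))
  alpha <- .siteBearings(sub)
  dVec <- .upperTri(pairValues(dgen))
  gDist <- .upperTri(geo)
  aVec <- .upperTri(alpha)
  angles <- seq(0, 180 - stepDeg, by = stepDeg)
  W <- vapply(angles, function(th)
    gDist * cos((aVec - th) * pi / 180)^2, numeric(length(gDist)))
  # r(theta) via standardized cross products; one shared permutation set
  zd <- dVec - mean(dVec)
  sdD <- sqrt(sum(zd^2))
  if (sdD == 0) stop("constant genetic matrix")
  Wc <- sweep(W, 2L, colMeans(W))
  sw <- sqrt(colSums(Wc^2))
  rObs <- as.numeric(crossprod(zd, Wc)) / (sdD * sw)
  p <- rep(NA_real_, length(angles))
  if (nPerm > 0L) {
    n <- length(labels)
    vGen <- pairValues(dgen)
    exceed <- numeric(length(angles))
    .withSeed(.childSeed(seed, "bearing"), {
      for (b in seq_len(nPerm)) {
        o <- sample(n)
        zp <- .upperTri(vGen[o, o])
        zp <- zp - mean(zp)
        rp <- as.numeric(crossprod(zp, Wc)) / (sqrt(sum(zp^2)) * sw)
        exceed <- exceed + (rp >= rObs)
      }
    })
    p <- (1 + exceed) / (nPerm + 1)
  }
  best <- which.max(rObs)
  list(angles = angles, r = rObs, p = p,
       argmax = angles[best], rMax = rObs[best],
       pAtMax = p[best], nPerm = nPerm, seed = seed)
}
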