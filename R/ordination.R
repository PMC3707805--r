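# Classical MDS with additive-constant correction, Procrustes comparison
# with permutation test (protest), and Gaussian-mixture clustering of
# ordination coordinates.

#' Classical multidimensional scaling of a distance matrix
#'
#' Metric MDS by eigendecomposition of the double-centered squared
#' distance matrix. When \code{correct = TRUE} and negative eigenvalues
#' occur, the smallest additive constant making the configuration
#' Euclidean (Cailliez) is added to the off-diagonal dissimilarities and
#' recorded.
#'
#' @param d a complete symmetric \linkS4class{PairMatrix} of kind
#'   \code{"distance"}
#' @param k number of output dimensions (default 2)
#' @param correct apply the additive-constant correction if needed
#' @return list with \code{coordinates} (n x k matrix, axes ordered by
#'   decreasing eigenvalue), \code{eigenvalues} (full corrected spectrum),
#'   \code{constantAdded} (0 when no correction was applied) and
#'   \code{varianceFractions} (per returned axis, against the positive part
#'   of the spectrum).
#' @export
classicalMds <- function(d, k = 2L, correct = TRUE) {
  stopifnot(is(d, "PairMatrix"))
  v <- pairValues(d)
  if (anyNA(v))
    stop("distance matrix has missing cells; run QC / fix inputs first")
  needAdd <- FALSE
  if (correct) {
    eig0 <- eigen(-0.5 * scale(t(scale(t(v^2), scale = FALSE)),
                               scale = FALSE), symmetric = TRUE,
                  only.values = TRUE)$values
    needAdd <- min(eig0) < -1e-9 * max(abs(eig0))
  }
  fit <- cmdscale(as.dist(v), k = k, eig = TRUE, add = needAdd)
  constant <- if (needAdd) fit$ac else 0
  ev <- fit$eig
  pos <- pmax(ev, 0)
  coords <- fit$points
  rownames(coords) <- pairLabels(d)
  list(coordinates = coords,
       eigenvalues = ev,
       constantAdded = constant,
       varianceFractions = pos[seq_len(ncol(coords))] / sum(pos))
}

#' Symmetric Procrustes comparison with permutation test
#'
#' Both configurations are centered and scaled to unit sum of squares and
#' superimposed by the optimal rotation (reflections allowed); the fit
#' correlation is \eqn{r = \sqrt{1 - m^2}} with \eqn{m^2} the minimized
#' residual. Significance is assessed by permuting the rows of \code{y}.
#' Thin wrapper over \code{vegan::protest} with rows matched by label.
#'
#' @param x,y numeric matrices with matching rownames (or equal row counts)
#' @param nPerm number of permutations (default 1000)
#' @param seed RNG seed for the permutation test
#' @return list with \code{r}, \code{p}, \code{nPerm}, and the underlying
#'   \code{vegan} protest object in \code{fit}.
#' @export
procrustesProtest <- function(x, y, nPerm = 1000L, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    common <- intersect(rownames(x), rownames(y))
    if (length(common) < nrow(x) || length(common) < nrow(y))
      stopifnot(length(common) >= 3L)
    x <- x[common, , drop = FALSE]
    y <- y[common, , drop = FALSE]
  }
  stopifnot(nrow(x) == nrow(y))
  if (nrow(x) < ncol(x)) stop("fewer rows than columns")
  fit <- .withSeed(seed,
                   vegan::protest(x, y, permutations = nPerm,
                                  symmetric = TRUE))
  list(r = sqrt(1 - fit$ss), p = fit$signif, nPerm = nPerm, fit = fit)
}

#' Per-site mean ordination coordinates
#'
#' Averages individual-level coordinates within each sampling site, the
#' form in which ordinations are compared with geography.
#'
#' @param coords individuals x k coordinate matrix with individual ids as
#'   rownames
#' @param sites a \linkS4class{SiteTable} assigning those individuals
#' @return sites x k matrix with site codes as rownames.
#' @export
siteMeanCoords <- function(coords, sites) {
  a <- siteAssignment(sites)[rownames(coords)]
  stopifnot(!anyNA(a))
  t(vapply(split(seq_len(nrow(coords)), a),
           function(i) colMeans(coords[i, , drop = FALSE]),
           numeric(ncol(coords))))
}

#' Geographic coordinates of sites as an ordination-comparable matrix
#'
#' Returns (longitude, latitude) pairs, the unprojected convention used
#' when comparing genetic ordinations to geography.
#'
#' @param sites a \linkS4class{SiteTable}
#' @return sites x 2 matrix (lon, lat) with site codes as rownames.
#' @export
geographicTarget <- function(sites) {
  s <- siteCoords(sites)
  m <- cbind(lon = s$lon, lat = s$lat)
  rownames(m) <- s$site
  m
}

#' Gaussian-mixture clustering of ordination coordinates
#'
#' Fits Gaussian mixtures over a range of component counts with multiple
#' covariance parameterizations via \code{mclust::Mclust} and selects the
#' model with the best BIC.
#'
#' @param coords numeric matrix of coordinates (finite values)
#' @param kRange candidate numbers of components (default 1:6)
#' @param seed RNG seed
#' @return list with \code{labels} (cluster assignment per row), \code{k}
#'   (selected number of components), \code{bic} and the fitted
#'   \code{mclust} model in \code{fit}.
#' @export
gmmCluster <- function(coords, kRange = 1:6, seed = 1L) {
  coords <- as.matrix(coords)
  stopifnot(all(is.finite(coords)))
  if (max(kRange) > nrow(coords)) stop("kRange exceeds number of points")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  fit <- .withSeed(seed, mclust::Mclust(coords, G = kRange,
                                        verbose = FALSE))
  list(labels = fit$classification, k = fit$G, bic = fit$bic, fit = fit)
}
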