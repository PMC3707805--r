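# Per-SNP geographic allele-frequency gradient model, individual placement
# by maximum likelihood under the fitted gradients, and the local Moran's I
# genome scan for clustered steep-gradient regions.

#' Fit per-SNP logistic allele-frequency gradients over geography
#'
#' Models each SNP's alternate-allele dosage as Binomial(2, logistic(a x +
#' b)) over standardized individual coordinates (longitude/latitude of the
#' assigned site, scaled to zero mean and unit variance per axis), fit by
#' iteratively reweighted least squares. The gradient steepness score is
#' the Euclidean norm of the slope vector. Fits that fail to converge or
#' run into separation have their slopes capped and are flagged.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param sites a \linkS4class{SiteTable} assigning every individual
#' @param slopeCap absolute cap on standardized slopes (25)
#' @return list with \code{fits} (data.frame: id, chromosome, position,
#'   ax, ay, b, magnitude, converged), \code{center} and \code{scale} of
#'   the coordinate standardization.
#' @export
fitSnpGradients <- function(gm, sites, slopeCap = 25) {
  a <- siteAssignment(sites)[individualIds(gm)]
  if (anyNA(a)) stop("individual(s) without site assignment")
  sc <- siteCoords(sites)
  xy <- cbind(x = sc$lon[match(a, sc$site)], y = sc$lat[match(a, sc$site)])
  center <- colMeans(xy)
  scl <- c(sd(xy[, 1L]), sd(xy[, 2L]))
  scl[scl == 0] <- 1
  xs <- sweep(sweep(xy, 2L, center), 2L, scl, "/")
  X <- cbind(1, xs)
  g <- genotypeCalls(gm)
  map <- markerMap(gm)
  nSnp <- nrow(g)
  res <- matrix(NA_real_, nSnp, 4L)
  conv <- logical(nSnp)
  for (s in seq_len(nSnp)) {
    gs <- g[s, ]
    ok <- !is.na(gs)
    if (sum(ok) < 5L) next
    fit <- suppressWarnings(
      glm.fit(X[ok, , drop = FALSE], gs[ok] / 2,
              weights = rep(2, sum(ok)), family = binomial()))
    cf <- fit$coefficients
    capped <- any(abs(cf[2:3]) > slopeCap)
    if (capped) cf[2:3] <- pmin(pmax(cf[2:3], -slopeCap), slopeCap)
    res[s, ] <- c(cf[2L], cf[3L], cf[1L],
                  sqrt(cf[2L]^2 + cf[3L]^2))
    conv[s] <- fit$converged && !capped && !anyNA(cf)
  }
  list(fits = data.frame(id = map$id, chromosome = map$chromosome,
                         position = map$position,
                         ax = res[, 1L], ay = res[, 2L], b = res[, 3L],
                         magnitude = res[, 4L], converged = conv),
       center = center, scale = scl)
}

#' Place individuals in gradient space by maximum likelihood
#'
#' For each individual, finds the 2-D standardized coordinate maximizing
#' the joint binomial likelihood of its genotypes under the fitted per-SNP
#' logistic surfaces (BFGS with analytic gradient, started at the
#' centroid). Non-converged SNP fits are excluded.
#'
#' @param fit result of \code{\link{fitSnpGradients}}
#' @param gm the \linkS4class{GenotypeMatrix} holding the individuals to
#'   place (markers must match the fitted SNPs by id)
#' @return individuals x 2 matrix of standardized coordinates (\code{NA}
#'   rows for failed optimizations, with a message).
#' @export
locateIndividuals <- function(fit, gm) {
  f <- fit$fits[fit$fits$converged, , drop = FALSE]
  idx <- match(f$id, markerMap(gm)$id)
  stopifnot(!anyNA(idx))
  g <- genotypeCalls(gm)[idx, , drop = FALSE]
  A <- cbind(f$ax, f$ay)
  b <- f$b
  out <- matrix(NA_real_, nIndividuals(gm), 2L,
                dimnames = list(individualIds(gm), c("x", "y")))
  for (i in seq_len(ncol(g))) {
    gi <- g[, i]
    ok <- !is.na(gi)
    if (sum(ok) < 3L) next
    Ai <- A[ok, , drop = FALSE]; bi <- b[ok]; gk <- gi[ok]
    # weak Gaussian penalty (sd 5 standardized units) keeps directions the
    # fitted gradients barely constrain from drifting to infinity
    nll <- function(xy) {
      eta <- Ai %*% xy + bi
      -sum(gk * eta - 2 * log1p(exp(eta))) + sum(xy^2) / 50
    }
    grad <- function(xy) {
      p <- plogis(Ai %*% xy + bi)
      -as.numeric(crossprod(Ai, gk - 2 * p)) + xy / 25
    }
    o <- tryCatch(optim(c(0, 0), nll, grad, method = "BFGS"),
                  error = function(e) NULL)
    if (!is.null(o) && o$convergence == 0L) out[i, ] <- o$par
  }
  if (anyNA(out[, 1L]))
    message(sum(is.na(out[, 1L])), " individual placement(s) failed")
  out
}

#' Local Moran's I genome scan for clustered extreme scores
#'
#' For marker i with score \eqn{Z_i},
#' \eqn{I_i = \frac{n}{(n-1) S^2} (Z_i - \bar Z) \sum_j w_{ij} (Z_j - \bar Z)}
#' where \eqn{w_{ij} = 1} for markers j != i within \code{windowBp} on the
#' same chromosome, n is the count of such neighbors, and \eqn{\bar Z},
#' \eqn{S^2} are by default the genome-wide mean and (sample) variance of
#' the scores (\code{normalization = "windowlocal"} recomputes them per
#' window). Markers with fewer than 2 neighbors are excluded. One-sided
#' p-values (positive local autocorrelation) come from reshuffling the
#' scores across all markers.
#'
#' @param scores named numeric vector of per-SNP scores
#' @param map data.frame with columns \code{chromosome}, \code{position},
#'   \code{id} matching \code{scores} (map order)
#' @param windowBp half-window in bp (50000)
#' @param nPerm permutations (10000)
#' @param seed RNG seed
#' @param normalization \code{"genomewide"} (default) or
#'   \code{"windowlocal"}
#' @return data.frame with id, chromosome, position, score, n (neighbor
#'   count), I, p (NA for excluded markers); attribute \code{nPerm}.
#' @export
localMoranScan <- function(scores, map, windowBp = 50000L,
                           nPerm = 10000L, seed = 1L,
                           normalization = c("genomewide", "windowlocal")) {
  normalization <- match.arg(normalization)
  stopifnot(length(scores) == nrow(map), all(is.finite(scores)))
  ord <- order(map$chromosome, map$position)
  map <- map[ord, , drop = FALSE]
  scores <- scores[ord]
  N <- length(scores)
  chrom <- map$chromosome
  pos <- map$position
  # per-marker neighbor window [loIdx, hiIdx] excluding self, same chrom
  loIdx <- hiIdx <- integer(N)
  for (ch in unique(chrom)) {
    k <- which(chrom == ch)
    p <- pos[k]
    loIdx[k] <- k[findInterval(p - windowBp, p, left.open = TRUE) + 1L]
    hiIdx[k] <- k[findInterval(p + windowBp, p)]
  }
  nNbr <- hiIdx - loIdx  # window size minus self

  moranI <- function(z) {
    zc <- z - mean(z)
    s2 <- var(z)
    if (s2 == 0) return(rep(0, N))
    cs <- c(0, cumsum(zc))
    nbrSum <- cs[hiIdx + 1L] - cs[loIdx] - zc
    ifelse(nNbr >= 2L,
           nNbr / ((nNbr - 1) * s2) * zc * nbrSum, NA_real_)
  }
  if (normalization == "windowlocal") {
    moranI <- function(z) {
      out <- rep(NA_real_, N)
      for (i in seq_len(N)) {
        if (nNbr[i] < 2L) next
        win <- setdiff(loIdx[i]:hiIdx[i], i)
        zw <- z[c(i, win)]
        m <- mean(zw); s2 <- var(zw)
        if (s2 == 0) { out[i] <- 0; next }
        out[i] <- nNbr[i] / ((nNbr[i] - 1) * s2) * (z[i] - m) *
          sum(z[win] - m)
      }
      out
    }
  }
  iObs <- moranI(scores)
  pv <- rep(NA_real_, N)
  if (nPerm > 0L) {
    exceed <- integer(N)
    nVal <- integer(N)
    .withSeed(.childSeed(seed, "moran"), {
      for (b in seq_len(nPerm)) {
        ip <- moranI(sample(scores))
        ok <- !is.na(ip) & !is.na(iObs)
        exceed[ok] <- exceed[ok] + (ip[ok] >= iObs[ok])
        nVal[ok] <- nVal[ok] + 1L
      }
    })
    pv <- ifelse(is.na(iObs), NA_real_, (1 + exceed) / (nVal + 1))
  }
  out <- data.frame(id = map$id, chromosome = chrom, position = pos,
                    score = scores, n = nNbr, I = iObs, p = pv)
  attr(out, "nPerm") <- nPerm
  out
}

#' Significant markers from a local Moran scan
#'
#' @param scan result of \code{\link{localMoranScan}}
#' @param pThreshold inclusion threshold on the permutation p (5e-4)
#' @return data.frame of markers with p < threshold, sorted by
#'   (chromosome, position); zero rows (with header) when none pass.
#' @export
manhattanTable <- function(scan, pThreshold = 5e-4) {
  out <- scan[!is.na(scan$p) & scan$p < pThreshold, , drop = FALSE]
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
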