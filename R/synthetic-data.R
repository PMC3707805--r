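# Synthetic clinal genotype datasets with known planted structure:
# a weak logistic allele-frequency cline at a configurable compass bearing,
# planted steep-gradient SNPs, frequency-shift outlier individuals, related
# pairs, and IBD segment tables. Ground truth is returned alongside.

#' Configuration for the synthetic clinal generator
#'
#' @param nSnps number of biallelic SNPs
#' @param clineBearing compass bearing of the planted cline, degrees
#'   clockwise from north in [0, 180)
#' @param clineStrength maximum allele-frequency range across the sampled
#'   extent for background SNPs, in [0, 0.5]; per-SNP ranges are drawn
#'   uniformly below it. The default 0.05 reproduces, at the shipped
#'   site table's cleaned sample sizes, the weak differentiation regime of the Dutch study (mean
#'   pairwise-subpopulation Fst in the 1e-4..1e-3 range, about half of all
#'   per-SNP estimates non-positive)
#' @param mafRange baseline allele-frequency range the per-SNP central
#'   frequency is drawn from
#' @param nOutliers number of planted frequency-shift outlier individuals
#'   (offset +0.15 on a random half of the SNPs)
#' @param nRelatedPairs number of planted related pairs (75\% of one
#'   member's genotypes copied into the other)
#' @param nSteepSnps number of SNPs with amplified gradient (frequency
#'   range 2 x clineStrength, capped)
#' @param missingRate per-call missing probability
#' @param nPerSite individuals per site: a single count, a named vector by
#'   site code, or NULL to use the site table's \code{n_clean} column
#' @param seed RNG seed, recorded in the output metadata
#' @return validated configuration list of class \code{synthConfig}.
#' @export
synthConfig <- function(nSnps = 2000L, clineBearing = 110,
                        clineStrength = 0.05, mafRange = c(0.1, 0.5),
                        nOutliers = 0L, nRelatedPairs = 0L,
                        nSteepSnps = 0L, missingRate = 0,
                        nPerSite = NULL, seed = 1L) {
  stopifnot(nSnps >= 1L, clineBearing >= 0, clineBearing < 180,
            clineStrength >= 0, clineStrength <= 0.5,
            nOutliers >= 0L, nRelatedPairs >= 0L, nSteepSnps >= 0L,
            missingRate >= 0, missingRate < 1,
            length(mafRange) == 2L, all(mafRange > 0), all(mafRange < 1))
  structure(list(nSnps = as.integer(nSnps), clineBearing = clineBearing,
                 clineStrength = clineStrength, mafRange = mafRange,
                 nOutliers = as.integer(nOutliers),
                 nRelatedPairs = as.integer(nRelatedPairs),
                 nSteepSnps = as.integer(nSteepSnps),
                 missingRate = missingRate, nPerSite = nPerSite,
                 seed = as.integer(seed)),
            class = "synthConfig")
}

# Marker map: SNPs spread over 22 autosomes with inter-marker gaps drawn
# uniform(50 kb, 350 kb), so most adjacent markers sit outside a 500 kb
# LD window but some fall inside it.
.synthMarkerMap <- function(nSnps) {
  chrom <- sort(rep_len(sprintf("%02d", 1:22), nSnps))
  pos <- integer(nSnps)
  for (ch in unique(chrom)) {
    k <- which(chrom == ch)
    pos[k] <- cumsum(as.integer(runif(length(k), 5e4, 3.5e5)))
  }
  data.frame(chromosome = chrom, position = pos,
             id = sprintf("snp%05d", seq_len(nSnps)))
}

#' Generate a clinal SNP dataset with planted ground truth
#'
#' Site-level allele frequencies are deterministic given the drawn per-SNP
#' intercepts and slopes: \eqn{p_s(site) = logistic(\alpha_s + \beta_s
#' u(site))} where u projects site coordinates (local-plane km) onto the
#' unit vector at the cline bearing, rescaled to span 1 across the sampled
#' extent. Individual genotypes are Binomial(2, p) draws; outliers get a
#' +0.15 frequency offset on a random half of the SNPs; each related pair
#' copies 75\% of one member's genotypes into the other.
#'
#' @param cfg a \code{\link{synthConfig}}
#' @param sites a \linkS4class{SiteTable}; any existing assignment is
#'   replaced by the generated individuals
#' @return list with \code{genotypes} (\linkS4class{GenotypeMatrix}),
#'   \code{sites} (the input \linkS4class{SiteTable} with the generated
#'   assignment), and \code{truth} (outlier ids, related pairs, steep SNP
#'   ids, true bearing, per-SNP gradient vector, seed).
#' @export
generateClinalDataset <- function(cfg, sites) {
  stopifnot(inherits(cfg, "synthConfig"))
  sc <- siteCoords(sites)
  stopifnot(nrow(sc) >= 1L)
  nPer <- cfg$nPerSite
  if (is.null(nPer)) {
    nPer <- if ("n_clean" %in% colnames(sc)) sc$n_clean else rep(15L, nrow(sc))
    names(nPer) <- sc$site
  } else if (length(nPer) == 1L) {
    nPer <- setNames(rep(as.integer(nPer), nrow(sc)), sc$site)
  }
  nPer <- nPer[sc$site]
  .withSeed(cfg$seed, {
    map <- .synthMarkerMap(cfg$nSnps)
    u <- .bearingProjection(sc$lat, sc$lon, cfg$clineBearing)
    u <- if (diff(range(u)) > 0) (u - mean(range(u))) / diff(range(u)) else
      rep(0, length(u))
    p0 <- runif(cfg$nSnps, cfg$mafRange[1L], cfg$mafRange[2L])
    alpha <- qlogis(p0)
    steep <- if (cfg$nSteepSnps > 0L)
      sample(cfg$nSnps, cfg$nSteepSnps) else integer(0)
    delta <- runif(cfg$nSnps, 0, cfg$clineStrength)
    delta[steep] <- min(2 * cfg$clineStrength, 0.45)
    beta <- sign(runif(cfg$nSnps) - 0.5) * delta / (p0 * (1 - p0))
    siteFreq <- plogis(matrix(alpha, cfg$nSnps, length(u)) +
                         outer(beta, u))   # snp x site
    ids <- unlist(lapply(seq_len(nrow(sc)), function(k)
      sprintf("%s_%02d", sc$site[k], seq_len(nPer[k]))))
    assignment <- setNames(rep(sc$site, nPer), ids)
    N <- length(ids)
    calls <- matrix(NA_integer_, cfg$nSnps, N,
                    dimnames = list(map$id, ids))
    col <- 0L
    for (k in seq_len(nrow(sc))) {
      if (nPer[k] == 0L) next
      pk <- siteFreq[, k]
      block <- matrix(rbinom(cfg$nSnps * nPer[k], 2L, pk),
                      cfg$nSnps, nPer[k])
      calls[, col + seq_len(nPer[k])] <- block
      col <- col + nPer[k]
    }
    outliers <- if (cfg$nOutliers > 0L) sample(ids, cfg$nOutliers) else
      character(0)
    for (id in outliers) {
      shifted <- sample(cfg$nSnps, floor(cfg$nSnps / 2))
      p <- pmin(pmax(siteFreq[shifted, match(assignment[id], sc$site)] +
                       0.15, 0.001), 0.999)
      calls[shifted, id] <- rbinom(length(shifted), 2L, p)
    }
    relatedPairs <- data.frame(id_a = character(), id_b = character())
    if (cfg$nRelatedPairs > 0L) {
      bigSites <- sc$site[nPer >= 2L]
      stopifnot(length(bigSites) >= 1L)
      used <- character(0)
      for (r in seq_len(cfg$nRelatedPairs)) {
        s <- sample(bigSites, 1L)
        cand <- setdiff(ids[assignment[ids] == s], c(used, outliers))
        if (length(cand) < 2L) next
        pr <- sample(cand, 2L)
        copyIdx <- sample(cfg$nSnps, ceiling(0.75 * cfg$nSnps))
        calls[copyIdx, pr[2L]] <- calls[copyIdx, pr[1L]]
        used <- c(used, pr)
        relatedPairs <- rbind(relatedPairs,
                              data.frame(id_a = pr[1L], id_b = pr[2L]))
      }
    }
    if (cfg$missingRate > 0) {
      miss <- runif(length(calls)) < cfg$missingRate
      calls[miss] <- NA_integer_
    }
    gm <- GenotypeMatrix(calls, map, ids)
    truth <- list(outliers = outliers, relatedPairs = relatedPairs,
                  steepSnps = map$id[steep],
                  trueBearing = cfg$clineBearing,
                  gradient = setNames(beta, map$id),
                  siteFreq = siteFreq, seed = cfg$seed)
    list(genotypes = gm, sites = assignSites(sites, assignment),
         truth = truth)
  })
}

#' Generate an IBD segment table with requested sharing
#'
#' Places the requested number of segments per pair uniformly within the
#' chromosome spans of the marker map; segment lengths are exponential
#' with the requested mean, truncated to fit.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param sharingSpec data.frame with columns \code{id_a}, \code{id_b},
#'   \code{n_segments}, \code{mean_len_bp}
#' @param seed RNG seed
#' @return An \linkS4class{IBDSegmentTable} honoring the requested counts
#'   exactly.
#' @export
generateIbdSegments <- function(gm, sharingSpec, seed = 1L) {
  ids <- individualIds(gm)
  stopifnot(all(sharingSpec$id_a %in% ids), all(sharingSpec$id_b %in% ids))
  map <- markerMap(gm)
  spans <- do.call(rbind, lapply(split(map$position, map$chromosome),
                                 range))
  spanLen <- spans[, 2L] - spans[, 1L]
  if (any(sharingSpec$mean_len_bp >= max(spanLen)))
    stop("requested mean segment length exceeds every chromosome span")
  .withSeed(seed, {
    rows <- list()
    for (r in seq_len(nrow(sharingSpec))) {
      k <- sharingSpec$n_segments[r]
      if (k == 0L) next
      for (j in seq_len(k)) {
        repeat {
          ch <- sample(rownames(spans), 1L, prob = spanLen / sum(spanLen))
          len <- stats::rexp(1L, 1 / sharingSpec$mean_len_bp[r])
          if (len >= 1 && len < spanLen[ch]) break
        }
        start <- floor(runif(1L, spans[ch, 1L], spans[ch, 2L] - len))
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = sharingSpec$id_a[r], id_b = sharingSpec$id_b[r],
          chromosome = ch, start_bp = as.integer(start),
          end_bp = as.integer(start + ceiling(len)))
      }
    }
    IBDSegmentTable(if (length(rows)) do.call(rbind, rows) else
      data.frame(id_a = character(), id_b = character(),
                 chromosome = character(), start_bp = integer(),
                 end_bp = integer()))
  })
}

#' The 54 Dutch sampling sites
#'
#' Site codes, WGS84 coordinates and sample sizes (initial and after
#' cleaning) of the 54 Dutch subpopulations shipped with the package.
#'
#' @return A \linkS4class{SiteTable} (no assignment attached); the
#'   \code{sites} data.frame carries \code{name}, \code{n_initial} and
#'   \code{n_clean} columns besides the coordinates.
#' @export
dutchSiteFixture <- function() {
  path <- system.file("extdata", "dutch_sites.tsv", package = "clinekit",
                      mustWork = TRUE)
  SiteTable(read.delim(path, stringsAsFactors = FALSE))
}
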