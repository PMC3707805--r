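# Independent brute-force oracles and small data builders shared by the
# test files. Oracles deliberately use different formulations from the
# package implementations.

# hand-built tiny GenotypeMatrix
tinyGm <- function(calls, positions = seq_len(nrow(calls)) * 1000L,
                   chromosome = "01",
                   ids = sprintf("i%02d", seq_len(ncol(calls)))) {
  GenotypeMatrix(calls,
                 data.frame(chromosome = chromosome, position = positions,
                            id = sprintf("s%03d", seq_len(nrow(calls)))),
                 ids)
}

gridSites <- function(nLat = 4, nLon = 4, latRange = c(51, 53),
                      lonRange = c(4, 6.5)) {
  g <- expand.grid(lat = seq(latRange[1], latRange[2], length.out = nLat),
                   lon = seq(lonRange[1], lonRange[2], length.out = nLon))
  SiteTable(data.frame(site = sprintf("G%02d", seq_len(nrow(g))),
                       lat = g$lat, lon = g$lon))
}

polygonSites <- function(n = 40, lat0 = 52, lon0 = 5, radiusDeg = 0.8) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  SiteTable(data.frame(site = sprintf("P%02d", seq_len(n)),
                       lat = lat0 + radiusDeg * sin(th),
                       lon = lon0 + radiusDeg * cos(th) /
                         cos(lat0 * pi / 180)))
}

# Kendall tau-b by O(n^2) pair enumeration with tie terms
tauOracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  conc <- disc <- 0
  tiedX <- tiedY <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    if (sx != 0 && sy != 0) {
      if (sx == sy) conc <- conc + 1 else disc <- disc + 1
    }
    if (sx == 0) tiedX <- tiedX + 1
    if (sy == 0) tiedY <- tiedY + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tiedX) * (n0 - tiedY))
}

# Exact HWE p by direct enumeration of heterozygote configurations using
# the multinomial/hypergeometric form (not the log-factorial recursion of
# the implementation)
hweOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n == 0) return(1)
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  prob <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (nB - h) / 2
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) -
          lchoose(2 * n, nA))
  }, numeric(1))
  prob <- prob / sum(prob)
  obs <- prob[hets == nAB]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# Weir-Cockerham two-population theta components, scalar step-by-step
# evaluation of the published a/b/c formulas from genotype counts
wcOracle <- function(c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2)
  p1 <- (2 * c1[1] + c1[2]) / (2 * n1)
  p2 <- (2 * c2[1] + c2[2]) / (2 * n2)
  h1 <- c1[2] / n1; h2 <- c2[2] / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# local Moran's I by explicit double loop over marker pairs
moranOracle <- function(scores, map, windowBp) {
  ord <- order(map$chromosome, map$position)
  map <- map[ord, ]; z <- scores[ord]
  N <- length(z)
  zbar <- mean(z); s2 <- var(z)
  out <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    nbr <- which(map$chromosome == map$chromosome[i] &
                   abs(map$position - map$position[i]) <= windowBp &
                   seq_len(N) != i)
    n <- length(nbr)
    if (n < 2) next
    if (s2 == 0) { out[i] <- 0; next }
    out[i] <- n / ((n - 1) * s2) * (z[i] - zbar) * sum(z[nbr] - zbar)
  }
  out
}

# genotypes drawn at explicit per-site frequencies (snp x site matrix)
drawAtFrequencies <- function(freqBySite, sites, nPer, seed) {
  sc <- siteCoords(sites)
  ids <- unlist(lapply(seq_len(nrow(sc)), function(k)
    sprintf("%s_%02d", sc$site[k], seq_len(nPer))))
  withr::with_seed(seed, {
    calls <- do.call(cbind, lapply(seq_len(nrow(sc)), function(k)
      matrix(rbinom(nrow(freqBySite) * nPer, 2, freqBySite[, k]),
             ncol = nPer)))
    gm <- GenotypeMatrix(
      calls, data.frame(chromosome = "01",
                        position = seq_len(nrow(freqBySite)) * 100000L,
                        id = sprintf("s%04d", seq_len(nrow(freqBySite)))),
      ids)
    list(gm = gm,
         sites = assignSites(sites, setNames(rep(sc$site, each = nPer),
                                             ids)))
  })
}
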