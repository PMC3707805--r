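# Spatially explicit two-wave range-expansion simulator: deterministic
# lattice demography (logistic growth, equal-split migration to habitable
# 4-neighbors, an optional coastal-discontinuity window with carrying
# capacity 0), forward-time binomial drift of SNP frequencies, sampling of
# diploid genotypes at present, and scenario comparison.

#' Define a rectangular lattice world
#'
#' @param nCols,nRows lattice dimensions
#' @param habitable logical matrix (nRows x nCols), TRUE where settlement
#'   is possible (default all TRUE)
#' @return list of class \code{latticeWorld}. Cells are indexed
#'   column-major: \code{cell = (col - 1) * nRows + row}; row 1 is north.
#' @export
latticeWorld <- function(nCols, nRows, habitable = NULL) {
  if (is.null(habitable)) habitable <- matrix(TRUE, nRows, nCols)
  stopifnot(nrow(habitable) == nRows, ncol(habitable) == nCols)
  structure(list(nCols = nCols, nRows = nRows,
                 habitable = as.vector(habitable)),
            class = "latticeWorld")
}

#' @describeIn latticeWorld column-major cell index of (row, col)
#' @param world a latticeWorld
#' @param row,col lattice coordinates
#' @export
cellIndex <- function(world, row, col) (col - 1L) * world$nRows + row

# 4-neighbor index matrix (one-based; 0 where no neighbor)
.neighborMatrix <- function(world) {
  C <- world$nCols * world$nRows
  nR <- world$nRows
  row <- ((seq_len(C) - 1L) %% nR) + 1L
  col <- ((seq_len(C) - 1L) %/% nR) + 1L
  up <- ifelse(row > 1L, seq_len(C) - 1L, 0L)
  dn <- ifelse(row < nR, seq_len(C) + 1L, 0L)
  lf <- ifelse(col > 1L, seq_len(C) - nR, 0L)
  rt <- ifelse(col < world$nCols, seq_len(C) + nR, 0L)
  cbind(up, dn, lf, rt)
}

#' Define a two-wave expansion scenario
#'
#' @param world a \code{\link{latticeWorld}}
#' @param wave1,wave2 lists with \code{origin} (cell index),
#'   \code{startGen} (generations before present), \code{K} (carrying
#'   capacity per cell), \code{r} (logistic growth rate), \code{m}
#'   (emigration fraction). wave1 is the hunter-gatherer layer, wave2 the
#'   farming layer; when wave2 reaches a wave1 cell the deme merges fully
#'   into the wave2 layer (its parameters apply from then on).
#' @param discontinuity NULL, or list with \code{cells} (cell indices),
#'   \code{startGen} (70), \code{endGen} (35): those cells have carrying
#'   capacity 0 (occupants removed, no immigration) for generations
#'   \code{startGen .. endGen+1} before present
#' @param sampleCells cells sampled at present
#' @param nSnps,mafMin,samplesPerCell genetics: number of SNPs retained
#'   after ascertainment at pooled minor-allele frequency >= mafMin, and
#'   diploid samples drawn per cell
#' @param seed RNG seed for the genetic process
#' @return validated list of class \code{scenarioConfig}.
#' @export
scenarioConfig <- function(world, wave1, wave2, discontinuity = NULL,
                           sampleCells, nSnps = 1000L, mafMin = 0.03,
                           samplesPerCell = 20L, seed = 1L) {
  C <- world$nCols * world$nRows
  stopifnot(wave1$origin >= 1L, wave1$origin <= C,
            wave2$origin >= 1L, wave2$origin <= C,
            wave1$startGen > wave2$startGen,
            all(sampleCells >= 1L), all(sampleCells <= C),
            wave1$m >= 0, wave1$m <= 1, wave2$m >= 0, wave2$m <= 1,
            wave1$r > 0, wave2$r > 0)
  if (!world$habitable[wave1$origin] || !world$habitable[wave2$origin])
    stop("wave origin cell is not habitable")
  if (!is.null(discontinuity)) {
    stopifnot(discontinuity$startGen > discontinuity$endGen,
              discontinuity$startGen < wave1$startGen,
              all(discontinuity$cells >= 1L),
              all(discontinuity$cells <= C))
  }
  structure(list(world = world, wave1 = wave1, wave2 = wave2,
                 discontinuity = discontinuity,
                 sampleCells = as.integer(sampleCells),
                 nSnps = as.integer(nSnps), mafMin = mafMin,
                 samplesPerCell = as.integer(samplesPerCell),
                 seed = as.integer(seed)),
            class = "scenarioConfig")
}

#' Scaled two-wave scenario on a 40 x 40 toy world
#'
#' A desk-scale analog of the full European setting: both waves start in
#' the southeast corner (wave 1: K = 500, r = 0.5, m = 0.4, 135
#' generations before present; wave 2: K = 5000, r = 0.8, m = 0.8, 90
#' generations BP), 39 sample cells sit in a mid-latitude block on the
#' western (coastal) edge, and the discontinuity variant empties the 28
#' westernmost of them between 70 and 35 generations BP.
#'
#' @param discontinuity include the coastal-discontinuity window?
#' @param nSnps,samplesPerCell,seed passed to \code{\link{scenarioConfig}}
#' @return A \code{\link{scenarioConfig}}.
#' @export
toyScenario <- function(discontinuity = FALSE, nSnps = 1000L,
                        samplesPerCell = 20L, seed = 1L) {
  world <- latticeWorld(40L, 40L)
  coastal <- as.integer(outer(14:20, 2:5,
                              function(r, c) cellIndex(world, r, c)))
  inland <- c(as.integer(cellIndex(world, 14:20, 6L)),
              as.integer(cellIndex(world, 14:17, 7L)))
  sampleCells <- c(coastal, inland)     # 28 coastal + 11 inland = 39
  origin <- cellIndex(world, 40L, 40L)  # southeast corner
  scenarioConfig(
    world,
    wave1 = list(origin = origin, startGen = 135L, K = 500, r = 0.5,
                 m = 0.4),
    wave2 = list(origin = origin, startGen = 90L, K = 5000, r = 0.8,
                 m = 0.8),
    discontinuity = if (discontinuity)
      list(cells = coastal, startGen = 70L, endGen = 35L) else NULL,
    sampleCells = sampleCells, nSnps = nSnps,
    samplesPerCell = samplesPerCell, seed = seed)
}

#' Run the deterministic lattice demography
#'
#' Per generation and cell: logistic growth with the layer's parameters,
#' emigration of fraction m split equally among habitable 4-neighbors,
#' arrival of immigrants (a hunter-gatherer cell reached by farming
#' migrants merges fully into the farming layer), capping at carrying
#' capacity, and removal of occupants of discontinuity cells during their
#' window. Purely deterministic: the genetic process can be rerun on the
#' same history with any seed.
#'
#' @param scenario a \code{\link{scenarioConfig}}
#' @return list with \code{sizes} ((T+1) x nCells deme sizes, row g is
#'   generation startGen - g + 1 before present), \code{layers} (0 empty /
#'   1 wave1 / 2 wave2), \code{resident}, \code{outContrib},
#'   \code{allowed} (T x nCells step decompositions consumed by
#'   \code{\link{runGenetics}}), \code{colonizationGen} (generations BP of
#'   first occupation, NA if never), \code{T}.
#' @export
runDemography <- function(scenario) {
  w <- scenario$world
  C <- w$nCols * w$nRows
  nbr <- .neighborMatrix(w)
  T <- scenario$wave1$startGen
  Kl <- c(scenario$wave1$K, scenario$wave2$K)
  rl <- c(scenario$wave1$r, scenario$wave2$r)
  ml <- c(scenario$wave1$m, scenario$wave2$m)
  disc <- scenario$discontinuity

  S <- numeric(C); layer <- integer(C)
  S[scenario$wave1$origin] <- Kl[1L]
  layer[scenario$wave1$origin] <- 1L

  sizes <- matrix(0, T + 1L, C); layers <- matrix(0L, T + 1L, C)
  resident <- outContrib <- matrix(0, T, C)
  allowedM <- matrix(0L, T, C)
  colGen <- rep(NA_integer_, C)
  colGen[S > 0] <- T
  sizes[1L, ] <- S; layers[1L, ] <- layer

  for (t in seq_len(T)) {
    gNext <- T - t   # generations BP of the state being computed
    discActive <- !is.null(disc) && gNext <= disc$startGen &&
      gNext > disc$endGen
    allowed <- w$habitable
    if (discActive) allowed[disc$cells] <- FALSE

    occ <- layer > 0L
    K <- ifelse(occ, Kl[pmax(layer, 1L)], 0)
    r <- ifelse(occ, rl[pmax(layer, 1L)], 0)
    m <- ifelse(occ, ml[pmax(layer, 1L)], 0)
    Sg <- ifelse(occ, S + r * S * (1 - S / pmax(K, 1e-12)), 0)
    Sg[Sg < 0] <- 0
    if (discActive) Sg[disc$cells] <- 0

    deg <- rowSums(matrix(nbr > 0L & allowed[pmax(nbr, 1L)],
                          nrow = C), na.rm = TRUE)
    out <- ifelse(deg > 0, m * Sg, 0)
    contrib <- ifelse(deg > 0, out / pmax(deg, 1L), 0)
    res <- Sg - out

    inflow <- numeric(C)
    inflowByLayer <- matrix(0, C, 2L)
    for (k in 1:4) {
      b <- nbr[, k]
      ok <- b > 0L & allowed
      src <- b[ok]
      inflow[ok] <- inflow[ok] + contrib[src]
      for (L in 1:2) {
        fromL <- contrib[src] * (layer[src] == L)
        inflowByLayer[ok, L] <- inflowByLayer[ok, L] + fromL
      }
    }
    newS <- res + inflow
    newLayer <- ifelse(layer == 2L | inflowByLayer[, 2L] > 0, 2L,
                       ifelse(layer == 1L | inflowByLayer[, 1L] > 0, 1L, 0L))
    newLayer[newS < 1e-6] <- 0L
    newS[newS < 1e-6] <- 0
    if (discActive) { newS[disc$cells] <- 0; newLayer[disc$cells] <- 0L }
    # immigration saturates at the layer's carrying capacity
    capped <- newLayer > 0L
    newS[capped] <- pmin(newS[capped], Kl[newLayer[capped]])

    if (gNext == scenario$wave2$startGen) {
      o2 <- scenario$wave2$origin
      if (newS[o2] <= 0)
        stop("wave 2 origin cell unoccupied at injection")
      newLayer[o2] <- 2L
    }

    S <- newS; layer <- newLayer
    sizes[t + 1L, ] <- S
    layers[t + 1L, ] <- layer
    resident[t, ] <- res
    outContrib[t, ] <- contrib
    allowedM[t, ] <- as.integer(allowed)
    newly <- is.na(colGen) & S > 0
    colGen[newly] <- gNext
  }
  list(sizes = sizes, layers = layers, resident = resident,
       outContrib = outContrib, allowed = allowedM,
       colonizationGen = colGen, T = T, nbr = nbr)
}

#' Forward-time genetics on a demographic history
#'
#' Each SNP starts at an ancestral frequency drawn uniform(0.05, 0.95) in
#' the wave-1 origin deme. Every generation, every occupied cell redraws
#' its allele frequency binomially (2N gametes) from the migration-weighted
#' parental pool; newly colonized cells inherit the migrant pool. At
#' present, diploid genotypes are drawn Binomial(2, p) for the requested
#' samples; batches of SNPs are simulated until \code{nSnps} pass the
#' pooled-sample MAF ascertainment.
#'
#' @param demography result of \code{\link{runDemography}}
#' @param scenario the matching \code{\link{scenarioConfig}}
#' @param seed RNG seed (defaults to the scenario's)
#' @return list with \code{frequencies} (nCells x nSnps at present, NA for
#'   empty cells), \code{genotypes} (\linkS4class{GenotypeMatrix} of
#'   sampled individuals), \code{sites} (\linkS4class{SiteTable} of cell
#'   centroids with assignment).
#' @export
runGenetics <- function(demography, scenario, seed = scenario$seed) {
  C <- ncol(demography$sizes)
  cells <- scenario$sampleCells
  if (any(demography$sizes[nrow(demography$sizes), cells] <= 0))
    stop("sample cell(s) empty at present: ",
         paste(cells[demography$sizes[nrow(demography$sizes),
                                      cells] <= 0], collapse = ", "))
  w <- scenario$world
  rowOf <- ((cells - 1L) %% w$nRows) + 1L
  colOf <- ((cells - 1L) %/% w$nRows) + 1L
  siteCodes <- sprintf("C%03d", seq_along(cells))
  # pseudo-coordinates: 0.1 degrees per cell, row 1 = north
  sitesDf <- data.frame(site = siteCodes,
                        lat = 50 + (w$nRows - rowOf) * 0.1,
                        lon = 3 + (colOf - 1L) * 0.1)

  .withSeed(.childSeed(seed, "genetics"), {
    freqKeep <- NULL
    batch <- ceiling(scenario$nSnps * 1.4)
    guard <- 0L
    while (is.null(freqKeep) || ncol(freqKeep) < scenario$nSnps) {
      guard <- guard + 1L
      if (guard > 50L) stop("MAF ascertainment failed to accumulate SNPs")
      F0 <- matrix(NA_real_, C, batch)
      F0[scenario$wave1$origin, ] <- runif(batch, 0.05, 0.95)
      Fend <- .geneticsForward(F0, demography$sizes, demography$resident,
                               demography$outContrib, demography$allowed,
                               demography$nbr)
      pcell <- Fend[cells, , drop = FALSE]
      pooled <- colMeans(pcell)
      maf <- pmin(pooled, 1 - pooled)
      pass <- maf >= scenario$mafMin
      freqKeep <- cbind(freqKeep, Fend[, pass, drop = FALSE])
    }
    freqKeep <- freqKeep[, seq_len(scenario$nSnps), drop = FALSE]
    nInd <- scenario$samplesPerCell
    ids <- as.vector(vapply(siteCodes, function(s)
      sprintf("%s_%02d", s, seq_len(nInd)), character(nInd)))
    calls <- matrix(NA_integer_, scenario$nSnps, length(ids))
    for (k in seq_along(cells)) {
      p <- freqKeep[cells[k], ]
      calls[, (k - 1L) * nInd + seq_len(nInd)] <-
        rbinom(scenario$nSnps * nInd, 2L, rep(p, nInd))
    }
    map <- data.frame(chromosome = "01",
                      position = seq_len(scenario$nSnps) * 100000L,
                      id = sprintf("sim%05d", seq_len(scenario$nSnps)))
    gm <- GenotypeMatrix(calls, map, ids)
    st <- SiteTable(sitesDf, setNames(rep(siteCodes, each = nInd), ids))
    list(frequencies = freqKeep, genotypes = gm, sites = st)
  })
}

#' Run a scenario end to end
#'
#' @param scenario a \code{\link{scenarioConfig}}
#' @return list with \code{demography}, \code{genetics} (see
#'   \code{\link{runGenetics}}) and the \code{scenario}.
#' @export
runScenario <- function(scenario) {
  demo <- runDemography(scenario)
  gen <- runGenetics(demo, scenario)
  list(demography = demo, genetics = gen, scenario = scenario)
}

#' Compare two simulated scenarios
#'
#' For each scenario: pairwise Weir-Cockerham Fst between sampled demes
#' (negatives clamped), classical MDS, and Procrustes against the deme
#' coordinates. Across scenarios: Procrustes of the two MDS
#' configurations, and a linear fit between the two bearing-correlogram
#' profiles r(theta) with its adjusted R-squared.
#'
#' @param outA,outB results of \code{\link{runScenario}} sharing the same
#'   sample-cell geometry
#' @param nPerm permutations for the Procrustes tests (999)
#' @param seed RNG seed
#' @return list with per-scenario \code{fst}, \code{mds},
#'   \code{protestGeo}; and cross-scenario \code{protestCross},
#'   \code{profileR2}, \code{bearingA}, \code{bearingB}.
#' @export
compareScenarios <- function(outA, outB, nPerm = 999L, seed = 1L) {
  sa <- outA$genetics$sites; sb <- outB$genetics$sites
  if (!isTRUE(all.equal(siteCoords(sa)[, c("site", "lat", "lon")],
                        siteCoords(sb)[, c("site", "lat", "lon")])))
    stop("scenarios do not share sample-cell geometry")
  one <- function(out, tag) {
    fst <- wcFst(out$genetics$genotypes, out$genetics$sites, minSize = 1L)
    mds <- classicalMds(PairMatrix(pairValues(fst$pairwise), "distance",
                                   pairLabels(fst$pairwise)), k = 2L)
    geo <- geographicTarget(out$genetics$sites)
    pg <- procrustesProtest(mds$coordinates, geo, nPerm = nPerm,
                            seed = .childSeed(seed, paste0("geo", tag)))
    bear <- bearingCorrelogram(fst$pairwise, out$genetics$sites,
                               stepDeg = 2L, nPerm = 0L)
    list(fst = fst, mds = mds, protestGeo = pg, bearing = bear)
  }
  A <- one(outA, "A")
  B <- one(outB, "B")
  pc <- procrustesProtest(A$mds$coordinates, B$mds$coordinates,
                          nPerm = nPerm, seed = .childSeed(seed, "cross"))
  fit <- stats::lm(B$bearing$r ~ A$bearing$r)
  list(A = A, B = B, protestCross = pc,
       profileR2 = summary(fit)$adj.r.squared,
       bearingArgmaxA = A$bearing$argmax,
       bearingArgmaxB = B$bearing$argmax)
}
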