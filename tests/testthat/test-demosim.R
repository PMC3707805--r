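# Lattice range-expansion simulator: demography, drift, scenario runs.

smallScenario <- function(discontinuity = FALSE, nSnps = 60L, seed = 1L) {
  world <- latticeWorld(12L, 12L)
  cells <- as.integer(outer(5:7, 2:4, function(r, c)
    cellIndex(world, r, c)))
  scenarioConfig(
    world,
    wave1 = list(origin = cellIndex(world, 12L, 12L), startGen = 100L,
                 K = 200, r = 0.5, m = 0.4),
    wave2 = list(origin = cellIndex(world, 12L, 12L), startGen = 80L,
                 K = 1000, r = 0.8, m = 0.8),
    discontinuity = if (discontinuity)
      list(cells = cells[1:6], startGen = 70L, endGen = 35L) else NULL,
    sampleCells = cells, nSnps = nSnps, samplesPerCell = 10L, seed = seed)
}

test_that("demography empties discontinuity cells exactly in the window", {
  sc <- smallScenario(TRUE)
  demo <- runDemography(sc)
  gensBP <- sc$wave1$startGen - (seq_len(nrow(demo$sizes)) - 1L)
  inWin <- gensBP <= 70 & gensBP > 35
  cells <- sc$discontinuity$cells
  expect_true(all(demo$sizes[inWin, cells] == 0))
  # occupied immediately before and soon after the window
  expect_true(all(demo$sizes[gensBP == 71, cells] > 0))
  expect_true(all(demo$sizes[gensBP == 30, cells] > 0))
})

test_that("total population never exceeds total carrying capacity", {
  demo <- runDemography(smallScenario(FALSE))
  KMax <- 144 * 1000
  expect_true(all(rowSums(demo$sizes) <= KMax + 1e-6))
})

test_that("the colonization front is monotone in lattice distance", {
  sc <- smallScenario(FALSE)
  demo <- runDemography(sc)
  C <- 144L
  row <- ((seq_len(C) - 1L) %% 12L) + 1L
  col <- ((seq_len(C) - 1L) %/% 12L) + 1L
  d <- abs(12L - row) + abs(12L - col)
  cg <- demo$colonizationGen
  expect_true(all(!is.na(cg)))
  means <- tapply(cg, d, mean)
  expect_true(all(diff(means) <= 0))      # farther = later (smaller BP)
  for (dd in sort(unique(d))[-1])         # no cell beats all nearer cells
    expect_false(min(cg[d == dd]) > max(cg[d == dd - 1]))
})

test_that("simulation output is seed-deterministic and layered correctly", {
  sc <- smallScenario(FALSE, nSnps = 30L, seed = 4L)
  a <- runScenario(sc)
  b <- runScenario(sc)
  expect_identical(a$genetics$frequencies, b$genetics$frequencies)
  expect_identical(genotypeCalls(a$genetics$genotypes),
                   genotypeCalls(b$genetics$genotypes))
  # demography is genetics-independent
  g2 <- runGenetics(a$demography, sc, seed = 999L)
  expect_false(identical(a$genetics$frequencies, g2$frequencies))
  expect_identical(a$demography$sizes, runDemography(sc)$sizes)
  # frequencies lie in [0, 1]; ascertainment holds
  expect_true(all(a$genetics$frequencies >= 0 &
                    a$genetics$frequencies <= 1, na.rm = TRUE))
  p <- rowMeans(genotypeCalls(a$genetics$genotypes)) / 2
  expect_true(all(pmin(p, 1 - p) >= 0.01))
})

test_that("isolated demes drift like Wright-Fisher populations", {
  # fixation probability equals the initial frequency
  set.seed(81)
  N <- 50; T <- 1500; nsnp <- 1500
  p0 <- runif(nsnp, 0.1, 0.9)
  Fend <- clinekit:::.geneticsForward(
    matrix(p0, 1, nsnp), matrix(N, T + 1, 1), matrix(N, T, 1),
    matrix(0, T, 1), matrix(1L, T, 1), matrix(0L, 1, 4))
  fixedUp <- Fend[1, ] == 1
  segregating <- Fend[1, ] > 0 & Fend[1, ] < 1
  expect_lt(mean(segregating), 0.01)
  se <- sqrt(mean(p0 * (1 - p0)) / nsnp + var(p0) / nsnp)
  expect_lt(abs(mean(fixedUp) - mean(p0)), 4 * se)

  # two isolated demes drift independently
  set.seed(82)
  p0 <- runif(400, 0.3, 0.7)
  F2 <- clinekit:::.geneticsForward(
    rbind(p0, p0), matrix(40, 81, 2), matrix(40, 80, 2),
    matrix(0, 80, 2), matrix(1L, 80, 2), matrix(0L, 2, 4))
  drift <- F2 - rbind(p0, p0)
  expect_lt(abs(cor(drift[1, ], drift[2, ])), 0.15)

  # no mutation: monomorphic SNPs stay monomorphic
  F3 <- clinekit:::.geneticsForward(
    matrix(c(0, 1, 0.5), 1), matrix(30, 51, 1), matrix(30, 50, 1),
    matrix(0, 50, 1), matrix(1L, 50, 1), matrix(0L, 1, 4))
  expect_equal(F3[1, 1], 0)
  expect_equal(F3[1, 2], 1)
})

test_that("a scenario compared with itself is a perfect match", {
  sc <- smallScenario(FALSE, nSnps = 80L, seed = 6L)
  out <- runScenario(sc)
  cmp <- compareScenarios(out, out, nPerm = 99, seed = 1)
  expect_gt(cmp$protestCross$r, 1 - 1e-9)
  expect_equal(cmp$profileR2, 1, tolerance = 1e-9)
})

test_that("a site-scrambled copy loses the cross-scenario correlation", {
  sc <- smallScenario(FALSE, nSnps = 80L, seed = 7L)
  out <- runScenario(sc)
  scram <- out
  st <- out$genetics$sites
  a <- siteAssignment(st)
  codes <- siteCoords(st)$site
  relabel <- withr::with_seed(3, setNames(sample(codes), codes))
  scram$genetics$sites <- assignSites(st, setNames(relabel[unname(a)],
                                                   names(a)))
  cmp <- compareScenarios(out, scram, nPerm = 199, seed = 2)
  expect_gt(cmp$protestCross$p, 0.05)
})

test_that("scenario validation catches bad configurations", {
  world <- latticeWorld(6L, 6L, habitable = matrix(c(FALSE,
                                                     rep(TRUE, 35)), 6))
  expect_error(scenarioConfig(
    world,
    wave1 = list(origin = 1L, startGen = 50L, K = 100, r = 0.5, m = 0.4),
    wave2 = list(origin = 36L, startGen = 30L, K = 500, r = 0.8, m = 0.8),
    sampleCells = 36L), "not habitable")
})
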