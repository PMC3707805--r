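# The cleaning chain: Tukey IBS screening, missingness, exact HWE,
# Kendall tau-b and LD pruning.

twoSites <- SiteTable(data.frame(site = c("AAA", "BBB"), lat = c(52, 53),
                                 lon = c(5, 6)))

test_that("a planted duplicate pair is flagged related, one member kept", {
  set.seed(21)
  cfg <- synthConfig(nSnps = 2000, clineStrength = 0.02, nPerSite = 12,
                     seed = 31)
  ds <- generateClinalDataset(cfg, twoSites)
  g <- genotypeCalls(ds$genotypes)
  g[, "AAA_02"] <- g[, "AAA_01"]          # exact duplicate
  gm <- GenotypeMatrix(g, markerMap(ds$genotypes), colnames(g))
  fl <- tukeyIbsOutliers(gm, ds$sites)
  rel <- fl$id[fl$reason == "related"]
  expect_true(any(c("AAA_01", "AAA_02") %in% rel))
  # lexicographic tie-break on equal missingness keeps the smaller id
  expect_true("AAA_02" %in% rel)
  expect_false("AAA_01" %in% rel)
})

test_that("a planted frequency-shift outlier is flagged", {
  hits <- 0
  for (s in 1:3) {
    cfg <- synthConfig(nSnps = 20000, clineStrength = 0.02, nPerSite = 15,
                       nOutliers = 1, seed = 300 + s)
    ds <- generateClinalDataset(cfg, twoSites)
    fl <- tukeyIbsOutliers(ds$genotypes, ds$sites)
    hits <- hits + (ds$truth$outliers %in% fl$id[fl$reason == "outlier"])
  }
  expect_gte(hits, 2)
})

test_that("homogeneous subpopulations rarely produce outlier flags", {
  oneSite <- SiteTable(data.frame(site = "AAA", lat = 52, lon = 5))
  tot <- 0
  for (s in 1:20) {
    cfg <- synthConfig(nSnps = 200, clineStrength = 0, nPerSite = 20,
                       seed = 1000 + s)
    ds <- generateClinalDataset(cfg, oneSite)
    fl <- tukeyIbsOutliers(ds$genotypes, ds$sites)
    tot <- tot + sum(fl$reason == "outlier")
  }
  expect_lte(tot, 2)
})

test_that("small subpopulations are skipped with a message", {
  gm <- tinyGm(matrix(0L, 5, 2), ids = c("x1", "x2"))
  st <- assignSites(SiteTable(data.frame(site = "AAA", lat = 52, lon = 5)),
                    c(x1 = "AAA", x2 = "AAA"))
  expect_message(fl <- tukeyIbsOutliers(gm, st), "skipped")
  expect_equal(nrow(fl), 0L)
})

test_that("missingness filter uses a strict per-subpopulation threshold", {
  set.seed(22)
  calls <- matrix(sample(0:2, 3 * 40, TRUE), 3, 40)
  ids <- c(sprintf("A%02d", 1:20), sprintf("B%02d", 1:20))
  calls[1, 1:3] <- NA            # 3/20 = 15% missing in site AAA
  calls[2, c(1:2, 21:22)] <- NA  # exactly 10% in both sites
  gm <- tinyGm(calls, ids = ids)
  st <- assignSites(twoSites, setNames(rep(c("AAA", "BBB"), each = 20),
                                       ids))
  kept <- missingnessFilter(gm, st, maxRate = 0.10)
  expect_false("s001" %in% kept)   # above threshold
  expect_true("s002" %in% kept)    # boundary: exactly 10% is kept
  expect_true("s003" %in% kept)    # fully typed
})

test_that("exact HWE test matches enumeration and drives the filter", {
  # all heterozygous: extreme departure
  expect_lt(hweExactTest(0, 50, 0), 1e-12)
  # perfect HW proportions: p in the upper range
  expect_gt(hweExactTest(25, 50, 25), 0.5)
  # monomorphic: defined as 1
  expect_equal(hweExactTest(30, 0, 0), 1)

  set.seed(23)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    nAB <- sample(0:n, 1); nAA <- sample(0:(n - nAB), 1)
    nBB <- n - nAB - nAA
    expect_equal(hweExactTest(nAA, nAB, nBB), hweOracle(nAA, nAB, nBB),
                 tolerance = 1e-12)
  }

  # filter removes the all-het SNP, keeps HW-proportioned and monomorphic
  calls <- rbind(rep(1L, 40),
                 rep(c(0L, 1L, 1L, 2L), 10),
                 rep(0L, 40))
  ids <- sprintf("A%02d", 1:40)
  gm <- tinyGm(calls, ids = ids)
  st <- assignSites(SiteTable(data.frame(site = "AAA", lat = 52, lon = 5)),
                    setNames(rep("AAA", 40), ids))
  kept <- hweFilter(gm, st)
  expect_equal(kept, c("s002", "s003"))
})

test_that("Kendall tau-b from the genotype table matches oracles", {
  x <- c(0L, 0L, 1L, 2L, 2L, 1L, 0L, 2L)
  expect_equal(kendallTauB(x, x), 1)
  expect_equal(kendallTauB(x, 2L - x), -1)

  x5 <- c(0L, 0L, 1L, 2L, 2L); y5 <- c(0L, 1L, 1L, 1L, 2L)
  expect_equal(kendallTauB(x5, y5), tauOracle(x5, y5))

  set.seed(24)
  for (i in 1:25) {
    a <- sample(c(0:2, NA), 30, TRUE, c(.3, .3, .3, .1))
    b <- sample(c(0:2, NA), 30, TRUE, c(.3, .3, .3, .1))
    t1 <- kendallTauB(a, b)
    ok <- !is.na(a) & !is.na(b)
    t2 <- if (length(unique(a[ok])) < 2 || length(unique(b[ok])) < 2)
      NA_real_ else unname(cor(a[ok], b[ok], method = "kendall"))
    expect_equal(t1, t2, tolerance = 1e-12)
  }
  expect_true(is.na(kendallTauB(c(NA, NA), c(0L, 1L))))
})

test_that("LD pruning removes near duplicates within the window only", {
  set.seed(25)
  base <- sample(0:2, 60, TRUE, c(.25, .5, .25))
  calls <- rbind(base,
                 base,                      # duplicate 1 kb downstream
                 sample(0:2, 60, TRUE),
                 base)                      # duplicate 600 kb downstream
  gm <- tinyGm(calls, positions = c(100000L, 101000L, 350000L, 701000L))
  kept <- ldPrune(gm)
  expect_false("s002" %in% kept)  # inside the window, |tau| = 1
  expect_true("s004" %in% kept)   # outside the 500 kb window
  expect_true(all(c("s001", "s003") %in% kept))
})

test_that("independent SNPs survive LD pruning almost entirely", {
  rates <- numeric(3)
  for (s in 1:3) {
    cfg <- synthConfig(nSnps = 400, clineStrength = 0.05, nPerSite = 30,
                       seed = 2000 + s)
    ds <- generateClinalDataset(cfg, twoSites)
    rates[s] <- length(ldPrune(ds$genotypes)) / 400
  }
  expect_true(all(rates >= 0.95))
})

test_that("the QC chain is idempotent apart from recomputed Tukey flags", {
  cfg <- synthConfig(nSnps = 400, clineStrength = 0.05, nPerSite = 12,
                     missingRate = 0.02, seed = 55)
  ds <- generateClinalDataset(cfg, dutchSiteFixture())
  first <- runQc(ds$genotypes, ds$sites)
  # with the individual set held fixed (a huge k disables the Tukey
  # fences), the marker filters remove nothing further
  again <- runQc(first$genotypes, ds$sites, k = 100)
  expect_equal(nrow(again$excludedSnps), 0L)
  expect_equal(nMarkers(again$genotypes), nMarkers(first$genotypes))
  expect_equal(nrow(again$excludedIndividuals), 0L)
  # recomputed Tukey fences on the trimmed pools may flag a few more
  # borderline pairs (an inherent property of quartile fences), but the
  # second pass must not cascade
  reflag <- runQc(first$genotypes, ds$sites)
  expect_lte(nrow(reflag$excludedIndividuals),
             max(3L, nrow(first$excludedIndividuals)))
})
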