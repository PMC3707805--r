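# Weir-Cockerham Fst and AMOVA.

test_that("combined Fst hits its analytic anchors", {
  st <- SiteTable(data.frame(site = c("P1", "P2"), lat = c(52, 53),
                             lon = c(5, 6)))
  # same frequency in both populations: near zero
  freq <- matrix(0.5, 200, 2)
  d <- drawAtFrequencies(freq, st, nPer = 100, seed = 41)
  f <- wcFst(d$gm, d$sites, minSize = 1)
  expect_lt(abs(pairValues(f$pairwise)["P1", "P2"]), 0.01)

  # fixed difference: exactly one
  freqFix <- cbind(rep(1, 100), rep(0, 100))
  dfx <- drawAtFrequencies(freqFix, st, nPer = 50, seed = 42)
  ffx <- wcFst(dfx$gm, dfx$sites, minSize = 1)
  expect_equal(pairValues(ffx$pairwise)["P1", "P2"], 1, tolerance = 1e-9)
})

test_that("per-SNP theta matches the symbolic WC84 evaluation", {
  st <- SiteTable(data.frame(site = c("P1", "P2"), lat = c(52, 53),
                             lon = c(5, 6)))
  mk <- function(c1, c2) {
    calls <- cbind(matrix(rep(c(0L, 1L, 2L), c1), nrow = 1),
                   matrix(rep(c(0L, 1L, 2L), c2), nrow = 1))
    ids <- c(sprintf("A%02d", seq_len(sum(c1))),
             sprintf("B%02d", seq_len(sum(c2))))
    gm <- tinyGm(calls, ids = ids)
    list(gm = gm,
         sites = assignSites(st, setNames(rep(c("P1", "P2"),
                                              c(sum(c1), sum(c2))), ids)))
  }
  # toy counts AA/AB/BB = (10,0,0) vs (0,0,10): fully fixed difference
  d <- mk(c(10, 0, 0), c(0, 0, 10))
  f <- wcFst(d$gm, d$sites, minSize = 1)
  o <- wcOracle(c(10, 0, 0), c(0, 0, 10))
  expect_equal(unname(f$perSnpTheta), o["a"] / sum(o), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unname(f$perSnpTheta), 1, tolerance = 1e-12)

  set.seed(43)
  for (i in 1:20) {
    c1 <- as.vector(rmultinom(1, sample(5:40, 1), runif(3)))
    c2 <- as.vector(rmultinom(1, sample(5:40, 1), runif(3)))
    o <- wcOracle(c1, c2)
    d <- mk(c1, c2)
    f <- wcFst(d$gm, d$sites, minSize = 1)
    expected <- if (sum(o) == 0 || is.nan(sum(o))) NA_real_ else
      o[["a"]] / sum(o)
    expect_equal(unname(f$perSnpTheta), expected, tolerance = 1e-12)
  }
})

test_that("combined Fst is a ratio of sums: order and duplication invariant", {
  st <- SiteTable(data.frame(site = c("P1", "P2"), lat = c(52, 53),
                             lon = c(5, 6)))
  set.seed(44)
  freq <- cbind(runif(60, .2, .8), runif(60, .2, .8))
  d <- drawAtFrequencies(freq, st, nPer = 30, seed = 45)
  f0 <- pairValues(wcFst(d$gm, d$sites, minSize = 1)$pairwise)["P1", "P2"]

  g <- genotypeCalls(d$gm)
  shuf <- sample(nrow(g))
  gmShuf <- GenotypeMatrix(g[shuf, ], markerMap(d$gm)[shuf, ],
                           colnames(g))
  fShuf <- pairValues(wcFst(gmShuf, d$sites,
                            minSize = 1)$pairwise)["P1", "P2"]
  expect_equal(fShuf, f0, tolerance = 1e-12)

  mm <- markerMap(d$gm)
  mm2 <- mm; mm2$id <- paste0(mm2$id, "dup"); mm2$position <- mm2$position + 7L
  gmDup <- GenotypeMatrix(rbind(g, g), rbind(mm, mm2), colnames(g))
  fDup <- pairValues(wcFst(gmDup, d$sites,
                           minSize = 1)$pairwise)["P1", "P2"]
  expect_equal(fDup, f0, tolerance = 1e-12)
})

test_that("pairwise matrix respects the subpopulation size floor", {
  st <- SiteTable(data.frame(site = c("P1", "P2", "P3"),
                             lat = c(52, 53, 51.5), lon = c(5, 6, 4.5)))
  freq <- matrix(runif(30, .2, .8), 30, 3)
  sc <- siteCoords(st)
  ids <- c(sprintf("A%02d", 1:12), sprintf("B%02d", 1:12),
           sprintf("C%02d", 1:5))
  set.seed(46)
  calls <- cbind(matrix(rbinom(30 * 12, 2, freq[, 1]), 30),
                 matrix(rbinom(30 * 12, 2, freq[, 2]), 30),
                 matrix(rbinom(30 * 5, 2, freq[, 3]), 30))
  gm <- tinyGm(calls, ids = ids)
  sta <- assignSites(st, setNames(rep(c("P1", "P2", "P3"),
                                      c(12, 12, 5)), ids))
  f <- wcFst(gm, sta, minSize = 10)
  expect_setequal(f$pairwisePops, c("P1", "P2"))
  expect_true(all(pairValues(f$pairwise) >= 0))
})

test_that("AMOVA components behave at the degenerate and planted extremes", {
  st <- SiteTable(data.frame(site = c("P1", "P2", "P3", "P4"),
                             lat = c(52, 52.5, 53, 53.5),
                             lon = c(5, 5.5, 6, 6.5)))
  groups <- c(P1 = "g1", P2 = "g1", P3 = "g2", P4 = "g2")

  # all individuals identical: every component zero
  ids <- sprintf("i%02d", 1:20)
  gmZ <- tinyGm(matrix(1L, 10, 20), ids = ids)
  stZ <- assignSites(st, setNames(rep(c("P1", "P2", "P3", "P4"), each = 5),
                                  ids))
  az <- amova(gmZ, stZ, groups, nPerm = 19, seed = 1)
  expect_equal(unname(az$components), c(0, 0, 0))
  expect_equal(unname(az$percent), c(0, 0, 0))

  # strongly diverged groups: large among-group share, small p (its floor
  # is set by the number of distinct site partitions, not 1/(B+1))
  st10 <- SiteTable(data.frame(site = sprintf("Q%02d", 1:10),
                               lat = seq(51, 53.5, length.out = 10),
                               lon = seq(4, 6.5, length.out = 10)))
  groups10 <- setNames(rep(c("g1", "g2"), each = 5), sprintf("Q%02d", 1:10))
  set.seed(47)
  freq <- matrix(runif(80, .25, .45), 80, 10)
  freq[, 6:10] <- 1 - freq[, 6:10]          # groups drawn far apart
  d <- drawAtFrequencies(freq, st10, nPer = 8, seed = 48)
  ad <- amova(d$gm, d$sites, groups10, nPerm = 99, seed = 2)
  expect_gt(ad$percent[["a"]], 20)
  expect_lte(ad$p[["amongGroups"]], 0.05)

  # group membership mismatch is an error
  expect_error(amova(d$gm, d$sites, groups[1:3], nPerm = 9, seed = 1),
               "without group")
})
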