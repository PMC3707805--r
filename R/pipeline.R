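# End-to-end orchestration: QC -> relationship matrices -> MDS/Procrustes
# -> Fst -> spatial tests -> gradient scan, from one configuration list,
# with per-stage seed substreams and a reproducibility manifest.

#' Configuration for \code{\link{runPipeline}}
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}, or a path readable by
#'   \code{\link{readGenotypes}}
#' @param sites a \linkS4class{SiteTable} (with assignment), or a sites
#'   TSV path (then \code{assignmentPath} is required)
#' @param format genotype file format when \code{genotypes} is a path
#' @param assignmentPath assignment TSV when \code{sites} is a path
#' @param stages character vector of enabled stages, a subset of
#'   \code{c("qc", "distances", "mds", "fst", "spatial", "scan")}
#' @param seed master seed; every stage derives its own substream, so
#'   disabling one stage does not perturb another
#' @param nPerm permutations for all permutation tests
#' @param scanPerm permutations for the local Moran scan
#' @param outDir output directory for stage TSVs and the manifest (NULL:
#'   nothing written)
#' @param qcArgs,fstArgs extra arguments for \code{\link{runQc}} /
#'   \code{\link{wcFst}}
#' @return configuration list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(genotypes, sites, format = "vcf",
                           assignmentPath = NULL,
                           stages = c("qc", "distances", "mds", "fst",
                                      "spatial", "scan"),
                           seed = 1L, nPerm = 999L, scanPerm = 2000L,
                           outDir = NULL, qcArgs = list(),
                           fstArgs = list()) {
  stopifnot(all(stages %in% c("qc", "distances", "mds", "fst", "spatial",
                              "scan")))
  structure(list(genotypes = genotypes, sites = sites, format = format,
                 assignmentPath = assignmentPath, stages = stages,
                 seed = as.integer(seed), nPerm = as.integer(nPerm),
                 scanPerm = as.integer(scanPerm), outDir = outDir,
                 qcArgs = qcArgs, fstArgs = fstArgs),
            class = "pipelineConfig")
}

#' Run the full cline analysis pipeline
#'
#' Stages run in fixed order; each stage's outputs (and a manifest with
#' seeds, per-stage counts and the package version) are returned and,
#' when an output directory is configured, written as TSV/JSON.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return list with the per-stage results (\code{qc}, \code{distances},
#'   \code{mds}, \code{fst}, \code{spatial}, \code{scan}; disabled stages
#'   are NULL) and \code{manifest}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  gm <- config$genotypes
  if (is.character(gm)) {
    if (!file.exists(gm)) stop("missing genotype input: ", gm)
    gm <- readGenotypes(gm, config$format)
  }
  sites <- config$sites
  if (is.character(sites)) {
    if (!file.exists(sites)) stop("missing sites input: ", sites)
    sites <- readSites(sites, config$assignmentPath)
  }
  seed <- config$seed
  on <- function(stage) stage %in% config$stages
  manifest <- list(seed = seed, stages = config$stages,
                   nPerm = config$nPerm,
                   version = as.character(packageVersion("clinekit")),
                   individualsIn = nIndividuals(gm), snpsIn = nMarkers(gm))
  res <- list()

  if (on("qc")) {
    res$qc <- do.call(runQc, c(list(gm, sites), config$qcArgs))
    gm <- res$qc$genotypes
    manifest$qcCounts <- res$qc$counts
  }
  manifest$individualsUsed <- nIndividuals(gm)
  manifest$snpsUsed <- nMarkers(gm)

  if (on("distances")) {
    d2 <- d2Distance(gm)
    res$distances <- list(ibs = ibsDistance(gm), d2 = d2,
                          covariance = covarianceFromD2(d2))
  }
  if (on("mds")) {
    dIbs <- if (!is.null(res$distances)) res$distances$ibs else
      ibsDistance(gm)
    mds <- classicalMds(dIbs, k = 2L)
    siteMeans <- siteMeanCoords(mds$coordinates, sites)
    geo <- geographicTarget(sites)[rownames(siteMeans), ]
    res$mds <- list(mds = mds, siteMeans = siteMeans,
                    protest = procrustesProtest(
                      siteMeans, geo, nPerm = config$nPerm,
                      seed = .childSeed(seed, "mds-protest")))
  }
  if (on("fst")) {
    res$fst <- do.call(wcFst, c(list(gm, sites), config$fstArgs))
  }
  if (on("spatial")) {
    geoD <- geodesicDistance(sites)
    cov <- if (!is.null(res$distances)) res$distances$covariance else
      covarianceFromD2(d2Distance(gm))
    auto <- spatialAutocorrelogram(cov, geoD, siteAssignment(sites),
                                   nPerm = config$nPerm,
                                   seed = .childSeed(seed, "autocorr"))
    spatial <- list(autocorrelogram = auto)
    if (!is.null(res$fst) && length(pairLabels(res$fst$pairwise)) >= 4L) {
      fstPm <- res$fst$pairwise
      keep <- pairLabels(fstPm)
      geoSub <- PairMatrix(pairValues(geoD)[keep, keep], "geographic",
                           keep)
      spatial$mantel <- mantelTest(fstPm, geoSub, nPerm = config$nPerm,
                                   seed = .childSeed(seed, "mantel"))
      spatial$bearing <- bearingCorrelogram(
        fstPm, sites, nPerm = config$nPerm,
        seed = .childSeed(seed, "bearing"))
    }
    res$spatial <- spatial
  }
  if (on("scan")) {
    fit <- fitSnpGradients(gm, sites)
    ok <- fit$fits$converged
    scan <- localMoranScan(setNames(fit$fits$magnitude[ok],
                                    fit$fits$id[ok]),
                           fit$fits[ok, c("chromosome", "position", "id")],
                           nPerm = config$scanPerm,
                           seed = .childSeed(seed, "scan"))
    res$scan <- list(gradients = fit, scan = scan,
                     significant = manhattanTable(scan))
  }
  manifest$stagesRun <- intersect(c("qc", "distances", "mds", "fst",
                                    "spatial", "scan"), config$stages)
  res$manifest <- manifest

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, name) write.table(
      df, file.path(config$outDir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(res$qc)) {
      wtsv(res$qc$excludedIndividuals, "qc_excluded_individuals.tsv")
      wtsv(res$qc$excludedSnps, "qc_excluded_snps.tsv")
    }
    if (!is.null(res$distances))
      writeMatrix(res$distances$ibs,
                  file.path(config$outDir, "ibs_distance.tsv"))
    if (!is.null(res$mds))
      wtsv(data.frame(site = rownames(res$mds$siteMeans),
                      res$mds$siteMeans), "mds_site_means.tsv")
    if (!is.null(res$fst))
      writeMatrix(res$fst$pairwise,
                  file.path(config$outDir, "fst_pairwise.tsv"))
    if (!is.null(res$spatial))
      wtsv(res$spatial$autocorrelogram$classes, "autocorrelogram.tsv")
    if (!is.null(res$scan)) wtsv(res$scan$scan, "moran_scan.tsv")
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
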