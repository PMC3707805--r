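#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor dist median quantile pchisq rbinom runif rnorm setNames
#'   complete.cases var optim glm.fit binomial plogis qlogis sd p.adjust
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom Rcpp sourceCpp
#' @useDynLib clinekit, .registration = TRUE
NULL

MISSING_CODE <- NA_integer_

#' GenotypeMatrix: diploid biallelic SNP genotypes with a marker map
#'
#' Container for a SNP-by-individual matrix of alternate-allele dosages
#' (0, 1, 2 or \code{NA} for missing), built on
#' \linkS4class{SummarizedExperiment}. Rows are markers, columns are
#' individuals; the marker map (chromosome, 1-based bp position, marker id)
#' lives in \code{rowData}. Positions are sorted within chromosome on
#' construction and must be strictly increasing.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}; the single
#'   assay is named \code{"calls"}.
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  g <- SummarizedExperiment::assay(object, "calls")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    msgs <- c(msgs, "calls must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chromosome", "position", "id") %in% colnames(rd)))
    msgs <- c(msgs, "rowData must have chromosome, position, id")
  else {
    if (anyDuplicated(rd$id))
      msgs <- c(msgs, "marker ids must be unique")
    for (ch in unique(rd$chromosome)) {
      pos <- rd$position[rd$chromosome == ch]
      if (length(pos) > 1L && any(diff(pos) <= 0)) {
        msgs <- c(msgs, sprintf(
          "positions not strictly increasing on chromosome %s", ch))
        break
      }
    }
  }
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "individual ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix, markers x individuals, entries 0/1/2/NA
#'   (alternate-allele dosage).
#' @param markerMap data.frame with columns \code{chromosome},
#'   \code{position} (1-based bp), \code{id}; one row per marker.
#' @param individualIds character vector of unique individual ids; defaults
#'   to \code{colnames(calls)}.
#' @return A \linkS4class{GenotypeMatrix}; markers are reordered by
#'   (chromosome, position).
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                      data.frame(chromosome = "1", position = c(100L, 200L),
#'                                 id = c("s1", "s2")),
#'                      c("a", "b"))
#' nMarkers(gm)
#' @export
GenotypeMatrix <- function(calls, markerMap, individualIds = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individualIds))
    stop("individual ids are required")
  markerMap <- as.data.frame(markerMap)
  stopifnot(nrow(markerMap) == nrow(calls),
            length(individualIds) == ncol(calls))
  markerMap$chromosome <- as.character(markerMap$chromosome)
  markerMap$position <- as.integer(markerMap$position)
  markerMap$id <- as.character(markerMap$id)
  ord <- order(markerMap$chromosome, markerMap$position)
  calls <- calls[ord, , drop = FALSE]
  markerMap <- markerMap[ord, , drop = FALSE]
  rownames(calls) <- markerMap$id
  colnames(calls) <- individualIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls),
    rowData = S4Vectors::DataFrame(markerMap, row.names = markerMap$id))
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix the dosage matrix (markers x individuals)
#' @param x,object a GenotypeMatrix
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @describeIn GenotypeMatrix marker map as a data.frame in map order
#' @export
markerMap <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))[, c("chromosome",
                                                      "position", "id")]

#' @describeIn GenotypeMatrix individual ids
#' @export
individualIds <- function(x) colnames(x)

#' @describeIn GenotypeMatrix number of markers
#' @export
nMarkers <- function(x) nrow(x)

#' @describeIn GenotypeMatrix number of individuals
#' @export
nIndividuals <- function(x) ncol(x)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object), "markers x", ncol(object),
      "individuals\n")
  cat("  chromosomes:",
      paste(unique(SummarizedExperiment::rowData(object)$chromosome),
            collapse = " "), "\n")
  g <- SummarizedExperiment::assay(object, "calls")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(g))))
})

#' SiteTable: sampling sites and individual-to-site assignment
#'
#' Holds sampling-site codes with WGS84 decimal-degree coordinates and a
#' mapping from individual ids to site codes.
#'
#' @slot sites data.frame with columns \code{site}, \code{lat}, \code{lon}
#'   (and optionally extra columns such as sample sizes).
#' @slot assignment named character vector: names are individual ids,
#'   values are site codes.
#' @export
setClass("SiteTable", representation(sites = "data.frame",
                                     assignment = "character"))

setValidity("SiteTable", function(object) {
  s <- object@sites
  msgs <- character()
  if (!all(c("site", "lat", "lon") %in% colnames(s)))
    return("sites needs columns site, lat, lon")
  if (anyDuplicated(s$site)) msgs <- c(msgs, "site codes must be unique")
  if (any(s$lat < -90 | s$lat > 90))
    msgs <- c(msgs, "latitude out of [-90, 90]")
  if (any(s$lon < -180 | s$lon > 180))
    msgs <- c(msgs, "longitude out of [-180, 180]")
  if (length(object@assignment)) {
    bad <- setdiff(unique(object@assignment), s$site)
    if (length(bad))
      msgs <- c(msgs, paste("assignment to unknown site(s):",
                            paste(bad, collapse = ", ")))
    if (is.null(names(object@assignment)) ||
        anyDuplicated(names(object@assignment)))
      msgs <- c(msgs, "assignment must be named by unique individual ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SiteTable
#'
#' @param sites data.frame with columns \code{site}, \code{lat}, \code{lon}.
#' @param assignment named character vector mapping individual id -> site code
#'   (may be empty and attached later with \code{assignSites}).
#' @return A \linkS4class{SiteTable}.
#' @export
SiteTable <- function(sites, assignment = character()) {
  sites <- as.data.frame(sites)
  sites$site <- as.character(sites$site)
  new("SiteTable", sites = sites,
      assignment = setNames(as.character(assignment), names(assignment)))
}

#' @describeIn SiteTable the site coordinate table
#' @param x,object a SiteTable
#' @export
siteCoords <- function(x) x@sites

#' @describeIn SiteTable named site vector over individuals
#' @export
siteAssignment <- function(x) x@assignment

#' @describeIn SiteTable replace the individual-to-site assignment
#' @param assignment named character vector individual -> site
#' @export
assignSites <- function(x, assignment) {
  new("SiteTable", sites = x@sites,
      assignment = setNames(as.character(assignment), names(assignment)))
}

setMethod("show", "SiteTable", function(object) {
  cat("SiteTable:", nrow(object@sites), "sites,",
      length(object@assignment), "assigned individuals\n")
})

#' PairMatrix: labelled symmetric pairwise matrix
#'
#' A symmetric matrix over labelled units (individuals or subpopulations)
#' tagged with its kind: \code{"distance"}, \code{"covariance"},
#' \code{"fst"} or \code{"geographic"}. Distance-kind matrices must have a
#' zero diagonal and nonnegative entries; fst-kind must be nonnegative.
#'
#' @slot labels ordered unit ids.
#' @slot values symmetric numeric matrix.
#' @slot kind one of distance, covariance, fst, geographic.
#' @export
setClass("PairMatrix", representation(labels = "character",
                                      values = "matrix",
                                      kind = "character"))

setValidity("PairMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!object@kind %in% c("distance", "covariance", "fst", "geographic"))
    msgs <- c(msgs, "unknown kind")
  if (nrow(v) != ncol(v) || nrow(v) != length(object@labels))
    return("values must be square and match labels")
  fin <- !is.na(v)
  if (max(abs(v[fin] - t(v)[fin]), 0) > 1e-9)
    msgs <- c(msgs, "matrix not symmetric within 1e-9")
  if (object@kind %in% c("distance", "geographic")) {
    if (any(abs(diag(v)) > 1e-12, na.rm = TRUE))
      msgs <- c(msgs, "distance diagonal must be zero")
    if (any(v[fin] < -1e-12))
      msgs <- c(msgs, "distances must be nonnegative")
  }
  if (object@kind == "fst" && any(v[fin] < -1e-12))
    msgs <- c(msgs, "fst values must be nonnegative (clamp upstream)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PairMatrix
#'
#' @param values symmetric numeric matrix (NA allowed for undefined cells).
#' @param kind "distance", "covariance", "fst" or "geographic".
#' @param labels unit ids; default \code{rownames(values)}.
#' @return A \linkS4class{PairMatrix}.
#' @export
PairMatrix <- function(values, kind, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  new("PairMatrix", labels = as.character(labels), values = values,
      kind = kind)
}

#' @describeIn PairMatrix the underlying numeric matrix
#' @param x,object a PairMatrix
#' @export
pairValues <- function(x) x@values

#' @describeIn PairMatrix the unit labels
#' @export
pairLabels <- function(x) x@labels

#' @describeIn PairMatrix the matrix kind tag
#' @export
pairKind <- function(x) x@kind

setMethod("show", "PairMatrix", function(object) {
  cat("PairMatrix (", object@kind, "): ", length(object@labels), " x ",
      length(object@labels), " units\n", sep = "")
})

#' IBDSegmentTable: shared identity-by-descent segments between pairs
#'
#' Records of genomic segments detected as identical by descent between
#' pairs of individuals; consumed by \code{\link{ibdSharing}}.
#'
#' @slot segments data.frame with columns \code{id_a}, \code{id_b},
#'   \code{chromosome}, \code{start_bp}, \code{end_bp}.
#' @export
setClass("IBDSegmentTable", representation(segments = "data.frame"))

setValidity("IBDSegmentTable", function(object) {
  s <- object@segments
  need <- c("id_a", "id_b", "chromosome", "start_bp", "end_bp")
  if (!all(need %in% colnames(s)))
    return(paste("segments needs columns", paste(need, collapse = ", ")))
  msgs <- character()
  if (nrow(s)) {
    if (any(s$id_a == s$id_b)) msgs <- c(msgs, "id_a must differ from id_b")
    if (any(s$start_bp >= s$end_bp))
      msgs <- c(msgs, "start_bp must be < end_bp")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an IBDSegmentTable
#'
#' @param segments data.frame with columns id_a, id_b, chromosome, start_bp,
#'   end_bp (zero rows allowed).
#' @return An \linkS4class{IBDSegmentTable}.
#' @export
IBDSegmentTable <- function(segments = data.frame(
    id_a = character(), id_b = character(), chromosome = character(),
    start_bp = integer(), end_bp = integer())) {
  segments <- as.data.frame(segments)
  segments$chromosome <- as.character(segments$chromosome)
  new("IBDSegmentTable", segments = segments)
}

#' @describeIn IBDSegmentTable segment records as a data.frame
#' @param x,object an IBDSegmentTable
#' @export
ibdSegments <- function(x) x@segments

setMethod("show", "IBDSegmentTable", function(object) {
  cat("IBDSegmentTable:", nrow(object@segments), "segments over",
      length(unique(c(object@segments$id_a, object@segments$id_b))),
      "individuals\n")
})
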