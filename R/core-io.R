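AUTOSOME_EXCLUDE <- c("X", "Y", "XY", "MT", "M", "chrX", "chrY", "chrM",
                      "chrMT", "23", "24", "25", "26")

#' Read diploid SNP genotypes
#'
#' Loads genotypes from VCF 4.x (GT field), PLINK text PED/MAP, or the
#' package's labelled TSV dialect, into a \linkS4class{GenotypeMatrix}.
#' Only biallelic autosomal SNPs are retained; dropped records are counted
#' in a message. Dosage counts copies of the alternate allele: for VCF the
#' ALT allele, for PED/MAP the in-file minor allele (ties broken towards
#' the alphabetically smaller allele), for TSV the codes are taken as-is.
#'
#' @param path file path. For \code{format = "plink_pedmap"} give the
#'   \code{.ped} path; the matching \code{.map} is found by extension swap
#'   (or pass \code{mapPath}).
#' @param format one of \code{"vcf"}, \code{"plink_pedmap"}, \code{"tsv"}.
#' @param mapPath optional explicit .map path for PED/MAP input.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path, format = c("vcf", "plink_pedmap", "tsv"),
                          mapPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         vcf = .readVcfGenotypes(path),
         plink_pedmap = .readPedMap(path, mapPath),
         tsv = .readTsvGenotypes(path))
}

.dropNonAutosomal <- function(chrom) !(chrom %in% AUTOSOME_EXCLUDE)

.readVcfGenotypes <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in ", path, ": ",
                                         conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  isSnp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  isAuto <- .dropNonAutosomal(fix$CHROM)
  keep <- isSnp & isAuto
  nDropped <- sum(!keep)
  if (nDropped) message(nDropped,
    " non-biallelic/non-SNP/non-autosomal record(s) dropped from ", path)
  if (!any(keep)) stop("no biallelic autosomal SNPs in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (anyDuplicated(colnames(gt)))
    stop("duplicate individual id in VCF header: ",
         paste(unique(colnames(gt)[duplicated(colnames(gt))]), collapse = ", "))
  gtClean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gtClean), ncol(gtClean),
                dimnames = dimnames(gtClean))
  dos[gtClean %in% c("0/0")] <- 0L
  dos[gtClean %in% c("0/1", "1/0")] <- 1L
  dos[gtClean %in% c("1/1")] <- 2L
  ids <- fix$ID[keep]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix$CHROM[keep][noId], ":", fix$POS[keep][noId])
  GenotypeMatrix(dos,
                 data.frame(chromosome = fix$CHROM[keep],
                            position = as.integer(fix$POS[keep]),
                            id = ids),
                 colnames(gt))
}

.readPedMap <- function(pedPath, mapPath = NULL) {
  if (is.null(mapPath)) mapPath <- sub("\\.ped$", ".map", pedPath)
  if (!file.exists(mapPath)) stop("map file not found: ", mapPath)
  map <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("malformed MAP file (expected 4 columns): ",
                           mapPath)
  names(map)[1:4] <- c("chromosome", "id", "cm", "position")
  ped <- read.table(pedPath, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  nSnp <- nrow(map)
  if (ncol(ped) != 6L + 2L * nSnp)
    stop("malformed PED file: ", pedPath, " has ", ncol(ped),
         " columns, expected ", 6L + 2L * nSnp)
  ids <- ped[[2L]]
  if (anyDuplicated(ids))
    stop("duplicate individual id in PED: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(nSnp) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(nSnp), drop = FALSE])
  dos <- matrix(NA_integer_, nSnp, length(ids),
                dimnames = list(map$id, ids))
  keep <- rep(TRUE, nSnp)
  for (s in seq_len(nSnp)) {
    als <- c(a1[, s], a2[, s])
    ok <- als != "0"
    alleles <- sort(unique(als[ok]))
    if (length(alleles) > 2L) { keep[s] <- FALSE; next }
    if (length(alleles) == 0L) { keep[s] <- FALSE; next }
    # alternate = in-file minor allele; ties -> alphabetically smaller
    if (length(alleles) == 1L) alt <- alleles else {
      cnt <- table(factor(als[ok], levels = alleles))
      alt <- if (cnt[[1L]] == cnt[[2L]]) alleles[1L] else
        alleles[which.min(cnt)]
    }
    d <- (a1[, s] == alt) + (a2[, s] == alt)
    d[a1[, s] == "0" | a2[, s] == "0"] <- NA
    dos[s, ] <- as.integer(d)
  }
  keep <- keep & .dropNonAutosomal(as.character(map$chromosome))
  if (any(!keep)) message(sum(!keep),
    " non-biallelic/non-autosomal marker(s) dropped from ", pedPath)
  GenotypeMatrix(dos[keep, , drop = FALSE],
                 data.frame(chromosome = as.character(map$chromosome)[keep],
                            position = as.integer(map$position)[keep],
                            id = map$id[keep]),
                 ids)
}

.readTsvGenotypes <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("chromosome", "position", "id")
  if (!all(need %in% colnames(x)))
    stop("genotype TSV must start with columns chromosome, position, id")
  indCols <- setdiff(colnames(x), need)
  if (!length(indCols)) stop("genotype TSV has no individual columns")
  if (anyDuplicated(indCols))
    stop("duplicate individual id in TSV: ",
         paste(unique(indCols[duplicated(indCols)]), collapse = ", "))
  dos <- as.matrix(x[, indCols, drop = FALSE])
  storage.mode(dos) <- "integer"
  keep <- .dropNonAutosomal(as.character(x$chromosome))
  if (any(!keep)) message(sum(!keep), " non-autosomal marker(s) dropped")
  GenotypeMatrix(dos[keep, , drop = FALSE],
                 x[keep, need], indCols)
}

#' Write genotypes as a minimal plain-text VCF
#'
#' Emits a VCF 4.2 file carrying only the GT field. Since dosage coding
#' abstracts away the actual bases, REF/ALT are written as A/C
#' placeholders; round-tripping through \code{\link{readGenotypes}}
#' reproduces the dosage matrix exactly.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
writeGenotypesVcf <- function(gm, path) {
  map <- markerMap(gm)
  g <- genotypeCalls(gm)
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[!is.na(g) & g == 0L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 2L] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clinekit",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", individualIds(gm)), collapse = "\t"))
  body <- paste(map$chromosome, map$position, map$id, "A", "C", ".", ".",
                ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a site table (and optional individual assignment)
#'
#' @param path TSV with columns \code{site}, \code{lat}, \code{lon}
#'   (extra columns are kept).
#' @param assignmentPath optional TSV with columns \code{individual},
#'   \code{site}. Individuals assigned to unknown sites raise an error
#'   naming the offenders.
#' @return A \linkS4class{SiteTable}.
#' @export
readSites <- function(path, assignmentPath = NULL) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("site", "lat", "lon") %in% colnames(s)))
    stop("site TSV must have columns site, lat, lon: ", path)
  assignment <- character()
  if (!is.null(assignmentPath)) {
    a <- read.delim(assignmentPath, stringsAsFactors = FALSE)
    if (!all(c("individual", "site") %in% colnames(a)))
      stop("assignment TSV must have columns individual, site")
    assignment <- setNames(as.character(a$site), a$individual)
  }
  SiteTable(s, assignment)
}

#' Write a site table and its assignment
#'
#' @param st a \linkS4class{SiteTable}
#' @param path sites TSV output path
#' @param assignmentPath optional assignment TSV output path
#' @return \code{path}, invisibly.
#' @export
writeSites <- function(st, path, assignmentPath = NULL) {
  write.table(siteCoords(st), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(assignmentPath)) {
    a <- siteAssignment(st)
    write.table(data.frame(individual = names(a), site = unname(a)),
                assignmentPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write / read a labelled pairwise matrix as TSV
#'
#' The first row and column hold the unit labels; values are written at
#' full precision so that \code{readMatrix(writeMatrix(m))} reproduces
#' \code{m} within 1e-12. Reading validates symmetry and rejects NaN cells.
#'
#' @param m a \linkS4class{PairMatrix}
#' @param path TSV path
#' @return \code{writeMatrix}: \code{path} invisibly; \code{readMatrix}:
#'   a \linkS4class{PairMatrix}.
#' @export
writeMatrix <- function(m, path) {
  stopifnot(is(m, "PairMatrix"), length(pairLabels(m)) > 0L)
  v <- pairValues(m)
  df <- data.frame(label = pairLabels(m),
                   apply(v, 2L, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(paste0("#kind=", pairKind(m)), pairLabels(m))
  write.table(df, path, sep = "\t", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrix
#' @export
readMatrix <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                  comment.char = "")
  kindCol <- colnames(x)[1L]
  if (!startsWith(kindCol, "#kind="))
    stop("not a clinekit matrix TSV (missing #kind header): ", path)
  kind <- sub("^#kind=", "", kindCol)
  labels <- as.character(x[[1L]])
  v <- as.matrix(x[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  if (!identical(colnames(v), labels))
    stop("row and column labels disagree in ", path)
  if (any(is.nan(v))) stop("NaN cell(s) in matrix file ", path)
  fin <- !is.na(v)
  if (max(abs(v[fin] - t(v)[fin]), 0) > 1e-9)
    stop("matrix in ", path, " is not symmetric")
  PairMatrix(v, kind = kind, labels = labels)
}
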