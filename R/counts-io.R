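# Loading, validating and transforming allele-count data.

#' Construct an AlleleCounts object from count matrices
#'
#' @param ref m x K matrix of counted-allele copies (integers, `NA` for
#'   missing cells).  Row names are locus identifiers, column names unit
#'   labels; defaults are generated when absent.
#' @param n m x K matrix of gametes sampled, `NA` exactly where `ref` is.
#' @return A validated [AlleleCounts-class] object.
#' @examples
#' acm <- alleleCounts(ref = cbind(P1 = c(1L, 0L), P2 = c(2L, 2L)),
#'                     n   = cbind(P1 = c(4L, 4L), P2 = c(4L, 4L)))
#' refCounts(acm)
#' @export
alleleCounts <- function(ref, n) {
  ref <- as.matrix(ref)
  n <- as.matrix(n)
  if (!all(dim(ref) == dim(n)))
    stop("'ref' and 'n' must have identical dimensions")
  if (is.null(colnames(ref))) colnames(ref) <- paste0("unit", seq_len(ncol(ref)))
  if (is.null(rownames(ref))) rownames(ref) <- paste0("L", seq_len(nrow(ref)))
  dimnames(n) <- dimnames(ref)
  storage.mode(ref) <- "integer"
  storage.mode(n) <- "integer"
  se <- SummarizedExperiment(assays = list(ref = ref, n = n))
  new("AlleleCounts", se)
}

#' @describeIn alleleCounts matrix of counted-allele copies.
#' @export
setMethod("refCounts", "AlleleCounts", function(x) assay(x, "ref"))

#' @describeIn alleleCounts matrix of gametes sampled.
#' @export
setMethod("nGametes", "AlleleCounts", function(x) assay(x, "n"))

#' @describeIn alleleCounts logical matrix flagging missing cells.
#' @export
setMethod("missingMask", "AlleleCounts", function(x) is.na(assay(x, "ref")))

#' @describeIn alleleCounts unit labels (column names).
#' @export
setMethod("unitLabels", "AlleleCounts", function(x) colnames(x))

setMethod("show", "AlleleCounts", function(object) {
  cat(sprintf("AlleleCounts: %d loci x %d units\n", nrow(object), ncol(object)))
  cat("units:", paste(utils::head(colnames(object), 8), collapse = ", "),
      if (ncol(object) > 8) "..." else "", "\n")
  nmiss <- sum(is.na(assay(object, "ref")))
  if (nmiss > 0) cat(sprintf("missing cells: %d\n", nmiss))
  invisible(object)
})

#' Read a tab-separated allele-count table
#'
#' The dialect is one header line `locus<TAB><unit>_ref<TAB><unit>_n ...`
#' (one `_ref`/`_n` column pair per unit), one body row per locus, literal
#' `NA` for missing cells, UTF-8, no quoting.  Which allele is counted is
#' fixed by the file (first allele of the data producer); all statistics in
#' the package are invariant to that orientation.
#'
#' @param path path to the TSV file.
#' @return An [AlleleCounts-class] object.
#' @seealso [writeCountsTable()]
#' @export
readCountsTable <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", na.strings = "NA",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5L || names(df)[1] != "locus")
    stop("malformed header: expected 'locus' then <unit>_ref/<unit>_n pairs")
  cn <- names(df)[-1]
  if (length(cn) %% 2L != 0L)
    stop("malformed header: unpaired unit columns")
  refCols <- cn[seq(1, length(cn), by = 2)]
  nCols <- cn[seq(2, length(cn), by = 2)]
  units <- sub("_ref$", "", refCols)
  if (!all(grepl("_ref$", refCols)) || !identical(paste0(units, "_n"), nCols))
    stop("malformed header: columns must alternate <unit>_ref, <unit>_n")
  if (anyDuplicated(units))
    stop("duplicate unit label in header: ",
         paste(unique(units[duplicated(units)]), collapse = ", "))
  loci <- as.character(df$locus)
  if (anyDuplicated(loci))
    stop("duplicate locus identifier: ",
         paste(utils::head(unique(loci[duplicated(loci)])), collapse = ", "))
  ref <- as.matrix(df[, refCols, drop = FALSE])
  n <- as.matrix(df[, nCols, drop = FALSE])
  dimnames(ref) <- dimnames(n) <- list(loci, units)
  bad <- which(!is.na(ref) & !is.na(n) & ref > n, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("count exceeds gametes at locus '%s', unit '%s'",
                 loci[bad[1, 1]], units[bad[1, 2]]))
  bad <- which(!is.na(n) & n < 2L, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("fewer than 2 gametes at locus '%s', unit '%s'",
                 loci[bad[1, 1]], units[bad[1, 2]]))
  if (!identical(is.na(ref), is.na(n)))
    stop("cells must be missing (NA) in both the _ref and _n column or neither")
  alleleCounts(ref, n)
}

#' Write an allele-count table in the package's TSV dialect
#'
#' @param acm an [AlleleCounts-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCountsTable <- function(acm, path) {
  ref <- refCounts(acm)
  n <- nGametes(acm)
  K <- ncol(ref)
  out <- matrix("", nrow(ref), 2L * K)
  out[, seq(1, 2 * K, by = 2)] <- ifelse(is.na(ref), "NA", as.character(ref))
  out[, seq(2, 2 * K, by = 2)] <- ifelse(is.na(n), "NA", as.character(n))
  hdr <- character(2L * K)
  hdr[seq(1, 2 * K, by = 2)] <- paste0(colnames(ref), "_ref")
  hdr[seq(2, 2 * K, by = 2)] <- paste0(colnames(ref), "_n")
  df <- data.frame(locus = rownames(ref), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("locus", hdr)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert diploid genotypes to two-gamete units
#'
#' Each diploid individual becomes a unit with two sampled gametes per
#' non-missing locus; the genotype (0, 1 or 2 copies of the counted allele)
#' becomes the allele count.
#'
#' @param genotypes m x I matrix of 0/1/2 genotype codes (`NA` missing).
#' @param labels optional individual labels (default: column names).
#' @return An [AlleleCounts-class] object with `n = 2` everywhere observed.
#' @export
diploidsToUnits <- function(genotypes, labels = colnames(genotypes)) {
  g <- as.matrix(genotypes)
  ok <- !is.na(g)
  if (any(!(g[ok] %in% c(0L, 1L, 2L))))
    stop("genotypes must be coded 0, 1 or 2 copies of the counted allele")
  if (!is.null(labels)) colnames(g) <- labels
  n <- matrix(2L, nrow(g), ncol(g))
  n[!ok] <- NA_integer_
  dimnames(n) <- dimnames(g)
  alleleCounts(g, n)
}

#' Pool units into larger population samples
#'
#' Per locus, a group's allele count (and gamete total) is the sum over its
#' non-missing members; a group cell is missing only when all members are
#' missing there.  Pooling diploid individuals of a homogeneous population
#' recovers the population-level allele counts.
#'
#' @param acm an [AlleleCounts-class] object.
#' @param grouping named character vector mapping every unit label to a
#'   group label.
#' @return An [AlleleCounts-class] object with one column per group, in
#'   first-appearance order of the groups.
#' @export
poolUnits <- function(acm, grouping) {
  units <- unitLabels(acm)
  if (is.null(names(grouping)) || !all(units %in% names(grouping)))
    stop("grouping must cover every unit label")
  unknown <- setdiff(names(grouping), units)
  if (length(unknown) > 0)
    stop("unknown unit label in grouping: ", paste(unknown, collapse = ", "))
  grouping <- grouping[units]
  groups <- unique(unname(grouping))
  if (any(is.na(grouping) | grouping == ""))
    stop("empty group label")
  ref <- refCounts(acm)
  n <- nGametes(acm)
  refG <- matrix(NA_integer_, nrow(ref), length(groups),
                 dimnames = list(rownames(ref), groups))
  nG <- refG
  for (g in groups) {
    memb <- which(grouping == g)
    r <- ref[, memb, drop = FALSE]
    m <- n[, memb, drop = FALSE]
    anyObs <- rowSums(!is.na(r)) > 0
    refG[anyObs, g] <- as.integer(rowSums(r, na.rm = TRUE)[anyObs])
    nG[anyObs, g] <- as.integer(rowSums(m, na.rm = TRUE)[anyObs])
  }
  alleleCounts(refG, nG)
}

#' Convert a VCF to population allele counts
#'
#' Reads diallelic SNVs from a (plain or bgzipped) VCF, counts ALT-allele
#' copies per sample, and pools samples into populations according to a
#' two-column map.  Samples absent from the map stay as individual
#' two-gamete units.  Multi-allelic and non-SNP records are dropped.
#'
#' @param vcfPath path to the VCF file.
#' @param popmapPath optional path to a two-column TSV `sample<TAB>population`
#'   (no header), or `NULL` to keep every sample as an individual unit.
#' @return An [AlleleCounts-class] object.
#' @export
vcfToCounts <- function(vcfPath, popmapPath = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required for VCF input")
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  snv <- vcfR::is.biallelic(vcf) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  vcf <- vcf[snv, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gtn <- gsub("\\|", "/", gt)
  counts[gtn %in% c("0/0")] <- 0L
  counts[gtn %in% c("0/1", "1/0")] <- 1L
  counts[gtn %in% c("1/1")] <- 2L
  loc <- paste(fix[snv, "CHROM"], fix[snv, "POS"], sep = ":")
  rownames(counts) <- make.unique(loc)
  acm <- diploidsToUnits(counts)
  if (is.null(popmapPath)) return(acm)
  pm <- read.delim(popmapPath, header = FALSE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  grouping <- setNames(as.character(pm[[2]]), as.character(pm[[1]]))
  units <- unitLabels(acm)
  full <- setNames(units, units)        # unmapped samples stay individual
  full[intersect(units, names(grouping))] <-
    grouping[intersect(units, names(grouping))]
  poolUnits(acm, full)
}
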