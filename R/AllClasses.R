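#' GenotypePanel: a diploid biallelic SNP genotype panel
#'
#' An S4 container for a sample-by-SNP diploid genotype panel, implemented as
#' a [SummarizedExperiment::RangedSummarizedExperiment] with one assay,
#' `"dosage"`, holding counts of the second (alt-like) allele per genotype
#' (0, 1, 2; `NA` = missing call). Rows are SNPs, columns are samples.
#'
#' Row ranges carry the marker map: SNP identifiers as names, chromosome as
#' seqnames, 1-based physical position, and the allele pair in metadata
#' columns `allele1`/`allele2` (dosage counts `allele2`; `allele2` is `NA`
#' for markers where only one allele was ever observed). Column data carry
#' the population label of every sample in `population`.
#'
#' Validity requires: unique SNP ids, strictly increasing positions within a
#' chromosome, dosages in \{0, 1, 2, NA\}, and a non-missing population label
#' for every sample.
#'
#' @seealso [GenotypePanel()] for construction, [dosages()], [markerMap()],
#'   [populations()] for access.
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

.validGenotypePanel <- function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids (rownames) must be present and unique")
  if (!"population" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'population' column")
  else if (anyNA(colData(object)$population))
    msg <- c(msg, "every sample needs a population label")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  rr <- rowRanges(object)
  if (length(rr)) {
    pos <- GenomicRanges::start(rr)
    chr <- as.character(GenomicRanges::seqnames(rr))
    if (any(pos < 1)) msg <- c(msg, "positions must be >= 1 (1-based)")
    ddup <- unlist(lapply(split(pos, chr), function(p) diff(p) <= 0))
    if (length(ddup) && any(ddup))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypePanel", .validGenotypePanel)

#' Construct a GenotypePanel
#'
#' @param dosage integer/numeric matrix of alt-allele dosages, SNPs in rows and
#'   samples in columns; values 0/1/2 with `NA` for missing calls. Row and
#'   column names are used as SNP and sample ids if `map`/`populations` do not
#'   name them.
#' @param map `data.frame` with columns `snp_id`, `chromosome`, `position_bp`
#'   and optionally `allele1`, `allele2` (defaults `"A"`/`"B"`). One row per
#'   SNP, same order as `dosage` rows; the constructor sorts markers by
#'   chromosome and position and reorders `dosage` accordingly.
#' @param populations named character vector mapping sample id to population
#'   label, or an unnamed vector in `dosage` column order.
#' @return A [GenotypePanel-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 3,
#'             dimnames = list(paste0("snp", 1:3), c("s1", "s2")))
#' map <- data.frame(snp_id = paste0("snp", 1:3), chromosome = "1",
#'                   position_bp = c(100L, 200L, 300L))
#' gp <- GenotypePanel(d, map, c(s1 = "POP_A", s2 = "POP_B"))
#' @export
GenotypePanel <- function(dosage, map, populations) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(map))
    stop("dimension mismatch: ", nrow(dosage), " dosage rows vs ",
         nrow(map), " map rows")
  need <- c("snp_id", "chromosome", "position_bp")
  if (!all(need %in% names(map)))
    stop("map needs columns: ", paste(need, collapse = ", "))
  if (nrow(map) == 0L) stop("no markers")
  if (is.null(map$allele1)) map$allele1 <- "A"
  if (is.null(map$allele2)) map$allele2 <- "B"
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")

  # sort by chromosome (order of first appearance) then position
  chr <- as.character(map$chromosome)
  ord <- order(match(chr, unique(chr)), map$position_bp)
  map <- map[ord, , drop = FALSE]
  dosage <- dosage[ord, , drop = FALSE]

  if (is.null(names(populations))) {
    if (length(populations) != ncol(dosage))
      stop("populations must be named by sample id or match sample count")
    names(populations) <- colnames(dosage)
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- names(populations)
  miss <- setdiff(colnames(dosage), names(populations))
  if (length(miss))
    stop("no population label for sample(s): ", paste(miss, collapse = ", "))

  rr <- GRanges(seqnames = as.character(map$chromosome),
                ranges = IRanges(start = map$position_bp, width = 1L))
  names(rr) <- map$snp_id
  mcols(rr)$allele1 <- as.character(map$allele1)
  mcols(rr)$allele2 <- as.character(map$allele2)
  rownames(dosage) <- map$snp_id

  cd <- DataFrame(population = unname(populations[colnames(dosage)]),
                  row.names = colnames(dosage))
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowRanges = rr, colData = cd)
  new("GenotypePanel", se)
}

#' Sved LD-decay fit
#'
#' S3 record returned by [fitSved()]: the decay coefficient of the hyperbolic
#' model E\[r2\] = 1/(1 + beta d), the residual sum of squares, the number of
#' pairs fitted, and the LD extent at the threshold used.
#'
#' @param x a `SvedFit`
#' @param ... ignored
#' @name SvedFit
NULL

#' @rdname SvedFit
#' @export
print.SvedFit <- function(x, ...) {
  cat("Sved hyperbolic LD-decay fit\n")
  cat(sprintf("  beta: %.6g per kb (%.6g per bp), n_pairs = %d, rss = %.4g\n",
              x$beta_per_kb, x$beta_per_bp, x$n_pairs, x$rss))
  if (is.finite(x$extent_kb))
    cat(sprintf("  extent r2_%.2g = %.4g kb\n", x$threshold, x$extent_kb))
  else
    cat(sprintf("  extent r2_%.2g = Inf (no detectable decay)\n", x$threshold))
  invisible(x)
}
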