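#' Alt-allele dosage matrix of a panel
#'
#' @param x a [GenotypePanel-class]
#' @param ... unused
#' @return Integer matrix, SNPs x samples, values 0/1/2 or `NA`.
#' @export
setMethod("dosages", "GenotypePanel", function(x, ...) assay(x, "dosage"))

#' Marker map of a panel
#'
#' @param x a [GenotypePanel-class]
#' @param ... unused
#' @return `data.frame` with columns `snp_id`, `chromosome`, `position_bp`,
#'   `allele1`, `allele2`, in panel row order.
#' @export
setMethod("markerMap", "GenotypePanel", function(x, ...) {
  rr <- rowRanges(x)
  data.frame(snp_id = names(rr),
             chromosome = as.character(GenomicRanges::seqnames(rr)),
             position_bp = GenomicRanges::start(rr),
             allele1 = mcols(rr)$allele1,
             allele2 = mcols(rr)$allele2,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Population labels of a panel
#'
#' `populations()` returns the per-sample labels (named by sample id);
#' `populationNames()` the unique labels in order of first appearance.
#'
#' @param x a [GenotypePanel-class]
#' @param ... unused
#' @export
setMethod("populations", "GenotypePanel", function(x, ...)
  setNames(as.character(colData(x)$population), colnames(x)))

#' @rdname populations
#' @export
setMethod("populationNames", "GenotypePanel", function(x)
  unique(as.character(colData(x)$population)))

setMethod("show", "GenotypePanel", function(object) {
  pops <- table(populations(object))
  cat("GenotypePanel:", nrow(object), "SNPs x", ncol(object), "samples\n")
  chr <- unique(as.character(GenomicRanges::seqnames(rowRanges(object))))
  cat("  chromosomes:", if (length(chr) > 8)
    paste(c(head(chr, 8), "..."), collapse = " ") else
      paste(chr, collapse = " "), "\n")
  cat("  populations:",
      paste(sprintf("%s(%d)", names(pops), pops), collapse = " "), "\n")
  d <- dosages(object)
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(d))))
})

#' Restrict a panel to selected populations or samples
#'
#' @param panel a [GenotypePanel-class]
#' @param populations character vector of population labels to keep
#' @return the column-subset panel
#' @export
subsetPopulations <- function(panel, populations) {
  labs <- populationNames(panel)
  unknown <- setdiff(populations, labs)
  if (length(unknown))
    stop("unknown population label(s): ", paste(unknown, collapse = ", "))
  panel[, arraypopgen::populations(panel) %in% populations]
}

.SEX_CHROMS <- c("X", "Y", "XY", "MT", "M", "23", "24", "25", "26")

#' Drop sex-chromosome and mitochondrial markers
#'
#' LD, F_ST and ROH stages operate on autosomal SNPs; chromosome labels
#' `X`, `Y`, `XY`, `MT`/`M` (and PLINK numeric codes 23-26) are removed.
#'
#' @param panel a [GenotypePanel-class]
#' @return the row-subset panel
#' @export
autosomalPanel <- function(panel) {
  chr <- as.character(GenomicRanges::seqnames(rowRanges(panel)))
  panel[!(chr %in% .SEX_CHROMS), ]
}
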