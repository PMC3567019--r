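#' Allele frequency of the counted (alt-like) allele
#'
#' Frequency of each SNP's `allele2` among called genotypes:
#' `sum(dosage) / (2 * n_called)`. With `snp` given, a single SNP is
#' evaluated and an all-missing subset is an error (distinct from frequency
#' 0); vectorised over all SNPs, all-missing rows yield `NA`.
#'
#' @param panel a [GenotypePanel-class]
#' @param snp optional single SNP id or row index
#' @param samples optional sample ids / indices / logical mask restricting the
#'   subset over which the frequency is computed
#' @return For a single `snp`, a list with `freq` and `n_called` (diploid
#'   individuals with a call). Otherwise a `data.frame` over all SNPs with
#'   columns `snp_id`, `freq`, `n_called`.
#' @export
alleleFreq <- function(panel, snp = NULL, samples = NULL) {
  d <- dosages(panel)
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  if (!is.null(snp)) {
    g <- d[snp, ]
    n <- sum(!is.na(g))
    if (n == 0L) stop("all genotypes missing for SNP '", snp,
                      "' in the requested subset")
    return(list(freq = sum(g, na.rm = TRUE) / (2 * n), n_called = n))
  }
  n <- rowSums(!is.na(d))
  f <- ifelse(n > 0L, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  data.frame(snp_id = rownames(d), freq = unname(f), n_called = unname(n),
             stringsAsFactors = FALSE)
}

#' Per-SNP call rate and minor allele frequency
#'
#' @param panel a [GenotypePanel-class]
#' @param samples optional subset of samples
#' @return `data.frame` with `snp_id`, `call_rate`, `maf` (MAF is `NA` where
#'   no genotype is called).
#' @export
snpStats <- function(panel, samples = NULL) {
  d <- dosages(panel)
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  n <- rowSums(!is.na(d))
  f <- ifelse(n > 0L, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  data.frame(snp_id = rownames(d),
             call_rate = unname(n / ncol(d)),
             maf = unname(pmin(f, 1 - f)),
             stringsAsFactors = FALSE)
}

#' SNP quality-control configuration
#'
#' The chip-QC rule: retain SNPs with call rate >= `min_call_rate` and minor
#' allele frequency >= `min_maf` (both inclusive), computed over all samples.
#'
#' @param min_call_rate fraction in \[0, 1\], default 0.9
#' @param min_maf fraction in \[0, 0.5\], default 0.05
#' @return list of class `FilterConfig`
#' @export
filterConfig <- function(min_call_rate = 0.9, min_maf = 0.05) {
  stopifnot(is.numeric(min_call_rate), min_call_rate >= 0, min_call_rate <= 1,
            is.numeric(min_maf), min_maf >= 0, min_maf <= 0.5)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf),
            class = "FilterConfig")
}

#' Filter SNPs on call rate and MAF
#'
#' Applies the informativeness filter. The per-SNP report (kept/dropped and
#' the reason) is attached to the returned panel's metadata as
#' `filter_report` and can be retrieved with [filterReport()].
#'
#' @param panel a [GenotypePanel-class]
#' @param config a [filterConfig()] (default: call rate >= 0.9, MAF >= 0.05)
#' @return the filtered panel (possibly with zero rows)
#' @export
filterSnps <- function(panel, config = filterConfig()) {
  st <- snpStats(panel)
  maf <- ifelse(is.na(st$maf), 0, st$maf)
  fail_cr <- st$call_rate < config$min_call_rate
  fail_maf <- maf < config$min_maf
  keep <- !fail_cr & !fail_maf
  reason <- rep("", nrow(st))
  reason[fail_maf] <- "maf"
  reason[fail_cr] <- "call_rate"
  reason[fail_cr & fail_maf] <- "call_rate+maf"
  report <- data.frame(snp_id = st$snp_id, call_rate = st$call_rate,
                       maf = st$maf, keep = keep, reason = reason,
                       stringsAsFactors = FALSE)
  out <- panel[keep, ]
  metadata(out)$filter_report <- report
  metadata(out)$filter_config <- unclass(config)
  if (!any(keep)) message("filterSnps: no SNP passed the filter")
  out
}

#' @rdname filterSnps
#' @export
filterReport <- function(panel) metadata(panel)$filter_report

#' Retain SNPs common at a given MAF in every super-group
#'
#' Reproduces the construction of a cross-group common-SNP subset: a SNP is
#' kept only if its MAF (over called genotypes) is at least `min_maf` within
#' every super-group of populations.
#'
#' @param panel a [GenotypePanel-class]
#' @param groups named list of character vectors partitioning (a subset of)
#'   the panel's populations into super-groups
#' @param min_maf inclusive MAF threshold, default 0.2
#' @return the row-subset panel
#' @export
mafSubset <- function(panel, groups, min_maf = 0.2) {
  stopifnot(is.list(groups), length(groups) >= 1)
  pops <- populations(panel)
  unknown <- setdiff(unlist(groups), unique(pops))
  if (length(unknown))
    stop("unknown population label(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(panel))
  for (g in groups) {
    st <- snpStats(panel, samples = pops %in% g)
    keep <- keep & !is.na(st$maf) & st$maf >= min_maf
  }
  panel[keep, ]
}
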