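#' Proportion of polymorphic SNPs in a population
#'
#' Fraction of the given SNPs at which both alleles are observed among called
#' genotypes within the population.
#'
#' @param panel a [GenotypePanel-class]
#' @param population population label
#' @param snps optional SNP ids / indices defining the subset (default: all)
#' @return P_N in \[0, 1\]
#' @export
proportionPolymorphic <- function(panel, population, snps = NULL) {
  d <- .popDosage(panel, population, snps)
  n <- rowSums(!is.na(d))
  cnt <- rowSums(d, na.rm = TRUE)
  seg <- n > 0 & cnt > 0 & cnt < 2 * n
  mean(seg[n > 0])
}

#' Expected heterozygosity in a population
#'
#' Mean over the SNP subset of the Hardy-Weinberg heterozygosity `2 p (1-p)`,
#' with `p` the within-population allele frequency over called genotypes.
#' SNPs with no called genotype in the population are excluded with a
#' warning.
#'
#' @inheritParams proportionPolymorphic
#' @return H_E in \[0, 0.5\] for biallelic markers
#' @export
expectedHeterozygosity <- function(panel, population, snps = NULL) {
  d <- .popDosage(panel, population, snps)
  n <- rowSums(!is.na(d))
  if (any(n == 0))
    warning(sum(n == 0), " SNP(s) with no called genotype excluded")
  p <- rowSums(d, na.rm = TRUE)[n > 0] / (2 * n[n > 0])
  mean(2 * p * (1 - p))
}

#' Allelic richness by rarefaction
#'
#' Expected number of distinct alleles observed in a random subsample of `g`
#' gene copies drawn without replacement, averaged over loci:
#' `sum_a [1 - choose(N - N_a, g) / choose(N, g)]` per locus, with `N` the
#' called gene copies and `N_a` the count of allele `a`. Computed in log
#' space via `lchoose`.
#'
#' @param counts matrix of allele counts, loci x alleles (for biallelic data
#'   two columns), or a [GenotypePanel-class] together with `population`
#' @param g rarefaction depth in gene copies; must not exceed any locus's
#'   total count
#' @param population,snps when `counts` is a panel: population label and
#'   optional SNP subset
#' @return mean allelic richness A_R (in \[1, 2\] for biallelic loci)
#' @export
allelicRichness <- function(counts, g, population = NULL, snps = NULL) {
  if (is(counts, "GenotypePanel")) {
    d <- .popDosage(counts, population, snps)
    n2 <- 2 * rowSums(!is.na(d))
    alt <- rowSums(d, na.rm = TRUE)
    counts <- cbind(n2 - alt, alt)
    rownames(counts) <- rownames(d)
  }
  counts <- as.matrix(counts)
  N <- rowSums(counts)
  if (any(N == 0)) stop("locus with zero called gene copies")
  if (g < 1) stop("g must be >= 1")
  if (any(g > N)) {
    bad <- which(g > N)[1]
    lab <- if (!is.null(rownames(counts))) rownames(counts)[bad] else bad
    stop("g = ", g, " exceeds the called gene copies at locus ", lab,
         " (N = ", min(N), " minimum)")
  }
  # P(allele a unseen in g draws without replacement) = C(N-Na, g) / C(N, g)
  p_unseen <- exp(lchoose(N - counts, g) - lchoose(N, g))
  p_unseen[counts == 0] <- 1   # absent alleles never observed
  mean(rowSums(1 - p_unseen))
}

.popDosage <- function(panel, population, snps = NULL) {
  if (!population %in% populationNames(panel))
    stop("unknown population: ", population)
  d <- dosages(panel)[, populations(panel) == population, drop = FALSE]
  if (!is.null(snps)) d <- d[snps, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty SNP subset")
  d
}

#' Per-population diversity summary
#'
#' One row per population with the three diversity measures over a common
#' SNP subset: proportion of polymorphic SNPs (P_N), allelic richness (A_R)
#' at rarefaction depth `g`, and expected heterozygosity (H_E). `n_snp_maf20`
#' counts subset SNPs with within-population MAF >= 0.2.
#'
#' @param panel a [GenotypePanel-class]
#' @param snps optional SNP subset (ids or indices)
#' @param g rarefaction depth in gene copies; `"auto"` (default) uses
#'   `2 * min` over populations of the smallest per-SNP called sample size,
#'   the standardization rarefaction analyses apply
#' @return `data.frame` with columns `population`, `n_samples`,
#'   `n_snp_maf20`, `P_N`, `A_R`, `H_E`, `g`
#' @export
diversitySummary <- function(panel, snps = NULL, g = "auto") {
  pops <- populationNames(panel)
  if (identical(g, "auto")) {
    gmin <- min(vapply(pops, function(pp) {
      d <- .popDosage(panel, pp, snps)
      min(rowSums(!is.na(d)))
    }, numeric(1)))
    g <- max(1, 2 * gmin)
  }
  res <- lapply(pops, function(pp) {
    d <- .popDosage(panel, pp, snps)
    n <- rowSums(!is.na(d))
    f <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA)
    data.frame(population = pp,
               n_samples = sum(populations(panel) == pp),
               n_snp_maf20 = sum(pmin(f, 1 - f) >= 0.2, na.rm = TRUE),
               P_N = proportionPolymorphic(panel, pp, snps),
               A_R = allelicRichness(panel, g, population = pp, snps = snps),
               H_E = expectedHeterozygosity(panel, pp, snps),
               g = g, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
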