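#' Allele-sharing (IBS) distance between two samples
#'
#' Over loci called in both samples, counts loci sharing 2, 1 or 0 alleles
#' identical by state, computes the average proportion of shared alleles
#' `Dst = (IBS2 + 0.5 IBS1) / N`, and the genetic distance `D = 1 - Dst`.
#'
#' @param panel a [GenotypePanel-class]
#' @param sample_a,sample_b sample ids or column indices
#' @return list with `ibs0`, `ibs1`, `ibs2`, `n` (loci compared), `dst`, `d`
#' @export
ibsDistance <- function(panel, sample_a, sample_b) {
  d <- dosages(panel)
  ga <- d[, sample_a]; gb <- d[, sample_b]
  ok <- !is.na(ga) & !is.na(gb)
  n <- sum(ok)
  if (n == 0L)
    stop("no locus called in both '", sample_a, "' and '", sample_b, "'")
  diffs <- abs(ga[ok] - gb[ok])
  # |ga-gb| = 0 -> IBS2 except het/het-opposite impossible for dosage;
  # dosage difference 0,1,2 maps to 2,1,0 shared alleles
  ibs <- 2L - diffs
  counts <- tabulate(ibs + 1L, nbins = 3L)   # ibs0, ibs1, ibs2
  dst <- (counts[3] + 0.5 * counts[2]) / n
  list(ibs0 = counts[1], ibs1 = counts[2], ibs2 = counts[3], n = n,
       dst = dst, d = 1 - dst)
}

#' All-pairs allele-sharing distance matrix
#'
#' Symmetric matrix of `1 - Dst` over all sample pairs, zero diagonal. Each
#' pair uses its own pairwise-complete locus set.
#'
#' @param panel a [GenotypePanel-class] with >= 2 samples
#' @return numeric matrix with sample ids as dimnames
#' @export
ibsDistanceMatrix <- function(panel) {
  g <- dosages(panel)
  ns <- ncol(g)
  if (ns < 2L) stop("need >= 2 samples")
  called <- !is.na(g)
  gz <- g; gz[!called] <- 0L
  # sum over loci of |ga - gb| via decomposition on dosage classes:
  # pairwise-complete |diff| sums computed with cross-products of indicators
  I0 <- (gz == 0L) & called; I1 <- (gz == 1L) & called; I2 <- (gz == 2L) & called
  n02 <- crossprod(I0, I2)               # pairs of opposite homozygotes
  n01 <- crossprod(I0, I1); n12 <- crossprod(I1, I2)
  N <- crossprod(called)
  sumdiff <- 2 * (n02 + t(n02)) + (n01 + t(n01)) + (n12 + t(n12))
  if (any(N[upper.tri(N)] == 0))
    stop("sample pair with zero overlapping called loci")
  dst <- (2 * N - sumdiff) / (2 * N)     # (IBS2 + 0.5 IBS1)/N in allele units
  D <- 1 - dst
  diag(D) <- 0
  dimnames(D) <- list(colnames(g), colnames(g))
  D
}
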