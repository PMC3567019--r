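#' Per-SNP Weir-Cockerham F_ST components
#'
#' The two-level ANOVA estimator of the fixation index. For each SNP with
#' `s` groups, `n_i` called gene copies (2 x called individuals) and group
#' allele frequencies `p_i`:
#' \deqn{MSP = \frac{1}{s-1} \sum_i n_i (p_i - \bar p)^2, \qquad
#'       MSG = \frac{1}{\sum_i (n_i - 1)} \sum_i n_i p_i (1 - p_i),}
#' \deqn{n_c = \frac{1}{s-1}\Big(\sum_i n_i - \frac{\sum_i n_i^2}{\sum_i n_i}\Big),
#'       \qquad \hat F_{ST} = \frac{MSP - MSG}{MSP + (n_c - 1) MSG},}
#' with \eqn{\bar p} the `n`-weighted mean frequency. Negative estimates
#' (no biological interpretation) are clamped to 0, and values above 1 to 1;
#' the raw value is also reported.
#'
#' @param panel a [GenotypePanel-class]
#' @param grouping how populations map to groups: `NULL` (each population is
#'   its own group), a named list of population-label vectors, or a named
#'   character vector population -> group
#' @param snps optional SNP subset (ids or indices)
#' @return `data.frame` with one row per SNP: `snp_id`, `chromosome`,
#'   `position_bp`, `s`, `msp`, `msg`, `n_c`, `pbar`, `fst_raw`, `fst`
#'   (clamped; `NA` where any group has zero called genotypes)
#' @export
perSnpFst <- function(panel, grouping = NULL, snps = NULL) {
  if (!is.null(snps)) panel <- panel[snps, ]
  grp <- .sampleGroups(panel, grouping)
  d <- dosages(panel)
  glev <- levels(grp)
  if (length(glev) < 2L) stop("need >= 2 groups")
  nmat <- fmat <- matrix(0, length(glev), nrow(d))
  for (gi in seq_along(glev)) {
    dg <- d[, grp == glev[gi], drop = FALSE]
    ncall <- rowSums(!is.na(dg))
    nmat[gi, ] <- 2 * ncall
    fmat[gi, ] <- ifelse(ncall > 0, rowSums(dg, na.rm = TRUE) / (2 * ncall),
                         NA)
  }
  comp <- .wcComponents(fmat, nmat)
  map <- markerMap(panel)
  data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
             position_bp = map$position_bp,
             s = comp$s, msp = comp$msp, msg = comp$msg, n_c = comp$n_c,
             pbar = comp$pbar, fst_raw = comp$raw, fst = comp$fst,
             stringsAsFactors = FALSE)
}

# vectorised W-C mean squares; fmat/nmat are groups x snps (gene copies)
.wcComponents <- function(fmat, nmat) {
  s <- nrow(fmat)
  valid <- colSums(nmat == 0 | is.na(fmat)) == 0
  nsum <- colSums(nmat)
  pbar <- colSums(nmat * fmat) / nsum
  msp <- colSums(nmat * sweep(fmat, 2, pbar)^2) / (s - 1)
  msg <- colSums(nmat * fmat * (1 - fmat)) / colSums(nmat - 1)
  n_c <- (nsum - colSums(nmat^2) / nsum) / (s - 1)
  raw <- (msp - msg) / (msp + (n_c - 1) * msg)
  raw[!valid] <- NA
  raw[valid & msp == 0 & msg == 0] <- NA  # uninformative: fixed everywhere
  list(s = s, msp = msp, msg = msg, n_c = n_c, pbar = pbar, raw = raw,
       fst = pmin(pmax(raw, 0), 1))
}

.sampleGroups <- function(panel, grouping) {
  pops <- populations(panel)
  if (is.null(grouping)) return(factor(pops, levels = unique(pops)))
  if (is.factor(grouping) && length(grouping) == length(pops))
    return(droplevels(grouping))   # pre-resolved sample-level factor
  if (is.list(grouping)) {
    unknown <- setdiff(unlist(grouping), unique(pops))
    if (length(unknown))
      stop("unknown population label(s): ", paste(unknown, collapse = ", "))
    g2p <- rep(names(grouping), lengths(grouping))
    names(g2p) <- unlist(grouping)
    lab <- g2p[pops]
  } else {
    lab <- grouping[pops]
  }
  factor(lab, levels = unique(lab[!is.na(lab)]))
}

#' Aggregate Weir-Cockerham F_ST over SNPs
#'
#' Reports the arithmetic mean and standard deviation of the clamped per-SNP
#' estimates (the genome-scan style summary) together with the multilocus
#' Weir-Cockerham estimate, the ratio of summed variance components
#' `sum(MSP - MSG) / sum(MSP + (n_c - 1) MSG)`, which is the recommended
#' aggregation when a single differentiation parameter is wanted (the mean
#' of per-locus ratios is systematically smaller under drift models).
#'
#' @inheritParams perSnpFst
#' @return list with `mean`, `sd`, `multilocus`, `n_snps` (valid loci),
#'   `n_excluded`, and the per-SNP `table`
#' @export
groupMeanFst <- function(panel, grouping = NULL, snps = NULL) {
  tab <- perSnpFst(panel, grouping, snps)
  ok <- !is.na(tab$fst)
  if (!any(ok)) stop("no SNP with a valid F_ST estimate")
  denom <- tab$msp + (tab$n_c - 1) * tab$msg
  multi <- sum((tab$msp - tab$msg)[ok]) / sum(denom[ok])
  list(mean = mean(tab$fst[ok]), sd = sd(tab$fst[ok]),
       multilocus = min(max(multi, 0), 1),
       n_snps = sum(ok), n_excluded = sum(!ok), table = tab)
}

#' Pairwise population F_ST matrix
#'
#' Multilocus Weir-Cockerham estimates for every pair of populations (or
#' super-groups); symmetric with zero diagonal.
#'
#' @param panel a [GenotypePanel-class]
#' @param grouping as in [perSnpFst()]; default: per population
#' @param snps optional SNP subset
#' @param per_snp_mean use the mean of clamped per-SNP values instead of the
#'   multilocus ratio
#' @return symmetric numeric matrix
#' @export
pairwiseFst <- function(panel, grouping = NULL, snps = NULL,
                        per_snp_mean = FALSE) {
  grp <- .sampleGroups(panel, grouping)
  glev <- levels(grp)
  if (length(glev) < 2L) stop("need >= 2 groups")
  M <- matrix(0, length(glev), length(glev), dimnames = list(glev, glev))
  for (i in seq_len(length(glev) - 1L))
    for (j in (i + 1L):length(glev)) {
      sel <- grp %in% glev[c(i, j)]
      res <- groupMeanFst(panel[, sel], grouping = factor(grp[sel]),
                          snps = snps)
      M[i, j] <- M[j, i] <- if (per_snp_mean) res$mean else res$multilocus
    }
  M
}
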