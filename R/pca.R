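#' Greedy LD pruning of a panel
#'
#' Sliding-window pruning of SNPs in strong pairwise linkage disequilibrium:
#' within windows of `window_snps` SNPs advanced by `step`, whenever a pair
#' of surviving SNPs has genotype correlation `r2 >= r2_threshold`, the
#' later (higher-position) SNP is dropped. Survivors within any window have
#' all pairwise r2 below the threshold. r2 is the squared Pearson correlation
#' of dosage vectors over pairwise-complete samples; pruning operates per
#' chromosome.
#'
#' @param panel a [GenotypePanel-class]
#' @param r2_threshold drop threshold in (0, 1\], default 0.2
#' @param window_snps window width in SNPs (default 50)
#' @param step window advance in SNPs (default 5)
#' @return the pruned panel; the dropped SNP ids are recorded in
#'   `metadata()$pruned_snps`
#' @export
ldPrune <- function(panel, r2_threshold = 0.2, window_snps = 50, step = 5) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1,
            window_snps >= 2, step >= 1)
  d <- dosages(panel)
  chr <- as.character(GenomicRanges::seqnames(rowRanges(panel)))
  keep <- rep(TRUE, nrow(d))
  for (cc in unique(chr)) {
    rows <- which(chr == cc)
    nloc <- length(rows)
    kp <- rep(TRUE, nloc)
    starts <- unique(c(seq(1L, max(1L, nloc - window_snps + 1L), by = step),
                       max(1L, nloc - window_snps + 1L)))
    for (s in starts) {
      win <- s:min(s + window_snps - 1L, nloc)
      alive <- win[kp[win]]
      if (length(alive) < 2L) next
      r2 <- suppressWarnings(
        cor(d[rows[alive], , drop = FALSE] |> t(),
            use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      for (a in seq_along(alive)) {
        if (!kp[alive[a]]) next
        later <- seq_along(alive)[-seq_len(a)]
        hit <- later[kp[alive[later]] & r2[a, later] >= r2_threshold]
        kp[alive[hit]] <- FALSE
      }
    }
    keep[rows] <- kp
  }
  out <- panel[keep, ]
  metadata(out)$pruned_snps <- rownames(panel)[!keep]
  metadata(out)$prune_params <- list(r2_threshold = r2_threshold,
                                     window_snps = window_snps, step = step)
  out
}

#' Principal component analysis of population structure
#'
#' Frequency-normalized PCA in the Patterson/EIGENSTRAT style: each SNP's
#' dosage vector is centred by twice its allele-frequency estimate and scaled
#' by `sqrt(2 p (1 - p))`; missing dosages are mean-imputed (zero after
#' centring); monomorphic or all-missing SNPs are excluded. The sample
#' covariance across SNPs is then eigendecomposed.
#'
#' @param panel a [GenotypePanel-class], normally LD-pruned first
#' @param k number of components to return (`k < n_samples`)
#' @return list of class `PcaResult` with `scores` (samples x k, unit-norm
#'   eigenvectors), `eigenvalues` (all `n_samples` eigenvalues,
#'   non-increasing), `var_explained` (fraction per returned component),
#'   `n_snps_used`
#' @export
panelPca <- function(panel, k = 10) {
  d <- dosages(panel)
  if (k >= ncol(d)) stop("k must be smaller than the number of samples")
  n <- rowSums(!is.na(d))
  p <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA)
  use <- !is.na(p) & p > 0 & p < 1
  d <- d[use, , drop = FALSE]; p <- p[use]
  x <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0
  cv <- crossprod(x) / nrow(x)          # samples x samples
  eg <- eigen(cv, symmetric = TRUE)
  scores <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(scores) <- colnames(d)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 eigenvalues = eg$values,
                 var_explained = eg$values[seq_len(k)] /
                   sum(pmax(eg$values, 0)),
                 n_snps_used = nrow(d)),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PCA of population structure:", nrow(x$scores), "samples,",
      x$n_snps_used, "SNPs\n")
  ve <- round(100 * x$var_explained, 1)
  cat("  variance explained (%):", paste(ve, collapse = " "), "\n")
  invisible(x)
}
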