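#' Pairwise genotype r2 within a maximum distance
#'
#' Squared Pearson correlation of alt-allele dosage vectors over
#' pairwise-complete samples, for all autosomal same-chromosome SNP pairs
#' within `max_distance_bp`. Before pairing, SNPs are screened within the
#' analysed sample subset: MAF >= `min_maf` and missingness < `max_missing`.
#' Pairs with a zero-variance dosage vector are skipped and counted in
#' `attr(, "n_skipped")`.
#'
#' @param panel a [GenotypePanel-class]
#' @param population optional population label (or vector of labels); default
#'   all samples
#' @param samples optional explicit sample ids (overrides `population`)
#' @param max_distance_bp maximum inter-SNP distance, default 1e6 (1,000 kb,
#'   inclusive)
#' @param min_maf within-subset MAF screen, default 0.10 (inclusive)
#' @param max_missing within-subset missingness screen, default 0.10
#'   (exclusive)
#' @return `data.frame` with `snp_a`, `snp_b`, `chromosome`, `distance_bp`,
#'   `r2`
#' @export
pairwiseR2 <- function(panel, population = NULL, samples = NULL,
                       max_distance_bp = 1e6, min_maf = 0.10,
                       max_missing = 0.10) {
  panel <- autosomalPanel(panel)
  if (is.null(samples) && !is.null(population))
    samples <- colnames(panel)[populations(panel) %in% population]
  if (is.null(samples)) samples <- colnames(panel)
  if (length(samples) < 2L) stop("need >= 2 samples")
  d <- dosages(panel)[, samples, drop = FALSE]
  st <- data.frame(call = rowMeans(!is.na(d)))
  n <- rowSums(!is.na(d))
  f <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA)
  maf <- pmin(f, 1 - f)
  use <- !is.na(maf) & maf >= min_maf & (1 - st$call) < max_missing
  d <- d[use, , drop = FALSE]
  map <- markerMap(panel)[use, , drop = FALSE]

  out <- vector("list", 0L); skipped <- 0L
  for (cc in unique(map$chromosome)) {
    rows <- which(map$chromosome == cc)
    if (length(rows) < 2L) next
    pos <- map$position_bp[rows]
    C <- suppressWarnings(cor(t(d[rows, , drop = FALSE]),
                              use = "pairwise.complete.obs"))
    dist <- abs(outer(pos, pos, "-"))
    sel <- upper.tri(C) & dist > 0 & dist <= max_distance_bp
    r2 <- C[sel]^2
    skipped <- skipped + sum(is.na(r2))
    ii <- row(C)[sel]; jj <- col(C)[sel]
    ok <- !is.na(r2)
    out[[length(out) + 1L]] <-
      data.frame(snp_a = map$snp_id[rows][ii[ok]],
                 snp_b = map$snp_id[rows][jj[ok]],
                 chromosome = cc,
                 distance_bp = dist[sel][ok],
                 r2 = r2[ok], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_a = character(), snp_b = character(),
               chromosome = character(), distance_bp = numeric(),
               r2 = numeric())
  attr(res, "n_skipped") <- skipped
  attr(res, "n_samples") <- length(samples)
  res
}

#' The 19 inter-SNP distance classes (kb)
#'
#' Bin edges 0-4, 4-8, 8-12, 12-20, 20-30, 30-40, 40-60, 60-80, 80-100,
#' 100-120, 120-160, 160-200, 200-250, 250-300, 300-360, 360-460, 460-620,
#' 620-800, 800-1000 kb. Intervals are left-closed/right-open, with the last
#' class closed at 1000 kb so every retained pair maps to exactly one class.
#'
#' @return numeric vector of 20 edges in kb
#' @export
ldBinEdges <- function() {
  c(0, 4, 8, 12, 20, 30, 40, 60, 80, 100, 120, 160, 200, 250, 300,
    360, 460, 620, 800, 1000)
}

#' Bin pairwise LD records by distance class
#'
#' @param records output of [pairwiseR2()]
#' @return `data.frame` with one row per distance class: `bin`, `lo_kb`,
#'   `hi_kb`, `n_pairs`, `mean_r2`
#' @export
binLd <- function(records) {
  edges <- ldBinEdges()
  dkb <- records$distance_bp / 1000
  if (any(dkb > max(edges)))
    stop("record beyond ", max(edges), " kb; filter upstream")
  idx <- findInterval(dkb, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  cnt <- tabulate(idx, nbins = nb)
  sums <- vapply(seq_len(nb), function(b) sum(records$r2[idx == b]),
                 numeric(1))
  data.frame(bin = paste0(edges[-length(edges)], "-", edges[-1]),
             lo_kb = edges[-length(edges)], hi_kb = edges[-1],
             n_pairs = cnt,
             mean_r2 = ifelse(cnt > 0, sums / cnt, NA),
             stringsAsFactors = FALSE)
}

#' Fit the Sved hyperbolic LD-decay model
#'
#' Least squares for `E[r2] = 1 / (1 + beta d)` with `beta >= 0`, fitted to
#' raw pairwise records by default, or to binned class means (at class
#' midpoints) with `binned = TRUE` input. The LD extent at threshold `t` is
#' `(1/t - 1) / beta`, the distance at which the fitted curve crosses `t`;
#' it is infinite (and flagged) when no decay is detectable.
#'
#' The 1-D minimisation is a golden-section search over `log10(beta)`;
#' `beta` is carried per bp internally and reported per kb as well.
#'
#' @param records output of [pairwiseR2()], or a [binLd()] table
#' @param threshold extent threshold `t`, default 0.3
#' @return list of class `SvedFit`: `beta_per_bp`, `beta_per_kb`, `rss`,
#'   `n_pairs`, `threshold`, `extent_bp`, `extent_kb`, `no_decay`
#' @export
fitSved <- function(records, threshold = 0.3) {
  if (all(c("mean_r2", "lo_kb") %in% names(records))) {
    keep <- records$n_pairs > 0
    dbp <- 1000 * (records$lo_kb + records$hi_kb)[keep] / 2
    r2 <- records$mean_r2[keep]
    npair <- sum(records$n_pairs)
  } else {
    dbp <- records$distance_bp
    r2 <- records$r2
    npair <- length(r2)
  }
  if (length(unique(dbp)) < 2L) stop("need >= 2 distinct distances")
  obj <- function(l10b) {
    b <- 10^l10b
    sum((r2 - 1 / (1 + b * dbp))^2)
  }
  opt <- optimize(obj, c(-12, 0), tol = 1e-13)
  beta_bp <- 10^opt$minimum
  rss0 <- sum((r2 - 1)^2)                   # beta = 0 (no decay)
  no_decay <- rss0 <= opt$objective + 1e-12
  if (no_decay) beta_bp <- 0
  extent_bp <- if (beta_bp > 0) (1 / threshold - 1) / beta_bp else Inf
  if (no_decay) warning("no detectable LD decay; extent is infinite")
  structure(list(beta_per_bp = beta_bp, beta_per_kb = beta_bp * 1000,
                 rss = if (no_decay) rss0 else opt$objective,
                 n_pairs = npair, threshold = threshold,
                 extent_bp = extent_bp, extent_kb = extent_bp / 1000,
                 no_decay = no_decay),
            class = "SvedFit")
}

#' Evaluate a fitted Sved curve
#'
#' @param fit a `SvedFit`
#' @param distance_bp distances in bp
#' @return predicted r2
#' @export
predictSved <- function(fit, distance_bp)
  1 / (1 + fit$beta_per_bp * distance_bp)

#' Pooled (inter-population) LD decay
#'
#' Pools a seeded random subsample of individuals across populations into one
#' panel and runs [pairwiseR2()] + [fitSved()] on the pool, measuring how far
#' LD is shared across populations.
#'
#' @param panel a [GenotypePanel-class]
#' @param populations populations to pool (default all)
#' @param n_per_pop samples drawn per population; populations smaller than
#'   this contribute all their samples (with a warning)
#' @param seed RNG seed for the subsample
#' @param ... passed to [pairwiseR2()]
#' @param threshold extent threshold for [fitSved()]
#' @return a `SvedFit`; chosen sample ids in `attr(, "samples")`
#' @export
interpopulationLd <- function(panel, populations = NULL, n_per_pop = 10,
                              seed = 1, threshold = 0.3, ...) {
  pops <- arraypopgen::populations(panel)
  if (is.null(populations)) populations <- unique(pops)
  set.seed(seed)
  chosen <- unlist(lapply(populations, function(pp) {
    ids <- colnames(panel)[pops == pp]
    if (length(ids) < n_per_pop) {
      warning("population ", pp, " has only ", length(ids),
              " samples; taking all")
      ids
    } else sort(sample(ids, n_per_pop))
  }))
  rec <- pairwiseR2(panel, samples = chosen, ...)
  fit <- fitSved(rec, threshold = threshold)
  attr(fit, "samples") <- chosen
  fit
}
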