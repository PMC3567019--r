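#' Runs-of-homozygosity configuration
#'
#' Parameters of the sliding-window ROH scan. Windows contain
#' `window_min_snps` consecutive SNPs and are valid only when their physical
#' span does not exceed `window_span_bp` (so sparse regions never contribute
#' windows); a valid window is called homozygous when it contains at most
#' `max_het_per_window` heterozygous and `max_missing_per_window` missing
#' calls. A SNP is ROH-eligible when the proportion of homozygous windows
#' among the valid windows covering it is at least `window_hit_proportion`;
#' the default `1 / window_min_snps` accepts a single homozygous covering
#' window, which keeps the boundaries of a clean homozygous tract intact so
#' the minimum-length rule is exact. Maximal runs of eligible SNPs, trimmed
#' to homozygous called endpoints, are emitted when their base-pair span is
#' at least `min_roh_length_bp`.
#'
#' @param window_span_bp maximum window span, default 5 Mb
#' @param window_min_snps SNPs per window, default 50
#' @param max_het_per_window allowed heterozygous calls, default 1
#' @param max_missing_per_window allowed missing calls, default 5
#' @param min_roh_length_bp minimum emitted run length, default 500 kb
#' @param window_hit_proportion eligibility threshold in (0, 1\]
#' @return list of class `RohConfig`
#' @export
rohConfig <- function(window_span_bp = 5e6, window_min_snps = 50,
                      max_het_per_window = 1, max_missing_per_window = 5,
                      min_roh_length_bp = 5e5,
                      window_hit_proportion = 1 / window_min_snps) {
  stopifnot(window_span_bp > 0, window_min_snps >= 2,
            max_het_per_window >= 0, max_missing_per_window >= 0,
            min_roh_length_bp > 0, min_roh_length_bp <= window_span_bp,
            window_hit_proportion > 0, window_hit_proportion <= 1)
  structure(as.list(environment()), class = "RohConfig")
}

#' Detect runs of homozygosity for one sample
#'
#' PLINK-style scan (see [rohConfig()] for the window rules). Coordinates
#' are 1-based inclusive; segment length is `end - start + 1`.
#'
#' @param panel a [GenotypePanel-class] (autosomes are used)
#' @param sample sample id or column index
#' @param config a [rohConfig()]
#' @return `data.frame` with `sample`, `chromosome`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_snps`, `n_het`, `n_missing`
#' @export
detectRoh <- function(panel, sample, config = rohConfig()) {
  panel <- autosomalPanel(panel)
  if (is.character(sample) && !sample %in% colnames(panel))
    stop("unknown sample: ", sample)
  g <- dosages(panel)[, sample]
  map <- markerMap(panel)
  segs <- list()
  for (cc in unique(map$chromosome)) {
    rows <- which(map$chromosome == cc)
    pos <- map$position_bp[rows]
    if (is.unsorted(pos, strictly = TRUE)) stop("unsorted map on chr ", cc)
    segs[[cc]] <- .rohChrom(g[rows], pos, cc, sample, config)
  }
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(sample = character(), chromosome = character(),
                      start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snps = integer(),
                      n_het = integer(), n_missing = integer())
  rownames(out) <- NULL
  out
}

.rohChrom <- function(g, pos, chrom, sample, cfg) {
  n <- length(g)
  W <- cfg$window_min_snps
  if (n < W) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  chet <- cumsum(het); cmis <- cumsum(mis)
  starts <- seq_len(n - W + 1L)
  span <- pos[starts + W - 1L] - pos[starts] + 1L
  valid <- span <= cfg$window_span_bp
  nhet <- chet[starts + W - 1L] - c(0, chet)[starts]
  nmis <- cmis[starts + W - 1L] - c(0, cmis)[starts]
  hom <- valid & nhet <= cfg$max_het_per_window &
    nmis <= cfg$max_missing_per_window
  # per-SNP counts of covering valid / homozygous windows via cumsum of
  # start indicators over the covering start range [i - W + 1, i]
  cval <- cumsum(c(0, as.numeric(valid)))
  chom <- cumsum(c(0, as.numeric(hom)))
  i <- seq_len(n)
  lo <- pmax(1L, i - W + 1L)
  hi <- pmin(i, n - W + 1L)
  has <- hi >= lo
  ncov <- nhit <- numeric(n)
  ncov[has] <- cval[hi[has] + 1L] - cval[lo[has]]
  nhit[has] <- chom[hi[has] + 1L] - chom[lo[has]]
  eligible <- ncov > 0 & nhit / pmax(ncov, 1) >= cfg$window_hit_proportion

  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    a <- begs[k]; b <- ends[k]
    # trim ends to homozygous called SNPs
    while (a <= b && (het[a] || mis[a])) a <- a + 1L
    while (b >= a && (het[b] || mis[b])) b <- b - 1L
    if (a > b) next
    len <- pos[b] - pos[a] + 1L
    if (len < cfg$min_roh_length_bp) next
    out[[length(out) + 1L]] <-
      data.frame(sample = sample, chromosome = chrom,
                 start_bp = pos[a], end_bp = pos[b], length_bp = len,
                 n_snps = b - a + 1L,
                 n_het = sum(het[a:b]), n_missing = sum(mis[a:b]),
                 stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Detect ROH for every sample of a panel
#'
#' @inheritParams detectRoh
#' @return row-bound [detectRoh()] tables for all samples
#' @export
detectRohAll <- function(panel, config = rohConfig()) {
  res <- lapply(colnames(panel), function(s) detectRoh(panel, s, config))
  do.call(rbind, res)
}

#' Autozygosity summaries from ROH segments
#'
#' Per-sample and per-population fraction of the analysed genome covered by
#' ROH, plus a segment-length histogram.
#'
#' @param segments a [detectRohAll()] table
#' @param panel the panel the segments came from (defines the analysed span
#'   and the population of each sample); alternatively give `genome_span_bp`
#' @param genome_span_bp analysed genome span in bp (overrides `panel`)
#' @param length_breaks_mb histogram class edges in Mb
#' @return list with `per_sample`, `per_population`, `histogram`
#' @export
rohSummary <- function(segments, panel = NULL, genome_span_bp = NULL,
                       length_breaks_mb = c(0.5, 1, 2, 4, 8, 16, Inf)) {
  if (is.null(genome_span_bp)) {
    if (is.null(panel)) stop("need panel or genome_span_bp")
    map <- markerMap(autosomalPanel(panel))
    genome_span_bp <- sum(vapply(split(map$position_bp, map$chromosome),
                                 function(p) diff(range(p)) + 1, numeric(1)))
  }
  if (genome_span_bp <= 0) stop("zero genome span")
  samp <- if (!is.null(panel)) colnames(panel) else unique(segments$sample)
  tot <- vapply(samp, function(s)
    sum(segments$length_bp[segments$sample == s]), numeric(1))
  per_sample <- data.frame(sample = samp, roh_bp = unname(tot),
                           fraction = unname(tot) / genome_span_bp,
                           stringsAsFactors = FALSE)
  per_population <- NULL
  if (!is.null(panel)) {
    pop <- populations(panel)[per_sample$sample]
    agg <- aggregate(per_sample$fraction, list(population = pop), mean)
    names(agg)[2] <- "mean_fraction"
    per_population <- agg[match(unique(pop), agg$population), ]
    rownames(per_population) <- NULL
  }
  br <- c(0, length_breaks_mb)
  idx <- findInterval(segments$length_bp / 1e6, br, rightmost.closed = FALSE)
  hist <- data.frame(
    class_mb = paste0(br[-length(br)], "-", br[-1]),
    n_segments = tabulate(idx, nbins = length(br) - 1L))
  list(per_sample = per_sample, per_population = per_population,
       histogram = hist, genome_span_bp = genome_span_bp)
}
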