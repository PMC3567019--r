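# Shared fixture builders (all generated in code; no data files).

# snps x samples panel from explicit dosage rows
toyPanel <- function(dosage, chromosome = "1", positions = NULL,
                     pops = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("snp%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  if (is.null(positions)) positions <- seq_len(nrow(dosage)) * 1000L
  if (is.null(pops)) pops <- setNames(rep("P1", ncol(dosage)),
                                      colnames(dosage))
  map <- data.frame(snp_id = rownames(dosage),
                    chromosome = rep(chromosome, length.out = nrow(dosage)),
                    position_bp = positions)
  GenotypePanel(dosage, map, pops)
}

# single-SNP two-population panel with exact group frequencies 0.8 / 0.2
# over 20 gene copies each (the worked Weir-Cockerham example)
wcExamplePanel <- function() {
  d1 <- c(rep(2L, 6), rep(1L, 4))            # p = 16/20 = 0.8
  d2 <- c(rep(0L, 6), rep(1L, 4))            # p = 4/20  = 0.2
  d <- matrix(c(d1, d2), nrow = 1,
              dimnames = list("snpX", paste0("s", 1:20)))
  toyPanel(d, pops = setNames(rep(c("A", "B"), each = 10), paste0("s", 1:20)))
}

# one-sample chromosome on a 5-kb grid, all-heterozygous background, with
# fully homozygous tracts planted at the given [start, end] intervals (bp)
rohPanel <- function(n_snps = 10000, spacing = 5000, plants = list()) {
  pos <- seq(spacing, by = spacing, length.out = n_snps)
  g <- rep(1L, n_snps)
  for (iv in plants) g[pos >= iv[1] & pos <= iv[2]] <- 2L
  d <- matrix(g, ncol = 1,
              dimnames = list(sprintf("m%05d", seq_len(n_snps)), "ind"))
  toyPanel(d, positions = pos, pops = c(ind = "P"))
}

# allele-count list in the shape alleleCountTable() returns
countFixture <- function(a, n) {
  L <- nrow(a)
  list(a = a, n = n, snp_id = sprintf("s%03d", seq_len(L)),
       chromosome = rep("1", L), position_bp = seq_len(L) * 1000)
}

quickScanConfig <- function(seed, L_pilot = 300, burn = 2000, samp = 6000)
  outlierScanConfig(n_pilot_runs = 8, pilot_length = L_pilot,
                    burn_in = burn, sampling_steps = samp, thinning = 5,
                    seed = seed)
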