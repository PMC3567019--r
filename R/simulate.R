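#' Draw population allele frequencies under the Balding-Nichols model
#'
#' Given ancestral frequencies `p` and a divergence parameter `fst` in (0, 1),
#' draws one population frequency per locus from
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)`, which has expectation
#' `p` and variance `fst * p * (1 - p)`.
#'
#' @param p numeric vector of ancestral frequencies, all in (0, 1)
#' @param fst divergence parameter in (0, 1)
#' @return numeric vector of population frequencies, same length as `p`
#' @export
simulatePopulationFrequencies <- function(p, fst) {
  if (!is.numeric(fst) || length(fst) != 1 || fst <= 0 || fst >= 1)
    stop("fst must be a single value in (0, 1)")
  if (any(p <= 0 | p >= 1)) stop("ancestral frequencies must be in (0, 1)")
  rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Configuration for the multi-population SNP panel simulator
#'
#' Defines a study design for [simulateGenotypes()]: marker layout,
#' populations with Balding-Nichols divergence (optionally nested in
#' super-groups), LD decay, missingness, admixed populations, planted
#' autozygous tracts and planted outlier loci. The seed fully determines the
#' simulated panel.
#'
#' @param seed integer RNG seed
#' @param n_snps total number of SNPs across all chromosomes
#' @param populations `data.frame` with columns `name`, `n` (diploid
#'   individuals) and `fst` (per-population divergence in (0, 1)); optional
#'   column `group` assigns populations to super-groups
#' @param groups optional named numeric vector of super-group divergences
#'   (group ancestor drawn Balding-Nichols around the global ancestral
#'   frequency; populations then diverge from their group ancestor)
#' @param snp_spacing_bp mean physical spacing between neighbouring SNPs
#' @param spacing_jitter gaps are drawn uniformly in
#'   `(1 +/- spacing_jitter) * snp_spacing_bp`; 0 gives an exact grid
#' @param n_chromosomes number of autosomes the SNPs are spread over
#' @param ld_beta_per_kb Sved decay coefficient of the generated LD
#'   (`E[r2] = 1/(1 + beta d_kb)`), a single value or one per population;
#'   `NULL` simulates linkage equilibrium (every SNP independent)
#' @param ld_region_bp length of the genomic regions over which the LD decay
#'   rate is constant; the hyperbolic decay emerges as an exponential-rate
#'   mixture across regions, so curve fidelity needs many regions
#' @param phase_mode `"shared"` (default): one haplotype-coupling orientation
#'   throughout, giving the analytic decay curve within every population;
#'   `"independent"`: per-SNP random orientation per population, which
#'   decorrelates LD phase between populations (at some cost in within-
#'   population r2 for loci away from frequency 0.5)
#' @param p_anc_range range of the uniform ancestral frequency distribution
#' @param missing_rate independent per-call missingness probability
#' @param admixture optional `data.frame(target, source1, source2, fraction)`;
#'   each haplotype of `target` is copied from `source1`'s generating process
#'   with probability `fraction`, else from `source2`'s
#' @param planted_roh optional `data.frame(population, individual, chromosome,
#'   start_bp, length_bp)`: within `[start_bp, start_bp + length_bp - 1]` the
#'   individual's second haplotype is overwritten with the first, forcing
#'   homozygosity
#' @param outlier_loci optional `data.frame(snp_index, fstar)`: those loci are
#'   redrawn with divergence `fstar` using antithetic Beta quantiles across
#'   super-groups (or populations when no groups are defined), guaranteeing
#'   strong differentiation while keeping Balding-Nichols marginals. With LD
#'   enabled, frequencies are region-constant, so the override applies to the
#'   locus's whole LD region
#' @return list of class `SimulationConfig`
#' @seealso [studyDesignConfig()] for the bundled 18-population design
#' @export
simulationConfig <- function(seed,
                             n_snps,
                             populations,
                             groups = NULL,
                             snp_spacing_bp = 55600,
                             spacing_jitter = 0.5,
                             n_chromosomes = 18,
                             ld_beta_per_kb = NULL,
                             ld_region_bp = 1e7,
                             phase_mode = c("shared", "independent"),
                             p_anc_range = c(0.05, 0.95),
                             missing_rate = 0.01,
                             admixture = NULL,
                             planted_roh = NULL,
                             outlier_loci = NULL) {
  phase_mode <- match.arg(phase_mode)
  populations <- as.data.frame(populations)
  stopifnot(all(c("name", "n", "fst") %in% names(populations)),
            nrow(populations) >= 1, all(populations$n >= 1))
  if (any(populations$fst <= 0 | populations$fst >= 1))
    stop("population fst values must be in (0, 1)")
  if (!is.null(groups)) {
    if (is.null(populations$group))
      stop("groups given but populations have no 'group' column")
    if (any(groups <= 0 | groups >= 1)) stop("group fst must be in (0, 1)")
    unknown <- setdiff(na.omit(populations$group), names(groups))
    if (length(unknown)) stop("group(s) without divergence: ",
                              paste(unknown, collapse = ", "))
  }
  if (!is.null(ld_beta_per_kb)) {
    if (!length(ld_beta_per_kb) %in% c(1L, nrow(populations)))
      stop("ld_beta_per_kb must be one value or one per population")
    if (any(ld_beta_per_kb < 0)) stop("ld_beta_per_kb must be >= 0")
  }
  stopifnot(missing_rate >= 0, missing_rate < 1,
            spacing_jitter >= 0, spacing_jitter < 1,
            n_snps >= n_chromosomes, n_chromosomes >= 1,
            p_anc_range[1] > 0, p_anc_range[2] < 1,
            p_anc_range[1] <= p_anc_range[2])
  if (!is.null(admixture)) {
    admixture <- as.data.frame(admixture)
    stopifnot(all(c("target", "source1", "source2", "fraction") %in%
                    names(admixture)))
    pool <- populations$name
    missing_src <- setdiff(c(admixture$source1, admixture$source2,
                             admixture$target), pool)
    if (length(missing_src))
      stop("admixture refers to unknown population(s): ",
           paste(missing_src, collapse = ", "))
    if (any(admixture$source1 %in% admixture$target |
            admixture$source2 %in% admixture$target))
      stop("admixture sources must not themselves be admixed targets")
    if (any(admixture$fraction <= 0 | admixture$fraction >= 1))
      stop("admixture fraction must be in (0, 1)")
  }
  if (!is.null(outlier_loci)) {
    outlier_loci <- as.data.frame(outlier_loci)
    stopifnot(all(c("snp_index", "fstar") %in% names(outlier_loci)))
    if (any(outlier_loci$fstar <= 0 | outlier_loci$fstar >= 1))
      stop("outlier fstar must be in (0, 1)")
    if (any(outlier_loci$snp_index < 1 | outlier_loci$snp_index > n_snps))
      stop("outlier snp_index out of range")
  }
  if (!is.null(planted_roh)) {
    planted_roh <- as.data.frame(planted_roh)
    stopifnot(all(c("population", "individual", "chromosome", "start_bp",
                    "length_bp") %in% names(planted_roh)))
  }
  structure(list(seed = as.integer(seed), n_snps = as.integer(n_snps),
                 populations = populations, groups = groups,
                 snp_spacing_bp = snp_spacing_bp,
                 spacing_jitter = spacing_jitter,
                 n_chromosomes = as.integer(n_chromosomes),
                 ld_beta_per_kb = ld_beta_per_kb,
                 ld_region_bp = ld_region_bp, phase_mode = phase_mode,
                 p_anc_range = p_anc_range, missing_rate = missing_rate,
                 admixture = admixture, planted_roh = planted_roh,
                 outlier_loci = outlier_loci),
            class = "SimulationConfig")
}

# antithetic Beta quantiles across k entities: entity 1 gets v, entity 2 gets
# 1-v, entity 3 a fresh v', ... guaranteeing divergence between the first two
.antitheticBN <- function(p_anc, fstar, k) {
  a <- p_anc * (1 - fstar) / fstar
  b <- (1 - p_anc) * (1 - fstar) / fstar
  v <- runif(ceiling(k / 2))
  u <- as.vector(rbind(v, 1 - v))[seq_len(k)]
  qbeta(u, a, b)
}

.chainHaplotypes <- function(H, p, surv, dir) {
  n <- length(p)
  u <- matrix(0, H, n)
  u[, 1L] <- runif(H)
  if (n > 1L) for (k in 2:n) {
    ren <- runif(H) >= surv[k - 1L]
    u[, k] <- ifelse(ren, runif(H), u[, k - 1L])
  }
  thr <- matrix(rep(ifelse(dir, p, 1 - p), each = H), H, n)
  z <- matrix(0L, H, n)
  z[dir[col(z)]] <- (u < thr)[dir[col(z)]]
  z[!dir[col(z)]] <- (u > thr)[!dir[col(z)]]
  z
}

#' Simulate a multi-population SNP genotype panel
#'
#' Generates a [GenotypePanel-class] under a [simulationConfig()]. Population
#' frequencies follow the Balding-Nichols model around uniform ancestral
#' frequencies (optionally through a super-group layer). With LD enabled,
#' haplotypes are built by a continuum-founder copying chain: each haplotype
#' carries a latent founder coordinate that survives between adjacent SNPs
#' with probability `exp(-lambda d)`; the rate `lambda = U * beta / 2` is
#' constant within `ld_region_bp` regions with `U` an Exp(1) multiplier
#' (quantile-stratified across regions), so the expected genotype correlation
#' satisfies `E[r2] = 1/(1 + beta d)` at distance `d`. Within an LD region
#' the population frequency is constant; in linkage-equilibrium mode every
#' SNP is independent with its own frequency.
#'
#' @param config a [simulationConfig()]
#' @return A [GenotypePanel-class]; the config (and the drawn ancestral
#'   frequencies' RNG seed) is echoed in `metadata(panel)$sim_config`.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nc <- config$n_chromosomes
  per_chr <- diff(round(seq(0, config$n_snps, length.out = nc + 1)))
  s <- config$snp_spacing_bp; j <- config$spacing_jitter
  pos_list <- lapply(per_chr, function(m)
    cumsum(pmax(1, round(runif(m, (1 - j) * s, (1 + j) * s)))))
  chr_names <- as.character(seq_len(nc))

  ld_mode <- !is.null(config$ld_beta_per_kb)
  pops <- config$populations
  npop <- nrow(pops)
  beta <- if (ld_mode) rep(config$ld_beta_per_kb, length.out = npop) else NULL

  # region layout (LD mode) or per-SNP layout (linkage equilibrium)
  if (ld_mode) {
    reg_list <- lapply(seq_len(nc), function(i)
      floor(pos_list[[i]] / config$ld_region_bp))
    nreg <- vapply(reg_list, function(r) as.integer(max(r)) + 1L, integer(1))
    R <- sum(nreg)
    reg_off <- cumsum(c(0L, head(nreg, -1L)))
    U <- sample(qexp((seq_len(R) - 0.5) / R))   # stratified Exp(1) multipliers
    unit_anc <- runif(R, config$p_anc_range[1], config$p_anc_range[2])
  } else {
    R <- config$n_snps
    unit_anc <- runif(R, config$p_anc_range[1], config$p_anc_range[2])
  }

  # group-ancestor frequencies per unit (region or SNP)
  has_groups <- !is.null(config$groups)
  if (has_groups) {
    gfreq <- matrix(vapply(names(config$groups), function(g)
      simulatePopulationFrequencies(unit_anc, config$groups[[g]]),
      numeric(R)), nrow = R,
      dimnames = list(NULL, names(config$groups)))
  }
  parentFor <- function(ip) {
    g <- if (has_groups) pops$group[ip] else NA
    if (has_groups && !is.na(g) && g %in% names(config$groups))
      gfreq[, g] else unit_anc
  }
  pfreq <- matrix(vapply(seq_len(npop), function(ip)
    simulatePopulationFrequencies(parentFor(ip), pops$fst[ip]), numeric(R)),
    nrow = R)

  # planted outlier loci: antithetic redraw across groups (or populations)
  if (!is.null(config$outlier_loci)) {
    snp_chr <- rep(seq_len(nc), per_chr)
    snp_in_chr <- unlist(lapply(per_chr, seq_len))
    for (r in seq_len(nrow(config$outlier_loci))) {
      k <- config$outlier_loci$snp_index[r]
      fstar <- config$outlier_loci$fstar[r]
      unit <- if (ld_mode)
        reg_off[snp_chr[k]] + reg_list[[snp_chr[k]]][snp_in_chr[k]] + 1L
      else k
      if (has_groups) {
        gl <- names(config$groups)
        gdraw <- .antitheticBN(unit_anc[unit], fstar, length(gl))
        names(gdraw) <- gl
        for (ip in seq_len(npop)) {
          g <- pops$group[ip]
          base <- if (!is.na(g) && g %in% gl) gdraw[[g]] else unit_anc[unit]
          pfreq[unit, ip] <-
            simulatePopulationFrequencies(min(max(base, 1e-4), 1 - 1e-4),
                                          pops$fst[ip])
        }
      } else {
        pfreq[unit, ] <- .antitheticBN(unit_anc[unit], fstar, npop)
      }
    }
  }

  adm <- config$admixture
  is_adm <- pops$name %in% (if (is.null(adm)) character() else adm$target)

  # per-population, per-chromosome haplotype generation
  hap_store <- vector("list", npop)   # haplotypes per pop per chr
  popHaps <- function(ip, H) {
    lapply(seq_len(nc), function(ic) {
      pos <- pos_list[[ic]]
      if (ld_mode) {
        reg <- reg_list[[ic]] + reg_off[ic] + 1L
        p <- pfreq[reg, ip]
        d_kb <- diff(pos) / 1000
        lam <- U[reg[-1L]] * beta[ip] / 2
        surv <- exp(-lam * d_kb)
        surv[diff(reg) != 0L] <- 0
        dir <- if (config$phase_mode == "independent")
          runif(length(pos)) < 0.5 else rep(TRUE, length(pos))
        .chainHaplotypes(H, p, surv, dir)
      } else {
        p <- pfreq[seq_along(pos) +
                     sum(lengths(pos_list[seq_len(ic - 1L)])), ip]
        matrix(rbinom(H * length(pos), 1L, rep(p, each = H)), H)
      }
    })
  }
  for (ip in which(!is_adm)) {
    H <- 2L * pops$n[ip]
    hap_store[[ip]] <- popHaps(ip, H)
  }
  for (ip in which(is_adm)) {
    H <- 2L * pops$n[ip]
    row <- adm[match(pops$name[ip], adm$target), ]
    s1 <- match(row$source1, pops$name); s2 <- match(row$source2, pops$name)
    from1 <- runif(H) < row$fraction
    h1 <- popHaps(s1, H); h2 <- popHaps(s2, H)
    hap_store[[ip]] <- lapply(seq_len(nc), function(ic) {
      z <- h2[[ic]]; z[from1, ] <- h1[[ic]][from1, ]; z
    })
  }

  # planted ROH: overwrite haplotype 2 with haplotype 1 inside the interval
  if (!is.null(config$planted_roh)) {
    pr <- config$planted_roh
    for (r in seq_len(nrow(pr))) {
      ip <- match(as.character(pr$population[r]), pops$name)
      if (is.na(ip)) stop("planted_roh: unknown population ",
                          pr$population[r])
      ic <- match(as.character(pr$chromosome[r]), chr_names)
      if (is.na(ic)) stop("planted_roh: unknown chromosome ",
                          pr$chromosome[r])
      ind <- pr$individual[r]
      if (ind < 1 || ind > pops$n[ip])
        stop("planted_roh: individual index out of range")
      pos <- pos_list[[ic]]
      lo <- pr$start_bp[r]; hi <- pr$start_bp[r] + pr$length_bp[r] - 1
      if (lo < 1 || hi > max(pos))
        stop("impossible ROH placement: [", lo, ", ", hi,
             "] outside chromosome ", chr_names[ic])
      idx <- which(pos >= lo & pos <= hi)
      if (length(idx)) {
        h <- hap_store[[ip]][[ic]]
        h[2L * ind, idx] <- h[2L * ind - 1L, idx]
        hap_store[[ip]][[ic]] <- h
      }
    }
  }

  # assemble dosage matrix (snps x samples), apply missingness
  dos_by_pop <- lapply(seq_len(npop), function(ip) {
    H <- 2L * pops$n[ip]
    do.call(rbind, lapply(seq_len(nc), function(ic) {
      z <- hap_store[[ip]][[ic]]
      t(z[seq(1L, H, 2L), , drop = FALSE] + z[seq(2L, H, 2L), , drop = FALSE])
    }))
  })
  dosage <- do.call(cbind, dos_by_pop)
  if (config$missing_rate > 0) {
    mask <- runif(length(dosage)) < config$missing_rate
    dosage[mask] <- NA_integer_
  }

  snp_id <- unlist(lapply(seq_len(nc), function(ic)
    sprintf("snp_%02d_%05d", ic, seq_len(per_chr[ic]))))
  map <- data.frame(snp_id = snp_id,
                    chromosome = rep(chr_names, per_chr),
                    position_bp = unlist(pos_list),
                    allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  sample_id <- unlist(lapply(seq_len(npop), function(ip)
    sprintf("%s_%02d", pops$name[ip], seq_len(pops$n[ip]))))
  rownames(dosage) <- snp_id
  colnames(dosage) <- sample_id
  pop_labels <- setNames(rep(pops$name, pops$n), sample_id)

  panel <- GenotypePanel(dosage, map, pop_labels)
  metadata(panel)$sim_config <- config
  panel
}

#' The bundled 18-population study design
#'
#' A [simulationConfig()] emulating a two-continent pig diversity panel:
#' 14 eastern (`CN01`-`CN14`) and 4 western (`WT01`-`WT04`) populations with
#' the study's sample sizes (304 animals in total), nested divergence
#' producing between-group differentiation around 0.3 and within-group
#' pairwise values around 0.1, a mean inter-SNP spacing of 55.6 kb, one
#' admixed eastern population (`CN10`, an `CN03` x `WT01` cross) and one
#' admixed western population (`WT04`, a `WT01` x `WT03` cross).
#'
#' @param seed integer seed
#' @param n_snps number of SNPs (default 52556, the informative-marker count
#'   the design emulates; scale down for quick runs)
#' @param ld_beta_per_kb Sved decay coefficient (default 0.01/kb, an LD
#'   extent r2_0.3 of ~233 kb); `NULL` for linkage equilibrium
#' @param missing_rate per-call missing probability
#' @param outlier_loci,planted_roh passed through to [simulationConfig()]
#' @return a `SimulationConfig`
#' @export
studyDesignConfig <- function(seed, n_snps = 52556, ld_beta_per_kb = 0.01,
                              missing_rate = 0.01, outlier_loci = NULL,
                              planted_roh = NULL) {
  cn_n <- c(16, 15, 32, 13, 13, 10, 15, 18, 11, 15, 21, 29, 16, 15)
  wt_n <- c(20, 20, 20, 5)
  pops <- data.frame(
    name = c(sprintf("CN%02d", 1:14), sprintf("WT%02d", 1:4)),
    n = c(cn_n, wt_n),
    fst = c(0.10, 0.14, 0.08, 0.15, 0.15, 0.06, 0.12, 0.09, 0.12, 0.08,
            0.09, 0.09, 0.08, 0.07, 0.12, 0.10, 0.09, 0.08),
    group = c(rep("CN", 14), rep("WT", 4)),
    stringsAsFactors = FALSE)
  simulationConfig(
    seed = seed, n_snps = n_snps, populations = pops,
    groups = c(CN = 0.12, WT = 0.12),
    snp_spacing_bp = 55600, n_chromosomes = 18,
    ld_beta_per_kb = ld_beta_per_kb, missing_rate = missing_rate,
    admixture = data.frame(target = c("CN10", "WT04"),
                           source1 = c("CN03", "WT01"),
                           source2 = c("WT01", "WT03"),
                           fraction = c(0.5, 0.5)),
    outlier_loci = outlier_loci, planted_roh = planted_roh)
}

#' Contrast designs of the bundled study layout
#'
#' Two-group contrasts matching the bundled design's analysis plan: the
#' `plateau` contrast opposes the two highland-type populations (`CN11`,
#' `CN12`) to all other populations; the `belted` contrast opposes seven
#' belted-phenotype populations to the remaining eleven.
#'
#' @param config a config from [studyDesignConfig()] (only population names
#'   are used)
#' @return named list of two-element lists of population-name vectors
#' @export
studyContrasts <- function(config = studyDesignConfig(seed = 1)) {
  nm <- config$populations$name
  plateau <- nm[nm %in% c("CN11", "CN12")]
  belted <- nm[nm %in% sprintf("CN%02d", c(1, 2, 4, 5, 8, 9, 13))]
  list(plateau = list(plateau = plateau, lowland = setdiff(nm, plateau)),
       belted = list(belted = belted, non_belted = setdiff(nm, belted)))
}
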