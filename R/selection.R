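#' Per-SNP allele-count table for the outlier scan
#'
#' Sufficient statistics of the hierarchical model: per SNP and group, the
#' count of the panel's counted (alt-like) allele and the number of called
#' gene copies. SNPs where any group has zero called copies are skipped and
#' listed in `attr(, "skipped")`.
#'
#' @param panel a [GenotypePanel-class], normally QC-filtered first
#'   ([filterSnps()])
#' @param grouping contrast design: named list of population vectors, named
#'   character vector population -> group, or `NULL` (per population)
#' @return list with matrices `a` (alt counts) and `n` (gene copies), both
#'   SNPs x groups, plus `snp_id`, `chromosome`, `position_bp`
#' @export
alleleCountTable <- function(panel, grouping = NULL) {
  grp <- .sampleGroups(panel, grouping)
  glev <- levels(grp)
  d <- dosages(panel)
  a <- n <- matrix(0L, nrow(d), length(glev),
                   dimnames = list(rownames(d), glev))
  for (gi in seq_along(glev)) {
    dg <- d[, grp == glev[gi], drop = FALSE]
    n[, gi] <- 2L * rowSums(!is.na(dg))
    a[, gi] <- rowSums(dg, na.rm = TRUE)
  }
  keep <- rowSums(n == 0L) == 0L
  map <- markerMap(panel)
  out <- list(a = a[keep, , drop = FALSE], n = n[keep, , drop = FALSE],
              snp_id = map$snp_id[keep], chromosome = map$chromosome[keep],
              position_bp = map$position_bp[keep])
  attr(out, "skipped") <- map$snp_id[!keep]
  out
}

#' Configuration for the Bayesian F_ST-outlier scan
#'
#' Chain lengths follow the published protocol: 10 pilot runs of 5,000
#' iterations tuning the proposal widths, then 100,000 recorded MCMC steps
#' after a burn-in of 50,000. `fast = TRUE` substitutes a short profile
#' (10 x 500 pilots, 5,000 burn-in, 10,000 sampling) for testing.
#'
#' @param n_pilot_runs,pilot_length pilot tuning schedule
#' @param burn_in,sampling_steps,thinning main chain schedule
#' @param prior_inclusion prior probability pi that a locus has a selection
#'   coefficient (default 0.5, i.e. prior odds 1 -- the value under which a
#'   Bayes factor of 10 corresponds to posterior probability 10/11 = 0.91)
#' @param alpha_prior_sd prior sd of the locus effect alpha ~ N(0, sd)
#' @param beta_prior_mean,beta_prior_sd prior of the group effect
#'   beta_j ~ N(mean, sd)
#' @param seed RNG seed (the scan is deterministic given the seed)
#' @param fast use the short test profile
#' @return list of class `OutlierScanConfig`
#' @export
outlierScanConfig <- function(n_pilot_runs = 10, pilot_length = 5000,
                              burn_in = 50000, sampling_steps = 100000,
                              thinning = 10, prior_inclusion = 0.5,
                              alpha_prior_sd = 1, beta_prior_mean = -2,
                              beta_prior_sd = 1.8, seed = 1, fast = FALSE) {
  if (fast) {
    pilot_length <- 500; burn_in <- 5000; sampling_steps <- 10000
    thinning <- 5
  }
  stopifnot(n_pilot_runs >= 1, pilot_length >= 1, burn_in >= 0,
            sampling_steps >= thinning, thinning >= 1,
            prior_inclusion > 0, prior_inclusion < 1,
            alpha_prior_sd > 0, beta_prior_sd > 0)
  structure(list(n_pilot_runs = n_pilot_runs, pilot_length = pilot_length,
                 burn_in = burn_in, sampling_steps = sampling_steps,
                 thinning = thinning, prior_inclusion = prior_inclusion,
                 alpha_prior_sd = alpha_prior_sd,
                 beta_prior_mean = beta_prior_mean,
                 beta_prior_sd = beta_prior_sd, seed = as.integer(seed)),
            class = "OutlierScanConfig")
}

#' Posterior model probability from a Bayes factor
#'
#' `PP = BF * prior_odds / (1 + BF * prior_odds)`. At prior odds 1 a Bayes
#' factor of 10 gives 10/11 (0.91 to two decimals) and a log10 Bayes factor
#' of 2 gives 100/101 (> 0.99).
#'
#' @param bf Bayes factor(s), >= 0
#' @param prior_odds prior odds of the selection model, default 1
#' @return posterior probability in \[0, 1)
#' @export
posteriorProbFromBf <- function(bf, prior_odds = 1) {
  if (any(bf < 0)) stop("negative Bayes factor")
  if (prior_odds <= 0) stop("prior odds must be positive")
  po <- bf * prior_odds
  po / (1 + po)
}

# beta-binomial log-likelihood matrix (loci x groups), marginalising the
# group-specific allele frequency analytically
.llMatrix <- function(a, n, p, alpha_eff, beta) {
  Fmat <- plogis(outer(alpha_eff, beta, "+"))
  Fmat <- pmin(pmax(Fmat, 1e-6), 1 - 1e-6)
  th <- 1 / Fmat - 1
  tp <- th * p; tq <- th * (1 - p)
  lbeta(a + tp, n - a + tq) - lbeta(tp, tq)
}

#' Bayesian F_ST-outlier scan by reversible-jump MCMC
#'
#' Hierarchical model for allele counts `a_ij ~ Binomial(n_ij, ptilde_ij)`
#' with `ptilde_ij ~ Beta(theta_ij p_i, theta_ij (1 - p_i))`,
#' `theta_ij = 1/F_ij - 1` and `logit(F_ij) = alpha_i + beta_j` (the
#' group-specific frequency is integrated out analytically, giving a
#' beta-binomial likelihood). The locus effect `alpha_i` is toggled by a
#' reversible-jump move with prior inclusion probability `pi`; inclusion
#' proposals draw `alpha` from its prior, so the acceptance ratio reduces to
#' the likelihood ratio times the prior odds. Ancestral frequencies `p_i`
#' have a Uniform(0,1) prior and reflective random-walk updates; `alpha_i`
#' and `beta_j` get random-walk Metropolis updates with proposal widths
#' tuned in pilot runs towards acceptance rates of 0.25-0.45.
#'
#' The posterior inclusion frequency `q_i` (clamped away from 0/1 by half a
#' sample unit) gives the Bayes factor
#' `BF_i = q_i / (1 - q_i) * (1 - pi) / pi`; evidence is classed `strong`
#' for log10 BF in (1, 2\] and `decisive` above 2.
#'
#' @param counts an [alleleCountTable()]
#' @param config an [outlierScanConfig()]
#' @return `data.frame` with `snp_id`, `chromosome`, `position_bp`, `q`,
#'   `bf`, `log10_bf`, `posterior_prob`, `evidence`, `alpha_mean` (posterior
#'   mean of the model-averaged locus effect); acceptance rates and tuned
#'   proposal widths in attributes
#' @export
runOutlierScan <- function(counts, config = outlierScanConfig()) {
  a <- counts$a; n <- counts$n
  L <- nrow(a); J <- ncol(a)
  if (is.null(L) || L < 1L) stop("need >= 1 SNP")
  if (J < 2L) stop("need >= 2 groups")
  set.seed(config$seed)
  pi0 <- config$prior_inclusion
  lodds <- log(pi0 / (1 - pi0))

  # state
  p <- (rowSums(a) + 1) / (rowSums(n) + 2)
  alpha <- rep(0, L); incl <- rep(FALSE, L)
  beta <- rep(config$beta_prior_mean, J)
  sp <- rep(0.1, L); sa <- rep(0.5, L); sb <- rep(0.3, J)

  ll <- .llMatrix(a, n, p, alpha * incl, beta)
  llrow <- rowSums(ll)

  acc <- list(p = 0, alpha = 0, beta = 0)
  cnt <- list(p = 0, alpha = 0, beta = 0)

  step <- function() {
    # p update (reflective RW, uniform prior)
    p1 <- p + rnorm(L, 0, sp)
    p1 <- ifelse(p1 < 0, -p1, p1); p1 <- ifelse(p1 > 1, 2 - p1, p1)
    p1 <- pmin(pmax(p1, 1e-9), 1 - 1e-9)
    ll1 <- .llMatrix(a, n, p1, alpha * incl, beta)
    l1 <- rowSums(ll1)
    ok <- log(runif(L)) < l1 - llrow
    p[ok] <<- p1[ok]; ll[ok, ] <<- ll1[ok, ]; llrow[ok] <<- l1[ok]
    acc$p <<- acc$p + sum(ok); cnt$p <<- cnt$p + L

    # alpha update for included loci
    ii <- which(incl)
    if (length(ii)) {
      a1 <- alpha; a1[ii] <- alpha[ii] + rnorm(length(ii), 0, sa[ii])
      ll1 <- .llMatrix(a[ii, , drop = FALSE], n[ii, , drop = FALSE],
                       p[ii], a1[ii], beta)
      l1 <- rowSums(ll1)
      dprior <- (alpha[ii]^2 - a1[ii]^2) / (2 * config$alpha_prior_sd^2)
      ok <- log(runif(length(ii))) < l1 - llrow[ii] + dprior
      ki <- ii[ok]
      alpha[ki] <<- a1[ki]; ll[ki, ] <<- ll1[ok, , drop = FALSE]
      llrow[ki] <<- l1[ok]
      acc$alpha <<- acc$alpha + sum(ok); cnt$alpha <<- cnt$alpha + length(ii)
    }

    # beta updates (one group at a time)
    for (jj in seq_len(J)) {
      b1 <- beta; b1[jj] <- beta[jj] + rnorm(1, 0, sb[jj])
      llj <- .llMatrix(a[, jj, drop = FALSE], n[, jj, drop = FALSE],
                       p, alpha * incl, b1[jj])
      dl <- sum(llj) - sum(ll[, jj])
      dpr <- ((beta[jj] - config$beta_prior_mean)^2 -
                (b1[jj] - config$beta_prior_mean)^2) /
        (2 * config$beta_prior_sd^2)
      if (log(runif(1)) < dl + dpr) {
        beta <<- b1; ll[, jj] <<- llj
        llrow <<- rowSums(ll)
        acc$beta <<- acc$beta + 1
      }
      cnt$beta <<- cnt$beta + 1
    }

    # reversible-jump toggle, proposing alpha from its prior
    aprop <- ifelse(incl, 0, rnorm(L, 0, config$alpha_prior_sd))
    eff1 <- ifelse(incl, 0, aprop)        # proposed alpha contribution
    ll1 <- .llMatrix(a, n, p, eff1, beta)
    l1 <- rowSums(ll1)
    ljump <- ifelse(incl, -lodds, lodds)  # prior odds for insert/delete
    ok <- log(runif(L)) < l1 - llrow + ljump
    ki <- which(ok)
    if (length(ki)) {
      newincl <- !incl[ki]
      alpha[ki] <<- ifelse(newincl, aprop[ki], 0)
      incl[ki] <<- newincl
      ll[ki, ] <<- ll1[ki, , drop = FALSE]
      llrow[ki] <<- l1[ki]
    }
  }

  # pilot runs: tune proposal widths to the target acceptance window
  for (pr in seq_len(config$n_pilot_runs)) {
    acc <- list(p = 0, alpha = 0, beta = 0)
    cnt <- list(p = 0, alpha = 0, beta = 0)
    for (it in seq_len(config$pilot_length)) step()
    tune <- function(s, rate) {
      rate[is.nan(rate)] <- 0.35
      pmin(pmax(s * exp(1.2 * (rate - 0.35)), 1e-4), 10)
    }
    sp <- tune(sp, rep(acc$p / max(cnt$p, 1), L))
    sa <- tune(sa, rep(acc$alpha / max(cnt$alpha, 1), L))
    sb <- tune(sb, rep(acc$beta / max(cnt$beta, 1), J))
  }
  rates <- c(p = acc$p / max(cnt$p, 1),
             alpha = if (cnt$alpha > 0) acc$alpha / cnt$alpha else NA,
             beta = acc$beta / max(cnt$beta, 1))
  bad <- !is.na(rates) & (rates < 0.05 | rates > 0.9)
  if (any(bad))
    stop("pilot tuning failed to reach a usable acceptance rate: ",
         paste(names(rates)[bad], round(rates[bad], 3), collapse = ", "))

  for (it in seq_len(config$burn_in)) step()

  m <- 0L
  qsum <- numeric(L); asum <- numeric(L)
  for (it in seq_len(config$sampling_steps)) {
    step()
    if (it %% config$thinning == 0L) {
      m <- m + 1L
      qsum <- qsum + incl
      asum <- asum + alpha * incl
    }
  }
  q <- pmin(pmax(qsum / m, 1 / (2 * m)), 1 - 1 / (2 * m))
  bf <- q / (1 - q) * (1 - pi0) / pi0
  lbf <- log10(bf)
  evidence <- cut(lbf, c(-Inf, 1, 2, Inf),
                  labels = c("none", "strong", "decisive"))
  out <- data.frame(snp_id = counts$snp_id, chromosome = counts$chromosome,
                    position_bp = counts$position_bp,
                    q = qsum / m, bf = bf, log10_bf = lbf,
                    posterior_prob = posteriorProbFromBf(bf),
                    evidence = as.character(evidence),
                    alpha_mean = asum / m,
                    stringsAsFactors = FALSE)
  attr(out, "acceptance") <- rates
  attr(out, "proposal_sd") <- list(p = sp, alpha = sa, beta = sb)
  attr(out, "config") <- config
  attr(out, "n_samples_kept") <- m
  out
}
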