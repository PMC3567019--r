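test_that("allele-count tables tally called gene copies per group", {
  d <- rbind(c(0L, 1L, 2L, 0L, 0L, 1L),
             c(NA, NA, NA, 0L, 1L, 2L),
             c(1L, 1L, 1L, 2L, 2L, NA))
  gp <- toyPanel(d, pops = setNames(rep(c("A", "B"), each = 3),
                                    sprintf("s%02d", 1:6)))
  ct <- alleleCountTable(gp, grouping = list(g1 = "A", g2 = "B"))
  # SNP 2 skipped: group g1 has zero called copies
  expect_identical(attr(ct, "skipped"), "snp002")
  expect_equal(unname(ct$a), rbind(c(3, 1), c(3, 4)))
  expect_equal(unname(ct$n), rbind(c(6, 6), c(6, 4)))
  expect_true(all(ct$a <= ct$n))
})

test_that("Bayes factor to posterior probability conversion is exact", {
  expect_equal(round(posteriorProbFromBf(10), 2), 0.91)
  expect_gte(posteriorProbFromBf(10^2), 0.99)
  expect_equal(posteriorProbFromBf(1), 0.5)
  expect_equal(posteriorProbFromBf(0), 0)
  expect_error(posteriorProbFromBf(-1), "negative")
  # exact monotonicity
  bf <- c(0, 0.5, 1, 3, 10, 100, 1e4)
  expect_true(all(diff(posteriorProbFromBf(bf)) > 0))
  # prior odds enter multiplicatively
  expect_equal(posteriorProbFromBf(10, prior_odds = 0.1), 0.5)
})

test_that("a planted divergent locus dominates the scan", {
  set.seed(42)
  L <- 120
  panc <- runif(L, 0.1, 0.9)
  pA <- simulatePopulationFrequencies(panc, 0.05)
  pB <- simulatePopulationFrequencies(panc, 0.05)
  pA[7] <- 0.98; pB[7] <- 0.02
  a <- cbind(rbinom(L, 60, pA), rbinom(L, 60, pB))
  counts <- countFixture(a, cbind(rep(60L, L), rep(60L, L)))
  scan <- runOutlierScan(counts, quickScanConfig(9))
  expect_equal(which.max(scan$log10_bf), 7L)
  expect_gt(scan$log10_bf[7], 2)
  expect_identical(scan$evidence[7], "decisive")
  expect_gt(scan$alpha_mean[7], 0)
  # few neutral loci reach "strong"
  expect_lte(mean(scan$log10_bf[-7] > 1), 0.05)
  # posterior probability column matches the conversion
  expect_equal(scan$posterior_prob, posteriorProbFromBf(scan$bf))
  # deterministic under a fixed seed
  scan2 <- runOutlierScan(counts, quickScanConfig(9))
  expect_identical(scan$q, scan2$q)
  expect_identical(scan$bf, scan2$bf)
})

test_that("allele relabelling leaves Bayes factors statistically unchanged", {
  set.seed(3)
  L <- 60
  panc <- runif(L, 0.2, 0.8)
  pA <- simulatePopulationFrequencies(panc, 0.05)
  pB <- simulatePopulationFrequencies(panc, 0.05)
  pA[11] <- 0.97; pB[11] <- 0.03
  a1 <- cbind(rbinom(L, 40, pA), rbinom(L, 40, pB))
  n <- cbind(rep(40L, L), rep(40L, L))
  scanA <- runOutlierScan(countFixture(a1, n),
                          quickScanConfig(5, burn = 1500, samp = 4000))
  scanB <- runOutlierScan(countFixture(n - a1, n),
                          quickScanConfig(6, burn = 1500, samp = 4000))
  # the flagged locus and its evidence class are orientation-free
  expect_equal(which.max(scanA$log10_bf), 11L)
  expect_equal(which.max(scanB$log10_bf), 11L)
  expect_identical(scanA$evidence[11], scanB$evidence[11])
  # inclusion frequencies agree within Monte-Carlo noise
  expect_lt(max(abs(scanA$q - scanB$q)), 0.35)
  expect_lt(mean(abs(scanA$q - scanB$q)), 0.1)
})

test_that("split-chain inclusion frequencies agree on a doubled run", {
  set.seed(8)
  L <- 80
  panc <- runif(L, 0.2, 0.8)
  a <- cbind(rbinom(L, 50, panc), rbinom(L, 50, panc))
  counts <- countFixture(a, cbind(rep(50L, L), rep(50L, L)))
  q1 <- runOutlierScan(counts, quickScanConfig(11, burn = 1500,
                                               samp = 4000))$q
  q2 <- runOutlierScan(counts, quickScanConfig(12, burn = 1500,
                                               samp = 8000))$q
  expect_lt(max(abs(q1 - q2)), 0.35)
  expect_lt(mean(abs(q1 - q2)), 0.1)
})

test_that("posterior alpha sign tracks the direction of divergence", {
  set.seed(21)
  L <- 80
  panc <- runif(L, 0.3, 0.7)
  pA <- simulatePopulationFrequencies(panc, 0.15)
  pB <- simulatePopulationFrequencies(panc, 0.15)
  # high-divergence plant and a balancing-style locus (identical counts)
  pA[5] <- 0.97; pB[5] <- 0.03
  a <- cbind(rbinom(L, 60, pA), rbinom(L, 60, pB))
  a[9, ] <- c(30L, 30L)
  counts <- countFixture(a, cbind(rep(60L, L), rep(60L, L)))
  scan <- runOutlierScan(counts, quickScanConfig(13))
  expect_gt(scan$alpha_mean[5], 0)
  expect_lte(scan$alpha_mean[9], 0)
})

test_that("configuration guards reject invalid settings", {
  expect_error(outlierScanConfig(prior_inclusion = 0), "prior_inclusion")
  expect_error(outlierScanConfig(sampling_steps = 1, thinning = 10))
  ct <- countFixture(cbind(1L, 1L), cbind(2L, 2L))
  expect_error(runOutlierScan(list(a = ct$a[, 1, drop = FALSE],
                                   n = ct$n[, 1, drop = FALSE],
                                   snp_id = "s", chromosome = "1",
                                   position_bp = 1), quickScanConfig(1)),
               ">= 2 groups")
})
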