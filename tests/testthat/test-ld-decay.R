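test_that("pairwise r2 matches hand Pearson computation and symmetries", {
  d <- rbind(c(0L, 1L, 2L, 0L, 2L),
             c(0L, 1L, 1L, 0L, 2L))
  gp <- toyPanel(d, positions = c(1000L, 2000L))
  rec <- pairwiseR2(gp, min_maf = 0, max_missing = 1)
  expect_equal(rec$r2, 9 / 11.2)
  expect_equal(rec$distance_bp, 1000)
  # identical vectors and complements both give r2 = 1
  d2 <- rbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L), c(2L, 1L, 0L, 2L))
  rec2 <- pairwiseR2(toyPanel(d2), min_maf = 0, max_missing = 1)
  expect_equal(rec2$r2, rep(1, 3))
  # flip invariance
  gpf <- toyPanel(rbind(d[1, ], 2L - d[2, ]), positions = c(1000L, 2000L))
  expect_equal(pairwiseR2(gpf, min_maf = 0, max_missing = 1)$r2, 9 / 11.2)
})

test_that("MAF/missingness screens and the distance cap are applied", {
  set.seed(30)
  base <- matrix(rbinom(10 * 40, 2, 0.5), 10)
  storage.mode(base) <- "integer"
  base[1, ] <- 0L                      # monomorphic -> MAF screen
  base[2, seq(1, 39, 2)] <- NA         # 50% missing -> missingness screen
  gp <- toyPanel(base, positions = seq(1e5, 1e6, length.out = 10) |>
                   as.integer())
  rec <- pairwiseR2(gp, max_distance_bp = 3e5)
  expect_false(any(c("snp001", "snp002") %in% c(rec$snp_a, rec$snp_b)))
  expect_true(all(rec$distance_bp <= 3e5))
  # X-linked SNPs never pair
  gpx <- toyPanel(base, chromosome = "X",
                  positions = seq(1e5, 1e6, length.out = 10) |> as.integer())
  expect_equal(nrow(pairwiseR2(gpx)), 0)
})

test_that("distance binning uses the 19 half-open classes", {
  rec <- data.frame(snp_a = "a", snp_b = "b", chromosome = "1",
                    distance_bp = c(150e3, 4e3, 1e6, 2e3, 21e3, 25e3),
                    r2 = c(0.5, 0.4, 0.1, 0.9, 0.2, 0.6))
  bins <- binLd(rec)
  expect_equal(nrow(bins), 19)
  expect_equal(sum(bins$n_pairs), nrow(rec))
  expect_equal(bins$n_pairs[bins$bin == "120-160"], 1)
  expect_equal(bins$n_pairs[bins$bin == "4-8"], 1)      # 4 kb: left-closed
  expect_equal(bins$n_pairs[bins$bin == "800-1000"], 1) # 1000 kb: closed top
  expect_equal(bins$mean_r2[bins$bin == "20-30"], 0.4)  # mean of .2, .6
  expect_error(binLd(data.frame(distance_bp = 2e6, r2 = 0.1)), "beyond")
})

test_that("the Sved fit recovers noiseless decay and inverts the extent", {
  dkb <- seq(1, 1000, by = 3)
  rec <- data.frame(distance_bp = dkb * 1000, r2 = 1 / (1 + 0.01 * dkb))
  fit <- fitSved(rec)
  expect_equal(fit$beta_per_kb, 0.01, tolerance = 1e-5)
  expect_lt(fit$rss, 1e-10)
  expect_equal(predictSved(fit, fit$extent_bp), 0.3, tolerance = 1e-12)
  # algebraic extent identities
  expect_equal(fitSved(rec, threshold = 0.5)$extent_kb, 100,
               tolerance = 1e-3)
  b <- 7 / 300
  rec2 <- data.frame(distance_bp = dkb * 1000, r2 = 1 / (1 + b * dkb))
  expect_equal(fitSved(rec2)$extent_kb, 100, tolerance = 1e-3)
  # binned input route
  fit_b <- fitSved(binLd(rec))
  expect_equal(fit_b$beta_per_kb, 0.01, tolerance = 0.05)
  # extent is monotone in beta and threshold
  expect_gt(fitSved(rec)$extent_kb, fitSved(rec2)$extent_kb)
  expect_gt(fitSved(rec, 0.2)$extent_kb, fitSved(rec, 0.4)$extent_kb)
  # no decay -> infinite extent, flagged
  flat <- data.frame(distance_bp = dkb * 1000, r2 = 1)
  expect_warning(fit0 <- fitSved(flat), "no detectable")
  expect_true(is.infinite(fit0$extent_kb))
})

test_that("pooling across populations shortens LD relative to within", {
  cfg <- simulationConfig(seed = 31, n_snps = 3000,
                          populations = data.frame(name = c("A", "B"),
                                                   n = c(40, 40),
                                                   fst = c(0.05, 0.05)),
                          n_chromosomes = 3, snp_spacing_bp = 20000,
                          spacing_jitter = 0.3, ld_beta_per_kb = 0.01,
                          missing_rate = 0, phase_mode = "independent",
                          p_anc_range = c(0.4, 0.6))
  pan <- simulateGenotypes(cfg)
  fitA <- fitSved(pairwiseR2(pan, population = "A"))
  fitB <- fitSved(pairwiseR2(pan, population = "B"))
  pool <- interpopulationLd(pan, n_per_pop = 40, seed = 3)
  expect_lt(pool$extent_kb, fitA$extent_kb)
  expect_lt(pool$extent_kb, fitB$extent_kb)
  # single population: pooling degenerates to the intrapopulation pipeline
  solo <- interpopulationLd(pan, populations = "A", n_per_pop = 40, seed = 5)
  expect_equal(solo$beta_per_kb, fitA$beta_per_kb)
  # deterministic subsample under a fixed seed
  s1 <- interpopulationLd(pan, n_per_pop = 10, seed = 7)
  s2 <- interpopulationLd(pan, n_per_pop = 10, seed = 7)
  expect_identical(attr(s1, "samples"), attr(s2, "samples"))
  expect_equal(s1$beta_per_kb, s2$beta_per_kb)
  # undersized population: take all, with a warning
  expect_warning(interpopulationLd(pan, populations = "A", n_per_pop = 100,
                                   seed = 1), "taking all")
})
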