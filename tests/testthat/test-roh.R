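test_that("clean planted tracts are called exactly; short ones are not", {
  # 700-kb plant on a 5-kb grid in an all-heterozygous background
  pan <- rohPanel(plants = list(c(2e6, 2.7e6)))
  seg <- detectRoh(pan, "ind")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, 2e6)
  expect_equal(seg$end_bp, 2.7e6)
  expect_equal(seg$length_bp, 700001)
  expect_equal(seg$n_het, 0)
  # 400-kb plant: below the 500-kb minimum
  expect_equal(nrow(detectRoh(rohPanel(plants = list(c(2e6, 2.4e6))), "ind")),
               0)
  # fully heterozygous chromosome: nothing
  expect_equal(nrow(detectRoh(rohPanel(), "ind")), 0)
  expect_error(detectRoh(pan, "nope"), "unknown sample")
})

test_that("planted-run sweep emits exactly the runs at or above 500 kb", {
  lengths_kb <- seq(350, 650, by = 50)
  gap <- 1.5e6
  start <- 2e6
  plants <- list()
  for (L in lengths_kb) {
    plants[[as.character(L)]] <- c(start, start + L * 1000)
    start <- start + L * 1000 + gap
  }
  pan <- rohPanel(n_snps = 6000, plants = plants)   # 30 Mb
  segs <- detectRoh(pan, "ind")
  emitted <- vapply(lengths_kb, function(L) {
    iv <- plants[[as.character(L)]]
    any(segs$start_bp <= iv[2] & segs$end_bp >= iv[1])
  }, logical(1))
  expect_identical(emitted, lengths_kb >= 500)
})

test_that("window allowances tolerate isolated het and missing calls", {
  pan <- rohPanel(plants = list(c(2e6, 4e6)))       # 2-Mb plant
  d <- dosages(pan)
  pos <- markerMap(pan)$position_bp
  inside <- which(pos >= 2e6 & pos <= 4e6)
  d[inside[150], 1] <- 1L                            # one het inside
  d[inside[c(60, 100, 260)], 1] <- NA                # sparse missing calls
  pan2 <- GenotypePanel(d, markerMap(pan), populations(pan))
  seg <- detectRoh(pan2, "ind")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_het, 1)
  expect_equal(seg$n_missing, 3)
  expect_gt(seg$length_bp, 1.9e6)
  # segments never overlap and output is deterministic
  expect_identical(seg, detectRoh(pan2, "ind"))
  pan3 <- rohPanel(plants = list(c(2e6, 2.6e6), c(5e6, 5.8e6)))
  segs <- detectRoh(pan3, "ind")
  expect_equal(nrow(segs), 2)
  o <- order(segs$start_bp)
  expect_true(all(segs$start_bp[o][-1] > segs$end_bp[o][-nrow(segs)]))
})

test_that("simulated planted ROH are recovered with >= 90% overlap", {
  cfg <- simulationConfig(seed = 19, n_snps = 4000,
                          populations = data.frame(name = "A", n = 5,
                                                   fst = 0.02),
                          n_chromosomes = 1, snp_spacing_bp = 10000,
                          spacing_jitter = 0.4, missing_rate = 0.01,
                          p_anc_range = c(0.3, 0.7),
                          planted_roh = data.frame(
                            population = "A", individual = 2,
                            chromosome = "1", start_bp = 1e7,
                            length_bp = 3e6))
  pan <- simulateGenotypes(cfg)
  segs <- detectRoh(pan, "A_02")
  cover <- sum(pmax(0, pmin(segs$end_bp, 1e7 + 3e6 - 1) -
                      pmax(segs$start_bp, 1e7) + 1))
  expect_gte(cover / 3e6, 0.9)
})

test_that("autozygosity summaries aggregate fractions and lengths", {
  segs <- data.frame(sample = c("a", "a", "b"), chromosome = "1",
                     start_bp = c(1, 4e6, 1), end_bp = c(2e6, 5e6, 6e5),
                     length_bp = c(2e6, 1e6, 6e5), n_snps = c(10, 5, 3),
                     n_het = 0, n_missing = 0)
  s <- rohSummary(segs, genome_span_bp = 1e8)
  expect_equal(s$per_sample$fraction[s$per_sample$sample == "a"], 0.03)
  expect_equal(s$per_sample$fraction[s$per_sample$sample == "b"], 0.006)
  expect_equal(sum(s$histogram$n_segments), 3)
  expect_error(rohSummary(segs, genome_span_bp = 0), "zero genome span")
  # empty segment set -> zero fractions
  s0 <- rohSummary(segs[0, ], genome_span_bp = 1e8)
  expect_equal(nrow(s0$per_sample), 0)
  # population with planted autozygosity exceeds one without
  pan <- rohPanel(n_snps = 3000, plants = list(c(2e6, 4e6)))
  pan2 <- rohPanel(n_snps = 3000)
  both <- cbind(dosages(pan), clean = dosages(pan2)[, 1])
  colnames(both) <- c("ind", "clean")
  gp <- GenotypePanel(both, markerMap(pan),
                      c(ind = "ROH", clean = "CLEAN"))
  summ <- rohSummary(detectRohAll(gp), panel = gp)
  fr <- setNames(summ$per_population$mean_fraction,
                 summ$per_population$population)
  expect_gt(fr["ROH"], fr["CLEAN"])
})
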