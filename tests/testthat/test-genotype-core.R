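test_that("PLINK text reading encodes dosages against the sorted allele pair", {
  dir <- withr::local_tempdir()
  writeLines(c("F1 s1 0 0 0 -9 A A A G",
               "F2 s2 0 0 0 -9 A G G G"),
             file.path(dir, "toy.ped"))
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200"),
             file.path(dir, "toy.map"))
  writeLines(c("s1\tP1", "s2\tP2"), file.path(dir, "toy.pop"))
  gp <- readPlinkPanel(file.path(dir, "toy"))
  # dosage counts the lexicographically greater allele (G)
  expect_identical(unname(dosages(gp)), matrix(c(0L, 1L, 1L, 2L), 2))
  expect_identical(markerMap(gp)$allele2, c("G", "G"))
  expect_identical(unname(populations(gp)), c("P1", "P2"))
})

test_that("malformed PLINK input is rejected with specific errors", {
  dir <- withr::local_tempdir()
  writeLines(character(), file.path(dir, "bad.map"))
  writeLines("F1 s1 0 0 0 -9 A A", file.path(dir, "bad.ped"))
  writeLines("s1\tP1", file.path(dir, "bad.pop"))
  expect_error(readPlinkPanel(file.path(dir, "bad")), "no markers")

  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200"),
             file.path(dir, "bad.map"))
  expect_error(readPlinkPanel(file.path(dir, "bad")), "dimension mismatch")

  writeLines(c("F1 s1 0 0 0 -9 A A A G",
               "F2 s1 0 0 0 -9 A A G G"), file.path(dir, "bad.ped"))
  expect_error(readPlinkPanel(file.path(dir, "bad")), "duplicate sample")

  writeLines(c("F1 s1 0 0 0 -9 A A A G",
               "F2 s2 0 0 0 -9 C A G T"), file.path(dir, "bad.ped"))
  writeLines(c("s1\tP1", "s2\tP2"), file.path(dir, "bad.pop"))
  expect_error(readPlinkPanel(file.path(dir, "bad")), "more than 2 alleles")
})

test_that("write/read round trip is lossless for dosages, map and labels", {
  set.seed(1)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 200, replace = TRUE), 20,
              dimnames = list(sprintf("snp%02d", 1:20),
                              sprintf("s%02d", 1:10)))
  gp <- toyPanel(d, chromosome = rep(c("1", "2"), each = 10),
                 positions = rep(seq(1e4, 1e5, by = 1e4), 2),
                 pops = setNames(rep(c("A", "B"), 5), sprintf("s%02d", 1:10)))
  prefix <- file.path(withr::local_tempdir(), "rt")
  writePlinkPanel(gp, prefix)
  gp2 <- readPlinkPanel(prefix)
  expect_identical(dosages(gp2), dosages(gp))
  expect_identical(markerMap(gp2)[, 1:3], markerMap(gp)[, 1:3])
  expect_identical(populations(gp2), populations(gp))
})

test_that("allele frequencies count called gene copies only", {
  gp <- toyPanel(rbind(c(0L, 1L, 2L, NA, 1L)))
  af <- alleleFreq(gp, snp = 1)
  expect_equal(af$freq, 4 / 8)          # {0,1,2,1} over 4 called
  expect_equal(af$n_called, 4)
  expect_equal(alleleFreq(toyPanel(rbind(c(2L, 2L))), snp = 1)$freq, 1)
  expect_error(alleleFreq(gp, snp = 1, samples = 4), "missing")
  # complement symmetry: frequency of allele1 = 1 - p
  p <- alleleFreq(gp, snp = 1)$freq
  flipped <- toyPanel(rbind(2L - c(0L, 1L, 2L, NA, 1L)))
  expect_equal(alleleFreq(flipped, snp = 1)$freq, 1 - p)
})

test_that("call-rate/MAF filter applies inclusive thresholds and reports reasons", {
  # 10 samples; rows: pass, low call rate (8/10), MAF exactly 0.05 (1/20),
  # MAF below (0/20 monomorphic), both failures
  d <- rbind(c(0L,0L,1L,1L,2L,2L,0L,1L,2L,0L),
             c(0L,0L,1L,1L,2L,2L,0L,1L,NA,NA),
             c(1L,rep(0L,9)),
             rep(0L,10),
             c(rep(0L,8),NA,NA))
  gp <- toyPanel(d)
  out <- filterSnps(gp, filterConfig(0.9, 0.05))
  rep <- filterReport(out)
  expect_identical(rep$keep, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(rep$reason[2], "call_rate")
  expect_identical(rep$reason[4], "maf")
  expect_identical(rep$reason[5], "call_rate+maf")
  expect_equal(nrow(out), 2)
  # idempotence
  again <- filterSnps(out, filterConfig(0.9, 0.05))
  expect_identical(dosages(again), dosages(out))
})

test_that("three of five hand-built SNPs survive both QC rules", {
  d <- rbind(c(0L,1L,2L,1L,0L,2L,1L,1L,0L,2L),   # pass
             c(rep(0L,9),1L),                     # maf 0.05 -> pass (inclusive)
             c(rep(0L,10)),                       # monomorphic -> drop
             c(0L,1L,2L,1L,0L,2L,1L,1L,NA,NA),   # call rate 0.8 -> drop
             c(2L,1L,0L,1L,2L,0L,1L,1L,2L,0L))   # pass
  out <- filterSnps(toyPanel(d), filterConfig(0.9, 0.05))
  expect_equal(nrow(out), 3)
})

test_that("mafSubset keeps only SNPs common in every super-group", {
  pops <- setNames(rep(c("A", "B"), each = 6), sprintf("s%02d", 1:12))
  set.seed(7)
  d <- matrix(sample(c(0L, 1L, 2L), 50 * 12, replace = TRUE,
                     prob = c(.5, .3, .2)), 50)
  gp <- toyPanel(d, pops = pops)
  sub <- mafSubset(gp, list(east = "A", west = "B"), min_maf = 0.2)
  # brute-force oracle: per-group MAF computed independently
  mafIn <- function(rows, g) {
    dd <- dosages(gp)[rows, populations(gp) == g, drop = FALSE]
    f <- rowSums(dd, na.rm = TRUE) / (2 * rowSums(!is.na(dd)))
    pmin(f, 1 - f)
  }
  expected <- rownames(gp)[mafIn(seq_len(50), "A") >= 0.2 &
                             mafIn(seq_len(50), "B") >= 0.2]
  expect_identical(rownames(sub), expected)
  expect_error(mafSubset(gp, list(x = "NOPE")), "unknown population")
  # one group, everything common -> identity
  all_sub <- mafSubset(gp, list(all = c("A", "B")), min_maf = 0)
  expect_identical(rownames(all_sub), rownames(gp))
})

test_that("panel validity catches bad dosages, labels and unsorted maps", {
  expect_error(toyPanel(rbind(c(0L, 3L))), "0, 1, 2")
  expect_error(GenotypePanel(matrix(0L, 1, 2,
                                    dimnames = list("a", c("x", "y"))),
                             data.frame(snp_id = "a", chromosome = "1",
                                        position_bp = 1L),
                             c(x = "P")), "no population")
  expect_error(toyPanel(matrix(0L, 2, 2), positions = c(5L, 5L)),
               "strictly increasing")
  # constructor sorts by position
  gp <- GenotypePanel(matrix(c(0L, 1L), 2, 1,
                             dimnames = list(c("b", "a"), "s1")),
                      data.frame(snp_id = c("b", "a"), chromosome = "1",
                                 position_bp = c(200L, 100L)),
                      c(s1 = "P"))
  expect_identical(rownames(gp), c("a", "b"))
})

test_that("autosomalPanel drops sex-labelled chromosomes", {
  gp <- toyPanel(matrix(0:1, 4, 2), chromosome = c("1", "2", "X", "Y"),
                 positions = rep(100L, 4))
  expect_identical(unique(markerMap(autosomalPanel(gp))$chromosome),
                   c("1", "2"))
})
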