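test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- simulationConfig(latitudes = c(50, 60), samplesPerLocation = 6,
                          nSites = 120, chromosomeLength = 20000,
                          inversionStart = 5001, inversionEnd = 15000,
                          seed = 5)
  s1 <- simulateInversionDataset(cfg)
  s2 <- simulateInversionDataset(cfg)
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  expect_identical(s1$truth$karyotype, s2$truth$karyotype)
  expect_identical(simulateClineCounts(1, -0.1, c(50, 60), 20, seed = 3),
                   simulateClineCounts(1, -0.1, c(50, 60), 20, seed = 3))
  m1 <- simulateMarkerRegion(seed = 9)
  m2 <- simulateMarkerRegion(seed = 9)
  expect_identical(m1$sSeq, m2$sSeq)
  expect_identical(m1$nSeq, m2$nSeq)
})

test_that("seed is mandatory and config invariants are enforced", {
  expect_error(simulationConfig(), "seed")
  expect_error(simulationConfig(seed = 1, fBg = 1), "fBg")
  expect_error(simulationConfig(seed = 1, inversionStart = 900,
                                inversionEnd = 2000000), "chromosome")
  # inversion with < 2 sites is a config error at generation time
  cfg <- simulationConfig(latitudes = c(50, 60), samplesPerLocation = 4,
                          nSites = 10, chromosomeLength = 1000000,
                          inversionStart = 1, inversionEnd = 10, seed = 2)
  expect_error(simulateInversionDataset(cfg), "fewer than 2 sites")
})

test_that("fully fixed inversion makes every heterokaryotype heterozygous", {
  cfg <- simulationConfig(latitudes = c(50, 60), samplesPerLocation = 15,
                          nSites = 200, chromosomeLength = 50000,
                          inversionStart = 10001, inversionEnd = 40000,
                          dInv = 1, muPoly = 0, seed = 21)
  sim <- simulateInversionDataset(cfg)
  kt <- sim$truth$karyotype
  inInv <- GenomicRanges::start(siteRanges(sim$genotypes)) >= 10001 &
    GenomicRanges::start(siteRanges(sim$genotypes)) <= 40000
  dHet <- dosages(sim$genotypes)[inInv, names(kt)[kt == "SN"], drop = FALSE]
  expect_true(all(dHet == 1L))
  # homokaryotypes are never heterozygous at inversion sites
  dHom <- dosages(sim$genotypes)[inInv, names(kt)[kt != "SN"], drop = FALSE]
  expect_true(all(dHom != 1L))
})

test_that("flat cline (beta1 = 0) yields a near-zero fitted slope", {
  tab <- simulateClineCounts(0, 0, seq(48, 68, by = 4), 500, seed = 13)
  fit <- fitBinomialCline(tab, "latitude")
  expect_lt(abs(clineSlope(fit)), 0.02)
  expect_gt(fit@lrtP, 0.01)
})

test_that("cline counts respect totals and HWE structure", {
  tab1 <- simulateClineCounts(0, 0, c(50, 55, 60), 1, seed = 1)
  expect_true(all(tab1$n_SS + tab1$n_SN + tab1$n_NN == 1))
  # pooled large simulation stays at Hardy-Weinberg (chi-square not
  # significant at alpha = 0.01)
  tab <- simulateClineCounts(0.4, 0, c(50, 55, 60, 65), 2000, seed = 31)
  pooled <- c(sum(tab$n_SS), sum(tab$n_SN), sum(tab$n_NN))
  hw <- hweTest(pooled)
  expect_gt(hw$p.value, 0.01)
})

test_that("marker region plants the diagnostic site as specified", {
  mr <- simulateMarkerRegion(seed = 4)
  expect_equal(nchar(mr$sAmplicon), 667)
  expect_equal(nchar(mr$nAmplicon), 667)
  # S arrangement carries the recognition site across the SNP, N does not
  expect_equal(length(inSilicoDigest(mr$sAmplicon, ecoRI())), 2)
  expect_equal(inSilicoDigest(mr$nAmplicon, ecoRI()), 667L)
  # SNP base differs, site spans it
  sC <- strsplit(mr$sSeq, "")[[1]]
  nC <- strsplit(mr$nSeq, "")[[1]]
  expect_true(sC[mr$truth$snpPos] != nC[mr$truth$snpPos])
  expect_identical(paste(sC[(mr$truth$snpPos - 3):(mr$truth$snpPos + 2)],
                         collapse = ""), "GAATTC")
  # impossible placements are config errors
  expect_error(simulateMarkerRegion(regionLength = 10, seed = 1), "config")
  expect_error(simulateMarkerRegion(regionLength = 500, seed = 1), "config")
})

test_that("viability simulation follows the clipped quadratic", {
  flat <- simulateViabilityExperiment(a = 0, b = 0, c = 0.5,
                                      temperatures = c(15, 20, 25, 30),
                                      eggs = 500, replicates = 6, seed = 8)
  expect_equal(nrow(flat), 24)
  byT <- tapply(flat$adults / flat$eggs, flat$temperature, mean)
  expect_true(all(abs(byT - 0.5) < 0.05))
  # clipping: far outside the zero-crossings nothing survives
  cold <- simulateViabilityExperiment(temperatures = 0, eggs = 100,
                                      replicates = 3, seed = 9)
  expect_true(all(cold$adults == 0))
})

test_that("TPC refit on a large simulated experiment recovers the truth", {
  # tolerance bands derived from a pilot run of the sampling variance at
  # this design (5 temperatures x 6 replicates x 2000 eggs)
  truth <- c(a = -0.00215, b = 0.086, c = -0.6)
  tab <- simulateViabilityExperiment(a = truth["a"], b = truth["b"],
                                     c = truth["c"], eggs = 2000,
                                     replicates = 6, seed = 77)
  fit <- fitQuadraticTpc(tab)
  expect_lt(abs(fit@coefficients["a"] - truth["a"]), 2e-4)
  expect_lt(abs(fit@coefficients["b"] - truth["b"]), 8e-3)
  expect_lt(abs(fit@coefficients["c"] - truth["c"]), 8e-2)
})

test_that("arrangement FST inside the inversion dwarfs background FST", {
  cfg <- simulationConfig(seed = 55)
  sim <- simulateInversionDataset(cfg)
  kt <- sim$truth$karyotype
  ss <- names(kt)[kt == "SS"]
  nn <- names(kt)[kt == "NN"]
  inside <- windowedFst(sim$genotypes, ss, nn, region = sim$truth$inversion)
  info <- sampleInfo(sim$genotypes)
  am <- rownames(info)[info$continent == "America"]
  eu <- rownames(info)[info$continent == "Europe"]
  outside <- windowedFst(sim$genotypes, am, eu,
                         region = GenomicRanges::GRanges(
                           "chr4", IRanges::IRanges(1, 299000)))
  expect_gt(globalFst(inside), 3 * globalFst(outside))
  expect_lt(abs(globalFst(outside) - 0.13), 0.05)
})
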