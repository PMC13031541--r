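test_that("noiseless quadratic data are recovered to machine precision", {
  # viability = -0.01 T^2 + 0.4 T - 3.74 takes exact hundredth values
  # 0.01, 0.26, 0.01 at 15/20/25 degrees, so adults/eggs is noiseless
  a <- -0.01; b <- 0.4; cc <- -3.74
  tab <- data.frame(temperature = rep(c(15, 20, 25), each = 2), eggs = 100L)
  v <- a * tab$temperature^2 + b * tab$temperature + cc
  tab$adults <- as.integer(round(v * 100))
  expect_true(all(abs(tab$adults / 100 - v) < 1e-12))
  fit <- fitQuadraticTpc(tab)
  expect_equal(unname(fit@coefficients), c(a, b, cc), tolerance = 1e-10)
  tr <- thermalTraits(fit)
  expect_equal(unname(tr["Topt"]), 20, tolerance = 1e-8)
  expect_equal(unname(tr["rmax"]), 0.26, tolerance = 1e-8)
})

test_that("closed-form traits agree with a fine-grid numerical search", {
  fits <- list(c(a = -0.01, b = 0.4, c = -3.74),
               c(a = -0.00215, b = 0.086, c = -0.6),
               c(a = -0.004, b = 0.2, c = -2.3))
  for (co in fits) {
    tr <- KaryoCline:::.tpcTraits(co["a"], co["b"], co["c"])
    grid <- seq(-20, 60, by = 0.001)
    v <- co["a"] * grid^2 + co["b"] * grid + co["c"]
    expect_equal(unname(tr["Topt"]), grid[which.max(v)], tolerance = 2e-3)
    expect_equal(unname(tr["rmax"]), max(v), tolerance = 1e-6)
    pos <- grid[v > 0]
    if (length(pos)) {
      expect_equal(unname(tr["CTmin"]), min(pos), tolerance = 2e-3)
      expect_equal(unname(tr["CTmax"]), max(pos), tolerance = 2e-3)
      expect_equal(unname(tr["tolerance"]), max(pos) - min(pos),
                   tolerance = 4e-3)
    }
    wide <- grid[v >= 0.8 * max(v)]
    expect_equal(unname(tr["breadth"]), max(wide) - min(wide),
                 tolerance = 4e-3)
  }
})

test_that("traits shift correctly under temperature translation", {
  tab <- simulateViabilityExperiment(eggs = 400, replicates = 6, seed = 61)
  fit <- fitQuadraticTpc(tab)
  shifted <- tab
  shifted$temperature <- shifted$temperature + 7
  fitS <- fitQuadraticTpc(shifted)
  trA <- thermalTraits(fit)
  trB <- thermalTraits(fitS)
  for (nm in c("Topt", "CTmin", "CTmax"))
    expect_equal(unname(trB[nm] - trA[nm]), 7, tolerance = 1e-6)
  for (nm in c("rmax", "tolerance", "breadth"))
    expect_equal(unname(trB[nm]), unname(trA[nm]), tolerance = 1e-6)
})

test_that("non-concave fits flag traits as undefined", {
  tab <- data.frame(temperature = c(10, 20, 30, 40), eggs = 100L,
                    adults = c(10L, 20L, 40L, 80L))
  fit <- fitQuadraticTpc(tab)
  expect_true(fit@coefficients["a"] >= 0)
  expect_true(all(is.na(thermalTraits(fit))))
  expect_error(fitQuadraticTpc(tab[tab$temperature < 25, ]),
               "3 distinct temperatures")
})

test_that("low-viability temperatures are excluded by the filter", {
  tab <- simulateViabilityExperiment(eggs = 300, replicates = 6, seed = 71)
  # the default curve leaves 10 degrees below 5% viability
  dv <- viabilityDevianceAnalysis(rbind(
    transform(tab, karyotype = "SS", continent = "America"),
    transform(simulateViabilityExperiment(eggs = 300, replicates = 6,
                                          seed = 72, karyotype = "NN"),
              continent = "America")),
    factors = c("karyotype", "temperature"), minMeanViability = 0.05)
  keptTemps <- levels(dv$model$model$temperature)
  expect_false("10" %in% keptTemps)
})

test_that("type-II deviance analysis matches car::Anova", {
  skip_if_not_installed("car")
  vt <- crossedViabilityTable(seed = 301)
  dv <- viabilityDevianceAnalysis(vt, minMeanViability = 0)
  ca <- car::Anova(dv$model, type = 2, test.statistic = "LR")
  caTerms <- rownames(ca)
  for (i in seq_len(nrow(dv$anova))) {
    j <- match(dv$anova$term[i], caTerms)
    expect_false(is.na(j))
    expect_equal(dv$anova$chisq[i], ca$`LR Chisq`[j], tolerance = 1e-8)
    expect_equal(dv$anova$df[i], ca$Df[j])
  }
})

test_that("opposite-sign karyotype-by-continent effect is detected", {
  hits <- vapply(1:8, function(s) {
    vt <- crossedViabilityTable(seed = 400 + 10 * s)
    dv <- viabilityDevianceAnalysis(vt, minMeanViability = 0)
    p <- dv$anova$p.value[dv$anova$term == "karyotype:continent"]
    p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("no karyotype effect stays near the nominal false-positive rate", {
  hits <- vapply(1:30, function(s) {
    a <- simulateViabilityExperiment(seed = 600 + 2 * s, karyotype = "SS")
    b <- simulateViabilityExperiment(seed = 601 + 2 * s, karyotype = "NN")
    dv <- viabilityDevianceAnalysis(rbind(a, b),
                                    factors = c("karyotype", "temperature"),
                                    minMeanViability = 0)
    dv$anova$p.value[dv$anova$term == "karyotype"] < 0.05
  }, logical(1))
  # 95% envelope for 30 draws at p = 0.05
  expect_lte(mean(hits), 0.17)
})

test_that("single-factor deviance analysis nests the cline LRT", {
  # binary-predictor viability analysis reduces to the same LRT as the
  # aggregated binomial cline machinery on the equivalent table
  a <- simulateViabilityExperiment(temperatures = 20, eggs = 200,
                                   replicates = 6, seed = 81,
                                   karyotype = "SS")
  b <- simulateViabilityExperiment(a = -0.0029, b = 0.116, c = -0.81,
                                   temperatures = 20, eggs = 200,
                                   replicates = 6, seed = 82,
                                   karyotype = "NN")
  vt <- rbind(a, b)
  dv <- viabilityDevianceAnalysis(vt, factors = "karyotype",
                                  minMeanViability = 0)
  # same LRT by hand with glm
  m0 <- glm(cbind(adults, eggs - adults) ~ 1, binomial, data = vt)
  m1 <- glm(cbind(adults, eggs - adults) ~ karyotype, binomial, data = vt)
  expect_equal(dv$anova$chisq[1], deviance(m0) - deviance(m1),
               tolerance = 1e-10)
})
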