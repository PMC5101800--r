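test_that("spearmanTest handles monotone, anti-monotone and constant input", {
  expect_equal(rho(spearmanTest(1:3, c(10, 20, 30))), 1)
  expect_equal(rho(spearmanTest(1:3, c(3, 2, 1))), -1)
  expect_warning(r <- spearmanTest(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rho(r)))
  expect_error(spearmanTest(1:2, 1:2), "at least 3")
  # monotone-transform invariance
  set.seed(41)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(rho(spearmanTest(x, y)), rho(spearmanTest(exp(x), y^3 + y)),
               tolerance = 1e-12)
})

test_that("spearmanTest matches the rank-then-Pearson oracle with ties", {
  set.seed(43)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    x <- sample(1:10, n, replace = TRUE)   # heavy ties
    y <- rnorm(n) + x / 3
    got <- spearmanTest(x, y)
    want <- bfSpearman(x, y)
    expect_equal(rho(got), want$rho, tolerance = 1e-12)
    expect_equal(pValue(got), want$p, tolerance = 1e-12)
  }
  # pairwise-complete deletion
  x <- c(1, 2, NA, 4, 5); y <- c(2, NA, 3, 8, 10)
  expect_equal(nObs(spearmanTest(x, y)), 3L)
})

test_that("CSC/CPC pick out codons tracking the kinetic value", {
  # frequency of AAA strictly increases with half-life across genes
  genes <- sprintf("g%d", 1:8)
  freq <- matrix(1 / 61, nrow = 8, ncol = 61,
                 dimnames = list(genes, senseCodons()))
  freq[, "AAA"] <- seq(0.01, 0.08, by = 0.01)
  hl <- setNames(seq(2, 100, length.out = 8), genes)
  csc <- suppressWarnings(computeCsc(freq, hl))
  expect_s4_class(csc, "CodonCorrelationVector")
  expect_equal(unname(codonValues(csc)["AAA"]), 1)
  # every other codon is constant -> NA with a warning
  expect_warning(computeCsc(freq, hl), "constant")
  expect_equal(nObs(csc), 8L)

  cpc <- suppressWarnings(computeCpc(freq, hl))
  expect_identical(cpc@kind, "CPC")
  expect_equal(codonValues(cpc), codonValues(csc))

  # rank invariance: monotone transform of the kinetic values
  csc2 <- suppressWarnings(computeCsc(freq, hl^3 + 5))
  expect_equal(codonValues(csc2), codonValues(csc))
})

test_that("CSC separates optimal from non-optimal codons in a coupled genome", {
  sim <- simulateStudy(simulationConfig(nGenes = 500, seed = 47))
  freq <- codonFrequencyMatrix(sim$sequences)
  hl <- setNames(sim$kinetics$half_life_min, sim$kinetics$gene_id)
  csc <- computeCsc(freq, hl)
  v <- codonValues(csc)
  opt <- isOptimal(sim$classification)
  expect_gt(mean(v[opt], na.rm = TRUE), mean(v[!opt], na.rm = TRUE))
})

test_that("sign partition is deterministic about zeros and missing values", {
  part <- signPartition(c(AAA = 0.2, AAC = -0.1, AAG = 0))
  expect_equal(part$positive, "AAA")
  expect_setequal(part$nonPositive, c("AAC", "AAG"))
  expect_warning(
    part2 <- signPartition(c(AAA = 0.2, AAC = NA, AAG = -1)), "dropped")
  expect_equal(part2$dropped, "AAC")
  allPos <- setNames(rep(0.5, 61), senseCodons())
  expect_length(signPartition(allPos)$positive, 61)
})

test_that("chi-square sign test reproduces published contingency statistics", {
  # cells (optimal+, nonopt+, optimal-, nonopt-) = (22, 4, 6, 29)
  s <- contingencySummary(totalPos = 26, observed = 22, nOpt = 28)
  expect_equal(round(s@expected, 1), 11.9)
  expect_equal(signif(pValue(s), 2), 6.7e-07)
  s2 <- contingencySummary(totalPos = 22, observed = 16, nOpt = 24)
  expect_equal(signif(pValue(s2), 2), 1.9e-04)
  # uncorrected statistic equals the classical sum((O-E)^2/E), ~27.4
  su <- contingencySummary(26, 22, 28, correct = FALSE)
  want <- bfChisq2x2(22, 6, 4, 29, correct = FALSE)
  expect_equal(su@chi2, want$chi2, tolerance = 1e-9)
  expect_equal(round(su@chi2, 2), 27.35)
  expect_equal(signif(pValue(su), 2), 1.7e-07)
  # near-null table: observed close to expected
  s0 <- contingencySummary(totalPos = 30, observed = 15, nOpt = 30,
                           nCodons = 60)
  expect_lt(s0@chi2, 0.1)
  expect_gt(pValue(s0), 0.9)
  expect_error(contingencySummary(0, 0, 28), "zero marginal")
})

test_that("chisqSignTest cross-classifies a correlation vector", {
  v <- setNames(c(rep(0.5, 20), rep(-0.5, 41)), senseCodons())
  cls <- optimalityClassification(senseCodons()[1:24], "cTE")
  s <- chisqSignTest(v, cls)
  expect_equal(s@totalPos, 20L)
  expect_equal(s@observed, 20L)    # all positives are optimal here
  expect_equal(s@nCodons, 61L)
  cells <- contingencyCells(s)
  expect_equal(sum(cells), 61)
  expect_equal(rowSums(cells), c(yes = 24, no = 37))
  # dropped codons shrink nCodons
  v[1] <- NA
  s2 <- suppressWarnings(chisqSignTest(v, cls))
  expect_equal(s2@nCodons, 60L)
})

test_that("Yates correction matches the closed-form oracle on random tables", {
  set.seed(53)
  for (i in 1:300) {
    repeat {
      cells <- as.vector(stats::rmultinom(1, 61, runif(4, 0.05, 1)))
      if (all(rowSums(matrix(cells, 2)) > 0) &&
          all(colSums(matrix(cells, 2)) > 0)) break
    }
    a <- cells[1]; c_ <- cells[2]; b <- cells[3]; d <- cells[4]
    s <- contingencySummary(totalPos = a + c_, observed = a,
                            nOpt = a + b, nCodons = 61)
    want <- bfChisq2x2(a, b, c_, d, correct = TRUE)
    expect_equal(s@chi2, want$chi2, tolerance = 1e-9)
    expect_equal(pValue(s), want$p, tolerance = 1e-9)
  }
})

test_that("contingency summaries reconstruct their marginals", {
  set.seed(59)
  for (i in 1:50) {
    nOpt <- sample(5:56, 1)
    totalPos <- sample(5:56, 1)
    observed <- sample(max(0, nOpt + totalPos - 61):min(nOpt, totalPos), 1)
    s <- tryCatch(contingencySummary(totalPos, observed, nOpt),
                  error = function(e) NULL)
    if (is.null(s)) next   # zero marginal draws are legitimately rejected
    cells <- contingencyCells(s)
    expect_equal(sum(cells), 61)
    expect_equal(unname(rowSums(cells)[1]), nOpt)
    expect_equal(unname(colSums(cells)[1]), totalPos)
    expect_equal(s@expected, nOpt * totalPos / 61, tolerance = 1e-12)
  }
})

test_that("partial Spearman matches identities and the residual oracle", {
  set.seed(61)
  z <- rnorm(40)
  x <- z + rnorm(40)
  expect_equal(rho(partialSpearman(x, x, z)), 1)
  expect_error(partialSpearman(x, rnorm(40), rep(1, 40)), "constant")
  expect_error(partialSpearman(1:10, rnorm(10), 1:10), "perfectly")

  for (i in 1:40) {
    n <- sample(6:30, 1)
    z <- rnorm(n); x <- z / 2 + rnorm(n); y <- z / 2 + rnorm(n)
    got <- partialSpearman(x, y, z)
    want <- bfPartialSpearman(x, y, z)
    expect_equal(rho(got), want$rho, tolerance = 1e-9)
    expect_equal(pValue(got), want$p, tolerance = 1e-9)
  }

  # independent z: partial close to the plain Spearman
  set.seed(67)
  x <- rnorm(200); y <- x / 2 + rnorm(200); z <- rnorm(200)
  expect_lt(abs(rho(partialSpearman(x, y, z)) - rho(spearmanTest(x, y))),
            0.05)
})

test_that("frameshifts destroy the CSC-optimality correlation", {
  sim <- simulateStudy(simulationConfig(nGenes = 300, seed = 71))
  hl <- setNames(sim$kinetics$half_life_min, sim$kinetics$gene_id)
  fs <- frameshiftControl(sim$sequences, hl, sim$weights)
  expect_equal(fs$shift, 0:2)
  expect_gt(fs$rho[1], 0.4)
  expect_lt(fs$p[1], 1e-3)
  expect_lt(abs(fs$rho[2]), fs$rho[1])
  expect_lt(abs(fs$rho[3]), fs$rho[1])
})
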