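test_that("identical configurations reproduce byte-identical studies", {
  cfg <- simulationConfig(nGenes = 40, seed = 11)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$kinetics, b$kinetics)
  expect_identical(a$motifs, b$motifs)
  expect_identical(adaptiveness(a$weights), adaptiveness(b$weights))
  # a different seed changes the draw
  c_ <- simulateStudy(simulationConfig(nGenes = 40, seed = 12))
  expect_false(identical(as.character(a$sequences),
                         as.character(c_$sequences)))
})

test_that("simulated weights split codons into the configured classes", {
  set.seed(1)
  wcls <- simulateWeights(simulationConfig(nOpt = 28))
  expect_equal(sum(isOptimal(wcls$classification)), 28)
  expect_equal(max(adaptiveness(wcls$weights)), 1)
  expect_true(all(adaptiveness(wcls$weights) > 0))
  # optimal codons are exactly the top-weight codons
  w <- adaptiveness(wcls$weights)
  expect_equal(sort(names(which(isOptimal(wcls$classification)))),
               sort(names(sort(w, decreasing = TRUE)[1:28])))
})

test_that("emitted CDSs are strict-valid and lengths match the configuration", {
  set.seed(2)
  cfg <- simulationConfig(nGenes = 1000, geneLengthRange = c(100, 500),
                          seed = 2)
  sim <- simulateStudy(cfg)
  w <- Biostrings::width(sim$sequences)
  expect_true(all(w %% 3 == 0))
  expect_true(all(w >= (100 + 2) * 3 & w <= (500 + 2) * 3))
  # mean body length tracks the configured mean (3 standard errors:
  # sd of Uniform(100, 500) is ~115.5, so se of the mean at n = 1000
  # is ~3.7 codons)
  expect_lt(abs(mean(sim$truth$length_codons) - 300), 11)
  # no internal stops: strict parsing accepts the whole genome
  f <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(sim$sequences, f)
  expect_silent(parsed <- parseCds(f, strict = TRUE))
  expect_length(parsed, 1000)
})

test_that("high-optimality genes carry higher tAI when the tilt is on", {
  sim <- simulateStudy(simulationConfig(nGenes = 300, seed = 6))
  q <- quantile(sim$truth$u, c(0.1, 0.9))
  expect_gt(mean(sim$truth$tai_g[sim$truth$u > q[2]]),
            mean(sim$truth$tai_g[sim$truth$u < q[1]]))
  # tilt off: codon usage decouples from the latent score
  sim0 <- simulateStudy(simulationConfig(nGenes = 300, tiltBeta = 0,
                                         seed = 5))
  r <- spearmanTest(sim0$truth$tai_g, sim0$truth$u)
  expect_gt(pValue(r), 0.05)
})

test_that("kinetic records are exactly steady-state consistent", {
  for (via in c("direct", "abundance")) {
    sim <- simulateStudy(simulationConfig(nGenes = 100, couplingVia = via,
                                          seed = 13))
    k <- sim$kinetics
    lambda <- log(2) / k$half_life_min
    expect_equal(k$synthesis_rate,
                 k$abundance * (sim$config$alpha + lambda),
                 tolerance = 1e-9)
  }
  # zero noise and zero coupling collapse half-lives to a constant
  flat <- simulateStudy(simulationConfig(nGenes = 20, couplingBeta = 0,
                                         synthesisCoupling = 0,
                                         noiseSd = 0, seed = 17))
  expect_equal(var(flat$kinetics$half_life_min), 0)
})

test_that("the abundance-mediated regime attenuates the partial correlation", {
  run <- function(via) {
    sim <- simulateStudy(simulationConfig(nGenes = 400, couplingVia = via,
                                          seed = 19))
    tai <- setNames(sim$truth$tai_g, sim$truth$gene_id)
    hl <- setNames(sim$kinetics$half_life_min, sim$kinetics$gene_id)
    m <- setNames(sim$kinetics$abundance, sim$kinetics$gene_id)
    c(marginal = rho(spearmanTest(tai, hl)),
      partial = rho(partialSpearman(tai, hl, m)))
  }
  direct <- run("direct")
  mediated <- run("abundance")
  # both regimes show the pairwise association
  expect_gt(direct["marginal"], 0.1)
  expect_gt(mediated["marginal"], 0.1)
  # controlling for abundance collapses it only in the mediated regime
  expect_lt(mediated["partial"], mediated["marginal"] / 2)
  expect_lt(abs(mediated["partial"]), abs(direct["partial"]) +
              (direct["marginal"] - mediated["partial"]))
})

test_that("motif annotations are integer-counted and optimality-coupled", {
  sim <- simulateStudy(simulationConfig(nGenes = 500, seed = 23))
  expect_true(all(sim$motifs$count >= 1))
  expect_true(all(sim$motifs$count == round(sim$motifs$count)))
  expect_true(all(sim$motifs$location %in% c("promoter", "5UTR", "3UTR")))
  # stabilizing motifs land preferentially on high-u genes
  u <- setNames(sim$truth$u, sim$truth$gene_id)
  stab <- sim$motifs$gene_id[grepl("^stab", sim$motifs$motif_id)]
  destab <- sim$motifs$gene_id[grepl("^destab", sim$motifs$motif_id)]
  expect_gt(mean(u[unique(stab)]), mean(u))
  expect_lt(abs(mean(u[unique(destab)]) - mean(u)), 0.08)
})

test_that("synthetic studies round-trip through the on-disk formats", {
  sim <- simulateStudy(simulationConfig(nGenes = 25, seed = 29))
  dir <- tempfile()
  paths <- writeSyntheticStudy(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- parseCds(paths["fasta"], strict = TRUE)
  expect_identical(as.character(back), as.character(sim$sequences))
  kin <- readKineticTable(paths["kinetics"])
  expect_equal(kin$half_life_min, sim$kinetics$half_life_min,
               tolerance = 1e-12)
  w <- readWeights(paths["weights"])
  expect_equal(adaptiveness(w), adaptiveness(sim$weights),
               tolerance = 1e-12)
  cls <- readClassifications(paths["classification"])
  expect_equal(isOptimal(cls[[1]]), isOptimal(sim$classification))
  ann <- readMotifTable(paths["motifs"])
  expect_equal(nrow(ann), nrow(sim$motifs))
})
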