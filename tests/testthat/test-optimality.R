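test_that("relativeAdaptiveness matches the exhaustive pairing oracle", {
  set.seed(11)
  anticodons <- unique(replicate(200, paste(
    sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")))
  for (rep in 1:8) {
    picked <- unique(c("AAA", sample(anticodons, sample(8:25, 1))))
    tgcn <- setNames(sample(0:12, length(picked), replace = TRUE), picked)
    tgcn["AAA"] <- max(1L, tgcn["AAA"])   # guarantees a decodable codon
    for (dom in c("eukaryote", "prokaryote")) {
      got <- relativeAdaptiveness(tgcn, domain = dom)
      expect_equal(adaptiveness(got),
                   bfTaiWeights(tgcn, domain = dom)[senseCodons()],
                   tolerance = 1e-12)
    }
  }
})

test_that("Watson-Crick-only decoding by the top tRNA gives weight 1", {
  # TTT is decoded by AAA (WC) and by the GAA anticodon via G:U;
  # give AAA the single highest copy number and nothing to GAA
  tgcn <- c(AAA = 10, CAT = 3, AGC = 2)
  w <- adaptiveness(relativeAdaptiveness(tgcn))
  expect_equal(unname(w["TTT"]), 1)
})

test_that("undecoded codons receive the geometric mean of nonzero weights", {
  tgcn <- c(AAA = 8, CAT = 4, TAT = 1)
  w <- adaptiveness(relativeAdaptiveness(tgcn))
  replaced <- setdiff(senseCodons(),
                      codonAnticodonPairs()$codon[
                        codonAnticodonPairs()$anticodon %in% names(tgcn)])
  expect_gt(length(replaced), 0)
  expect_equal(unique(round(unname(w[replaced]), 12)),
               round(exp(mean(log(unname(w[setdiff(senseCodons(),
                                                   replaced)])))), 12))
})

test_that("adaptiveness weights are invariant to tGCN rescaling", {
  tgcn <- c(AAA = 6, GAA = 3, CAT = 2, TAT = 1, AGC = 5)
  w1 <- adaptiveness(relativeAdaptiveness(tgcn))
  w2 <- adaptiveness(relativeAdaptiveness(tgcn * 7))
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("taiG is the geometric mean of weights with multiplicity", {
  w <- setNames(rep(0.5, 61), senseCodons())
  w["AAA"] <- 1
  wgt <- new("AdaptivenessWeights", weights = w, provenance = "computed")
  # single codon type: taiG equals that codon's weight
  p <- codonProfile(strrep("GCT", 10), geneId = "g")
  expect_equal(taiG(p, wgt), 0.5)
  # two codons 0.25 and 1 -> sqrt(0.25) = 0.5
  w2 <- w; w2["GCT"] <- 0.25; w2["AAA"] <- 1
  wgt2 <- new("AdaptivenessWeights", weights = w2, provenance = "computed")
  p2 <- codonProfile("GCTAAA", geneId = "g")
  expect_equal(taiG(p2, wgt2), 0.5)
})

test_that("taiG matches the product-form oracle on random genes", {
  set.seed(13)
  raw <- runif(61, 0.05, 1)
  w <- setNames(raw / max(raw), senseCodons())
  wgt <- new("AdaptivenessWeights", weights = w, provenance = "computed")
  for (i in 1:10) {
    codons <- sample(senseCodons(), 300, replace = TRUE)
    p <- codonProfile(paste(codons, collapse = ""), geneId = "g")
    expect_equal(taiG(p, wgt), bfTaiG(codons, w), tolerance = 1e-12)
  }
  # matrix method agrees with the profile method
  seqs <- Biostrings::DNAStringSet(
    c(a = paste(sample(senseCodons(), 50, replace = TRUE), collapse = ""),
      b = paste(sample(senseCodons(), 80, replace = TRUE), collapse = "")))
  counts <- codonCountMatrix(seqs)
  tg <- taiG(counts, wgt)
  expect_equal(unname(tg["a"]),
               taiG(codonProfile(as.character(seqs)["a"], "a"), wgt))
})

test_that("taiG is monotone in synonymous upgrades and bounded by parts", {
  set.seed(17)
  raw <- runif(61, 0.05, 1)
  w <- setNames(raw / max(raw), senseCodons())
  wgt <- new("AdaptivenessWeights", weights = w, provenance = "computed")
  aa <- codonAminoAcids()
  # swapping one codon for a higher-weight synonym never lowers taiG
  fam <- names(aa)[aa == "L"]  # leucine: 6 codons
  lo <- fam[which.min(w[fam])]; hi <- fam[which.max(w[fam])]
  codons <- sample(senseCodons(), 60, replace = TRUE)
  codons[1] <- lo
  upgraded <- codons; upgraded[1] <- hi
  expect_gte(bfTaiG(upgraded, w), bfTaiG(codons, w))
  expect_gte(taiG(codonProfile(paste(upgraded, collapse = ""), "g"), wgt),
             taiG(codonProfile(paste(codons, collapse = ""), "g"), wgt))
  # concatenation lies between the parts
  a <- sample(senseCodons(), 40, replace = TRUE)
  b <- sample(senseCodons(), 70, replace = TRUE)
  tab <- taiG(codonProfile(paste(c(a, b), collapse = ""), "ab"), wgt)
  expect_gte(tab, min(taiG(codonProfile(paste(a, collapse = ""), "a"), wgt),
                      taiG(codonProfile(paste(b, collapse = ""), "b"), wgt)))
  expect_lte(tab, max(taiG(codonProfile(paste(a, collapse = ""), "a"), wgt),
                      taiG(codonProfile(paste(b, collapse = ""), "b"), wgt)))
})

test_that("percentOptimal partitions to 100 and handles edge fractions", {
  cls <- optimalityClassification(head(senseCodons(), 24), "cTE")
  inv <- optimalityClassification(tail(senseCodons(), 61 - 24), "anti")
  allOpt <- paste(rep(senseCodons()[isOptimal(cls)][1], 5), collapse = "")
  expect_equal(percentOptimal(codonProfile(allOpt, "g"), cls), 100)
  noneOpt <- paste(rep(senseCodons()[!isOptimal(cls)][1], 5), collapse = "")
  expect_equal(percentOptimal(codonProfile(noneOpt, "g"), cls), 0)
  # 3 of 12 optimal
  oc <- senseCodons()[isOptimal(cls)][1]
  nc <- senseCodons()[!isOptimal(cls)][1]
  p <- codonProfile(paste(c(rep(oc, 3), rep(nc, 9)), collapse = ""), "g")
  expect_equal(percentOptimal(p, cls), 25)
  # complement classification sums to 100 gene-wise
  set.seed(19)
  seqs <- simulateStudy(simulationConfig(nGenes = 20, seed = 19))$sequences
  counts <- codonCountMatrix(seqs)
  expect_equal(unname(percentOptimal(counts, cls) +
                        percentOptimal(counts, inv)),
               rep(100, nrow(counts)), tolerance = 1e-12)
})

test_that("weight and classification readers validate their tables", {
  tf <- tempfile()
  write.table(data.frame(codon = senseCodons(),
                         weight = seq(0.01, 1, length.out = 61)),
              tf, sep = "\t", row.names = FALSE)
  w <- readWeights(tf)
  expect_s4_class(w, "AdaptivenessWeights")
  expect_identical(w@provenance, "loaded")

  write.table(data.frame(codon = senseCodons()[-5],
                         weight = rep(0.5, 60)),
              tf, sep = "\t", row.names = FALSE)
  expect_error(readWeights(tf), senseCodons()[5])

  write.table(data.frame(codon = senseCodons(),
                         weight = c(1.2, rep(0.5, 60))),
              tf, sep = "\t", row.names = FALSE)
  expect_error(readWeights(tf), "\\(0, 1\\]")

  write.table(data.frame(codon = rep(senseCodons(), 2),
                         metric = rep(c("cTE", "nTE"), each = 61),
                         optimal = c(rep(1, 30), rep(0, 31), rep(1, 35), rep(0, 26))),
              tf, sep = "\t", row.names = FALSE)
  cls <- readClassifications(tf)
  expect_named(cls, c("cTE", "nTE"))
  expect_equal(sum(isOptimal(cls$cTE)), 30)
})

test_that("nTE weights follow demand and are abundance-scale invariant", {
  w <- setNames(rep(0.5, 61), senseCodons())
  w[c("AAA", "GCT", "TTT")] <- c(1, 0.8, 0.6)
  wgt <- new("AdaptivenessWeights", weights = w, provenance = "computed")
  # toy 3-gene system, hand-computable demand
  seqs <- Biostrings::DNAStringSet(c(
    g1 = "AAAGCT", g2 = "AAAAAA", g3 = "TTTGCT"))
  counts <- codonCountMatrix(seqs)
  m <- c(g1 = 2, g2 = 1, g3 = 4)
  # demand: AAA = 1*2 + 2*1 = 4; GCT = 1*2 + 1*4 = 6; TTT = 1*4 = 4
  got <- suppressWarnings(computeNte(wgt, counts, m))
  gw <- adaptiveness(got)
  # only the three used codons have finite demand; others are NA
  expect_true(all(is.na(gw[setdiff(senseCodons(),
                                   c("AAA", "GCT", "TTT"))])))
  hand <- c(AAA = 1 / (4 / 6), GCT = 0.8 / 1, TTT = 0.6 / (4 / 6))
  hand <- hand / max(hand)
  expect_equal(gw[c("AAA", "GCT", "TTT")], hand, tolerance = 1e-12)
  # doubling abundance changes nothing
  got2 <- suppressWarnings(computeNte(wgt, counts, m * 2))
  expect_equal(adaptiveness(got2), gw, tolerance = 1e-12)
  # uniform demand preserves tAI ranks
  seqsU <- Biostrings::DNAStringSet(c(
    u1 = paste(senseCodons(), collapse = "")))
  cU <- codonCountMatrix(seqsU)
  set.seed(23)
  raw <- runif(61, 0.1, 1)
  wR <- new("AdaptivenessWeights",
            weights = setNames(raw / max(raw), senseCodons()),
            provenance = "computed")
  nteU <- computeNte(wR, cU, c(u1 = 5))
  expect_equal(rank(adaptiveness(nteU)), rank(adaptiveness(wR)))
})

test_that("geneOptimality combines scores per gene", {
  set.seed(29)
  sim <- simulateStudy(simulationConfig(nGenes = 15, seed = 29))
  counts <- codonCountMatrix(sim$sequences)
  tab <- geneOptimality(counts, sim$weights, list(sim$classification))
  expect_named(tab, c("gene_id", "tai_g", "pct_optimal_cTE"))
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$tai_g > 0 & tab$tai_g <= 1))
  expect_true(all(tab$pct_optimal_cTE >= 0 & tab$pct_optimal_cTE <= 100))
})
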