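# Independent brute-force oracles, written directly from the defining
# formulas. They share no code with the implementations under test.

# Spearman: average-rank transform, then explicit product-moment sums,
# p from the t approximation on n - 2 df.
bfSpearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  n <- length(rx)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  r <- num / den
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(tt), n - 2), n = n)
}

# First-order partial Spearman via regression residuals of the ranks.
bfPartialSpearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- residuals(lm(rx ~ rz))
  ey <- residuals(lm(ry ~ rz))
  r <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  n <- length(rx)
  tt <- r * sqrt((n - 3) / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(tt), n - 3))
}

# 2x2 chi-square from the classical formulas: expected cells from the
# marginals, Yates deviation (|O - E| - 1/2, floored at 0), upper-tail
# chi-square with 1 df.
bfChisq2x2 <- function(a, b, c, d, correct = TRUE) {
  O <- c(a, b, c, d)
  n <- sum(O)
  E <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  dev <- abs(O - E)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / E)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Rank-sum W with normal approximation, tie correction and continuity
# correction, one-sided.
bfWilcoxNormal <- function(x, y, alternative = "greater") {
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y); N <- nx + ny
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  sigma <- sqrt((nx * ny / 12) *
                  ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
  mu <- nx * ny / 2
  if (alternative == "greater") {
    p <- pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
  } else {
    p <- pnorm((W - mu + 0.5) / sigma)
  }
  list(W = W, p = p)
}

# Exact rank-sum null by exhaustive enumeration of all choose(N, nx)
# group assignments (tie-free scores only).
bfWilcoxExact <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  Wobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  Ws <- apply(combn(N, nx), 2L, function(idx)
    sum(seq_len(N)[idx]) - nx * (nx + 1) / 2)
  list(W = Wobs,
       pGreater = mean(Ws >= Wobs),
       pLess = mean(Ws <= Wobs),
       pEqual = mean(Ws == Wobs))
}

# Gene-level tAI as the literal product-then-root geometric mean over
# the gene's codons with multiplicity.
bfTaiG <- function(codons, w) prod(w[codons])^(1 / length(codons))

# tAI weight vector by explicit per-codon enumeration of decoding
# anticodons (Watson-Crick plus the third-base wobble decoder, with the
# ATG/ATA special cases), independent of the package's pairing table.
bfTaiWeights <- function(tgcn, s = c(wc = 0, gu = 0.41, ic = 0.28,
                                     ia = 0.9999, ug = 0.68, la = 0.89),
                         domain = "eukaryote") {
  sense <- setdiff(
    sort(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1L, paste, collapse = "")),
    c("TAA", "TAG", "TGA"))
  rc <- function(codon) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", codon), "")[[1]]),
          collapse = "")
  }
  cn <- function(ac) if (ac %in% names(tgcn)) unname(tgcn[[ac]]) else 0
  W <- setNames(numeric(length(sense)), sense)
  for (codon in sense) {
    third <- substr(codon, 3L, 3L)
    stem <- substr(codon, 1L, 2L)
    W[codon] <- (1 - s[["wc"]]) * cn(rc(codon)) +
      switch(third,
             T = (1 - s[["gu"]]) * cn(rc(paste0(stem, "C"))),
             C = (1 - s[["ic"]]) * cn(rc(paste0(stem, "T"))),
             A = (1 - s[["ia"]]) * cn(rc(paste0(stem, "T"))),
             G = (1 - s[["ug"]]) * cn(rc(paste0(stem, "A"))))
    if (codon == "ATG") W[codon] <- (1 - s[["wc"]]) * cn("CAT")
    if (codon == "ATA" && domain == "prokaryote")
      W[codon] <- (1 - s[["wc"]]) * cn("TAT") + (1 - s[["la"]]) * cn("CAT")
  }
  w <- W / max(W)
  nz <- w > 0
  w[!nz] <- exp(mean(log(w[nz])))
  w
}

# Naive complete-linkage agglomeration returning the sorted merge
# heights; d is a full symmetric distance matrix.
bfCompleteLinkageHeights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# Write a small FASTA fixture and return its path.
writeFastaFixture <- function(records, file = tempfile(fileext = ".fa")) {
  writeLines(unlist(mapply(function(id, seq) c(paste0(">", id), seq),
                           names(records), records, SIMPLIFY = FALSE)),
             file)
  file
}
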