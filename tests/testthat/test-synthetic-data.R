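test_that("host tables hit their GC3 target once bias strength reaches 1", {
  for (target in c(0.25, 0.4, 0.65, 0.8)) {
    tab <- makeHostCut(target, biasStrength = 1.2, seed = 17)
    expect_lt(abs(gc3(tab) - target), 0.05)
  }
  low <- makeHostCut(0.25, 1.2, seed = 18)
  expect_lt(gc3(low), 0.5)
})

test_that("zero bias gives the uniform table and strong GC bias GC-ending top codons", {
  flat <- makeHostCut(0.5, biasStrength = 0)
  expect_equal(enc(flat, estimator = "plugin"), 61)
  rich <- makeHostCut(0.9, biasStrength = 2, seed = 19)
  fams <- codonFamilies(geneticCode(rich))
  deg <- degeneracy(geneticCode(rich))
  for (aa in names(fams)[deg >= 2]) {
    top <- fams[[aa]][which.max(codonCounts(rich)[fams[[aa]]])]
    expect_true(substr(top, 3, 3) %in% c("G", "C"))
  }
  expect_error(makeHostCut(1.2), "0, 1")
})

test_that("regime tables land on the COUSIN anchors of their construction", {
  host <- makeHostCut(0.75, 1.5, seed = 20)
  expect_equal(cousin(codonCounts(deriveRegimeCut(host, "matched")), host), 1,
               tolerance = 1e-12)
  eq <- deriveRegimeCut(host, "equal_usage")
  expect_equal(cousin(codonCounts(eq), host), 0, tolerance = 1e-12)
  expect_lt(cousin(codonCounts(deriveRegimeCut(host, "opposite")), host), 0)
  expect_gt(cousin(codonCounts(deriveRegimeCut(host, "exaggerated")), host), 1)
  expect_error(deriveRegimeCut(host, "exaggerated", gamma = 1), "gamma")
})

test_that("a two-codon family reflects exactly under the opposite regime", {
  host <- codonUsageTable(c(TTT = 800, TTC = 200), label = "phe")
  opp <- deriveRegimeCut(host, "opposite")
  f <- synonymousFreq(opp)[c("TTT", "TTC")]
  expect_equal(unname(f), c(0.2, 0.8), tolerance = 1e-3)
  expect_equal(cousin(codonCounts(opp)[c("TTT", "TTC")], host), -1,
               tolerance = 1e-3)
})

test_that("simulation is byte-identical under a fixed seed, and subsets reproduce", {
  host <- makeHostCut(0.7, 1.5, seed = 21)
  spec <- simulationSpec(30, table = host, seed = 22)
  a <- simulateCdsSet(spec)
  b <- simulateCdsSet(spec)
  expect_identical(as.character(sequences(a$cds)), as.character(sequences(b$cds)))
  expect_identical(a$expression, b$expression)
  fa <- tempfile(fileext = ".fna"); fb <- tempfile(fileext = ".fna")
  writeCdsFasta(a$cds, fa); writeCdsFasta(b$cds, fb)
  expect_identical(readLines(fa), readLines(fb))
  # the per-gene seed sequence makes a smaller run a prefix of a larger one
  small <- simulateCdsSet(simulationSpec(10, table = host, seed = 22))
  expect_identical(as.character(sequences(small$cds)),
                   as.character(sequences(a$cds))[1:10])
})

test_that("invalid simulation specs name the offending field", {
  host <- makeHostCut(0.7, 1.5, seed = 23)
  expect_error(simulationSpec(0, table = host), "nGenes")
  expect_error(simulationSpec(10, table = "x"), "table")
  expect_error(simulationSpec(10, table = host, biasLink = -1), "biasLink")
  expect_error(simulationSpec(10, table = host,
                              aaFreq = c(A = 0.5, C = 0.5)), "aaFreq")
})

test_that("realized codon frequencies converge to the generating table", {
  host <- makeHostCut(0.7, 1.5, seed = 24)
  sim <- simulateCdsSet(simulationSpec(200, table = host, lengthMean = 300,
                                       biasLink = 0, seed = 25))
  obs <- codonCounts(codonUsageTable(sim$cds))
  fams <- codonFamilies(geneticCode(host))
  fr <- synonymousFreq(host)
  x2 <- 0; df <- 0
  for (aa in names(fams)) {
    cc <- fams[[aa]]
    if (length(cc) < 2) next
    n <- sum(obs[cc])
    if (n == 0) next
    expd <- n * fr[cc]
    keep <- expd > 0
    x2 <- x2 + sum((obs[cc][keep] - expd[keep])^2 / expd[keep])
    df <- df + sum(keep) - 1
  }
  expect_gt(stats::pchisq(x2, df, lower.tail = FALSE), 0.01)
})

test_that("highly expressed genes carry sharper codon usage (lower ENC)", {
  host <- makeHostCut(0.75, 1.5, seed = 26)
  sim <- simulateCdsSet(simulationSpec(400, table = host, biasLink = 3,
                                       seed = 27))
  pts <- encPoints(sim$cds)
  pd <- flagTopExpressed(pts, sim$expression, fraction = 0.05)
  p <- pd@points
  expect_lt(mean(p$enc[p$highly_expressed], na.rm = TRUE),
            mean(p$enc[!p$highly_expressed], na.rm = TRUE))
})

test_that("per-gene scores of simulated regimes land in the four quadrants", {
  host <- makeHostCut(0.8, 1.5, seed = 28)
  centers <- vapply(c("matched", "equal_usage", "opposite", "exaggerated"),
    function(r) {
      tab <- deriveRegimeCut(host, r)
      sim <- simulateCdsSet(simulationSpec(300, table = tab, seed = 29,
                                           label = r))
      huberLocation(scoreTable(scoreSet(sim$cds, host))$cousin59)
    }, numeric(1))
  expect_lt(abs(centers[["matched"]] - 1), 0.1)
  expect_lt(abs(centers[["equal_usage"]]), 0.1)
  expect_lt(centers[["opposite"]], 0)
  expect_gt(centers[["exaggerated"]], 1)
})

test_that("planted EVE regions are reproducible with truthful coordinates", {
  a <- plantEveRegion(0.58, 0.35, 6000, tirLen = 20, seed = 30,
                      genomeLen = 20000)
  b <- plantEveRegion(0.58, 0.35, 6000, tirLen = 20, seed = 30,
                      genomeLen = 20000)
  expect_identical(as.character(a$sequence), as.character(b$sequence))
  s <- as.character(a$sequence)[[1]]
  tr <- a$truth
  expect_equal(nchar(s), 20000L)
  left <- substr(s, tr$left_arm[1] + 1, tr$left_arm[2])
  right <- substr(s, tr$right_arm[1] + 1, tr$right_arm[2])
  expect_equal(
    right,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(left))))

  none <- plantEveRegion(0.58, 0.35, 6000, tirLen = 0, seed = 31)
  expect_false(none$truth$tir_present)
  expect_error(plantEveRegion(0.5, 0.5, 5000, genomeLen = 1000), "longer")
  expect_error(plantEveRegion(1.5, 0.5, 100), "0, 1")
})
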