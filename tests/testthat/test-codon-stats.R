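test_that("codon usage tables count, pool and normalize correctly", {
  set <- cdsSet(c(g = "ATGGCTGCTTAA"), label = "t")
  tab <- codonUsageTable(set)
  expect_equal(unname(codonCounts(tab)[c("ATG", "GCT")]), c(1, 2))
  expect_equal(unname(synonymousFreq(tab)["GCT"]), 1)

  # additivity over members with disjoint codons
  s2 <- cdsSet(c(a = "ATGGCTTAA", b = "TGGCCGTAA"), label = "t2")
  t2 <- codonUsageTable(s2)
  expect_equal(unname(codonCounts(t2)[c("ATG", "GCT", "TGG", "CCG")]),
               c(1, 1, 1, 1))

  # Ala codons 4,3,2,1 -> f_syn 0.4, 0.3, 0.2, 0.1
  ala <- codonUsageTable(c(GCT = 4, GCC = 3, GCA = 2, GCG = 1))
  expect_equal(unname(synonymousFreq(ala)[c("GCT", "GCC", "GCA", "GCG")]),
               c(0.4, 0.3, 0.2, 0.1))

  # observed families have f_syn summing to one
  ref <- toyBiasedRef()
  fams <- codonFamilies(geneticCode(ref))
  for (aa in names(fams))
    if (aaCounts(ref)[[aa]] > 0)
      expect_equal(sum(synonymousFreq(ref)[fams[[aa]]]), 1, tolerance = 1e-12)

  expect_error(codonUsageTable(cdsSet(c(g = "NNNNNN"), label = "n")), "N")
})

test_that("codon usage table TSV round trip preserves counts", {
  ref <- toyBiasedRef()
  path <- tempfile(fileext = ".tsv")
  writeCodonUsageTable(ref, path)
  expect_equal(nrow(utils::read.delim(path)), 64L)
  back <- readCodonUsageTable(path)
  expect_equal(codonCounts(back), codonCounts(ref))
})

test_that("GC3 follows the third-base rule with stops excluded", {
  expect_equal(gc3(c("ATG", "GCT", "GCG")), 2 / 3)
  expect_equal(gc3(c("GCC", "GGG", "ACG")), 1)
  set <- cdsSet(c(g = "ATGGCTTAA"), label = "t")
  expect_equal(unname(gc3(set)), 0.5)  # G,T counted; stop excluded
  expect_warning(v <- gc3(character(0)), "undefined")
  expect_true(is.na(v))
})

test_that("ENC hits its analytic anchors", {
  code <- standardGeneticCode()
  oneEach <- rep(vapply(codonFamilies(code), `[`, character(1), 1L), 2)
  expect_equal(enc(oneEach, estimator = "plugin"), 20)
  expect_equal(enc(oneEach, estimator = "bias_corrected"), 20)

  uniform <- stats::setNames(rep(10, 61), senseCodons(code))
  expect_equal(enc(codonUsageTable(uniform), estimator = "plugin"), 61)

  # single 2-fold family at f = (0.8, 0.2): F = 0.68, ENC = 1 + 1/0.68
  gene <- c(rep("TTT", 4), "TTC", "ATG")
  expect_equal(enc(gene, estimator = "plugin"), 1 + 1 / 0.68,
               tolerance = 1e-12)

  expect_warning(v <- enc("ATG", estimator = "plugin"), "undefined")
  expect_true(is.na(v))
})

test_that("plug-in ENC stays in [20, 61] and the corrected form converges to it", {
  ref <- toyBiasedRef()
  probs <- codonCounts(ref) / sum(codonCounts(ref))
  set.seed(3)
  for (rep in 1:10) {
    gene <- c(randomCodons(400, probs),
              rep(vapply(.oracleFams, `[`, character(1), 1L), 1))
    v <- enc(gene, estimator = "plugin")
    expect_gte(v, 20); expect_lte(v, 61)
  }
  # the estimator gap decays like 1/length
  set.seed(4)
  gap <- vapply(c(100, 1000, 10000), function(n) {
    g <- randomCodons(n, probs)
    abs(enc(g, "bias_corrected") - enc(g, "plugin"))
  }, numeric(1))
  expect_lt(gap[2], gap[1])
  expect_lt(gap[3], gap[2])
  expect_lt(gap[3], gap[1] / 10)
})

test_that("the ENC null curve matches direct substitution and its symmetry", {
  expect_equal(encNull(0.5), 60.5)
  expect_equal(encNull(0), 31)
  expect_equal(encNull(1), 32)
  s <- seq(0, 1, by = 0.01)
  expect_equal(encNull(s) - s, encNull(1 - s) - (1 - s), tolerance = 1e-12)
  expect_error(encNull(1.2), "0, 1")
  expect_error(encNull(-0.1), "0, 1")
})

test_that("CAI anchors: preferred-only gene scores 1, mixed usage scores the geometric mean", {
  ref <- toyBiasedRef()
  code <- geneticCode(ref)
  fams <- codonFamilies(code)
  best <- vapply(names(fams)[degeneracy(code) >= 2], function(aa) {
    f <- fams[[aa]]
    f[which.max(codonCounts(ref)[f])]
  }, character(1))
  expect_equal(cai(rep(best, 3), ref), 1)

  # 2-fold family with reference (0.8, 0.2): sqrt(1 * 0.25) = 0.5
  ref2 <- codonUsageTable(c(TTT = 8, TTC = 2))
  expect_equal(cai(c("TTT", "TTC"), ref2), 0.5)

  # uniform reference makes every codon preferred
  uniformRef <- codonUsageTable(
    stats::setNames(rep(10, 61), senseCodons(code)))
  expect_equal(cai(c("GCT", "GCA", "TTT", "CGG"), uniformRef), 1)

  expect_warning(v <- cai(c("ATG", "TGG"), ref), "undefined")
  expect_true(is.na(v))
})

test_that("CAI is invariant to rescaling reference counts", {
  ref <- toyBiasedRef()
  scaled <- codonUsageTable(codonCounts(ref) * 7, label = "scaled")
  set.seed(9)
  for (rep in 1:10) {
    g <- randomCodons(sample(30:100, 1))
    expect_equal(cai(g, ref), cai(g, scaled), tolerance = 1e-12)
  }
})

test_that("COUSIN anchors: self scores 1, uniform scores 0, reflection flips sign", {
  ref <- toyBiasedRef()
  self <- cousinBoth(codonCounts(ref), ref)
  expect_equal(self$cousin18, 1, tolerance = 1e-12)
  expect_equal(self$cousin59, 1, tolerance = 1e-12)

  uniform <- stats::setNames(rep(6, 61), senseCodons(geneticCode(ref)))
  u <- cousinBoth(uniform, ref)
  expect_equal(u$cousin18, 0, tolerance = 1e-12)
  expect_equal(u$cousin59, 0, tolerance = 1e-12)

  # single 2-fold family, ref (0.8, 0.2): query (1,0) -> 5/3, (0,1) -> -5/3
  ref2 <- codonUsageTable(c(TTT = 8, TTC = 2))
  expect_equal(cousin(c("TTT", "TTT"), ref2), 0.30 / 0.18, tolerance = 1e-9)
  expect_equal(cousin(c("TTC", "TTC"), ref2), -0.30 / 0.18, tolerance = 1e-9)

  # an entirely uniform reference is uninformative
  uniRef <- codonUsageTable(uniform)
  expect_warning(v <- cousin(c("GCT", "GCT"), uniRef), "undefined")
  expect_true(is.na(v))
})

test_that("COUSIN anchors hold across random references", {
  for (seed in 1:8) {
    ref <- toyBiasedRef(seed = 100 + seed)
    expect_equal(cousinBoth(codonCounts(ref), ref)$cousin59, 1,
                 tolerance = 1e-12)
    uniform <- stats::setNames(rep(4, 61), senseCodons(geneticCode(ref)))
    expect_equal(cousinBoth(uniform, ref)$cousin59, 0, tolerance = 1e-12)
  }
})

test_that("naive per-family enumeration reproduces ENC, CAI and COUSIN", {
  ref <- toyBiasedRef()
  refCounts <- codonCounts(ref)
  set.seed(21)
  for (rep in 1:60) {
    g <- randomCodons(sample(10:60, 1))
    cnt <- countsOf(g)
    for (est in c("plugin", "bias_corrected")) {
      expect_equal(suppressWarnings(enc(g, estimator = est)),
                   naiveEnc(g, est), tolerance = 1e-9)
    }
    expect_equal(suppressWarnings(cai(g, ref)),
                 naiveCai(g, refCounts), tolerance = 1e-9)
    got <- suppressWarnings(cousinBoth(cnt, ref))
    want <- naiveCousin(cnt, refCounts)
    expect_equal(got$cousin18, want$cousin18, tolerance = 1e-9)
    expect_equal(got$cousin59, want$cousin59, tolerance = 1e-9)
  }
})

test_that("scoreSet scores every CDS and propagates undefined values", {
  ref <- toyBiasedRef()
  seqs <- c(a = "ATGGCTGCAGCTTAA", b = "ATGTTTTTCAAATAA",
            mw = "ATGTGGATGTAA")  # Met/Trp only -> cai undefined
  ss <- scoreSet(cdsSet(seqs, label = "q"), ref)
  df <- scoreTable(ss)
  expect_equal(nrow(df), 3L)
  expect_true(is.na(df$cai[df$cds_id == "mw"]))
  expect_false(anyNA(df$cai[df$cds_id != "mw"]))
  expect_error(scoreSet(cdsSet(character(0), label = "e"), ref))
})

test_that("self-scoring a set per gene centres COUSIN59 near 1", {
  host <- makeHostCut(0.75, 1.5, seed = 5)
  sim <- simulateCdsSet(simulationSpec(150, table = host, seed = 6,
                                       biasLink = 0))
  tab <- codonUsageTable(sim$cds)
  df <- scoreTable(scoreSet(sim$cds, tab))
  expect_lt(abs(huberLocation(df$cousin59) - 1), 0.1)
  pooled <- pooledScores(sim$cds, tab)
  expect_equal(unname(pooled["cousin59"]), 1, tolerance = 1e-12)
})
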