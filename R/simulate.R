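#' @include robust-compare.R
NULL

# expected GC3 of a host table built with tilt beta, uniform amino acids
.expectedGc3 <- function(beta, code) {
  fams <- codonFamilies(code)
  p <- vapply(fams, function(cc) {
    isGc <- substr(cc, 3L, 3L) %in% c("G", "C")
    w <- exp(beta * isGc)
    sum(w[isGc]) / sum(w)
  }, numeric(1))
  mean(p)
}

#' Build a biased host codon usage table
#'
#' Constructs a codon usage table whose within-family preferences are
#' softmax-tilted toward G/C-ending codons (or away from them, when
#' `gc3Target < 0.5`). The tilt is calibrated numerically so that for
#' `biasStrength >= 1` the realized GC3 of the table lands close to
#' `gc3Target`; weaker bias interpolates toward uniform usage. On top of the
#' third-base tilt, a seeded GC-class-centred preference perturbation
#' (stronger with `biasStrength`) differentiates codons that share a third-base
#' class, so families acquire distinct top codons the way real genomes do.
#' `biasStrength = 0` yields the exactly uniform table (plug-in ENC 61).
#'
#' @param gc3Target target GC3 in (0, 1); values below the code's floor
#'   (about 0.1, set by the invariant G-ending Met and Trp codons) saturate
#' @param biasStrength bias dial, >= 0; 1 reaches the target tilt
#' @param seed integer seed for the within-class perturbation
#' @param scale total codon count of the realized table
#' @param code genetic code
#' @return a [CodonUsageTable-class] labelled by its parameters
#' @export
makeHostCut <- function(gc3Target, biasStrength = 1.5, seed = 1L,
                        scale = 2e5, code = standardGeneticCode()) {
  if (!is.finite(gc3Target) || gc3Target <= 0 || gc3Target >= 1)
    stop("gc3Target must lie in (0, 1)")
  if (biasStrength < 0) stop("biasStrength must be >= 0")
  fams <- codonFamilies(code)
  label <- sprintf("host_gc3_%.2f_bias_%.2f", gc3Target, biasStrength)
  if (biasStrength == 0) {
    counts <- unlist(lapply(fams, function(cc)
      stats::setNames(rep(round(scale / 20 / length(cc)), length(cc)), cc)))
    names(counts) <- sub("^.*\\.", "", names(counts))
    return(codonUsageTable(counts, label = label, code = code))
  }
  lo <- .expectedGc3(-20, code); hi <- .expectedGc3(20, code)
  target <- min(max(gc3Target, lo + 1e-4), hi - 1e-4)
  beta <- stats::uniroot(function(b) .expectedGc3(b, code) - target,
                         c(-20, 20), tol = 1e-9)$root
  betaEff <- beta * min(biasStrength, 1)
  sigma <- 0.2 * tanh(biasStrength)
  counts <- .withSeed(seed, {
    unlist(lapply(fams, function(cc) {
      isGc <- substr(cc, 3L, 3L) %in% c("G", "C")
      u <- stats::rnorm(length(cc), 0, sigma)
      # centre the perturbation within each third-base class so it sharpens
      # preferences without moving the family's expected GC3
      for (cl in unique(isGc)) u[isGc == cl] <- u[isGc == cl] - mean(u[isGc == cl])
      w <- exp(betaEff * isGc + u)
      stats::setNames(round(scale / 20 * w / sum(w)), cc)
    }))
  })
  names(counts) <- sub("^.*\\.", "", names(counts))
  codonUsageTable(pmax(counts, 1), label = label, code = code)
}

#' Derive a virus codon usage regime from a host table
#'
#' Produces the four virus-versus-host codon usage regimes the score
#' distributions distinguish: `matched` copies the host preferences
#' (COUSIN = 1 on the table), `equal_usage` makes every family uniform
#' (COUSIN = 0), `opposite` reflects each family's frequencies about the
#' equal-usage point, f'(c) proportional to max(2 e_a - f(c), eps)
#' (COUSIN < 0), and `exaggerated` sharpens them, f'(c) proportional to
#' f(c)^gamma with gamma > 1 (COUSIN > 1). Amino-acid totals are preserved so
#' only within-family preferences change.
#'
#' @param host a non-uniform [CodonUsageTable-class]
#' @param regime one of "matched", "equal_usage", "opposite", "exaggerated"
#' @param gamma sharpening exponent for `exaggerated` (> 1)
#' @param eps floor preventing zero-probability codons in `opposite`
#' @return a [CodonUsageTable-class]
#' @export
deriveRegimeCut <- function(host, regime = c("matched", "equal_usage",
                                             "opposite", "exaggerated"),
                            gamma = 2, eps = 0.01) {
  regime <- match.arg(regime)
  stopifnot(methods::is(host, "CodonUsageTable"))
  code <- geneticCode(host)
  label <- paste0(host@sourceLabel, "_", regime)
  if (regime == "matched") {
    tab <- codonUsageTable(codonCounts(host), label = label, code = code)
    return(tab)
  }
  if (regime == "exaggerated" && gamma <= 1)
    stop("gamma must be > 1 for the exaggerated regime")
  fams <- codonFamilies(code)
  fr <- synonymousFreq(host)
  aaN <- aaCounts(host)
  counts <- unlist(lapply(names(fams), function(aa) {
    cc <- fams[[aa]]
    k <- length(cc)
    tot <- max(aaN[[aa]], 1000)
    if (regime == "equal_usage") {
      # exact within-family uniformity, not a rounded approximation
      return(stats::setNames(rep(max(round(tot / k), 1), k), cc))
    }
    f <- fr[cc]
    if (anyNA(f)) f <- rep(1 / k, k)
    fNew <- switch(regime,
      opposite = { v <- pmax(2 / k - f, eps); v / sum(v) },
      exaggerated = { v <- f^gamma; v / sum(v) })
    stats::setNames(round(tot * fNew), cc)
  }))
  codonUsageTable(pmax(counts, 0), label = label, code = code)
}

#' Specification of a synthetic CDS study condition
#'
#' Bundles and validates everything [simulateCdsSet()] needs: number of genes,
#' gene-length distribution (in codons), amino-acid frequencies, the codon
#' usage table genes are drawn from, the log-normal expression model, and the
#' expression-bias link that concentrates sharper codon usage in highly
#' expressed genes.
#'
#' @param nGenes number of genes (>= 1)
#' @param table the [CodonUsageTable-class] codons are drawn from (a host
#'   table or a regime table from [deriveRegimeCut()])
#' @param lengthMean,lengthSd normal distribution of body length in codons;
#'   lengths are floored at 10 codons
#' @param aaFreq named amino-acid frequency vector over the 20 amino acids
#'   (default uniform), must sum to 1
#' @param exprMu,exprSigma log-normal (meanlog, sdlog) of FPKM
#' @param biasLink strength of the expression-bias coupling (>= 0): a gene at
#'   expression quantile q samples codons from the table's frequencies raised
#'   to 1 + biasLink * max(0, (q - 0.8)/0.2)^2, so only the upper expression
#'   tail is sharpened (lower ENC in highly expressed genes, as on real ENC
#'   plots) while the bulk of the distribution keeps the table's preferences
#' @param label label of the generated set
#' @param rank rank of the generated set
#' @param seed global seed; a per-gene seed sequence derives from it, so any
#'   subset of genes is reproducible independently
#' @return a validated spec (list with class "SimulationSpec")
#' @export
simulationSpec <- function(nGenes, table, lengthMean = 300, lengthSd = 80,
                           aaFreq = NULL, exprMu = 1, exprSigma = 1.5,
                           biasLink = 1, label = "sim", rank = "species",
                           seed = 1L) {
  if (!is.numeric(nGenes) || nGenes < 1) stop("invalid field: nGenes")
  if (!methods::is(table, "CodonUsageTable")) stop("invalid field: table")
  if (!is.numeric(lengthMean) || lengthMean < 10)
    stop("invalid field: lengthMean (mean length must allow >= 10 codons)")
  if (!is.numeric(lengthSd) || lengthSd < 0) stop("invalid field: lengthSd")
  aas <- names(codonFamilies(geneticCode(table)))
  if (is.null(aaFreq)) aaFreq <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  if (!setequal(names(aaFreq), aas) || abs(sum(aaFreq) - 1) > 1e-8)
    stop("invalid field: aaFreq (must cover the 20 amino acids and sum to 1)")
  if (!is.numeric(biasLink) || biasLink < 0) stop("invalid field: biasLink")
  if (!is.numeric(exprSigma) || exprSigma < 0) stop("invalid field: exprSigma")
  if (!is.numeric(seed)) stop("invalid field: seed")
  structure(list(nGenes = as.integer(nGenes), table = table,
                 lengthMean = lengthMean, lengthSd = lengthSd,
                 aaFreq = aaFreq[aas], exprMu = exprMu, exprSigma = exprSigma,
                 biasLink = biasLink, label = label, rank = rank,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Simulate a CDS set with a paired expression table
#'
#' Per gene: a body length is drawn, amino acids are drawn from the spec's
#' frequencies, and codons are drawn within each family from the spec table's
#' relative synonymous frequencies, sharpened for highly expressed genes
#' according to the expression-bias link (see [simulationSpec()]). Every gene
#' starts with ATG and ends with TAA. FPKM values are log-normal. The run is
#' fully reproducible from the seed, gene by gene.
#'
#' @param spec a [simulationSpec()]
#' @return list with elements `cds` (a [CdsSet-class]) and `expression`
#'   (data.frame gene_id, fpkm)
#' @export
simulateCdsSet <- function(spec) {
  if (!inherits(spec, "SimulationSpec")) stop("need a SimulationSpec")
  code <- geneticCode(spec$table)
  fams <- codonFamilies(code)
  fr <- synonymousFreq(spec$table)
  famFreq <- lapply(fams, function(cc) {
    f <- fr[cc]
    if (anyNA(f) || sum(f) == 0) f <- rep(1 / length(cc), length(cc))
    stats::setNames(as.numeric(f), cc)
  })
  aas <- names(spec$aaFreq)
  n <- spec$nGenes
  ids <- sprintf("gene_%05d", seq_len(n))
  seqs <- character(n)
  fpkm <- numeric(n)
  for (i in seq_len(n)) {
    gSeed <- (spec$seed + i * 9973L) %% 2147483647L
    res <- .withSeed(gSeed, {
      len <- max(10L, round(stats::rnorm(1, spec$lengthMean, spec$lengthSd)))
      e <- stats::rlnorm(1, spec$exprMu, spec$exprSigma)
      q <- stats::plnorm(e, spec$exprMu, spec$exprSigma)
      # sharpening confined to the upper expression tail: genes below the
      # 80th percentile sample the table as-is, the top twentieth sharpens
      # most -- translational selection acts on highly expressed genes
      gamma <- 1 + spec$biasLink * max(0, (q - 0.8) / 0.2)^2
      aaSeq <- sample(aas, len, replace = TRUE, prob = spec$aaFreq)
      cod <- character(len)
      for (aa in unique(aaSeq)) {
        idx <- which(aaSeq == aa)
        p <- famFreq[[aa]]^gamma
        cod[idx] <- sample(names(p), length(idx), replace = TRUE,
                           prob = p / sum(p))
      }
      list(seq = paste0("ATG", paste(cod, collapse = ""), "TAA"), fpkm = e)
    })
    seqs[i] <- res$seq
    fpkm[i] <- res$fpkm
  }
  names(seqs) <- ids
  list(cds = cdsSet(seqs, label = spec$label, rank = spec$rank, code = code),
       expression = data.frame(gene_id = ids, fpkm = fpkm))
}

#' Write an expression table as TSV
#' @param expr data.frame(gene_id, fpkm)
#' @param path output path
#' @export
writeExpressionTable <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.randomDna <- function(n, gc) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Plant a synthetic integrated viral region in a host-like background
#'
#' Generates a background contig at one GC content with an embedded region at
#' a different GC content whose ends are exact reverse-complement arms
#' (terminal inverted repeats) of the requested length — the synthetic ground
#' truth for the GC-profile and inverted-repeat scanners.
#'
#' @param genomeGc,regionGc GC content of the background and of the planted
#'   region, each in (0, 1)
#' @param regionLen length of the planted region in bp
#' @param tirLen arm length in bp (0 plants no repeat; truth records absence)
#' @param seed integer seed
#' @param genomeLen total contig length in bp
#' @param contigId name of the contig
#' @return list with `sequence` (one-element named [Biostrings::DNAStringSet])
#'   and `truth` (list of all planted coordinates, 0-based half-open)
#' @export
plantEveRegion <- function(genomeGc, regionGc, regionLen, tirLen = 20L,
                           seed = 1L, genomeLen = 30000L,
                           contigId = "synthetic_contig_1") {
  for (v in c(genomeGc, regionGc))
    if (!is.finite(v) || v <= 0 || v >= 1) stop("GC contents must lie in (0, 1)")
  if (tirLen < 0) stop("tirLen must be >= 0")
  if (regionLen > genomeLen) stop("region longer than the genome")
  if (2 * tirLen > regionLen) stop("arms longer than the region")
  .withSeed(seed, {
    start <- sample.int(genomeLen - regionLen + 1L, 1L) - 1L  # 0-based
    core <- .randomDna(regionLen - 2L * tirLen, regionGc)
    if (tirLen > 0L) {
      arm <- .randomDna(tirLen, regionGc)
      region <- paste0(arm, core, .revComp(arm))
    } else region <- core
    left <- .randomDna(start, genomeGc)
    right <- .randomDna(genomeLen - start - regionLen, genomeGc)
    seqs <- Biostrings::DNAStringSet(paste0(left, region, right))
    names(seqs) <- contigId
    truth <- list(
      contig_id = contigId, genome_gc = genomeGc, region_gc = regionGc,
      region_start = start, region_end = start + regionLen,
      tir_present = tirLen > 0L, tir_len = as.integer(tirLen),
      left_arm = if (tirLen > 0L) c(start, start + tirLen) else NULL,
      right_arm = if (tirLen > 0L)
        c(start + regionLen - tirLen, start + regionLen) else NULL,
      seed = as.integer(seed))
    list(sequence = seqs, truth = truth)
  })
}
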