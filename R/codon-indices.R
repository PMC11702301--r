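#' @include codon-usage.R
NULL

#' GC content at the third codon position (GC3)
#'
#' Fraction of counted codons (non-stop, N-free; see [cdsSet()] for the
#' counting rules) whose third base is G or C. All counted codons enter,
#' including Met and Trp.
#'
#' @param x a character vector of codons, a [CodonUsageTable-class], or a
#'   [CdsSet-class] (one value per member CDS)
#' @return GC3 in [0, 1]; NA with a warning when no codon is counted
#' @examples
#' gc3(c("ATG", "GCT", "GCG"))  # third bases G, T, G -> 2/3
#' @export
setGeneric("gc3", function(x) standardGeneric("gc3"))

.gc3FromCounts <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) {
    warning("GC3 undefined: no counted codons")
    return(NA_real_)
  }
  third <- substr(names(counts), 3L, 3L)
  sum(counts[third %in% c("G", "C")]) / tot
}

#' @rdname gc3
setMethod("gc3", "character", function(x) {
  if (length(x) == 0L) {
    warning("GC3 undefined: no counted codons")
    return(NA_real_)
  }
  mean(substr(x, 3L, 3L) %in% c("G", "C"))
})

#' @rdname gc3
setMethod("gc3", "CodonUsageTable", function(x) .gc3FromCounts(codonCounts(x)))

#' @rdname gc3
setMethod("gc3", "CdsSet", function(x) {
  vapply(cdsCodons(x), function(cc) suppressWarnings(gc3(cc)), numeric(1))
})

#' Effective number of codons (ENC)
#'
#' Wright-style ENC: per degenerate family a, the codon homozygosity F_a is
#' estimated either as the plug-in sum of squared relative synonymous
#' frequencies, or bias-corrected as (n_a * sum f^2 - 1) / (n_a - 1) with n_a
#' the family's codon count (defined only for n_a >= 2). F is averaged within
#' each degeneracy class over the observed families, and
#' ENC = n1 + sum_k N_k / Fbar_k, where n1 is the number of observed
#' single-codon amino acids and N_k the number of observed families of
#' degeneracy k. ENC runs from 20 (one codon per amino acid, all families
#' present) to 61 (equal usage); sampling noise above 61 is capped at 61.
#'
#' When the single 3-fold family (Ile) is observed but its F is undefined
#' under the bias-corrected estimator, Fbar_3 is interpolated as
#' (Fbar_2 + Fbar_4)/2 when both neighbours exist; a degeneracy class with no
#' usable F estimate is omitted from the sum.
#'
#' @param x a character vector of codons, a [CodonUsageTable-class], or a
#'   [CdsSet-class] (one value per member CDS)
#' @param estimator "bias_corrected" (default; the usual per-gene estimator)
#'   or "plugin"
#' @return ENC; NA with a warning when no degenerate family has a defined F
#' @examples
#' # one synonymous codon per amino acid, every family present twice -> 20
#' code <- standardGeneticCode()
#' top <- vapply(codonFamilies(code), `[`, character(1), 1L)
#' enc(rep(top, 2), estimator = "plugin")
#' @export
setGeneric("enc", function(x, estimator = c("bias_corrected", "plugin"))
  standardGeneric("enc"))

.encFromCounts <- function(counts, code, estimator) {
  fams <- codonFamilies(code)
  deg <- degeneracy(code)
  n1 <- 0L
  famF <- list(`2` = numeric(0), `3` = numeric(0),
               `4` = numeric(0), `6` = numeric(0))
  famN <- c(`2` = 0L, `3` = 0L, `4` = 0L, `6` = 0L)
  for (aa in names(fams)) {
    n <- sum(counts[fams[[aa]]])
    if (n == 0) next
    k <- deg[[aa]]
    if (k == 1L) { n1 <- n1 + 1L; next }
    kk <- as.character(k)
    famN[[kk]] <- famN[[kk]] + 1L
    f <- counts[fams[[aa]]] / n
    S <- sum(f^2)
    Fa <- if (estimator == "plugin") S
          else if (n >= 2) (n * S - 1) / (n - 1) else NA_real_
    if (!is.na(Fa)) famF[[kk]] <- c(famF[[kk]], Fa)
  }
  Fbar <- vapply(famF, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
  # interpolate the lone 3-fold class when observed but inestimable
  if (famN[["3"]] > 0L && is.na(Fbar[["3"]]) &&
      !is.na(Fbar[["2"]]) && !is.na(Fbar[["4"]]))
    Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
  usable <- famN > 0L & !is.na(Fbar) & Fbar > 0
  if (!any(usable)) {
    warning("ENC undefined: no degenerate family with a defined homozygosity")
    return(NA_real_)
  }
  min(n1 + sum(famN[usable] / Fbar[usable]), 61)
}

#' @rdname enc
setMethod("enc", "character", function(x, estimator) {
  estimator <- match.arg(estimator)
  tab <- codonUsageTable(x)
  .encFromCounts(codonCounts(tab), geneticCode(tab), estimator)
})

#' @rdname enc
setMethod("enc", "CodonUsageTable", function(x, estimator) {
  estimator <- match.arg(estimator)
  .encFromCounts(codonCounts(x), geneticCode(x), estimator)
})

#' @rdname enc
setMethod("enc", "CdsSet", function(x, estimator) {
  estimator <- match.arg(estimator)
  code <- standardGeneticCode()
  sense <- senseCodons(code)
  vapply(cdsCodons(x), function(cc) {
    if (length(cc) == 0L) return(NA_real_)
    cnt <- stats::setNames(numeric(length(sense)), sense)
    tb <- table(cc)
    cnt[names(tb)] <- tb
    suppressWarnings(.encFromCounts(cnt, code, estimator))
  }, numeric(1))
})

#' ENC expected under mutational bias alone
#'
#' The no-selection null curve for ENC-GC3 plots:
#' ENC0(s) = 2 + s + 29 / (s^2 + (1 - s)^2), with s the GC3 value. Genes far
#' below this curve are candidates for translational selection.
#'
#' @param s GC3 value(s) in [0, 1]
#' @return expected ENC, vectorized over `s`
#' @examples
#' encNull(c(0, 0.5, 1))  # 31, 60.5, 32
#' @export
encNull <- function(s) {
  if (any(!is.finite(s)) || any(s < 0 | s > 1))
    stop("s must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean, over a gene's counted codons in degenerate families
#' (Met, Trp and stops excluded), of the relative adaptiveness
#' w(c) = f_ref(c) / max f_ref within the family. A gene that always uses the
#' reference's most frequent synonymous codon scores 1. Reference codons with
#' zero count receive w = 0.5 / (family max count), the standard pseudo-count;
#' families entirely absent from the reference are uninformative and score
#' w = 1.
#'
#' @param x a character vector of codons, a [CodonUsageTable-class] (pooled
#'   CAI of a whole set), or a [CdsSet-class] (one value per member)
#' @param ref reference [CodonUsageTable-class]
#' @return CAI in [0, 1]; NA with a warning for genes with no codon in a
#'   degenerate family
#' @export
setGeneric("cai", function(x, ref) standardGeneric("cai"))

.caiWeights <- function(ref) {
  code <- geneticCode(ref)
  fams <- codonFamilies(code)
  deg <- degeneracy(code)
  cnt <- codonCounts(ref)
  w <- stats::setNames(rep(NA_real_, length(cnt)), names(cnt))
  for (aa in names(fams)) {
    if (deg[[aa]] < 2L) next
    cc <- fams[[aa]]
    m <- max(cnt[cc])
    w[cc] <- if (m == 0) 1 else pmax(cnt[cc], 0.5) / m
  }
  w
}

.caiFromCounts <- function(counts, ref) {
  w <- .caiWeights(ref)
  use <- !is.na(w) & counts > 0
  n <- sum(counts[use])
  if (n == 0) {
    warning("CAI undefined: no codon in a degenerate family")
    return(NA_real_)
  }
  exp(sum(counts[use] * log(w[use])) / n)
}

#' @rdname cai
setMethod("cai", signature("character", "CodonUsageTable"), function(x, ref) {
  tab <- codonUsageTable(x, code = geneticCode(ref))
  .caiFromCounts(codonCounts(tab), ref)
})

#' @rdname cai
setMethod("cai", signature("CodonUsageTable", "CodonUsageTable"),
  function(x, ref) .caiFromCounts(codonCounts(x), ref))

#' @rdname cai
setMethod("cai", signature("CdsSet", "CodonUsageTable"), function(x, ref) {
  sense <- senseCodons(geneticCode(ref))
  vapply(cdsCodons(x), function(cc) {
    cnt <- stats::setNames(numeric(length(sense)), sense)
    if (length(cc)) { tb <- table(cc); cnt[names(tb)] <- tb }
    suppressWarnings(.caiFromCounts(cnt, ref))
  }, numeric(1))
})

#' COUSIN codon usage similarity index
#'
#' CAI-like comparison of a query against a reference codon usage table,
#' normalized against the null of equal synonymous usage, so that 1 means the
#' query shares the reference's preferences, 0 means equal usage, values in
#' (0,1) the same preferences at smaller magnitude, values above 1 the same
#' preferences exaggerated, and negative values opposite preferences.
#'
#' For each degenerate family a present in the query whose reference usage is
#' non-uniform: num_a = sum_c f_q(c) (f_r(c) - e_a) and
#' den_a = sum_c f_r(c) (f_r(c) - e_a), with e_a = 1/k_a. The family-weighted
#' variant (COUSIN18) averages num_a/den_a over families; the
#' amino-acid-weighted variant (COUSIN59) is the ratio of query-count-weighted
#' sums, sum_a n_a num_a / sum_a n_a den_a.
#'
#' @param query a character vector of codons, a named vector of codon counts,
#'   or a [CodonUsageTable-class]
#' @param ref reference [CodonUsageTable-class]
#' @param variant 59 (amino-acid-weighted, default) or 18 (family-weighted)
#' @return the index value (unbounded); NA with a warning when no eligible
#'   family exists (e.g. an entirely uniform reference)
#' @examples
#' ref <- codonUsageTable(c(GCT = 8, GCC = 2), label = "ref")
#' cousin(c("GCT", "GCT"), ref)           # preferred only -> > 1
#' cousin(c(GCT = 1, GCC = 1), ref)       # equal usage -> 0
#' @export
cousin <- function(query, ref, variant = 59) {
  variant <- as.character(variant[1L])
  if (!variant %in% c("18", "59")) stop("variant must be 18 or 59")
  both <- cousinBoth(query, ref)
  both[[paste0("cousin", variant)]]
}

#' Both COUSIN variants at once
#' @inheritParams cousin
#' @return named list with elements `cousin18` and `cousin59`
#' @export
cousinBoth <- function(query, ref) {
  if (is.character(query) || is.numeric(query))
    query <- codonUsageTable(query, code = geneticCode(ref))
  stopifnot(methods::is(query, "CodonUsageTable"),
            methods::is(ref, "CodonUsageTable"))
  .cousinFromTables(codonCounts(query), ref)
}

.cousinFromTables <- function(qCounts, ref) {
  code <- geneticCode(ref)
  fams <- codonFamilies(code)
  deg <- degeneracy(code)
  fr <- synonymousFreq(ref)
  num <- den <- wt <- numeric(0)
  for (aa in names(fams)) {
    k <- deg[[aa]]
    if (k < 2L) next
    cc <- fams[[aa]]
    nq <- sum(qCounts[cc])
    if (nq == 0) next
    fra <- fr[cc]
    if (anyNA(fra)) next                       # family unseen in reference
    e <- 1 / k
    d <- sum(fra * (fra - e))
    if (d <= 0) next                           # uniform reference family
    fq <- qCounts[cc] / nq
    num <- c(num, sum(fq * (fra - e)))
    den <- c(den, d)
    wt <- c(wt, nq)
  }
  if (length(num) == 0L) {
    warning("COUSIN undefined: no informative family shared with the reference")
    return(list(cousin18 = NA_real_, cousin59 = NA_real_))
  }
  list(cousin18 = mean(num / den),
       cousin59 = sum(wt * num) / sum(wt * den))
}

#' ScoreSet: per-CDS CAI and COUSIN scores against a reference
#'
#' One row per query CDS with its CAI, COUSIN18 and COUSIN59 values against a
#' reference codon usage table. Undefined scores are kept as NA, never
#' dropped.
#'
#' @slot queryLabel label of the query set
#' @slot referenceLabel label of the reference table
#' @slot scores data.frame(cds_id, cai, cousin18, cousin59)
#' @seealso [scoreSet()], [compareDistributions()]
#' @export
setClass("ScoreSet",
  representation(
    queryLabel = "character",
    referenceLabel = "character",
    scores = "data.frame"
  )
)

setValidity("ScoreSet", function(object) {
  need <- c("cds_id", "cai", "cousin18", "cousin59")
  if (!all(need %in% names(object@scores)))
    return("scores must have columns cds_id, cai, cousin18, cousin59")
  ok <- is.na(object@scores$cai) |
    (object@scores$cai >= 0 & object@scores$cai <= 1)
  if (!all(ok)) return("cai must lie in [0, 1]")
  TRUE
})

#' Score every CDS of a query set against a reference table
#'
#' @param queries a [CdsSet-class]
#' @param ref reference [CodonUsageTable-class]
#' @return a [ScoreSet-class]
#' @export
scoreSet <- function(queries, ref) {
  stopifnot(methods::is(queries, "CdsSet"), methods::is(ref, "CodonUsageTable"))
  codons <- cdsCodons(queries)
  if (length(codons) == 0L) stop("empty query set")
  sense <- senseCodons(geneticCode(ref))
  rows <- lapply(codons, function(cc) {
    cnt <- stats::setNames(numeric(length(sense)), sense)
    if (length(cc)) { tb <- table(cc); cnt[names(tb)] <- tb }
    cb <- suppressWarnings(.cousinFromTables(cnt, ref))
    c(cai = suppressWarnings(.caiFromCounts(cnt, ref)),
      cousin18 = cb$cousin18, cousin59 = cb$cousin59)
  })
  m <- do.call(rbind, rows)
  df <- data.frame(cds_id = names(codons), cai = m[, "cai"],
                   cousin18 = m[, "cousin18"], cousin59 = m[, "cousin59"],
                   row.names = NULL)
  new("ScoreSet", queryLabel = setLabel(queries),
      referenceLabel = ref@sourceLabel, scores = df)
}

#' Pooled (set-level) scores of a query set against a reference
#'
#' Pools the query's codon counts into one table and scores that table,
#' complementing the per-CDS distributions of [scoreSet()].
#' @inheritParams scoreSet
#' @return named numeric: cai, cousin18, cousin59
#' @export
pooledScores <- function(queries, ref) {
  tab <- codonUsageTable(queries, code = geneticCode(ref))
  cb <- cousinBoth(tab, ref)
  c(cai = cai(tab, ref), cousin18 = cb$cousin18, cousin59 = cb$cousin59)
}

#' @describeIn ScoreSet-class the per-CDS score table
#' @param x a ScoreSet
#' @export
scoreTable <- function(x) x@scores

#' @export
#' @describeIn ScoreSet-class coerce to data.frame
setMethod("as.data.frame", "ScoreSet",
  function(x, row.names = NULL, optional = FALSE, ...) x@scores)

setMethod("show", "ScoreSet", function(object) {
  cat("ScoreSet:", object@queryLabel, "vs", object@referenceLabel, "\n")
  df <- object@scores
  cat(" ", nrow(df), "CDSs;",
      sum(is.na(df$cousin59)), "undefined\n")
  cat("  median cousin59:", round(stats::median(df$cousin59, na.rm = TRUE), 4),
      " median cai:", round(stats::median(df$cai, na.rm = TRUE), 4), "\n")
})

#' Write a ScoreSet as TSV
#' @param x a [ScoreSet-class]
#' @param path output path
#' @export
writeScoreSet <- function(x, path) {
  df <- scoreTable(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
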