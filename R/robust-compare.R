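#' @include codon-indices.R
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL uses the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Huber M-estimator of location
#'
#' Iterated winsorized mean with the scale fixed at the MAD: starting from the
#' median, observations are clipped to within k scale units of the current
#' centre and averaged, until the centre moves by less than `tol` scale units.
#' When the MAD is zero the median is returned.
#'
#' @param values numeric vector (NAs dropped)
#' @param k winsorizing constant in MAD units (default 1.5, the conventional
#'   default of robust-location routines)
#' @param tol relative convergence tolerance
#' @param maxIter iteration cap
#' @return the location estimate
#' @examples
#' huberLocation(c(1, 2, 3, 100))
#' @export
huberLocation <- function(values, k = 1.5, tol = 1e-6, maxIter = 50L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  s <- madScale(values)
  mu <- stats::median(values)
  if (s == 0) return(mu)
  for (i in seq_len(maxIter)) {
    mu1 <- mean(pmin(pmax(values, mu - k * s), mu + k * s))
    if (abs(mu1 - mu) < tol * s) return(mu1)
    mu <- mu1
  }
  mu
}

#' Median absolute deviation (normal-consistent)
#'
#' constant * median(|x - median(x)|); the default constant 1.4826 makes the
#' MAD consistent for the standard deviation under normality.
#'
#' @param values numeric vector (NAs dropped)
#' @param constant consistency constant
#' @return the MAD (>= 0)
#' @export
madScale <- function(values, constant = 1.4826) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  stats::mad(values, constant = constant)
}

#' Wilcoxon rank-sum test with continuity correction
#'
#' Mann-Whitney rank-sum statistic with mid-ranks for ties and a two-sided
#' p-value from the normal approximation with tie-corrected variance and 0.5
#' continuity correction (the conventional large-sample form). Degenerate
#' input with every value identical across both samples is flagged and
#' returns p = 1 by convention.
#'
#' @param x,y numeric samples (NAs dropped)
#' @param continuity apply the 0.5 continuity correction
#' @return list with `W` (rank-sum statistic of x, Mann-Whitney form), `p`
#'   (two-sided), and `degenerate` flag
#' @export
wilcoxonRankSum <- function(x, y, continuity = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(W = length(x) * length(y) / 2, p = 1, degenerate = TRUE))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = continuity)
  )
  list(W = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Hodges-Lehmann location difference
#'
#' Median of all pairwise differences host_i - virus_j, the standard shift
#' estimate reported alongside a rank-sum test. When the number of pairs
#' exceeds `maxPairs`, a seeded uniform subsample of pairs is used.
#'
#' @param host,virus numeric score vectors (NAs dropped); the result is
#'   oriented host - virus
#' @param maxPairs largest number of pairs enumerated exactly
#' @param seed seed for the pair subsample (only used when subsampling)
#' @return the shift estimate
#' @examples
#' locationDifference(c(3, 4, 5), c(1, 2, 3))  # 2
#' @export
locationDifference <- function(host, virus, maxPairs = 1e7, seed = NULL) {
  host <- host[is.finite(host)]; virus <- virus[is.finite(virus)]
  if (length(host) == 0L || length(virus) == 0L)
    stop("both samples must be non-empty")
  np <- as.double(length(host)) * length(virus)
  if (np <= maxPairs)
    return(stats::median(outer(host, virus, `-`)))
  .withSeed(seed, {
    i <- sample.int(length(host), maxPairs, replace = TRUE)
    j <- sample.int(length(virus), maxPairs, replace = TRUE)
    stats::median(host[i] - virus[j])
  })
}

#' ComparisonSummary: robust comparison of virus and host score distributions
#'
#' Holds everything reported per virus-host panel: Huber-M centre and MAD of
#' each group, the Hodges-Lehmann location difference oriented host - virus,
#' the Wilcoxon rank-sum statistic and two-sided p-value, sample sizes, and
#' the empirical 2.5/50/97.5 percentiles of each group.
#'
#' @seealso [compareDistributions()]
#' @export
setClass("ComparisonSummary",
  representation(
    virusLabel = "character", hostLabel = "character",
    huberVirus = "numeric", madVirus = "numeric",
    huberHost = "numeric", madHost = "numeric",
    locationDifference = "numeric",
    wilcoxonW = "numeric", pValue = "numeric",
    nVirus = "integer", nHost = "integer",
    ci95Virus = "numeric", ci95Host = "numeric"
  )
)

setValidity("ComparisonSummary", function(object) {
  msg <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (object@madVirus < 0 || object@madHost < 0)
    msg <- c(msg, "MAD must be non-negative")
  if (object@nVirus < 1L || object@nHost < 1L)
    msg <- c(msg, "both groups need at least one value")
  if (length(msg)) msg else TRUE
})

#' Compare virus and host score distributions
#'
#' Computes the full robust comparison of two per-CDS score distributions
#' (typically COUSIN59 columns from [scoreSet()]): Huber-M and MAD per group,
#' Wilcoxon rank-sum with continuity correction, and the Hodges-Lehmann
#' location difference oriented host - virus (so an opposite-preference virus
#' against a self-similar host yields a positive difference, and an
#' exaggerated-preference virus a negative one).
#'
#' @param virus,host numeric score vectors (NAs dropped)
#' @param virusLabel,hostLabel labels carried into the summary
#' @param maxPairs,seed passed to [locationDifference()]
#' @return a [ComparisonSummary-class]
#' @export
compareDistributions <- function(virus, host,
                                 virusLabel = "virus", hostLabel = "host",
                                 maxPairs = 1e7, seed = NULL) {
  virus <- virus[is.finite(virus)]; host <- host[is.finite(host)]
  if (length(virus) == 0L || length(host) == 0L)
    stop("both score vectors must contain finite values")
  wt <- wilcoxonRankSum(host, virus)
  q <- c(0.025, 0.5, 0.975)
  new("ComparisonSummary",
      virusLabel = virusLabel, hostLabel = hostLabel,
      huberVirus = huberLocation(virus), madVirus = madScale(virus),
      huberHost = huberLocation(host), madHost = madScale(host),
      locationDifference = locationDifference(host, virus,
                                              maxPairs = maxPairs, seed = seed),
      wilcoxonW = wt$W, pValue = wt$p,
      nVirus = length(virus), nHost = length(host),
      ci95Virus = stats::quantile(virus, q, names = FALSE),
      ci95Host = stats::quantile(host, q, names = FALSE))
}

# conventional reporting style for vanishingly small p-values
.formatP <- function(p) if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 4)

setMethod("show", "ComparisonSummary", function(object) {
  cat("ComparisonSummary:", object@virusLabel, "vs", object@hostLabel, "\n")
  cat(sprintf("  virus (n = %d): Huber-M %.3f, MAD %.3f\n",
              object@nVirus, object@huberVirus, object@madVirus))
  cat(sprintf("  host  (n = %d): Huber-M %.3f, MAD %.3f\n",
              object@nHost, object@huberHost, object@madHost))
  cat(sprintf("  location difference (host - virus) = %.3f, W = %.1f, P %s\n",
              object@locationDifference, object@wilcoxonW,
              .formatP(object@pValue)))
})

#' Coerce a ComparisonSummary to a plain list
#' @param x a [ComparisonSummary-class]
#' @return named list of all fields (p-value at full precision)
#' @export
summaryAsList <- function(x) {
  list(virus_label = x@virusLabel, host_label = x@hostLabel,
       huber_virus = x@huberVirus, mad_virus = x@madVirus,
       huber_host = x@huberHost, mad_host = x@madHost,
       location_difference = x@locationDifference,
       wilcoxon_W = x@wilcoxonW, p_value = x@pValue,
       p_printed = .formatP(x@pValue),
       n_virus = x@nVirus, n_host = x@nHost,
       ci95_virus = x@ci95Virus, ci95_host = x@ci95Host)
}

#' Write a ComparisonSummary as JSON or TSV
#' @param x a [ComparisonSummary-class]
#' @param path output path
#' @param format "json" or "tsv"
#' @export
writeComparisonSummary <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  l <- summaryAsList(x)
  if (format == "json") {
    jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    flat <- l[!vapply(l, function(v) length(v) > 1L, logical(1))]
    flat <- lapply(flat, function(v) if (is.numeric(v)) signif(v, 6L) else v)
    utils::write.table(as.data.frame(flat), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Per-gene ENC-GC3 points for a CDS set
#'
#' @param set a [CdsSet-class]
#' @param estimator ENC estimator, see [enc()]
#' @return data.frame(gene_id, s, enc): s is GC3; genes with undefined values
#'   carry NA
#' @export
encPoints <- function(set, estimator = "bias_corrected") {
  data.frame(gene_id = names(cdsCodons(set)),
             s = unname(gc3(set)),
             enc = unname(enc(set, estimator = estimator)),
             row.names = NULL)
}

#' EncPlotData: ENC-GC3 points with the null curve and expression flags
#'
#' @slot points data.frame(gene_id, s, enc, highly_expressed)
#' @slot nullCurve data.frame(s, enc) sampled from [encNull()]
#' @slot topFraction fraction of genes flagged as highly expressed
#' @slot report list: ids missing from the expression table, tie warnings
#' @seealso [flagTopExpressed()]
#' @export
setClass("EncPlotData",
  representation(
    points = "data.frame",
    nullCurve = "data.frame",
    topFraction = "numeric",
    report = "list"
  )
)

#' Flag the most highly expressed genes on an ENC plot
#'
#' Flags exactly ceiling(fraction * N) genes with the highest expression
#' (N = number of ENC points), the proxy for highly expressed genes on
#' ENC-GC3 plots. Ties at the cutoff are broken by lexicographic gene id for
#' determinism (with a warning); genes absent from the expression table are
#' never flagged and are counted in the report.
#'
#' @param points data.frame(gene_id, s, enc) from [encPoints()]
#' @param expr expression table from [readExpressionTable()]
#' @param fraction top fraction to flag, in (0, 1]; default 0.05
#' @return an [EncPlotData-class]
#' @export
flagTopExpressed <- function(points, expr, fraction = 0.05) {
  stopifnot(is.data.frame(points), all(c("gene_id", "s", "enc") %in% names(points)))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  extra <- setdiff(expr$gene_id, points$gene_id)
  if (length(extra))
    stop("expression ids absent from the point set: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  nFlag <- ceiling(fraction * nrow(points))
  known <- expr[expr$gene_id %in% points$gene_id, , drop = FALSE]
  ord <- order(-known$fpkm, known$gene_id)
  ranked <- known[ord, , drop = FALSE]
  take <- utils::head(ranked, nFlag)
  tieWarned <- FALSE
  if (nrow(ranked) > nFlag && nFlag > 0L &&
      ranked$fpkm[nFlag] == ranked$fpkm[nFlag + 1L]) {
    warning("expression ties at the cutoff broken by gene id")
    tieWarned <- TRUE
  }
  missing <- setdiff(points$gene_id, expr$gene_id)
  pts <- points
  pts$highly_expressed <- pts$gene_id %in% take$gene_id
  sGrid <- seq(0, 1, by = 0.005)
  new("EncPlotData",
      points = pts,
      nullCurve = data.frame(s = sGrid, enc = encNull(sGrid)),
      topFraction = fraction,
      report = list(n_flagged = nrow(take),
                    n_missing_expression = length(missing),
                    missing_ids = missing, tie_at_cutoff = tieWarned))
}

setMethod("show", "EncPlotData", function(object) {
  cat("EncPlotData:", nrow(object@points), "genes,",
      sum(object@points$highly_expressed), "flagged as highly expressed",
      sprintf("(top %.0f%%)\n", 100 * object@topFraction))
})

#' Write ENC plot data as TSV
#'
#' Writes the point table (gene_id, s, enc, highly_expressed) to `path` and,
#' optionally, the sampled null curve next to it.
#' @param x an [EncPlotData-class]
#' @param path output TSV for the points
#' @param nullCurvePath optional output TSV for the null curve
#' @export
writeEncPlotData <- function(x, path, nullCurvePath = NULL) {
  pts <- x@points
  pts$s <- signif(pts$s, 6L); pts$enc <- signif(pts$enc, 6L)
  utils::write.table(pts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nullCurvePath)) {
    nc <- x@nullCurve
    nc$enc <- signif(nc$enc, 6L)
    utils::write.table(nc, nullCurvePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Plot ENC against GC3 with the no-selection null curve
#'
#' Base-graphics rendering of an ENC plot: one point per gene, highly
#' expressed genes highlighted, and the mutational-bias-only expectation as a
#' continuous curve.
#' @param x an [EncPlotData-class]
#' @param ... passed to [graphics::plot()]
#' @export
plotEnc <- function(x, ...) {
  pts <- x@points
  graphics::plot(pts$s, pts$enc, pch = 16, cex = 0.4,
                 col = ifelse(pts$highly_expressed, "dodgerblue3", "grey60"),
                 xlab = "GC3", ylab = "ENC", xlim = c(0, 1), ylim = c(15, 62),
                 ...)
  graphics::lines(x@nullCurve$s, x@nullCurve$enc, col = "red2", lwd = 2)
}
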