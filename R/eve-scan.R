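#' @include simulate.R
NULL

#' GcProfile: sliding-window GC/AT percentages along a contig
#'
#' Windowed nucleotide composition used to visualize candidate integrated
#' viral regions, whose GC content often departs sharply from the host
#' background. Percentages are computed over counted (non-N) bases; an all-N
#' window is NA. Coordinates are 0-based half-open throughout.
#'
#' @slot contigId contig name
#' @slot window,step window and step in bp
#' @slot profile data.frame(start, end, gc_pct, at_pct, n_bases, partial)
#' @seealso [gcProfile()], [regionGcContrast()]
#' @export
setClass("GcProfile",
  representation(
    contigId = "character",
    window = "integer",
    step = "integer",
    profile = "data.frame"
  )
)

setValidity("GcProfile", function(object) {
  p <- object@profile
  ok <- is.na(p$gc_pct) | (p$gc_pct + p$at_pct <= 100 + 1e-9)
  if (!all(ok)) return("gc_pct + at_pct must not exceed 100")
  if (is.unsorted(p$start)) return("windows must be ordered by start")
  TRUE
})

.asDnaString <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1L) stop("expected a single sequence")
    return(list(id = names(seq)[1L], s = seq[[1L]]))
  }
  if (methods::is(seq, "DNAString")) return(list(id = "contig", s = seq))
  if (is.character(seq) && length(seq) == 1L)
    return(list(id = "contig", s = Biostrings::DNAString(toupper(seq))))
  stop("seq must be a DNAString(Set) or a single character string")
}

#' Sliding-window GC/AT profile
#'
#' @param seq a [Biostrings::DNAString], one-element DNAStringSet, or a
#'   character string
#' @param window window size in bp (>= 1)
#' @param step step in bp (>= 1); step == window gives a partition
#' @param contigId contig name (taken from the DNAStringSet name when present)
#' @return a [GcProfile-class]; the trailing partial window is included and
#'   marked
#' @examples
#' p <- gcProfile("GGGGAAAA", window = 4, step = 4)
#' gcProfileTable(p)$gc_pct  # 100, 0
#' @export
gcProfile <- function(seq, window = 1000L, step = 500L, contigId = NULL) {
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  x <- .asDnaString(seq)
  if (is.null(contigId)) contigId <- x$id
  len <- length(x$s)
  if (len == 0L) stop("empty sequence")
  starts0 <- seq.int(0L, len - 1L, by = step)
  ends0 <- pmin(starts0 + window, len)
  v <- Biostrings::Views(x$s, start = starts0 + 1L, end = ends0)
  freq <- Biostrings::letterFrequency(v, letters = c("CG", "AT"))
  nBases <- freq[, "C|G"] + freq[, "A|T"]
  gc <- ifelse(nBases > 0, 100 * freq[, "C|G"] / nBases, NA_real_)
  at <- ifelse(nBases > 0, 100 * freq[, "A|T"] / nBases, NA_real_)
  prof <- data.frame(start = starts0, end = ends0, gc_pct = gc, at_pct = at,
                     n_bases = nBases, partial = (ends0 - starts0) < window)
  new("GcProfile", contigId = contigId, window = as.integer(window),
      step = as.integer(step), profile = prof)
}

#' @describeIn GcProfile-class the window table
#' @param x a GcProfile
#' @export
gcProfileTable <- function(x) x@profile

setMethod("show", "GcProfile", function(object) {
  p <- object@profile
  cat("GcProfile:", object@contigId,
      sprintf("(window %d, step %d, %d windows)\n",
              object@window, object@step, nrow(p)))
  cat("  GC%: ", paste(round(stats::quantile(p$gc_pct, c(0, .5, 1), na.rm = TRUE), 1),
                       collapse = " / "), " (min/median/max)\n", sep = "")
})

#' Write a GC profile as TSV or bedGraph
#' @param x a [GcProfile-class]
#' @param path output path
#' @param format "tsv" (full table) or "bedgraph" (contig, start, end, gc_pct)
#' @export
writeGcProfile <- function(x, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  p <- x@profile
  if (format == "tsv") {
    p$gc_pct <- signif(p$gc_pct, 6L); p$at_pct <- signif(p$at_pct, 6L)
    utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bg <- data.frame(chrom = x@contigId, start = p$start, end = p$end,
                     value = signif(p$gc_pct, 6L))
    utils::write.table(bg, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' GC contrast of a candidate region against its flanks
#'
#' Mean windowed GC inside versus outside a region (windows assigned by
#' midpoint) and their difference in percentage points — negative when the
#' region is AT-richer than the background, the typical signature of a viral
#' insertion in a GC-rich host.
#'
#' @param profile a [GcProfile-class]
#' @param region numeric c(start, end), 0-based half-open
#' @return list(gc_in, gc_out, delta); gc_out is NA (with a warning) when the
#'   region covers every window
#' @export
regionGcContrast <- function(profile, region) {
  stopifnot(methods::is(profile, "GcProfile"), length(region) == 2L)
  p <- profile@profile
  mid <- (p$start + p$end) / 2
  inside <- mid >= region[1L] & mid < region[2L]
  if (!any(inside)) stop("region overlaps no window")
  gcIn <- mean(p$gc_pct[inside], na.rm = TRUE)
  if (all(inside)) {
    warning("region covers the whole profile; no outside windows")
    return(list(gc_in = gcIn, gc_out = NA_real_, delta = NA_real_))
  }
  gcOut <- mean(p$gc_pct[!inside], na.rm = TRUE)
  list(gc_in = gcIn, gc_out = gcOut, delta = gcIn - gcOut)
}

#' Terminal inverted repeats at the ends of a candidate region
#'
#' Locally aligns the first `maxSearch` bp of the region against the reverse
#' complement of its last `maxSearch` bp (match +1, mismatch -1, gap -2) and
#' reports arm pairs of length >= `minArm` whose mismatch fraction (mismatches
#' plus indel characters over the arm length) is at most `maxMismatchFrac`.
#' Giant-virus insertions are typically flanked by such arms; their presence
#' supports a genuine integration over an assembly artifact.
#'
#' @param seq contig sequence (DNAString, one-element DNAStringSet, or string)
#' @param region numeric c(start, end) of the candidate region, 0-based
#'   half-open
#' @param minArm minimum arm length in bp (>= 4)
#' @param maxMismatchFrac tolerated mismatch fraction within the arm
#' @param maxSearch how far into each region end to search, bp
#' @return data.frame(left_start, left_end, right_start, right_end, arm_len,
#'   mismatches), 0-based half-open, longest arm first; zero rows when no arm
#'   qualifies
#' @export
findTerminalInvertedRepeats <- function(seq, region, minArm = 10L,
                                        maxMismatchFrac = 0.1,
                                        maxSearch = 2000L) {
  x <- .asDnaString(seq)
  len <- length(x$s)
  if (minArm < 4L) stop("minArm must be >= 4")
  if (region[1L] < 0 || region[2L] > len || region[1L] >= region[2L])
    stop("region must lie within the sequence")
  regLen <- region[2L] - region[1L]
  empty <- data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      arm_len = integer(0), mismatches = integer(0))
  if (regLen < 2L * minArm) {
    warning("region shorter than twice the minimum arm length")
    return(empty)
  }
  segMax <- min(maxSearch, floor(regLen / 2))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  # Scan at several terminal window sizes: genuine arms sit at the region
  # termini and survive tight windows, whereas a spurious internal alignment
  # that happens to outscore a short true arm in the widest window does not.
  segLens <- unique(pmax(pmin(segMax, c(segMax, 512L, 128L, 4L * minArm)),
                         minArm))
  hits <- empty
  for (segLen in segLens) {
    left <- Biostrings::subseq(x$s, start = region[1L] + 1L, width = segLen)
    right <- Biostrings::subseq(x$s, start = region[2L] - segLen + 1L,
                                width = segLen)
    rcRight <- Biostrings::reverseComplement(right)
    aln <- Biostrings::pairwiseAlignment(left, rcRight, type = "local",
                                         substitutionMatrix = sm,
                                         gapOpening = 0, gapExtension = 2)
    pr <- aln@pattern@range
    sr <- aln@subject@range
    armLen <- max(IRanges::width(pr), IRanges::width(sr))
    ni <- Biostrings::nindel(aln)
    nIndel <- Biostrings::insertion(ni)[1L, "WidthSum"] +
      Biostrings::deletion(ni)[1L, "WidthSum"]
    mism <- Biostrings::nmismatch(aln) + nIndel
    if (armLen < minArm || mism / armLen > maxMismatchFrac) next
    a0 <- region[1L]
    hits <- rbind(hits, data.frame(
      left_start = a0 + IRanges::start(pr) - 1L,
      left_end = a0 + IRanges::end(pr),
      right_start = region[2L] - IRanges::end(sr),
      right_end = region[2L] - IRanges::start(sr) + 1L,
      arm_len = as.integer(armLen),
      mismatches = as.integer(mism)))
  }
  hits <- hits[!duplicated(hits[, c("left_start", "left_end",
                                    "right_start", "right_end")]), ,
               drop = FALSE]
  hits <- hits[order(-hits$arm_len, hits$mismatches), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read candidate regions from a 3+ column BED file
#' @param path BED path (chrom, start, end, 0-based half-open; no header)
#' @return data.frame(chrom, start, end)
#' @export
readRegionsBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("BED needs at least chrom, start, end")
  df <- df[, 1:3]
  names(df) <- c("chrom", "start", "end")
  if (any(df$start < 0) || any(df$end <= df$start))
    stop("malformed BED intervals")
  df
}

#' Write inverted-repeat hits as BED and/or JSON
#' @param hits data.frame from [findTerminalInvertedRepeats()]
#' @param contigId contig name for the BED rows
#' @param bedPath,jsonPath output paths (either may be NULL)
#' @export
writeTirHits <- function(hits, contigId, bedPath = NULL, jsonPath = NULL) {
  if (!is.null(bedPath)) {
    if (nrow(hits)) {
      bed <- data.frame(
        chrom = contigId,
        start = c(hits$left_start, hits$right_start),
        end = c(hits$left_end, hits$right_end),
        name = rep(sprintf("tir_arm_%d", seq_len(nrow(hits))), 2L))
      bed <- bed[order(bed$start), ]
      utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else file.create(bedPath)
  }
  if (!is.null(jsonPath))
    jsonlite::write_json(hits, jsonPath, dataframe = "rows", pretty = TRUE)
  invisible(NULL)
}
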