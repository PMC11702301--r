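#' @include genetic-code.R
NULL

#' CdsSet: a validated set of coding sequences
#'
#' Container for the CDS collections every statistic operates on: host
#' genome-wide CDS sets and viral CDS sets pooled at the species, genus or
#' family level. Sequences are validated on construction: lowercase is
#' upper-cased, ambiguity codes other than N are mapped to N, trailing 1-2 nt
#' of an incomplete terminal codon are trimmed (with a warning), and per-CDS
#' codon lists are pre-computed under the counting rules shared by all
#' downstream statistics (codons containing N excluded; counting stops before
#' the first in-frame stop codon, so terminal stops and post-stop sequence of
#' pseudogenized genes never enter any count).
#'
#' @slot label taxon/group name
#' @slot rank one of "species", "genus", "family", "host"
#' @slot sequences a [Biostrings::DNAStringSet] (validated, length multiple of 3)
#' @slot codons list of per-CDS counted codon vectors (parallel to sequences)
#' @slot loadReport list of per-rule validation counts
#'
#' @seealso [readCdsFasta()], [codonUsageTable()], [scoreSet()]
#' @export
setClass("CdsSet",
  representation(
    label = "character",
    rank = "character",
    sequences = "DNAStringSet",
    codons = "list",
    loadReport = "list"
  )
)

setValidity("CdsSet", function(object) {
  msg <- character()
  if (!object@rank %in% c("species", "genus", "family", "host"))
    msg <- c(msg, "rank must be one of species/genus/family/host")
  if (length(object@sequences) == 0L)
    msg <- c(msg, "CdsSet must contain at least one sequence")
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "member ids must be present and unique")
  if (any(Biostrings::width(object@sequences) %% 3L != 0L))
    msg <- c(msg, "sequence lengths must be multiples of 3 after validation")
  if (length(object@codons) != length(object@sequences))
    msg <- c(msg, "codons cache must parallel sequences")
  if (length(msg)) msg else TRUE
})

# Split one validated sequence into counted codons: drop codons containing N,
# stop counting before the first in-frame stop codon.
.codonize <- function(s, stops) {
  n <- nchar(s)
  if (n < 3L) return(list(codons = character(0), nN = 0L, stopped = FALSE))
  starts <- seq.int(1L, n - 2L, by = 3L)
  cod <- substring(s, starts, starts + 2L)
  hit <- which(cod %in% stops)
  stopped <- length(hit) > 0L
  if (stopped) cod <- cod[seq_len(hit[1L] - 1L)]
  hasN <- grepl("N", cod, fixed = TRUE)
  list(codons = cod[!hasN], nN = sum(hasN), stopped = stopped)
}

#' Construct a CdsSet from sequences
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet];
#'   names are the unique CDS ids
#' @param label taxon or group name
#' @param rank taxonomic rank of the pool: "species", "genus", "family" or "host"
#' @param code genetic code (standard nuclear code by default)
#' @return a [CdsSet-class]; its `loadReport()` records how many sequences
#'   were trimmed, how many codons were dropped for containing N, and how many
#'   CDSs were truncated at an internal stop codon
#' @examples
#' s <- cdsSet(c(g1 = "ATGGCTGCTTAA"), label = "toy")
#' loadReport(s)$n_sequences
#' @export
cdsSet <- function(sequences, label = "unnamed", rank = "species",
                   code = standardGeneticCode()) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (length(sequences) == 0L)
    stop("empty sequence set for '", label, "'")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every CDS needs an id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate CDS id(s): ", paste(unique(dup), collapse = ", "))

  seqs <- toupper(sequences)
  # IUPAC ambiguity codes other than N carry too little information for codon
  # counting; collapse them to N so one exclusion rule applies.
  seqs <- gsub("[^ACGTN]", "N", seqs)
  len <- nchar(seqs)
  extra <- len %% 3L
  nTrim <- sum(extra != 0L)
  if (nTrim > 0L) {
    warning(nTrim, " sequence(s) trimmed to a multiple of 3 nt")
    seqs <- substr(seqs, 1L, len - extra)
  }
  keep <- nchar(seqs) >= 3L
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    warning(nDropped, " sequence(s) shorter than one codon dropped")
  seqs <- seqs[keep]
  if (length(seqs) == 0L)
    stop("no sequence of at least one codon left after validation")

  stops <- stopCodons(code)
  parts <- lapply(unname(seqs), .codonize, stops = stops)
  codons <- lapply(parts, `[[`, "codons")
  names(codons) <- names(seqs)
  report <- list(
    n_sequences = length(seqs),
    n_trimmed = nTrim,
    n_dropped_short = nDropped,
    n_codons_with_N = sum(vapply(parts, `[[`, integer(1), "nN")),
    n_stop_truncated = sum(vapply(parts, `[[`, logical(1), "stopped"))
  )
  new("CdsSet", label = label, rank = rank,
      sequences = Biostrings::DNAStringSet(seqs),
      codons = codons, loadReport = report)
}

#' Read a CDS set from a nucleotide FASTA file
#'
#' @param path FASTA file (multi-record, wrapped or single-line)
#' @param label taxon/group label; defaults to the file name
#' @param rank pool rank, see [cdsSet()]
#' @param code genetic code
#' @return a [CdsSet-class]
#' @export
readCdsFasta <- function(path, label = NULL, rank = "species",
                         code = standardGeneticCode()) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  cdsSet(x, label = label, rank = rank, code = code)
}

#' Write a CdsSet to FASTA
#'
#' Writes the validated sequences; a write/read round trip preserves ids and
#' sequences exactly.
#' @param set a [CdsSet-class]
#' @param path output FASTA path
#' @export
writeCdsFasta <- function(set, path) {
  Biostrings::writeXStringSet(sequences(set), path, width = 70L)
  invisible(path)
}

#' @describeIn CdsSet-class validated sequences as a DNAStringSet
#' @param set a CdsSet
#' @export
sequences <- function(set) set@sequences

#' @describeIn CdsSet-class per-CDS counted codon vectors
#' @export
cdsCodons <- function(set) set@codons

#' @describeIn CdsSet-class label of the set
#' @export
setLabel <- function(set) set@label

#' @describeIn CdsSet-class validation counts recorded on load
#' @export
loadReport <- function(set) set@loadReport

#' Write a load report as JSON
#' @param set a [CdsSet-class]
#' @param path output path
#' @export
writeLoadReport <- function(set, path) {
  jsonlite::write_json(loadReport(set), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

setMethod("show", "CdsSet", function(object) {
  cat("CdsSet:", object@label, sprintf("(rank: %s)\n", object@rank))
  cat(" ", length(object@sequences), "CDSs,",
      sum(lengths(object@codons)), "counted codons\n")
  r <- object@loadReport
  cat("  trimmed:", r$n_trimmed, " N-codons dropped:", r$n_codons_with_N,
      " stop-truncated:", r$n_stop_truncated, "\n")
})

#' Read a per-gene expression table
#'
#' Expects a TSV with header columns `gene_id` and `fpkm`. Rows that do not
#' have two fields or a numeric fpkm are rejected with their line numbers;
#' negative fpkm or duplicated gene ids are errors.
#'
#' @param path TSV file
#' @return data.frame with columns `gene_id` (character) and `fpkm` (numeric)
#' @export
readExpressionTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty expression table: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header[1:2], c("gene_id", "fpkm")))
    stop("expression table must have header gene_id<TAB>fpkm")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(data.frame(gene_id = character(0), fpkm = numeric(0)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  fpkm <- suppressWarnings(
    as.numeric(vapply(fields, function(f) f[2L][1L], character(1)))
  )
  bad <- sort(union(bad, which(is.na(fpkm))))
  if (length(bad)) {
    warning("rejected ", length(bad), " malformed row(s) at line(s): ",
            paste(bad + 1L, collapse = ", "))
    fields <- fields[-bad]
    fpkm <- fpkm[-bad]
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  neg <- which(fpkm < 0)
  if (length(neg))
    stop("negative fpkm at line(s): ",
         paste(setdiff(seq_along(body), bad)[neg] + 1L, collapse = ", "))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  data.frame(gene_id = ids, fpkm = fpkm)
}
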