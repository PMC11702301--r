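#' @include genetic-code.R cds-set.R
NULL

#' CodonUsageTable: pooled codon counts and synonymous frequencies
#'
#' The central summary every index is computed from: counts of the 61 sense
#' codons (stop codons never enter any count), the within-family relative
#' synonymous frequencies f(c) = count(c) / count(aa), the per-amino-acid
#' totals, and the equal-usage null frequencies e_a = 1/k_a for each family of
#' degeneracy k_a. Tables can be built per gene or pooled over a whole CDS set
#' (species, genus or family level).
#'
#' @slot sourceLabel label of the sequence set the counts came from
#' @slot counts named numeric (61 sense codons), non-negative integers
#' @slot fSyn named numeric: relative synonymous frequency per codon; NA for
#'   codons of unobserved families
#' @slot aaCounts named numeric: total count per amino acid
#' @slot code the [GeneticCode-class] the family structure derives from
#'
#' @seealso [codonUsageTable()], [enc()], [cai()], [cousin()]
#' @export
setClass("CodonUsageTable",
  representation(
    sourceLabel = "character",
    counts = "numeric",
    fSyn = "numeric",
    aaCounts = "numeric",
    code = "GeneticCode"
  )
)

setValidity("CodonUsageTable", function(object) {
  msg <- character()
  sense <- senseCodons(object@code)
  if (!identical(names(object@counts), sense))
    msg <- c(msg, "counts must be named by the sense codons, in code order")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  fams <- codonFamilies(object@code)
  for (aa in names(fams)) {
    tot <- sum(object@counts[fams[[aa]]])
    if (tot > 0) {
      s <- sum(object@fSyn[fams[[aa]]])
      if (abs(s - 1) > 1e-12)
        msg <- c(msg, sprintf("f_syn for family %s does not sum to 1", aa))
    }
  }
  if (length(msg)) msg else TRUE
})

.tableFromCounts <- function(counts, label, code) {
  sense <- senseCodons(code)
  full <- stats::setNames(numeric(length(sense)), sense)
  bad <- setdiff(names(counts), sense)
  if (length(bad))
    stop("not sense codons of the code: ", paste(bad, collapse = ", "))
  full[names(counts)] <- counts
  fams <- codonFamilies(code)
  aaCounts <- vapply(fams, function(cc) sum(full[cc]), numeric(1))
  fSyn <- stats::setNames(rep(NA_real_, length(sense)), sense)
  for (aa in names(fams)) {
    if (aaCounts[[aa]] > 0)
      fSyn[fams[[aa]]] <- full[fams[[aa]]] / aaCounts[[aa]]
  }
  new("CodonUsageTable", sourceLabel = label, counts = full,
      fSyn = fSyn, aaCounts = aaCounts, code = code)
}

#' Build a codon usage table
#'
#' @param x a [CdsSet-class] (counts pooled over all members), a character
#'   vector of codons, or a named numeric vector of per-codon counts
#' @param label source label recorded in the table
#' @param code genetic code
#' @return a [CodonUsageTable-class]
#' @examples
#' s <- cdsSet(c(g = "ATGGCTGCTTAA"), label = "toy")
#' tab <- codonUsageTable(s)
#' codonCounts(tab)[c("ATG", "GCT")]
#' @export
setGeneric("codonUsageTable",
  function(x, label = NULL, code = standardGeneticCode())
    standardGeneric("codonUsageTable"))

#' @rdname codonUsageTable
setMethod("codonUsageTable", "CdsSet", function(x, label, code) {
  codons <- unlist(cdsCodons(x), use.names = FALSE)
  if (length(codons) == 0L)
    stop("no counted codons in set '", setLabel(x), "' (all N or empty)")
  if (is.null(label)) label <- setLabel(x)
  .tableFromCounts(table(codons), label, code)
})

#' @rdname codonUsageTable
setMethod("codonUsageTable", "character", function(x, label, code) {
  if (is.null(label)) label <- "codons"
  if (length(x) == 0L) stop("no codons supplied")
  .tableFromCounts(table(x), label, code)
})

#' @rdname codonUsageTable
setMethod("codonUsageTable", "numeric", function(x, label, code) {
  if (is.null(names(x))) stop("counts must be named by codon")
  if (is.null(label)) label <- "counts"
  .tableFromCounts(x, label, code)
})

#' @describeIn CodonUsageTable-class per-codon counts (61 sense codons)
#' @param tab a CodonUsageTable
#' @export
codonCounts <- function(tab) tab@counts

#' @describeIn CodonUsageTable-class relative synonymous frequencies
#' @export
synonymousFreq <- function(tab) tab@fSyn

#' @describeIn CodonUsageTable-class per-amino-acid totals
#' @export
aaCounts <- function(tab) tab@aaCounts

#' @describeIn CodonUsageTable-class equal-usage null frequency 1/k per codon
#' @export
equalUsageFreq <- function(tab) {
  deg <- degeneracy(tab@code)
  aa <- codonToAa(tab@code)[names(tab@counts)]
  stats::setNames(1 / as.numeric(deg[aa]), names(tab@counts))
}

#' @describeIn CodonUsageTable-class the genetic code of the table
#' @export
geneticCode <- function(tab) tab@code

setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable:", object@sourceLabel, "\n")
  cat(" ", sum(object@counts), "codons over",
      sum(object@aaCounts > 0), "amino acids;",
      "GC3 =", round(gc3(object), 4), "\n")
})

#' Write a codon usage table as TSV
#'
#' 64 rows (codon, aa, count, f_syn); stop codons carry count 0 and empty
#' f_syn.
#' @param tab a [CodonUsageTable-class]
#' @param path output path
#' @export
writeCodonUsageTable <- function(tab, path) {
  code <- tab@code
  codons <- allCodons()
  aa <- codonToAa(code)[codons]
  count <- ifelse(aa == "*", 0, tab@counts[codons])
  fsyn <- ifelse(aa == "*", NA_real_, tab@fSyn[codons])
  df <- data.frame(codon = codons, aa = unname(aa),
                   count = unname(count), f_syn = unname(fsyn))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a codon usage table written by [writeCodonUsageTable()]
#' @param path TSV path
#' @param label source label; defaults to file name
#' @param code genetic code
#' @return a [CodonUsageTable-class]
#' @export
readCodonUsageTable <- function(path, label = NULL, code = standardGeneticCode()) {
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "numeric", "numeric"))
  if (!all(c("codon", "aa", "count") %in% names(df)))
    stop("expected columns codon, aa, count")
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  keep <- df$aa != "*"
  counts <- stats::setNames(df$count[keep], df$codon[keep])
  .tableFromCounts(counts[senseCodons(code)], label, code)
}
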