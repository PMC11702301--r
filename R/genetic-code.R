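#' GeneticCode: codon-to-amino-acid map with synonymous family structure
#'
#' Represents a genetic code as the map from the 64 trinucleotides over
#' \{A,C,G,T\} to amino acids (one-letter symbols, \code{"*"} for stop),
#' together with the derived synonymous-family structure used by every
#' codon-usage statistic in the package: for each amino acid the ordered list
#' of its synonymous codons and its degeneracy (1, 2, 3, 4 or 6).
#'
#' Under the standard nuclear code there are 3 stop codons, 2 single-codon
#' amino acids (Met, Trp) and 18 degenerate families with degeneracies
#' \{2: nine families, 3: one, 4: five, 6: three\}.
#'
#' @slot name label for the code
#' @slot codonToAa named character of length 64; values are amino-acid
#'   one-letter symbols or \code{"*"}
#' @slot families named list: amino acid -> character vector of its codons,
#'   alphabetically ordered
#' @slot degeneracy named integer: amino acid -> family size
#'
#' @export
setClass("GeneticCode",
  representation(
    name = "character",
    codonToAa = "character",
    families = "list",
    degeneracy = "integer"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- character()
  if (length(object@codonToAa) != 64L)
    msg <- c(msg, "codonToAa must map exactly 64 codons")
  if (!setequal(names(object@codonToAa), allCodons()))
    msg <- c(msg, "codonToAa names must be the 64 trinucleotides over ACGT")
  aas <- setdiff(unique(object@codonToAa), "*")
  if (!setequal(names(object@families), aas))
    msg <- c(msg, "families must cover every non-stop amino acid")
  for (aa in names(object@families)) {
    fam <- object@families[[aa]]
    if (!identical(sort(fam), sort(names(object@codonToAa)[object@codonToAa == aa])))
      msg <- c(msg, sprintf("family for %s does not partition the code", aa))
    if (!identical(object@degeneracy[[aa]], length(fam)))
      msg <- c(msg, sprintf("degeneracy for %s disagrees with family size", aa))
  }
  if (length(msg)) msg else TRUE
})

#' All 64 codons over the DNA alphabet
#' @return character vector of 64 trinucleotides, alphabetical
#' @keywords internal
allCodons <- function() {
  b <- c("A", "C", "G", "T")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

#' The standard nuclear genetic code (translation table 1)
#'
#' Built from \code{Biostrings::GENETIC_CODE}. This is the only code the
#' package uses; organelle codes are out of scope.
#'
#' @return a [GeneticCode-class] object
#' @examples
#' code <- standardGeneticCode()
#' degeneracy(code)[c("M", "W", "L")]
#' @export
standardGeneticCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc))
  map <- as.character(gc[codons])
  names(map) <- codons
  aas <- sort(setdiff(unique(map), "*"))
  fams <- lapply(aas, function(a) sort(codons[map == a]))
  names(fams) <- aas
  deg <- vapply(fams, length, integer(1))
  new("GeneticCode", name = "standard", codonToAa = map,
      families = fams, degeneracy = deg)
}

#' @describeIn GeneticCode-class amino acid for each sense/stop codon
#' @param code a GeneticCode
#' @export
codonToAa <- function(code) code@codonToAa

#' @describeIn GeneticCode-class synonymous families (amino acid -> codons)
#' @export
codonFamilies <- function(code) code@families

#' @describeIn GeneticCode-class degeneracy class of each amino acid
#' @export
degeneracy <- function(code) code@degeneracy

#' @describeIn GeneticCode-class stop codons of the code
#' @export
stopCodons <- function(code) names(code@codonToAa)[code@codonToAa == "*"]

#' @describeIn GeneticCode-class the sense (non-stop) codons, alphabetical
#' @export
senseCodons <- function(code) names(code@codonToAa)[code@codonToAa != "*"]

setMethod("show", "GeneticCode", function(object) {
  deg <- object@degeneracy
  cat("GeneticCode:", object@name, "\n")
  cat(" ", length(object@codonToAa), "codons,",
      length(stopCodons(object)), "stops,",
      sum(deg >= 2), "degenerate families\n")
  tab <- table(deg[deg >= 2])
  cat("  degeneracy classes:",
      paste(sprintf("%s-fold x %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})
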