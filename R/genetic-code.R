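## Genetic-code helpers used throughout the package. All codons are handled
## as 3-letter DNA strings (T, not U); transcription happens only at the
## RNA-energetics boundary.

#' Translate DNA codons under the standard genetic code
#'
#' @param codons character vector of 3-letter DNA codons (case-insensitive).
#' @return character vector of one-letter amino acids; `"*"` for stops.
#' @examples
#' translateCodons(c("AAA", "CTG", "TAA"))
#' @export
translateCodons <- function(codons) {
    codons <- toupper(as.character(codons))
    bad <- !grepl("^[ACGT]{3}$", codons)
    if (any(bad)) {
        stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "))
    }
    unname(Biostrings::GENETIC_CODE[codons])
}

#' Synonymous codons of a codon
#'
#' Returns every codon encoding the same amino acid, excluding the input
#' codon itself. A stop codon is rejected.
#'
#' @param codon single 3-letter DNA codon.
#' @return character vector (possibly empty, e.g. for ATG).
#' @examples
#' synonymousCodons("AAA")  # "AAG"
#' synonymousCodons("ATG")  # character(0)
#' @export
synonymousCodons <- function(codon) {
    aa <- translateCodons(codon)
    if (aa == "*") stop("stop codon has no synonymous sense codons: ", codon)
    gc <- Biostrings::GENETIC_CODE
    setdiff(names(gc)[gc == aa], toupper(codon))
}

#' Test synonymy of codon pairs
#'
#' @param a,b character vectors of DNA codons, recycled to common length.
#' @return logical vector: do `a` and `b` encode the same amino acid?
#' @export
isSynonymous <- function(a, b) {
    translateCodons(a) == translateCodons(b)
}

## Split a nucleotide string into codons; errors if not a multiple of 3.
codonsOf <- function(sequence) {
    sequence <- toupper(gsub("\\s", "", as.character(sequence)[1L]))
    if (nchar(sequence) %% 3L != 0L) {
        stop("sequence length ", nchar(sequence), " is not a multiple of 3")
    }
    substring(sequence,
              seq(1L, nchar(sequence), by = 3L),
              seq(3L, nchar(sequence), by = 3L))
}

## Canonical variant label "<AA><position>_<mutCodon>", e.g. "K4_AAA".
variantLabel <- function(position, wtCodon, mutCodon) {
    paste0(translateCodons(wtCodon), position, "_", toupper(mutCodon))
}

gcCount <- function(codons) {
    vapply(strsplit(toupper(codons), ""), function(x) sum(x %in% c("G", "C")),
           integer(1))
}
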