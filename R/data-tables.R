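## Accessors for the packaged reference tables under inst/extdata. All are
## plain TSV so they can be inspected, versioned and replaced by the user.

extdata <- function(file) {
    path <- system.file("extdata", file, package = "synoscan")
    if (path == "") stop("packaged table not found: ", file)
    path
}

#' Packaged codon-usage frequency table
#'
#' Genome-wide codon usage for *Escherichia coli* K-12, expressed per 1000
#' codons. "Rare" and "optimal" codons throughout the package are defined
#' by the ranking in this table. Supply your own table with the same
#' columns (`codon`, `amino_acid`, `usage_per_1000`) to work with another
#' species.
#'
#' @return data.frame with columns `codon`, `amino_acid`, `usage_per_1000`.
#' @export
codonUsageTable <- function() {
    utils::read.delim(extdata("codon_usage_ecoli_k12.tsv"),
                      stringsAsFactors = FALSE)
}

#' Packaged tRNA pool-fraction table (synthetic)
#'
#' Percent of the total cellular tRNA pool decoding each codon, one row per
#' (codon, decoding tRNA) pair; codons decoded by several tRNAs have
#' several rows and are summed by [relTrnaAbundance()]. The packaged values
#' are a *synthetic* stand-in derived from the packaged gene-copy table by
#' assuming pool fractions proportional to gene copy number; replace with
#' measured abundances for quantitative work.
#'
#' @return data.frame with columns `codon`, `anticodon`, `amino_acid`,
#'   `fraction_percent`.
#' @export
trnaFractionTable <- function() {
    utils::read.delim(extdata("trna_fraction_synthetic_ecoli.tsv"),
                      stringsAsFactors = FALSE)
}

#' Packaged tRNA gene-copy-number table (synthetic)
#'
#' Gene copy number per tRNA anticodon, patterned on the *E. coli* K-12
#' tRNA gene set (copy numbers and anticodon repertoire of realistic
#' magnitude, but synthetic: not a curated database export). Anticodons are
#' written 5'->3' as DNA; the two CAT rows (elongator Met and the
#' lysidine-modified Ile isoacceptor) are distinguished by `amino_acid`.
#'
#' @return data.frame with columns `amino_acid`, `anticodon`, `tgcn`.
#' @export
trnaGeneCopyTable <- function() {
    utils::read.delim(extdata("trna_tgcn_synthetic_ecoli.tsv"),
                      stringsAsFactors = FALSE)
}

#' Wobble selective-constraint defaults for tAI weights
#'
#' Standard published selective-constraint values `s` for codon:anticodon
#' wobble pairings; the contribution of an anticodon to a codon's tAI
#' weight is `(1 - s) * tGCN`. Watson-Crick pairings have `s = 0`.
#'
#' @return data.frame with columns `pairing`, `s`, `description`.
#' @export
wobblePenalties <- function() {
    utils::read.delim(extdata("wobble_penalties.tsv"),
                      stringsAsFactors = FALSE)
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector over the 20 standard amino acids (one-letter
#'   codes); positive values are hydrophobic.
#' @export
kyteDoolittleScale <- function() {
    tab <- utils::read.delim(extdata("kyte_doolittle.tsv"),
                             stringsAsFactors = FALSE)
    stats::setNames(tab$kd, tab$amino_acid)
}
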