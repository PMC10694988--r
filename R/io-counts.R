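#' Default column schema for count tables
#'
#' Maps the logical fields of a per-variant count table to column names in
#' the TSV on disk. Override individual entries to read tables with
#' different headers.
#'
#' @param ... named overrides, e.g. `position = "codon_index"`.
#' @return named character vector of column names.
#' @export
countTableSchema <- function(...) {
    schema <- c(position = "position", wt_codon = "wt_codon",
                mut_codon = "mut_codon",
                res_rep1 = "res_rep1", res_rep2 = "res_rep2",
                sen_rep1 = "sen_rep1", sen_rep2 = "sen_rep2",
                relE_rep1 = "relE_rep1", relE_rep2 = "relE_rep2",
                is_wt = "is_wt")
    ov <- c(...)
    if (length(ov)) {
        unknown <- setdiff(names(ov), names(schema))
        if (length(unknown)) {
            stop("unknown schema field(s): ", paste(unknown, collapse = ", "))
        }
        schema[names(ov)] <- ov
    }
    schema
}

#' Read a per-variant read-count table
#'
#' Reads a tab-delimited table with one row per variant (plus one reference
#' row flagged by the `is_wt` column) and read-count columns for three
#' strains in two replicates. Codon synonymy is validated against the
#' standard genetic code; the result is a [SynMutExperiment-class].
#'
#' @param path file path of a UTF-8, tab-delimited table with a header.
#' @param schema column mapping from [countTableSchema()].
#' @return A [SynMutExperiment-class].
#' @export
readCountTable <- function(path, schema = countTableSchema()) {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(unname(schema), colnames(tab))
    if (length(missing)) {
        stop("count table is missing column(s): ",
             paste(missing, collapse = ", "))
    }
    countCols <- c("res_rep1", "res_rep2", "sen_rep1", "sen_rep2",
                   "relE_rep1", "relE_rep2")
    counts <- as.matrix(tab[, schema[countCols], drop = FALSE])
    colnames(counts) <- countCols
    if (any(is.na(counts)) || any(counts < 0)) {
        stop("read counts must be non-negative and complete")
    }
    wt <- toupper(tab[[schema["wt_codon"]]])
    mut <- toupper(tab[[schema["mut_codon"]]])
    syn <- isSynonymous(wt, mut)
    if (!all(syn)) {
        i <- which(!syn)[1L]
        stop(sprintf("row %d: %s -> %s is not a synonymous substitution (%s -> %s)",
                     i, wt[i], mut[i],
                     translateCodons(wt[i]), translateCodons(mut[i])))
    }
    SynMutExperiment(counts = counts,
                     position = tab[[schema["position"]]],
                     wtCodon = wt, mutCodon = mut,
                     isRef = tab[[schema["is_wt"]]] != 0)
}

#' Write a SynMutExperiment back to the count-table TSV schema
#'
#' @param x a [SynMutExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path) {
    rd <- rowData(x)
    cnt <- assay(x, "counts")
    out <- data.frame(position = rd$position, wt_codon = rd$wtCodon,
                      mut_codon = rd$mutCodon, cnt,
                      is_wt = as.integer(rd$isRef),
                      check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    invisible(path)
}

#' Per-condition fraction representation of each variant
#'
#' Within each strain x replicate column, each variant's reads are divided
#' by the column total (all retained variants plus the reference), giving a
#' composition that sums to one. Fractions are intended to be computed
#' after [filterByResistantDepth()], so that they form a proper composition
#' of the analysed variant set.
#'
#' @param x a [SynMutExperiment-class].
#' @return numeric matrix of fractions, same dimensions as the counts.
#' @export
computeFractions <- function(x) {
    cnt <- assay(x, "counts")
    tot <- colSums(cnt)
    if (any(tot == 0)) {
        stop("condition(s) with zero total reads: ",
             paste(colnames(cnt)[tot == 0], collapse = ", "))
    }
    sweep(cnt, 2L, tot, "/")
}

#' Filter variants by resistant-strain sequencing depth
#'
#' A variant is retained only if its resistant-strain read count is at
#' least `minReads` in *both* replicates (the threshold itself is
#' retained). The reference row is exempt and always kept; a warning is
#' emitted if it would have failed the filter, since downstream scoring is
#' a ratio to the reference and will error on a zero reference count.
#'
#' @param x a [SynMutExperiment-class].
#' @param minReads minimum resistant-strain reads per replicate.
#' @return the filtered [SynMutExperiment-class].
#' @export
filterByResistantDepth <- function(x, minReads = 20) {
    r1 <- strainCounts(x, "resistant", 1L)
    r2 <- strainCounts(x, "resistant", 2L)
    keep <- r1 >= minReads & r2 >= minReads
    ref <- referenceIndex(x)
    if (!keep[ref]) {
        warning("reference variant below the resistant-depth threshold; ",
                "retained anyway (counts ", r1[ref], ", ", r2[ref], ")")
        keep[ref] <- TRUE
    }
    x[keep, ]
}
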