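# Shared in-code fixtures: a tiny two-variant experiment with hand-checkable
# counts, and builders for arbitrary count matrices and alignments.

suppressPackageStartupMessages(library(SummarizedExperiment))

condNames <- c("res_rep1", "res_rep2", "sen_rep1", "sen_rep2",
               "relE_rep1", "relE_rep2")

## counts: named list of per-condition vectors (variants..., ref last)
makeExperiment <- function(counts, position, wtCodon, mutCodon, isRef) {
    m <- do.call(cbind, counts[condNames])
    SynMutExperiment(counts = m, position = position, wtCodon = wtCodon,
                     mutCodon = mutCodon, isRef = isRef)
}

## one variant (K4_AAA) + WT reference, equal counts everywhere
makeTinyExperiment <- function(variant = 100L, ref = 100L) {
    makeExperiment(
        counts = setNames(rep(list(c(variant, ref)), 6), condNames),
        position = c(4L, 4L), wtCodon = c("AAG", "AAG"),
        mutCodon = c("AAA", "AAG"), isRef = c(FALSE, TRUE))
}

writeCountTsv <- function(df, path = tempfile(fileext = ".tsv")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

## well-formed 3-row table: two variants plus the WT reference row
toyCountTable <- function() {
    data.frame(position = c(4, 5, 4), wt_codon = c("AAG", "GGC", "AAG"),
               mut_codon = c("AAA", "GGA", "AAG"),
               res_rep1 = c(30, 40, 100), res_rep2 = c(25, 45, 110),
               sen_rep1 = c(10, 50, 90), sen_rep2 = c(12, 55, 95),
               relE_rep1 = c(20, 60, 80), relE_rep2 = c(22, 65, 85),
               is_wt = c(0, 0, 1))
}

toyAlignmentMatrix <- function(rows) {
    m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
    rownames(m) <- names(rows)
    m
}

## toy codon-usage table covering one lysine box
toyUsage <- function() {
    data.frame(codon = c("AAA", "AAG"), amino_acid = "K",
               usage_per_1000 = c(20, 10))
}

viennaAvailable <- function() {
    Sys.which("RNAduplex") != "" && Sys.which("RNAfold") != ""
}
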