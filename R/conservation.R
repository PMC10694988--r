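#' Read a multiple alignment as a character matrix
#'
#' Convenience readers for FASTA and Clustal alignments; rows are
#' sequences, columns alignment positions.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param type `"dna"` or `"protein"`.
#' @return character matrix with sequence ids as row names.
#' @export
readAlignment <- function(path, format = c("fasta", "clustal"),
                          type = c("dna", "protein")) {
    format <- match.arg(format)
    type <- match.arg(type)
    aln <- if (type == "dna") {
        Biostrings::readDNAMultipleAlignment(path, format = format)
    } else {
        Biostrings::readAAMultipleAlignment(path, format = format)
    }
    alignmentMatrix(aln)
}

#' Filter homolog hits by identity and query coverage
#'
#' Retains hits with percent identity at most `maxIdentity` (to exclude
#' near-duplicates of the query) and query coverage within
#' `[minCoverage, maxCoverage]`; all boundaries inclusive. Idempotent.
#'
#' @param hits data.frame with columns `id`, `percent_identity`,
#'   `query_coverage`.
#' @param maxIdentity,minCoverage,maxCoverage filter bounds in percent.
#' @return the retained rows of `hits`.
#' @export
filterHomologs <- function(hits, maxIdentity = 95, minCoverage = 90,
                           maxCoverage = 100) {
    need <- c("id", "percent_identity", "query_coverage")
    if (!all(need %in% colnames(hits))) {
        stop("hits must have columns: ", paste(need, collapse = ", "))
    }
    keep <- hits$percent_identity <= maxIdentity &
        hits$query_coverage >= minCoverage &
        hits$query_coverage <= maxCoverage
    hits[keep, , drop = FALSE]
}

alignmentMatrix <- function(alignment) {
    if (is.matrix(alignment)) {
        return(toupper(alignment))
    }
    strs <- if (is(alignment, "MultipleAlignment")) {
        as.character(Biostrings::unmasked(alignment))
    } else if (is(alignment, "XStringSet")) {
        as.character(alignment)
    } else {
        stop("alignment must be a character matrix, MultipleAlignment ",
             "or XStringSet")
    }
    widths <- nchar(strs)
    if (length(unique(widths)) != 1L) stop("ragged alignment")
    m <- do.call(rbind, strsplit(toupper(strs), ""))
    rownames(m) <- names(strs)
    m
}

#' Codon-level conservation from an in-frame nucleotide alignment
#'
#' For each codon position of the (ungapped, in-frame) WT row, tallies the
#' codons observed among the homolog rows. Codons containing gaps or
#' ambiguous bases, and codons encoding a different amino acid than the WT
#' codon, are excluded from the synonymous tally but counted separately.
#' The WT codon is classed `"most"` conserved when its count is the strict
#' maximum among observed synonymous codons, `"least"` when the strict
#' minimum, and `"intermediate"` otherwise (including all ties); positions
#' where no homolog contributes a synonymous codon are `NA`.
#'
#' @param alignment character matrix or `DNAMultipleAlignment` (rows
#'   named), all rows the same width.
#' @param wtRow id (row name) of the WT sequence; must be ungapped with
#'   length divisible by 3.
#' @return list with `perPosition` (a list of named synonymous-codon count
#'   vectors) and `summary`, a data.frame with `position`, `wtCodon`,
#'   `wtCount`, `synTotal`, `nonSynCount`, `gapCount`, `wtFraction`,
#'   `wtClass`.
#' @export
codonConservation <- function(alignment, wtRow) {
    m <- alignmentMatrix(alignment)
    if (!wtRow %in% rownames(m)) stop("wtRow not found: ", wtRow)
    wt <- m[wtRow, ]
    if (any(wt == "-")) stop("WT row must be ungapped")
    if (length(wt) %% 3L != 0L) {
        stop("WT length ", length(wt), " violates the reading frame")
    }
    hom <- m[setdiff(rownames(m), wtRow), , drop = FALSE]
    L <- length(wt) %/% 3L
    perPosition <- vector("list", L)
    rows <- vector("list", L)
    for (j in seq_len(L)) {
        cols <- (3L * (j - 1L) + 1L):(3L * j)
        wtCodon <- paste(wt[cols], collapse = "")
        wtAA <- translateCodons(wtCodon)
        cod <- apply(hom[, cols, drop = FALSE], 1L, paste, collapse = "")
        valid <- grepl("^[ACGT]{3}$", cod)
        gapCount <- sum(!valid)
        aa <- rep(NA_character_, length(cod))
        aa[valid] <- translateCodons(cod[valid])
        syn <- valid & aa == wtAA
        tally <- table(cod[syn])
        counts <- as.integer(tally)
        names(counts) <- names(tally)
        perPosition[[j]] <- counts
        wtCount <- if (wtCodon %in% names(counts)) counts[[wtCodon]] else 0L
        ## rank the WT codon among observed synonymous codons (its own zero
        ## count included when unobserved); strict extrema only, ties are
        ## intermediate
        vals <- counts
        if (!wtCodon %in% names(vals)) {
            vals <- c(vals, stats::setNames(0L, wtCodon))
        }
        cls <- if (length(counts) == 0L) {
            NA_character_
        } else if (wtCount == max(vals) && sum(vals == max(vals)) == 1L) {
            "most"
        } else if (wtCount == min(vals) && sum(vals == min(vals)) == 1L) {
            "least"
        } else {
            "intermediate"
        }
        rows[[j]] <- data.frame(position = j, wtCodon = wtCodon,
                                wtCount = wtCount, synTotal = sum(counts),
                                nonSynCount = sum(valid & !syn),
                                gapCount = gapCount,
                                wtFraction = if (sum(counts) > 0) {
                                    wtCount / sum(counts)
                                } else NA_real_,
                                wtClass = cls)
    }
    list(perPosition = perPosition, summary = do.call(rbind, rows))
}

#' Residue-level conservation from a protein alignment
#'
#' For each WT residue, the percentage of homolog rows carrying the same
#' residue at that column, among rows with a non-gap residue there.
#' All-gap columns are reported `NA`.
#'
#' @param alignment character matrix or `AAMultipleAlignment`.
#' @param wtRow id of the (ungapped) WT row.
#' @return numeric vector of percentages, one per WT residue.
#' @export
residueConservation <- function(alignment, wtRow) {
    m <- alignmentMatrix(alignment)
    if (!wtRow %in% rownames(m)) stop("wtRow not found: ", wtRow)
    wt <- m[wtRow, ]
    if (any(wt == "-")) stop("WT row must be ungapped")
    hom <- m[setdiff(rownames(m), wtRow), , drop = FALSE]
    vapply(seq_along(wt), function(j) {
        col <- hom[, j]
        present <- col != "-" & col != "." & col != "X"
        if (!any(present)) return(NA_real_)
        100 * sum(col[present] == wt[j]) / sum(present)
    }, numeric(1))
}

#' Distribution of WT codons over conservation classes
#'
#' @param conservation result of [codonConservation()].
#' @return named numeric vector of fractions over
#'   `c("most", "intermediate", "least")`, summing to 1 over classified
#'   positions.
#' @export
conservedCodonSummary <- function(conservation) {
    cls <- conservation$summary$wtClass
    cls <- cls[!is.na(cls)]
    if (length(cls) == 0L) stop("no classified positions")
    tab <- table(factor(cls, levels = c("most", "intermediate", "least")))
    stats::setNames(as.numeric(tab) / length(cls),
                    c("most", "intermediate", "least"))
}
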