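#' Region partition of a gene
#'
#' Default partition into an N-terminal (1-13), middle (14-86) and
#' C-terminal (87-101) region; bounds are configurable but must be
#' contiguous, non-overlapping and cover `1..L`.
#'
#' @param nTermEnd last position of the N-terminal region.
#' @param middleEnd last position of the middle region.
#' @param length gene length in codons.
#' @return a named list of `c(start, end)` pairs with class
#'   `"regionPartition"`.
#' @export
regionPartition <- function(nTermEnd = 13, middleEnd = 86, length = 101) {
    if (!(1 <= nTermEnd && nTermEnd < middleEnd && middleEnd < length)) {
        stop("regions must be contiguous, ordered and within 1..length")
    }
    nTermEnd <- as.integer(nTermEnd)
    middleEnd <- as.integer(middleEnd)
    length <- as.integer(length)
    structure(list(`N-terminal` = c(1L, nTermEnd),
                   middle = c(nTermEnd + 1L, middleEnd),
                   `C-terminal` = c(middleEnd + 1L, length)),
              class = "regionPartition")
}

#' Region containing each position
#'
#' @param position integer vector of codon positions.
#' @param partition a [regionPartition()].
#' @return character vector of region labels.
#' @examples
#' regionOf(c(13, 14, 87))
#' @export
regionOf <- function(position, partition = regionPartition()) {
    L <- partition[[length(partition)]][2L]
    if (any(position < 1L | position > L)) {
        stop("position outside 1..", L)
    }
    breaks <- c(0L, vapply(partition, `[`, integer(1), 2L))
    names(partition)[findInterval(position, breaks + 1L,
                                  rightmost.closed = FALSE)]
}

#' Position-averaged scores
#'
#' Arithmetic mean of a score over all variants at each codon position.
#'
#' @param scores data.frame-like with a `position` column.
#' @param value name of the score column to average.
#' @return data.frame with `position` and `mean`; positions with no data
#'   are absent.
#' @export
positionAverage <- function(scores, value = "esCcdB") {
    v <- scores[[value]]
    pos <- scores$position
    ok <- !is.na(v)
    agg <- tapply(v[ok], pos[ok], mean)
    data.frame(position = as.integer(names(agg)), mean = as.numeric(agg))
}

#' Centred moving average
#'
#' Length-preserving centred mean over a sliding window; truncated windows
#' at the edges.
#'
#' @param values numeric vector.
#' @param window window width (>= 1; width 1 is the identity).
#' @return numeric vector of the same length.
#' @examples
#' movingAverage(1:5, 5)  # centre value 3
#' @export
movingAverage <- function(values, window = 5) {
    if (length(values) == 0L) stop("empty input")
    if (window < 1) stop("window must be >= 1")
    half <- (window - 1) %/% 2
    n <- length(values)
    vapply(seq_len(n), function(i) {
        lo <- max(1L, i - half)
        hi <- min(n, i + (window - 1L) - half)
        mean(values[lo:hi])
    }, numeric(1))
}

#' Pearson correlation matrix with a significance mask
#'
#' Pairwise Pearson correlations over the given columns, with two-sided
#' p-values from the t distribution on n - 2 degrees of freedom,
#' pairwise-complete observations, and a logical mask flagging
#' correlations significant at `alpha` (the convention of crossing out
#' cells with p above the cutoff in correlation heat maps). No
#' multiple-testing correction is applied by default, matching common
#' practice for these figure-level matrices; set `adjust = "BH"` for
#' Benjamini-Hochberg within the upper triangle.
#'
#' @param data data.frame-like of numeric columns.
#' @param variables column names to correlate (default: all numeric).
#' @param alpha significance cutoff for the mask.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list with matrices `r`, `p`, `n` and logical `significant`, of
#'   class `"synCorrelation"`.
#' @export
correlationMatrix <- function(data, variables = NULL, alpha = 0.05,
                              adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    data <- as.data.frame(data)
    if (is.null(variables)) {
        variables <- names(data)[vapply(data, is.numeric, logical(1))]
    }
    k <- length(variables)
    r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables,
                                                          variables))
    for (i in seq_len(k)) {
        for (j in seq_len(k)) {
            x <- data[[variables[i]]]
            y <- data[[variables[j]]]
            ok <- is.finite(x) & is.finite(y)
            nn <- sum(ok)
            n[i, j] <- nn
            if (i == j) {
                r[i, j] <- 1
                p[i, j] <- 0
                next
            }
            if (nn < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
                next  # cell reported missing
            }
            rij <- stats::cor(x[ok], y[ok])
            r[i, j] <- rij
            tstat <- rij * sqrt((nn - 2) / (1 - rij^2))
            p[i, j] <- 2 * stats::pt(abs(tstat), df = nn - 2,
                                     lower.tail = FALSE)
        }
    }
    if (adjust == "BH") {
        ut <- upper.tri(p)
        p[ut] <- stats::p.adjust(p[ut], method = "BH")
        p[lower.tri(p)] <- t(p)[lower.tri(p)]
    }
    structure(list(r = r, p = p, n = n, significant = p <= alpha),
              class = "synCorrelation")
}

#' @export
print.synCorrelation <- function(x, digits = 2, ...) {
    cat("Pearson correlation matrix (X = not significant):\n")
    out <- format(round(x$r, digits))
    out[!x$significant | is.na(x$r)] <- "X"
    print(out, quote = FALSE)
    invisible(x)
}

#' Coefficient of variation of scores per codon position
#'
#' Sample standard deviation divided by the mean, over variants at each
#' position; positions with fewer than two variants (or non-positive
#' mean) are `NA`.
#'
#' @param scores data.frame-like with `position` and a score column.
#' @param value score column name.
#' @return data.frame with `position`, `n`, `cv`.
#' @export
coefficientOfVariation <- function(scores, value = "esCcdB") {
    pos <- scores$position
    v <- scores[[value]]
    agg <- tapply(v, pos, function(x) {
        x <- x[!is.na(x)]
        if (length(x) < 2L || mean(x) <= 0) return(NA_real_)
        stats::sd(x) / mean(x)
    })
    nvar <- tapply(v, pos, function(x) sum(!is.na(x)))
    data.frame(position = as.integer(names(agg)),
               n = as.integer(nvar), cv = as.numeric(agg))
}

#' Hyperactive / inactive variant counts per amino acid
#'
#' @param scores output of [scoreVariants()] (needs `aa` and
#'   `activityClass`).
#' @return data.frame with one row per standard amino acid and counts of
#'   hyperactive and inactive variants.
#' @export
aaPhenotypeCounts <- function(scores) {
    aas <- sort(unique(unname(Biostrings::GENETIC_CODE)))
    aas <- setdiff(aas, "*")
    aa <- factor(scores$aa, levels = aas)
    data.frame(
        aa = aas,
        hyperactive = as.integer(table(aa[scores$activityClass ==
                                              "hyperactive"])),
        inactive = as.integer(table(aa[scores$activityClass ==
                                           "inactive"])))
}

#' Run the full scoring pipeline and write a report bundle
#'
#' Orchestrates simulate (or read) -> filter -> normalise -> score ->
#' classify -> covariates -> summaries, writing TSV outputs and a plain
#' run log (no timestamps, so a rerun with the same seed and inputs is
#' byte-identical).
#'
#' @param config list with either `simulate` (arguments to
#'   [simulateSynScreen()]) or `countTable` (path for [readCountTable()]
#'   plus optional `gene`, a codon vector or nucleotide string for
#'   covariates); optional `thresholds`, `minReads`, `referenceLabel`,
#'   `regions` (a [regionPartition()]).
#' @param outdir output directory.
#' @return invisibly, a list with the scores, covariates (or `NULL`),
#'   correlation object and region summary.
#' @export
runPipeline <- function(config, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    logLines <- c("synoscan pipeline run")
    if (!is.null(config$simulate)) {
        se <- do.call(simulateSynScreen, config$simulate)
        gene <- metadata(se)$gene
        logLines <- c(logLines,
                      paste0("input: simulated screen (seed ",
                             config$simulate$seed, ", depth ",
                             format(metadata(se)$depth, scientific = FALSE),
                             ")"))
    } else if (!is.null(config$countTable)) {
        se <- readCountTable(config$countTable)
        gene <- config$gene
        logLines <- c(logLines, paste0("input: ", config$countTable))
    } else {
        stop("config must provide either $simulate or $countTable")
    }
    thresholds <- if (is.null(config$thresholds)) synThresholds() else
        config$thresholds
    minReads <- if (is.null(config$minReads)) 20 else config$minReads
    scores <- scoreVariants(se, thresholds = thresholds,
                            minReads = minReads,
                            referenceLabel = config$referenceLabel)
    writeTsv(as.data.frame(scores), file.path(outdir, "scores.tsv"))
    covariates <- NULL
    if (!is.null(gene)) {
        keep <- !scores$isRef
        covariates <- covariateTable(
            gene, scores[keep, c("position", "wtCodon", "mutCodon")])
        writeTsv(as.data.frame(covariates),
                 file.path(outdir, "covariates.tsv"))
        merged <- cbind(as.data.frame(scores[keep, ]),
                        as.data.frame(covariates[, c("deltaGc", "rcu",
                                                     "rcuDv", "rtrnaA")]))
        corr <- correlationMatrix(merged,
                                  c("esCcdB", "esRelE", "esCcdBDv",
                                    "esRelEDv", "deltaGc", "rcu", "rcuDv",
                                    "rtrnaA"))
        writeTsv(data.frame(variable = rownames(corr$r),
                            as.data.frame(corr$r), check.names = FALSE),
                 file.path(outdir, "correlations.tsv"))
    } else {
        corr <- NULL
    }
    L <- max(scores$position)
    regions <- if (is.null(config$regions)) {
        regionPartition(min(13, L - 2), min(86, L - 1), L)
    } else config$regions
    reg <- regionOf(scores$position, regions)
    summary <- do.call(rbind, lapply(split(seq_len(nrow(scores)), reg),
        function(i) {
            data.frame(region = reg[i][1L], nVariants = length(i),
                       meanEsCcdB = mean(scores$esCcdB[i]),
                       meanEsRelE = mean(scores$esRelE[i]))
        }))
    summary <- summary[order(match(summary$region, names(regions))), ]
    writeTsv(summary, file.path(outdir, "region_summary.tsv"))
    logLines <- c(logLines,
                  paste0("variants scored: ", nrow(scores)),
                  paste0("reference: ", metadata(scores)$reference),
                  paste0("thresholds: hyperactive < ",
                         thresholds@hyperactiveMax, ", inactive > ",
                         thresholds@inactiveMin))
    writeLines(logLines, file.path(outdir, "run_log.txt"))
    invisible(list(scores = scores, covariates = covariates,
                   correlations = corr, regionSummary = summary))
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
}
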