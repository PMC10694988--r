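#' Deep-sequencing ratio between a selective and the resistant condition
#'
#' Ratio of a variant's fraction representation in a selective condition
#' (sensitive or reporter strain) to its fraction in the matching resistant
#' replicate. Variants absent from the selective condition get ratio 0; a
#' zero resistant fraction for a retained variant indicates the depth
#' filter was not applied and is an error.
#'
#' @param fSelective,fResistant numeric vectors of fractions, same length.
#' @return numeric vector of ratios.
#' @export
deepseqRatio <- function(fSelective, fResistant) {
    if (length(fSelective) != length(fResistant)) {
        stop("fraction vectors must have equal length")
    }
    if (any(fResistant <= 0)) {
        stop("zero resistant-strain fraction for a retained variant; ",
             "apply filterByResistantDepth() before computing ratios")
    }
    fSelective / fResistant
}

#' Enrichment score relative to the reference variant
#'
#' @param ratio numeric vector of deep-sequencing ratios.
#' @param ratioRef the reference variant's ratio in the same condition.
#' @return `ratio / ratioRef`; the reference variant scores exactly 1.
#' @export
enrichmentScore <- function(ratio, ratioRef) {
    if (length(ratioRef) != 1L || !is.finite(ratioRef) || ratioRef <= 0) {
        stop("reference ratio must be a single positive number ",
             "(reference dropout in the selective condition?)")
    }
    ratio / ratioRef
}

#' Score a synonymous-variant screen
#'
#' Runs the normalisation pipeline on a [SynMutExperiment-class]: depth
#' filter, per-condition fraction representations, per-replicate
#' selective/resistant ratios, enrichment scores relative to the reference,
#' replicate averaging, per-position degree-of-variation statistics and
#' phenotype classification.
#'
#' The reference may be re-assigned with `referenceLabel`, e.g. to re-score
#' a double-variant library against a parent hyperactive mutation instead
#' of the wild type; the named variant then anchors all scores at 1.
#' Reporter-strain scores obtained under a re-assigned reference compress
#' near the new anchor and should be interpreted with caution.
#'
#' @param x a [SynMutExperiment-class].
#' @param thresholds a [SynThresholds-class].
#' @param minReads resistant-depth filter (see [filterByResistantDepth()]).
#' @param average `"arithmetic"` (default) or `"geometric"` combination of
#'   the two per-replicate scores.
#' @param referenceLabel optional label of the variant to use as reference.
#' @param pseudocount added to every count before scoring (default 0). A
#'   small pseudocount (e.g. 0.5) keeps log-based statistics defined for
#'   variants that drop out of a selective condition.
#' @return a [S4Vectors::DataFrame] with one row per retained variant:
#'   identity columns, per-replicate and averaged `esCcdB`/`esRelE`
#'   scores, `esCcdBDv`/`esRelEDv` degree-of-variation values (log2),
#'   `depleted` flag, and `activityClass`/`regulationClass`/`phenotype`.
#' @export
scoreVariants <- function(x, thresholds = synThresholds(), minReads = 20,
                          average = c("arithmetic", "geometric"),
                          referenceLabel = NULL, pseudocount = 0) {
    average <- match.arg(average)
    if (!is.null(referenceLabel)) {
        rd <- rowData(x)
        j <- match(referenceLabel, rd$label)
        if (is.na(j)) stop("referenceLabel not found: ", referenceLabel)
        rd$isRef <- seq_len(nrow(x)) == j
        rowData(x) <- rd
    }
    x <- filterByResistantDepth(x, minReads = minReads)
    ref <- referenceIndex(x)
    cnt <- assay(x, "counts")
    if (any(cnt[ref, ] == 0) && pseudocount == 0) {
        stop("reference variant has zero reads in condition(s): ",
             paste(colnames(cnt)[cnt[ref, ] == 0], collapse = ", "))
    }
    if (pseudocount > 0) {
        SummarizedExperiment::assay(x, "counts") <- cnt + pseudocount
        ## validity requires integer counts; bypass via direct fractions
        frac <- sweep(cnt + pseudocount, 2L, colSums(cnt + pseudocount), "/")
    } else {
        frac <- computeFractions(x)
    }
    esRep <- function(strain, rep) {
        fSel <- frac[, conditionCol(x, strain, rep)]
        fRes <- frac[, conditionCol(x, "resistant", rep)]
        ratio <- deepseqRatio(fSel, fRes)
        unname(enrichmentScore(ratio, ratio[ref]))
    }
    ccdb1 <- esRep("sensitive", 1L); ccdb2 <- esRep("sensitive", 2L)
    rele1 <- esRep("relE", 1L);      rele2 <- esRep("relE", 2L)
    comb <- function(a, b) {
        if (average == "arithmetic") (a + b) / 2 else sqrt(a * b)
    }
    esCcdB <- comb(ccdb1, ccdb2)
    esRelE <- comb(rele1, rele2)
    rd <- rowData(x)
    cls <- classifyPhenotype(esCcdB, esRelE, thresholds)
    res <- DataFrame(label = rd$label, position = rd$position,
                     wtCodon = rd$wtCodon, mutCodon = rd$mutCodon,
                     aa = rd$aa, isRef = rd$isRef,
                     esCcdBRep1 = ccdb1, esCcdBRep2 = ccdb2,
                     esRelERep1 = rele1, esRelERep2 = rele2,
                     esCcdB = esCcdB, esRelE = esRelE,
                     esCcdBDv = degreeOfVariation(esCcdB, rd$position),
                     esRelEDv = degreeOfVariation(esRelE, rd$position),
                     depleted = esCcdB == 0 | esRelE == 0,
                     activityClass = cls$activityClass,
                     regulationClass = cls$regulationClass,
                     phenotype = cls$phenotype)
    rownames(res) <- rd$label
    metadata(res) <- list(thresholds = thresholds, minReads = minReads,
                          average = average, pseudocount = pseudocount,
                          reference = rd$label[ref])
    res
}

conditionCol <- function(x, strain, replicate) {
    cd <- colData(x)
    j <- which(cd$strain == strain & cd$replicate == replicate)
    if (length(j) != 1L) stop("condition not found: ", strain, " ", replicate)
    j
}

#' Classify variants by activity and operon regulation
#'
#' Activity from the toxin-strain score (hyperactive strictly below
#' `hyperactiveMax`, inactive strictly above `inactiveMin`, otherwise
#' intermediate); regulation from the reporter score (repressing strictly
#' above the neutral point, derepressing strictly below, otherwise
#' neutral). A combined phenotype (`"H+D"`, `"H+R"`, `"I+D"`, `"I+R"`) is
#' assigned only when the activity is non-intermediate *and* the regulation
#' non-neutral; every other combination is `"neutral"`. Scores equal to a
#' threshold are not called (strict inequalities).
#'
#' @param esCcdB,esRelE numeric score vectors.
#' @param thresholds a [SynThresholds-class].
#' @return `DataFrame` with `activityClass`, `regulationClass`, `phenotype`.
#' @examples
#' classifyPhenotype(c(0.42, 2, 1), c(0.35, 1.5, 1), synThresholds())
#' @export
classifyPhenotype <- function(esCcdB, esRelE, thresholds = synThresholds()) {
    activity <- ifelse(esCcdB < thresholds@hyperactiveMax, "hyperactive",
                ifelse(esCcdB > thresholds@inactiveMin, "inactive",
                       "intermediate"))
    regulation <- ifelse(esRelE > thresholds@releNeutral, "repressing",
                  ifelse(esRelE < thresholds@releNeutral, "derepressing",
                         "neutral"))
    phenotype <- ifelse(
        activity == "intermediate" | regulation == "neutral", "neutral",
        paste0(ifelse(activity == "hyperactive", "H", "I"), "+",
               ifelse(regulation == "derepressing", "D", "R")))
    DataFrame(activityClass = activity, regulationClass = regulation,
              phenotype = phenotype)
}

#' Degree of variation of a multiplicative score within codon positions
#'
#' Each score is first mapped to its fold distance from neutrality,
#' `x = max(s, 1/s)`, and then compared on a log2 scale with the least
#' deviating variant at the same position: `DoV = log2(x / min(x))`. The
#' per-position minimiser scores exactly 0. Non-positive scores (selective
#' dropouts) yield `NA` with a warning.
#'
#' @param scores positive numeric vector (enrichment scores, relative
#'   codon usage, ...).
#' @param positions codon position of each score.
#' @return non-negative numeric vector (log2 units), `NA` for dropouts.
#' @examples
#' degreeOfVariation(c(0.5, 2, 4), c(1, 1, 1))  # 0 0 1
#' @export
degreeOfVariation <- function(scores, positions) {
    if (length(scores) != length(positions)) {
        stop("scores and positions must have equal length")
    }
    ok <- is.finite(scores) & scores > 0
    if (!all(ok)) {
        warning(sum(!ok), " variant(s) with non-positive score excluded ",
                "from degree-of-variation")
    }
    x <- ifelse(ok, pmax(scores, 1 / scores), NA_real_)
    xmin <- stats::ave(x, positions,
                       FUN = function(v) {
                           if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
                       })
    log2(x / xmin)
}

#' Data-driven threshold suggestion by k-means on log2 scores
#'
#' Clusters `log2(scores)` into `k` groups and returns the midpoints
#' between adjacent cluster extremes, mapped back to the linear scale, as
#' candidate activity thresholds. Advisory only: classification defaults to
#' the fixed thresholds of [synThresholds()].
#'
#' @param scores positive numeric vector.
#' @param k number of clusters.
#' @param seed RNG seed (k-means uses random restarts).
#' @param nstart number of random restarts.
#' @return numeric vector of `k - 1` boundaries, ascending, linear scale.
#' @export
kmeansThresholds <- function(scores, k = 3, seed = 1, nstart = 100) {
    scores <- scores[is.finite(scores) & scores > 0]
    if (k < 2) stop("k must be at least 2 to define a boundary")
    if (length(unique(scores)) < k) {
        stop("need at least k distinct positive scores")
    }
    ls <- log2(scores)
    set.seed(seed)
    km <- stats::kmeans(ls, centers = k, nstart = nstart)
    ord <- order(km$centers)
    bounds <- vapply(seq_len(k - 1L), function(i) {
        hi <- max(ls[km$cluster == ord[i]])
        lo <- min(ls[km$cluster == ord[i + 1L]])
        (2^hi + 2^lo) / 2
    }, numeric(1))
    sort(bounds)
}
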