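#' GC-content change of a codon substitution
#'
#' Number of G/C bases in the mutant codon minus the number in the WT
#' codon. For synonymous substitutions the difference is bounded by 3 in
#' absolute value (attained only across six-fold degenerate boxes).
#'
#' @param mutCodon,wtCodon DNA codons (vectors recycled to common length).
#' @return integer vector in `[-3, 3]`.
#' @examples
#' deltaGC("AAA", "AAG")  # -1
#' @export
deltaGC <- function(mutCodon, wtCodon) {
    ok <- grepl("^[ACGT]{3}$", toupper(c(mutCodon, wtCodon)))
    if (!all(ok)) stop("invalid nucleotide in codon(s)")
    gcCount(mutCodon) - gcCount(wtCodon)
}

usageLookup <- function(codons, usage) {
    i <- match(toupper(codons), toupper(usage$codon))
    if (anyNA(i)) {
        stop("codon(s) absent from usage table: ",
             paste(unique(codons[is.na(i)]), collapse = ", "))
    }
    usage$usage_per_1000[i]
}

#' Relative codon usage (RCU) of a synonymous substitution
#'
#' Ratio of genome-wide usage frequency of the mutant codon to that of the
#' WT codon. Values above 1 indicate substitution toward a more frequently
#' used ("more optimal") codon.
#'
#' @param mutCodon,wtCodon synonymous DNA codons (vectorised).
#' @param usage usage table, see [codonUsageTable()].
#' @return positive numeric vector.
#' @export
relCodonUsage <- function(mutCodon, wtCodon, usage = codonUsageTable()) {
    if (!all(isSynonymous(mutCodon, wtCodon))) {
        stop("relative codon usage is defined for synonymous pairs only")
    }
    fWt <- usageLookup(wtCodon, usage)
    if (any(fWt <= 0)) stop("WT codon with zero usage frequency")
    usageLookup(mutCodon, usage) / fWt
}

#' Relative tRNA abundance (RtrnaA) of a synonymous substitution
#'
#' Ratio of the percent of the cellular tRNA pool decoding the mutant codon
#' to the percent decoding the WT codon. Codons decoded by several tRNAs
#' sum the pool fractions of all their decoders.
#'
#' @param mutCodon,wtCodon synonymous DNA codons (vectorised).
#' @param trna pool-fraction table, see [trnaFractionTable()].
#' @return positive numeric vector.
#' @export
relTrnaAbundance <- function(mutCodon, wtCodon, trna = trnaFractionTable()) {
    if (!all(isSynonymous(mutCodon, wtCodon))) {
        stop("relative tRNA abundance is defined for synonymous pairs only")
    }
    pool <- function(codons) {
        agg <- tapply(trna$fraction_percent, toupper(trna$codon), sum)
        v <- agg[toupper(codons)]
        if (anyNA(v)) {
            stop("codon(s) absent from tRNA table: ",
                 paste(unique(codons[is.na(v)]), collapse = ", "))
        }
        unname(v)
    }
    pool(mutCodon) / pool(wtCodon)
}

#' Relative-adaptiveness (CAI) weights from a usage table
#'
#' For each sense codon, `w = f / max(f)` over its synonymous box, so the
#' most-used synonym of every amino acid gets weight 1.
#'
#' @param usage usage table, see [codonUsageTable()].
#' @return named numeric vector over the 61 sense codons, values in (0, 1].
#' @export
caiWeights <- function(usage = codonUsageTable()) {
    usage <- usage[translateCodons(usage$codon) != "*", ]
    aa <- translateCodons(usage$codon)
    fmax <- stats::ave(usage$usage_per_1000, aa, FUN = max)
    stats::setNames(usage$usage_per_1000 / fmax, toupper(usage$codon))
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of relative-adaptiveness weights over all codons,
#' computed in the log domain for numerical stability.
#'
#' @param codons character vector of sense DNA codons (a whole CDS), or a
#'   single nucleotide string of length divisible by 3.
#' @param weights named codon weight vector, see [caiWeights()].
#' @return value in (0, 1]; 1 for a gene of maximal-weight codons only.
#' @export
cai <- function(codons, weights = caiWeights()) {
    if (length(codons) == 1L && nchar(codons) > 3L) codons <- codonsOf(codons)
    codons <- toupper(codons)
    if (any(translateCodons(codons) == "*")) {
        stop("stop codon inside gene")
    }
    w <- weights[codons]
    if (anyNA(w)) {
        stop("codon(s) without a weight: ",
             paste(unique(codons[is.na(w)]), collapse = ", "))
    }
    exp(mean(log(w)))
}

#' Ratio of codon adaptation indices of two genes
#'
#' @param geneA,geneB codon vectors or nucleotide strings.
#' @param weights codon weight vector, see [caiWeights()].
#' @return `cai(geneA) / cai(geneB)`; above 1 iff gene A is the better
#'   adapted of the two.
#' @export
caiRatio <- function(geneA, geneB, weights = caiWeights()) {
    cai(geneA, weights) / cai(geneB, weights)
}

## --- tAI ------------------------------------------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## Anticodon (5'->3', DNA) Watson-Crick cognate to a codon.
wcAnticodon <- function(codon) {
    n <- strsplit(toupper(codon), "")[[1L]]
    paste0(COMPLEMENT[n[3L]], COMPLEMENT[n[2L]], COMPLEMENT[n[1L]])
}

## Contributions of table anticodons to one codon's raw tAI weight under
## standard prokaryotic wobble rules. Returns data.frame(anticodon, s, aa).
codonRecognition <- function(codon, sVals) {
    codon <- toupper(codon)
    n3 <- substr(codon, 3L, 3L)
    wc <- wcAnticodon(codon)
    body <- substr(wc, 2L, 3L)
    rec <- data.frame(anticodon = wc, pairing = "WC", aa = NA_character_,
                      stringsAsFactors = FALSE)
    wob <- switch(n3,
        T = data.frame(anticodon = paste0("G", body), pairing = "GU"),
        C = data.frame(anticodon = paste0("A", body), pairing = "IC"),
        A = data.frame(anticodon = paste0("A", body), pairing = "IA"),
        G = data.frame(anticodon = paste0("T", body), pairing = "UG"))
    wob$aa <- NA_character_
    rec <- rbind(rec, wob)
    if (codon == "ATA") {
        ## bacterial Ile AUA isoacceptor: lysidine-modified CAT anticodon
        rec <- rbind(rec, data.frame(anticodon = "CAT", pairing = "LA",
                                     aa = "I"))
    }
    if (codon == "ATG") rec$aa[rec$anticodon == "CAT"] <- "M"
    rec$s <- sVals[rec$pairing]
    rec
}

#' tRNA adaptation index weights from a gene-copy-number table
#'
#' For each sense codon the raw weight is the sum over recognising
#' anticodons of `(1 - s) * tGCN`, with `s` the wobble selective
#' constraint; weights are normalised by their maximum and codons with
#' zero weight are replaced by the geometric mean of the non-zero weights.
#'
#' @param tgcn gene-copy table, see [trnaGeneCopyTable()].
#' @param penalties wobble-penalty table, see [wobblePenalties()].
#' @return named numeric vector over the 61 sense codons, values in (0, 1].
#' @export
taiWeights <- function(tgcn = trnaGeneCopyTable(),
                       penalties = wobblePenalties()) {
    if (nrow(tgcn) == 0L) stop("empty gene-copy table")
    sVals <- stats::setNames(penalties$s, penalties$pairing)
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    raw <- vapply(sense, function(codon) {
        rec <- codonRecognition(codon, sVals)
        w <- 0
        for (i in seq_len(nrow(rec))) {
            hit <- toupper(tgcn$anticodon) == rec$anticodon[i]
            if (!is.na(rec$aa[i])) hit <- hit & tgcn$amino_acid == rec$aa[i]
            if (rec$anticodon[i] == "CAT" && is.na(rec$aa[i])) {
                ## generic rules must not co-opt the Ile/Met CAT isoacceptors
                hit <- hit & FALSE
            }
            w <- w + sum((1 - rec$s[i]) * tgcn$tgcn[hit])
        }
        w
    }, numeric(1))
    w <- raw / max(raw)
    if (any(w == 0)) {
        w[w == 0] <- exp(mean(log(w[w > 0])))
    }
    w
}

#' tRNA adaptation index of a gene or single codon
#'
#' Geometric mean of per-codon tAI weights.
#'
#' @param codons sense DNA codons or a nucleotide string.
#' @param weights named weight vector, see [taiWeights()].
#' @return value in (0, 1].
#' @export
tai <- function(codons, weights = taiWeights()) {
    if (length(codons) == 1L && nchar(codons) > 3L) codons <- codonsOf(codons)
    codons <- toupper(codons)
    if (any(translateCodons(codons) == "*")) stop("stop codon inside gene")
    w <- weights[codons]
    if (anyNA(w)) stop("codon(s) without a tAI weight")
    exp(mean(log(w)))
}

## --- wobble base & hydropathy ---------------------------------------------

#' Third (wobble) base of codons
#'
#' @param codons DNA codon vector.
#' @return character vector of third-position bases.
#' @export
wobbleBase <- function(codons) {
    codons <- toupper(codons)
    if (!all(grepl("^[ACGT]{3}$", codons))) stop("invalid codon(s)")
    substr(codons, 3L, 3L)
}

#' Wobble-base composition of a variant set
#'
#' Counts and fractions of A/C/G/T at the third codon position, e.g. for
#' the mutant codons of one phenotype class within one gene region.
#'
#' @param codons DNA codon vector (possibly empty).
#' @return data.frame with columns `base`, `count`, `fraction` (all zero
#'   for an empty set).
#' @export
wobbleComposition <- function(codons) {
    bases <- c("A", "C", "G", "T")
    counts <- table(factor(wobbleBase(codons), levels = bases))
    n <- sum(counts)
    data.frame(base = bases, count = as.integer(counts),
               fraction = if (n > 0) as.numeric(counts) / n else rep(0, 4))
}

#' Hydropathy profile of a protein sequence
#'
#' Per-residue Kyte-Doolittle hydropathy, optionally smoothed with a
#' centred moving average (edges use truncated windows, so the profile
#' keeps the sequence length).
#'
#' @param protein amino-acid string or character vector of residues.
#' @param scale named hydropathy values, see [kyteDoolittleScale()].
#' @param window odd window width; 1 (default) disables smoothing.
#' @return numeric vector, one value per residue.
#' @export
hydropathyProfile <- function(protein, scale = kyteDoolittleScale(),
                              window = 1) {
    if (length(protein) == 1L) protein <- strsplit(protein, "")[[1L]]
    protein <- toupper(protein)
    v <- scale[protein]
    if (anyNA(v)) {
        stop("unknown residue(s): ",
             paste(unique(protein[is.na(v)]), collapse = ", "))
    }
    movingAverage(unname(v), window = window)
}

#' Per-variant codon-level covariates
#'
#' Combines the codon-usage metrics into one table: GC change, relative
#' codon usage and its per-position degree of variation, relative tRNA
#' abundance, gene-level CAI and tAI of the mutant and WT gene, and the
#' mutant wobble base.
#'
#' @param gene WT gene as a codon vector or nucleotide string.
#' @param variants data.frame-like with `position`, `wtCodon`, `mutCodon`
#'   (e.g. the output of [enumerateSynonymousLibrary()] or the identity
#'   columns of [scoreVariants()]).
#' @param usage,trna,weightsCai,weightsTai parameter tables; packaged
#'   defaults.
#' @return `DataFrame` with one row per variant.
#' @export
covariateTable <- function(gene, variants, usage = codonUsageTable(),
                           trna = trnaFractionTable(),
                           weightsCai = caiWeights(usage),
                           weightsTai = taiWeights()) {
    if (length(gene) == 1L) gene <- codonsOf(gene)
    gene <- toupper(gene)
    pos <- as.integer(variants$position)
    wt <- toupper(variants$wtCodon)
    mut <- toupper(variants$mutCodon)
    if (any(pos < 1L | pos > length(gene))) {
        stop("variant position outside gene")
    }
    if (any(gene[pos] != wt)) {
        stop("variant wtCodon disagrees with the gene sequence")
    }
    L <- length(gene)
    caiWt <- cai(gene, weightsCai)
    taiWt <- tai(gene, weightsTai)
    rcu <- relCodonUsage(mut, wt, usage)
    ## single-codon substitution: gene-level index scales by (w_mut/w_wt)^(1/L)
    caiMut <- caiWt * (weightsCai[mut] / weightsCai[wt])^(1 / L)
    taiMut <- taiWt * (weightsTai[mut] / weightsTai[wt])^(1 / L)
    DataFrame(label = variantLabel(pos, wt, mut), position = pos,
              wtCodon = wt, mutCodon = mut,
              deltaGc = deltaGC(mut, wt),
              rcu = rcu,
              rcuDv = degreeOfVariation(rcu, pos),
              rtrnaA = relTrnaAbundance(mut, wt, trna),
              caiMut = unname(caiMut), caiWt = caiWt,
              taiMut = unname(taiMut), taiWt = taiWt,
              wobbleBase = wobbleBase(mut))
}
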