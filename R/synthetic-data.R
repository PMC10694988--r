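## Seeded generator for synonymous-variant libraries and three-strain,
## two-replicate read-count tables with known ground truth. The generator
## is an invented surrogate for raw screening data: it emulates a library
## of all single synonymous codon variants of a ~100-codon toxin gene,
## observed as multinomial read counts in a neutral (resistant) strain, a
## strain selecting against free toxin (sensitive) and a reporter strain
## selecting with the amount of toxin-antitoxin complex (relE).

#' Random sense-codon gene
#'
#' Generates a gene of `nCodons` sense codons (ATG first, no internal
#' stops), used as the WT backbone for simulations and tests.
#'
#' @param nCodons gene length in codons.
#' @param seed RNG seed.
#' @return character vector of codons.
#' @export
randomSynGene <- function(nCodons = 101, seed = 1) {
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    set.seed(seed)
    c("ATG", sample(sense, nCodons - 1L, replace = TRUE))
}

#' Enumerate all single synonymous codon variants of a gene
#'
#' For each codon position, every synonymous codon other than the WT
#' codon, in deterministic order (position, then codon lexicographic).
#' Synonymy guarantees no stop codon can arise.
#'
#' @param gene codon vector or nucleotide string of sense codons.
#' @return data.frame with `position`, `wtCodon`, `mutCodon`, `aa`,
#'   `label`.
#' @examples
#' enumerateSynonymousLibrary(c("ATG", "AAA"))  # one variant: K2_AAG
#' @export
enumerateSynonymousLibrary <- function(gene) {
    if (length(gene) == 1L) gene <- codonsOf(gene)
    gene <- toupper(gene)
    if (any(translateCodons(gene) == "*")) stop("internal stop codon")
    rows <- lapply(seq_along(gene), function(j) {
        syn <- sort(synonymousCodons(gene[j]))
        if (length(syn) == 0L) return(NULL)
        data.frame(position = j, wtCodon = gene[j], mutCodon = syn)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
        return(data.frame(position = integer(0), wtCodon = character(0),
                          mutCodon = character(0), aa = character(0),
                          label = character(0)))
    }
    out$aa <- translateCodons(out$wtCodon)
    out$label <- variantLabel(out$position, out$wtCodon, out$mutCodon)
    out
}

#' Map mechanistic variant parameters to true selection ratios
#'
#' An intentionally simple model of the operon's selection logic. Each
#' variant has a translational efficiency `epsilon` and folded fraction
#' `phi` (WT: both 1), giving functional toxin `t = epsilon * phi`. Up to
#' `alpha` units of toxin are sequestered by the antitoxin
#' (`complex = min(t, alpha)`); the remainder is free toxin. The amount of
#' promoter-repressing complex equals the sequestered complex, minus an
#' optional conditional-cooperativity term `gamma * max(0, t - alpha)`
#' (excess toxin disrupting the repressing complex; `gamma = 0` disables
#' it), floored at 0. Survival ratios are then
#' `rhoSen = exp(-kF * (free - freeWT))` in the sensitive strain and
#' `rhoRelE = exp(-kR * (derepression - derepressionWT))` in the reporter
#' strain, with `derepression = alpha - repressingComplex`. The WT maps to
#' `(1, 1)` exactly.
#'
#' @param epsilon,phi positive numeric vectors (recycled), WT value 1.
#' @param kF,kR selection strengths of the two screens.
#' @param alpha antitoxin capacity in WT-toxin units.
#' @param gamma conditional-cooperativity (complex-disruption) coefficient.
#' @return data.frame with `rhoSen` and `rhoRelE`.
#' @export
truthFromMechanism <- function(epsilon, phi = 1, kF = 1, kR = 1,
                               alpha = 1.2, gamma = 0) {
    if (any(epsilon <= 0) || any(phi <= 0)) {
        stop("epsilon and phi must be positive")
    }
    n <- max(length(epsilon), length(phi))
    epsilon <- rep_len(epsilon, n)
    phi <- rep_len(phi, n)
    derepression <- function(t) {
        complex <- pmin(t, alpha)
        repressing <- pmax(0, complex - gamma * pmax(0, t - alpha))
        alpha - repressing
    }
    free <- function(t) pmax(0, t - alpha)
    t <- epsilon * phi
    data.frame(
        rhoSen = exp(-kF * (free(t) - free(1))),
        rhoRelE = exp(-kR * (derepression(t) - derepression(1))))
}

#' Simulate read-count tables for a synonymous-variant screen
#'
#' Draws one multinomial sample of size `depth` per strain x replicate.
#' Expected fractions are the library composition `p` in the resistant
#' strain, `p * rhoSen` (renormalised) in the sensitive strain and
#' `p * rhoRelE` in the reporter strain. Each draw uses its own substream
#' of the master seed (fixed per-condition offsets), so adding a condition
#' never perturbs existing draws and a fixed seed gives byte-identical
#' tables.
#'
#' @param variants data.frame from [enumerateSynonymousLibrary()] (or with
#'   the same columns); the reference row is appended automatically.
#' @param truth data.frame with `rhoSen`, `rhoRelE`, one row per variant
#'   (WT anchor handled internally with both ratios 1).
#' @param depth reads per condition.
#' @param seed master RNG seed.
#' @param p library composition over the variants plus WT (defaults to
#'   uniform); must be a probability simplex.
#' @param replicates number of replicates per strain.
#' @return a [SynMutExperiment-class]; the simulation truth is stored in
#'   `metadata(x)$truth`.
#' @export
sampleCounts <- function(variants, truth, depth = 1e6, seed = 1, p = NULL,
                         replicates = 2L) {
    n <- nrow(variants)
    if (nrow(truth) != n) stop("truth must have one row per variant")
    if (any(truth$rhoSen <= 0) || any(truth$rhoRelE <= 0)) {
        stop("true ratios must be positive")
    }
    if (is.null(p)) p <- rep(1 / (n + 1L), n + 1L)
    if (length(p) != n + 1L || any(p <= 0) || abs(sum(p) - 1) > 1e-8) {
        stop("p must be a positive simplex over variants + WT")
    }
    rho <- list(resistant = rep(1, n + 1L),
                sensitive = c(truth$rhoSen, 1),
                relE = c(truth$rhoRelE, 1))
    cols <- list()
    for (ci in seq_along(rho)) {
        strain <- names(rho)[ci]
        for (r in seq_len(replicates)) {
            probs <- p * rho[[ci]]
            probs <- probs / sum(probs)
            set.seed(seed + 100L * ci + r)
            nm <- paste0(c(resistant = "res", sensitive = "sen",
                           relE = "relE")[strain], "_rep", r)
            cols[[nm]] <- as.integer(stats::rmultinom(1L, depth, probs))
        }
    }
    counts <- do.call(cbind, cols)
    ## the reference row is the unmutated gene; book-keep it under the
    ## first variant's position with an identity codon pair
    wtPos <- variants$position[1L]
    wtCodon <- variants$wtCodon[1L]
    se <- SynMutExperiment(
        counts = counts,
        position = c(variants$position, wtPos),
        wtCodon = c(variants$wtCodon, wtCodon),
        mutCodon = c(variants$mutCodon, wtCodon),
        isRef = c(rep(FALSE, n), TRUE),
        metadata = list(truth = cbind(variants,
                                      truth[, c("rhoSen", "rhoRelE")]),
                        depth = depth, seed = seed))
    se
}

#' One-call simulation of a synonymous-variant screen
#'
#' Convenience wrapper: random gene, full synonymous library (optionally
#' truncated to `nVariants`), ground truth in direct-ratio or mechanistic
#' mode, and multinomial counts.
#'
#' @param nCodons gene length in codons.
#' @param nVariants optional cap on the number of variants (first
#'   `nVariants` in enumeration order).
#' @param mode `"direct"` (ratios drawn log-normally, or given) or
#'   `"mechanistic"` (via [truthFromMechanism()]).
#' @param rhoSen,rhoRelE direct-mode true ratios (length 1 or per
#'   variant); drawn log-normal with `sdLog` when `NULL`.
#' @param sdLog standard deviation of `log(rho)` for drawn ratios.
#' @param epsilon,phi,kF,kR,alpha,gamma mechanistic-mode parameters.
#' @param depth,seed,p,replicates passed to [sampleCounts()].
#' @return a [SynMutExperiment-class] with `metadata(x)$truth`.
#' @export
simulateSynScreen <- function(nCodons = 101, nVariants = NULL,
                              mode = c("direct", "mechanistic"),
                              rhoSen = NULL, rhoRelE = NULL, sdLog = 0.5,
                              epsilon = 1, phi = 1, kF = 1, kR = 1,
                              alpha = 1.2, gamma = 0,
                              depth = 1e6, seed = 1, p = NULL,
                              replicates = 2L) {
    mode <- match.arg(mode)
    gene <- randomSynGene(nCodons, seed = seed)
    variants <- enumerateSynonymousLibrary(gene)
    if (!is.null(nVariants)) {
        if (nVariants > nrow(variants)) {
            stop("gene yields only ", nrow(variants), " variants")
        }
        variants <- variants[seq_len(nVariants), ]
    }
    n <- nrow(variants)
    truth <- if (mode == "direct") {
        set.seed(seed + 7L)
        data.frame(
            rhoSen = if (is.null(rhoSen)) {
                exp(stats::rnorm(n, 0, sdLog))
            } else rep_len(rhoSen, n),
            rhoRelE = if (is.null(rhoRelE)) {
                exp(stats::rnorm(n, 0, sdLog))
            } else rep_len(rhoRelE, n))
    } else {
        truthFromMechanism(rep_len(epsilon, n), rep_len(phi, n),
                           kF = kF, kR = kR, alpha = alpha, gamma = gamma)
    }
    se <- sampleCounts(variants, truth, depth = depth, seed = seed, p = p,
                       replicates = replicates)
    metadata(se)$gene <- gene
    se
}

#' Write a simulated screen to disk
#'
#' Emits the count table in the standard TSV schema, the ground-truth
#' table, and the WT gene as FASTA.
#'
#' @param x a simulated [SynMutExperiment-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCountTable(x, file.path(dir, "counts.tsv"))
    md <- metadata(x)
    if (!is.null(md$truth)) {
        utils::write.table(md$truth, file.path(dir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(md$gene)) {
        gene <- Biostrings::DNAStringSet(paste(md$gene, collapse = ""))
        names(gene) <- "synthetic_gene"
        Biostrings::writeXStringSet(gene, file.path(dir, "gene.fasta"))
    }
    invisible(dir)
}
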