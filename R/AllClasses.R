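#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   rowData<- colData
NULL

STRAINS <- c("resistant", "sensitive", "relE")

#' Container for a synonymous-variant screening experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are single
#' synonymous codon variants of one gene (plus exactly one reference row,
#' usually the wild type) and whose columns are strain x replicate
#' sequencing conditions. The `"counts"` assay holds raw read counts.
#'
#' Row metadata: `position` (1-based codon index), `wtCodon`, `mutCodon`
#' (3-letter DNA codons encoding the same amino acid), `aa`, `label`
#' (e.g. `"K4_AAA"`), `isRef` (logical; `TRUE` exactly once). Column
#' metadata: `strain` (one of `"resistant"`, `"sensitive"`, `"relE"`) and
#' `replicate`.
#'
#' @aliases SynMutExperiment-class
#' @export
setClass("SynMutExperiment", contains = "SummarizedExperiment")

setValidity("SynMutExperiment", function(object) {
    msg <- character(0)
    rd <- rowData(object)
    need <- c("position", "wtCodon", "mutCodon", "aa", "label", "isRef")
    if (!all(need %in% colnames(rd))) {
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    }
    cd <- colData(object)
    if (!all(c("strain", "replicate") %in% colnames(cd))) {
        return("colData must contain 'strain' and 'replicate'")
    }
    if (!all(cd$strain %in% STRAINS)) {
        msg <- c(msg, paste("strain must be one of:",
                            paste(STRAINS, collapse = ", ")))
    }
    if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
        msg <- c(msg, "assay 'counts' is required")
    } else {
        cnt <- assay(object, "counts")
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
    }
    if (sum(rd$isRef) != 1L) {
        msg <- c(msg, "exactly one reference (isRef) row is required")
    }
    nonref <- !rd$isRef
    if (any(nonref & rd$wtCodon == rd$mutCodon)) {
        msg <- c(msg, "non-reference rows must have mutCodon != wtCodon")
    }
    syn <- isSynonymous(rd$wtCodon, rd$mutCodon)
    if (!all(syn)) {
        msg <- c(msg, paste("non-synonymous codon pair in row(s):",
                            paste(which(!syn), collapse = ", ")))
    }
    if (anyDuplicated(rd$label)) {
        msg <- c(msg, paste("duplicate variant:",
                            rd$label[duplicated(rd$label)][1L]))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SynMutExperiment
#'
#' @param counts integer matrix, variants x conditions. Column names follow
#'   the `<strain>_rep<k>` convention (`res_rep1`, ..., `relE_rep2`) unless
#'   `colData` is supplied explicitly.
#' @param position integer vector of 1-based codon positions.
#' @param wtCodon,mutCodon DNA codons per row; synonymous by construction.
#'   The reference row conventionally has `mutCodon == wtCodon`.
#' @param isRef logical vector flagging the single reference row.
#' @param colData optional `DataFrame` with `strain` and `replicate`.
#' @param metadata optional list stored in the object metadata.
#' @return A [SynMutExperiment-class] object.
#' @examples
#' se <- SynMutExperiment(
#'     counts   = matrix(50L, 2, 6, dimnames = list(NULL, c(
#'         "res_rep1", "res_rep2", "sen_rep1",
#'         "sen_rep2", "relE_rep1", "relE_rep2"))),
#'     position = c(4L, 4L), wtCodon = c("AAG", "AAG"),
#'     mutCodon = c("AAG", "AAA"), isRef = c(TRUE, FALSE))
#' se
#' @export
SynMutExperiment <- function(counts, position, wtCodon, mutCodon, isRef,
                             colData = NULL, metadata = list()) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    wtCodon <- toupper(wtCodon)
    mutCodon <- toupper(mutCodon)
    if (is.null(colData)) {
        colData <- conditionColData(colnames(counts))
    }
    rd <- DataFrame(position = as.integer(position),
                    wtCodon = wtCodon, mutCodon = mutCodon,
                    aa = translateCodons(wtCodon),
                    label = variantLabel(position, wtCodon, mutCodon),
                    isRef = as.logical(isRef))
    rownames(counts) <- rd$label
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowData = rd, colData = colData,
                               metadata = metadata)
    new("SynMutExperiment", se)
}

## Derive strain/replicate colData from `<strain>_rep<k>` column names.
conditionColData <- function(nms) {
    if (is.null(nms)) stop("count matrix must have condition column names")
    m <- regmatches(nms, regexec("^(res|sen|relE)_rep([0-9]+)$", nms))
    bad <- lengths(m) != 3L
    if (any(bad)) {
        stop("unrecognized condition column(s): ",
             paste(nms[bad], collapse = ", "))
    }
    strain <- vapply(m, `[`, "", 2L)
    strain <- c(res = "resistant", sen = "sensitive", relE = "relE")[strain]
    DataFrame(strain = unname(strain),
              replicate = as.integer(vapply(m, `[`, "", 3L)),
              row.names = nms)
}

setMethod("show", "SynMutExperiment", function(object) {
    rd <- rowData(object)
    cat("SynMutExperiment with", nrow(object), "variants",
        sprintf("(reference: %s)\n", rd$label[rd$isRef]))
    cat(" positions:", min(rd$position), "-", max(rd$position), "\n")
    cat(" conditions:", paste(colnames(object), collapse = ", "), "\n")
})

#' @describeIn SynMutExperiment Variant labels (e.g. `"K4_AAA"`).
#' @param x a `SynMutExperiment`.
#' @export
variantLabels <- function(x) rowData(x)$label

#' @describeIn SynMutExperiment Index of the reference row.
#' @export
referenceIndex <- function(x) which(rowData(x)$isRef)

#' @describeIn SynMutExperiment Count vector for one strain/replicate.
#' @param strain one of `"resistant"`, `"sensitive"`, `"relE"`.
#' @param replicate replicate number.
#' @export
strainCounts <- function(x, strain, replicate) {
    cd <- colData(x)
    j <- which(cd$strain == strain & cd$replicate == replicate)
    if (length(j) != 1L) {
        stop("condition not found (or not unique): ", strain,
             " replicate ", replicate)
    }
    assay(x, "counts")[, j]
}

#' Classification thresholds for enrichment scores
#'
#' Holds the activity and regulation cutoffs used by [classifyPhenotype()]:
#' a variant is hyperactive when its toxin-strain enrichment score falls
#' strictly below `hyperactiveMax`, inactive strictly above `inactiveMin`,
#' and repressing/derepressing when its reporter-strain score lies strictly
#' above/below `releNeutral`.
#'
#' @aliases SynThresholds-class
#' @export
setClass("SynThresholds", representation(hyperactiveMax = "numeric",
                                         inactiveMin = "numeric",
                                         releNeutral = "numeric"))

setValidity("SynThresholds", function(object) {
    if (object@hyperactiveMax >= object@inactiveMin) {
        "hyperactiveMax must be < inactiveMin"
    } else TRUE
})

#' @param hyperactiveMax upper bound (exclusive) for the hyperactive class.
#' @param inactiveMin lower bound (exclusive) for the inactive class.
#' @param releNeutral neutral point of the reporter score.
#' @return `synThresholds()` returns a `SynThresholds` object.
#' @rdname SynThresholds-class
#' @examples
#' synThresholds()
#' @export
synThresholds <- function(hyperactiveMax = 0.7, inactiveMin = 1.8,
                          releNeutral = 1) {
    new("SynThresholds", hyperactiveMax = hyperactiveMax,
        inactiveMin = inactiveMin, releNeutral = releNeutral)
}

setMethod("show", "SynThresholds", function(object) {
    cat(sprintf(
        "SynThresholds: hyperactive < %g, inactive > %g, repressing > %g\n",
        object@hyperactiveMax, object@inactiveMin, object@releNeutral))
})
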