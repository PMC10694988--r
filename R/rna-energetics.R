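#' Thermodynamic folding engine backed by the ViennaRNA command-line tools
#'
#' A thin, deterministic interface to `RNAduplex` (bimolecular duplex
#' interaction energies, intramolecular structure disallowed) and `RNAfold`
#' (single-strand minimum free energy and MFE structure) under the current
#' Turner nearest-neighbour parameters. Both programs must be on the
#' `PATH`. Temperature defaults to 37 degrees C; dangling ends are left at
#' the engine default. Predicted interaction energies that are not
#' stabilising (`>= 0`) are reported as 0 ("no stable duplex").
#'
#' @aliases ViennaEngine-class
#' @export
setClass("ViennaEngine", representation(temperature = "numeric"))

#' @param temperature folding temperature in degrees Celsius.
#' @return a `ViennaEngine`.
#' @rdname ViennaEngine-class
#' @export
viennaEngine <- function(temperature = 37) {
    for (tool in c("RNAduplex", "RNAfold")) {
        if (Sys.which(tool) == "") {
            stop(tool, " not found on the PATH; install ViennaRNA")
        }
    }
    new("ViennaEngine", temperature = temperature)
}

setMethod("show", "ViennaEngine", function(object) {
    cat("ViennaEngine (RNAduplex/RNAfold), T =", object@temperature, "C\n")
})

toRNA <- function(x) gsub("T", "U", toupper(x))

parseEnergies <- function(lines) {
    m <- regmatches(lines, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", lines))
    as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

runVienna <- function(tool, args, input) {
    out <- suppressWarnings(system2(tool, args = args, input = input,
                                    stdout = TRUE, stderr = FALSE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
        stop(tool, " failed with status ", status)
    }
    out
}

#' Bimolecular duplex interaction energies
#'
#' Minimum interaction free energy of each query sequence with a common
#' target, computed by `RNAduplex` (intramolecular structure within each
#' strand disallowed). DNA input is transcribed to RNA. Energies `>= 0`
#' are clamped to 0 (no stable duplex).
#'
#' @param engine a [ViennaEngine-class].
#' @param queries character vector of sequences (DNA or RNA).
#' @param target single target sequence.
#' @return numeric vector of energies in kcal/mol, all `<= 0`.
#' @export
duplexEnergies <- function(engine, queries, target) {
    if (length(queries) == 0L) return(numeric(0))
    if (any(nchar(queries) == 0L) || nchar(target) == 0L) {
        stop("empty sequence")
    }
    input <- as.vector(rbind(toRNA(queries), toRNA(target)))
    out <- runVienna("RNAduplex",
                     c("-T", format(engine@temperature)), input)
    e <- parseEnergies(out[grepl("\\(\\s*-?[0-9.]+\\)\\s*$", out)])
    if (length(e) != length(queries)) {
        stop("RNAduplex returned ", length(e), " energies for ",
             length(queries), " queries")
    }
    pmin(e, 0)
}

#' Single-strand minimum free energies
#'
#' MFE of each sequence under the full intramolecular model (`RNAfold`).
#'
#' @inheritParams duplexEnergies
#' @param sequences character vector (DNA or RNA).
#' @return numeric vector of MFE values in kcal/mol, all `<= 0`.
#' @export
foldEnergies <- function(engine, sequences) {
    if (length(sequences) == 0L) return(numeric(0))
    out <- runVienna("RNAfold",
                     c("--noPS", "-T", format(engine@temperature)),
                     toRNA(sequences))
    struct <- out[grepl("^[.()]+\\s+\\(", out)]
    e <- parseEnergies(struct)
    if (length(e) != length(sequences)) {
        stop("RNAfold returned ", length(e), " energies for ",
             length(sequences), " sequences")
    }
    pmin(e, 0)
}

#' MFE structure of a single sequence
#'
#' @inheritParams duplexEnergies
#' @param sequence one sequence (DNA or RNA).
#' @return list with `structure` (dot-bracket string) and `mfe` (kcal/mol).
#' @export
foldStructure <- function(engine, sequence) {
    out <- runVienna("RNAfold",
                     c("--noPS", "-T", format(engine@temperature)),
                     toRNA(sequence))
    line <- out[grepl("^[.()]+\\s+\\(", out)][1L]
    list(structure = sub("\\s.*$", "", line), mfe = parseEnergies(line))
}

## --- transcripts ----------------------------------------------------------

#' Model of the toxin mRNA used for energy calculations
#'
#' The transcript is the coding sequence plus a fixed upstream stretch
#' (default 18 nt) holding the putative Shine-Dalgarno region, stored as
#' RNA. For a 306-nt CDS the standard transcript is 324 nt with the start
#' codon at position 19.
#'
#' @aliases TranscriptModel-class
#' @export
setClass("TranscriptModel", representation(sequence = "character",
                                           cdsStart = "integer",
                                           cdsLength = "integer",
                                           sdOffset = "integer"))

setValidity("TranscriptModel", function(object) {
    msg <- character(0)
    if (object@cdsLength %% 3L != 0L) {
        msg <- c(msg, "cdsLength must be divisible by 3")
    }
    if (nchar(object@sequence) != object@cdsStart - 1L + object@cdsLength) {
        msg <- c(msg, "sequence length must equal upstream + cdsLength")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TranscriptModel", function(object) {
    cat(sprintf("TranscriptModel: %d nt (%d nt upstream + %d nt CDS)\n",
                nchar(object@sequence), object@cdsStart - 1L,
                object@cdsLength))
})

#' @describeIn TranscriptModel the RNA sequence of the transcript.
#' @param x a `TranscriptModel`.
#' @export
transcriptSequence <- function(x) x@sequence

#' Build the (mutant) transcript for a variant
#'
#' Extracts the CDS plus `upstream` nucleotides from an operon sequence
#' and substitutes the variant codon. With `variant = NULL` the WT
#' transcript is returned. The substitution must be synonymous.
#'
#' @param operon operon nucleotide string (DNA or RNA).
#' @param cdsStart 1-based position of the first CDS base in `operon`.
#' @param cdsLength CDS length in nucleotides (multiple of 3).
#' @param variant optional list/row with `position`, `wtCodon`, `mutCodon`.
#' @param upstream upstream stretch length included in the transcript.
#' @return a [TranscriptModel-class].
#' @export
buildTranscript <- function(operon, cdsStart, cdsLength, variant = NULL,
                            upstream = 18L) {
    operon <- toupper(as.character(operon)[1L])
    if (cdsStart - upstream < 1L ||
        cdsStart + cdsLength - 1L > nchar(operon)) {
        stop("CDS with upstream stretch does not fit in the operon sequence")
    }
    tx <- substr(operon, cdsStart - upstream, cdsStart + cdsLength - 1L)
    if (!is.null(variant)) {
        pos <- as.integer(variant$position)
        if (pos < 1L || pos > cdsLength %/% 3L) {
            stop("variant position beyond the CDS")
        }
        at <- upstream + 3L * (pos - 1L) + 1L
        have <- gsub("U", "T", substr(tx, at, at + 2L))
        wt <- toupper(variant$wtCodon)
        mut <- toupper(variant$mutCodon)
        if (have != wt) {
            stop("transcript codon ", have, " at position ", pos,
                 " does not match variant wtCodon ", wt)
        }
        if (!isSynonymous(wt, mut)) {
            stop("substitution changes the encoded amino acid")
        }
        substr(tx, at, at + 2L) <- mut
    }
    new("TranscriptModel", sequence = toRNA(tx),
        cdsStart = as.integer(upstream + 1L),
        cdsLength = as.integer(cdsLength), sdOffset = 1L)
}

#' Shine-Dalgarno : anti-Shine-Dalgarno duplex energy
#'
#' Minimum bimolecular interaction energy between a putative SD sequence
#' and the 16S rRNA anti-SD consensus, the standard measure of
#' ribosome-binding-site strength.
#'
#' @param sdSequence putative SD sequence (DNA or RNA).
#' @param asdSequence anti-SD sequence; consensus `"CACCUCCU"`.
#' @param engine a [ViennaEngine-class].
#' @return energy in kcal/mol (`<= 0`).
#' @examples
#' \dontrun{sdDuplexEnergy("AAAGAGGT")  # -6.7}
#' @export
sdDuplexEnergy <- function(sdSequence, asdSequence = "CACCUCCU",
                           engine = viennaEngine()) {
    duplexEnergies(engine, sdSequence, asdSequence)
}

## --- window profiles ------------------------------------------------------

#' Sliding-window energy profile
#'
#' Ordered per-window energies over a transcript: either the anti-SD
#' duplex interaction of each window (ribosome-pausing propensity) or the
#' single-strand MFE of each window.
#'
#' @aliases EnergyProfile-class
#' @export
setClass("EnergyProfile", representation(windowSize = "integer",
                                         step = "integer",
                                         energies = "numeric",
                                         sequence = "character"))

setValidity("EnergyProfile", function(object) {
    L <- nchar(object@sequence)
    expected <- (L - object@windowSize) %/% object@step + 1L
    msg <- character(0)
    if (length(object@energies) != expected) {
        msg <- c(msg, sprintf("expected %d windows, got %d", expected,
                              length(object@energies)))
    }
    if (any(object@energies > 0)) msg <- c(msg, "energies must be <= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "EnergyProfile", function(object) {
    cat(sprintf("EnergyProfile: %d windows of %d nt (step %d), mean %.2f kcal/mol\n",
                length(object@energies), object@windowSize, object@step,
                mean(object@energies)))
})

#' @describeIn EnergyProfile the per-window energy vector.
#' @param x an `EnergyProfile`.
#' @export
profileEnergies <- function(x) x@energies

slidingWindows <- function(sequence, window, step) {
    L <- nchar(sequence)
    if (L < window) {
        stop("sequence (", L, " nt) shorter than the window (", window, ")")
    }
    starts <- seq(1L, L - window + 1L, by = step)
    substring(sequence, starts, starts + window - 1L)
}

#' Anti-SD interaction profile along a transcript
#'
#' For every `window`-nt window of the transcript, the bimolecular duplex
#' interaction energy with the anti-SD sequence. Internal SD-like motifs
#' show up as strongly negative windows (putative ribosome pause sites).
#'
#' @param transcript a [TranscriptModel-class] or sequence string.
#' @param engine a [ViennaEngine-class].
#' @param window window width in nt.
#' @param step window step in nt.
#' @param asdSequence anti-SD sequence.
#' @return an [EnergyProfile-class].
#' @export
asdWindowProfile <- function(transcript, engine = viennaEngine(),
                             window = 10L, step = 1L,
                             asdSequence = "CACCUCCU") {
    seqc <- if (is(transcript, "TranscriptModel")) {
        transcriptSequence(transcript)
    } else toRNA(transcript)
    wins <- slidingWindows(seqc, window, step)
    new("EnergyProfile", windowSize = as.integer(window),
        step = as.integer(step),
        energies = duplexEnergies(engine, wins, asdSequence),
        sequence = seqc)
}

#' Average mutant-minus-WT anti-SD energy difference
#'
#' The per-window differences are averaged over the *affected* windows by
#' default (windows whose sequence differs between mutant and WT, at most
#' `window + 2` for a single codon change); averaging a 3-nt local effect
#' over all windows of a long transcript would dilute it toward zero. The
#' two conventions are related algebraically: the affected-window mean
#' equals the all-window mean times (total windows / affected windows),
#' because unaffected windows contribute zero difference. Negative values
#' mean the mutant has stronger internal anti-SD pairing (more predicted
#' pausing) than WT; positive values mean less pausing.
#'
#' @param mutantProfile,wtProfile [EnergyProfile-class] objects computed
#'   with identical window/step settings on equal-length transcripts.
#' @param windows `"affected"` (default) or `"all"`.
#' @return mean energy difference in kcal/mol; exactly 0 for the identity
#'   variant.
#' @export
deltaASD <- function(mutantProfile, wtProfile,
                     windows = c("affected", "all")) {
    windows <- match.arg(windows)
    stopProfileMismatch(mutantProfile, wtProfile)
    d <- mutantProfile@energies - wtProfile@energies
    if (windows == "all") return(mean(d))
    mw <- slidingWindows(mutantProfile@sequence, mutantProfile@windowSize,
                         mutantProfile@step)
    ww <- slidingWindows(wtProfile@sequence, wtProfile@windowSize,
                         wtProfile@step)
    aff <- mw != ww
    if (!any(aff)) return(0)
    mean(d[aff])
}

stopProfileMismatch <- function(a, b) {
    if (a@windowSize != b@windowSize || a@step != b@step ||
        nchar(a@sequence) != nchar(b@sequence)) {
        stop("profiles differ in window, step or transcript length")
    }
}

#' Windowed average minimum free energy of a transcript
#'
#' Mean single-strand MFE over all `window`-nt sliding windows.
#'
#' @inheritParams asdWindowProfile
#' @return mean MFE in kcal/mol (`<= 0`).
#' @export
mfeWindowAverage <- function(transcript, engine = viennaEngine(),
                             window = 30L, step = 1L) {
    seqc <- if (is(transcript, "TranscriptModel")) {
        transcriptSequence(transcript)
    } else toRNA(transcript)
    mean(foldEnergies(engine, slidingWindows(seqc, window, step)))
}

#' Mutant-minus-WT windowed MFE difference
#'
#' @param mutantAvg,wtAvg values from [mfeWindowAverage()] under the same
#'   windowing.
#' @return `mutantAvg - wtAvg`; positive values indicate a destabilised
#'   mutant transcript.
#' @export
deltaMFE <- function(mutantAvg, wtAvg) mutantAvg - wtAvg

#' Predicted accessibility of the ribosome-binding site
#'
#' Folds a short region around the SD sequence and reports the fraction of
#' SD-span bases left unpaired in the MFE structure (1 = fully
#' accessible, 0 = fully occluded).
#'
#' @param region nucleotide string containing the SD sequence.
#' @param sdSpan integer vector of positions of the SD within `region`
#'   (e.g. `17:24`).
#' @param engine a [ViennaEngine-class].
#' @return fraction in `[0, 1]`.
#' @export
rbsAccessibility <- function(region, sdSpan, engine = viennaEngine()) {
    region <- toRNA(region)
    if (length(sdSpan) == 0L) stop("empty SD span")
    if (min(sdSpan) < 1L || max(sdSpan) > nchar(region)) {
        stop("SD span outside the region")
    }
    fold <- foldStructure(engine, region)
    paired <- strsplit(fold$structure, "")[[1L]] != "."
    mean(!paired[sdSpan])
}
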