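# All tests here exercise the ViennaRNA-backed engine, which the package
# requires at run time (RNAduplex/RNAfold on the PATH).

engine <- viennaEngine()

test_that("transcripts are the upstream stretch plus the substituted CDS", {
    set.seed(2)
    gene <- randomSynGene(102, seed = 2)           # 306-nt CDS
    operon <- paste0(paste(rep("ACGT", 10), collapse = ""),
                     paste(gene, collapse = ""), "GGTT")
    cdsStart <- 41L
    wt <- buildTranscript(operon, cdsStart, 306L)
    expect_equal(nchar(transcriptSequence(wt)), 324L)
    expect_false(grepl("T", transcriptSequence(wt)))  # RNA

    v <- list(position = 4, wtCodon = gene[4],
              mutCodon = synonymousCodons(gene[4])[1])
    mut <- buildTranscript(operon, cdsStart, 306L, variant = v)
    d <- which(strsplit(transcriptSequence(mut), "")[[1]] !=
                   strsplit(transcriptSequence(wt), "")[[1]])
    expect_true(length(d) >= 1 && all(d %in% 28:30))

    expect_error(buildTranscript(operon, cdsStart, 306L,
                                 variant = list(position = 103,
                                                wtCodon = "AAA",
                                                mutCodon = "AAG")),
                 "beyond")
    expect_error(buildTranscript(operon, cdsStart, 306L,
                                 variant = list(position = 4,
                                                wtCodon = gene[4],
                                                mutCodon = "GGG")))
})

test_that("duplex energies are non-positive and detect SD-like motifs", {
    e <- duplexEnergies(engine, c("AAAAAAAAAA", "AAAGGAGGAA"), "CACCUCCU")
    expect_equal(e[1], 0)        # no stable duplex with poly-A
    expect_lt(e[2], e[1])        # internal SD motif binds the anti-SD
    expect_error(duplexEnergies(engine, "", "CACCUCCU"), "empty")
})

test_that("anti-SD window profiles have the expected geometry", {
    p1 <- asdWindowProfile("AAAGGAGGUA", engine)   # exactly one window
    expect_length(profileEnergies(p1), 1)
    polyA <- asdWindowProfile(strrep("A", 20), engine)
    expect_equal(profileEnergies(polyA), rep(0, 11))
    # window-count formula over assorted geometries
    for (L in c(10, 17, 30)) {
        for (w in c(5, 10)) {
            for (s in c(1, 3)) {
                p <- asdWindowProfile(strrep("A", L), engine,
                                      window = w, step = s)
                expect_length(profileEnergies(p), (L - w) %/% s + 1)
            }
        }
    }
    expect_error(asdWindowProfile("AAAA", engine, window = 10), "shorter")
})

test_that("delta-aSD averages affected windows and is 0 for identity", {
    wtSeq <- paste0(strrep("A", 12), "CAAC", strrep("A", 12))
    mutSeq <- sub("CAAC", "GAGG", wtSeq)  # creates an internal SD motif
    wt <- asdWindowProfile(wtSeq, engine)
    mut <- asdWindowProfile(mutSeq, engine)
    expect_equal(deltaASD(wt, wt), 0)
    dAff <- deltaASD(mut, wt, windows = "affected")
    expect_lt(dAff, 0)  # more pausing than WT
    # algebraic relation between the two averaging conventions
    dAll <- deltaASD(mut, wt, windows = "all")
    wins <- nchar(wtSeq) - 10 + 1
    affected <- sum(substring(mutSeq, 1:wins, 10:nchar(mutSeq)) !=
                        substring(wtSeq, 1:wins, 10:nchar(wtSeq)))
    expect_equal(dAff, dAll * wins / affected)
    expect_error(deltaASD(mut, asdWindowProfile(strrep("A", 40), engine)),
                 "differ")
})

test_that("windowed MFE averages behave like the single-window MFE", {
    hairpin <- "GGGGGGCAAAAGCCCCCCAAAAAAAAAAAA"  # 30 nt, stable stem-loop
    expect_equal(mfeWindowAverage(hairpin, engine),
                 foldEnergies(engine, hairpin))
    expect_equal(mfeWindowAverage(strrep("A", 40), engine), 0)
    expect_lt(mfeWindowAverage(paste0(hairpin, hairpin), engine), 0)
    expect_equal(deltaMFE(-10, -12), 2)
    expect_equal(deltaMFE(-12, -10), -deltaMFE(-10, -12))
})

test_that("RBS accessibility is the unpaired fraction of the SD span", {
    open <- paste0(strrep("A", 16), "AGGAGG", strrep("A", 16))
    expect_equal(rbsAccessibility(open, 17:22, engine), 1)
    # SD buried in a perfect hairpin stem
    sd <- "AGGAGG"
    stem <- paste0(sd, "GCGCGC", "AAAA", "GCGCGC", "CCUCCU")
    acc <- rbsAccessibility(stem, 1:6, engine)
    expect_equal(acc, 0)
    expect_error(rbsAccessibility(open, integer(0), engine), "empty")
    expect_error(rbsAccessibility(open, 30:50, engine), "outside")
})
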