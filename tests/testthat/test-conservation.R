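test_that("homolog filters apply inclusive identity/coverage bounds", {
    hits <- data.frame(id = letters[1:5],
                       percent_identity = c(96, 95, 80, 80, 94),
                       query_coverage = c(95, 100, 89, 90, 98))
    kept <- filterHomologs(hits)
    expect_equal(kept$id, c("b", "d", "e"))  # 96% identity and 89% coverage out
    # idempotent
    expect_equal(filterHomologs(kept), kept)
    expect_error(filterHomologs(data.frame(id = 1)), "columns")
})

test_that("codon conservation classes match a brute-force tally", {
    # 5-homolog toy alignment over a 3-codon WT (AAA GGA TTA)
    aln <- toyAlignmentMatrix(c(
        wt = "AAAGGATTA",
        h1 = "AAAGGATTA",
        h2 = "AAAGGTCTG",   # GGT syn; CTG syn (Leu)
        h3 = "AAGGGTTTA",
        h4 = "AAAG--CTA",   # gapped codon 2; CTA syn
        h5 = "AACGGCTTA"))  # AAC = Asn (non-synonymous at codon 1)
    res <- codonConservation(aln, "wt")
    s <- res$summary
    # codon 1: syn counts AAA=3, AAG=1; AAC excluded as non-synonymous
    expect_equal(res$perPosition[[1]][["AAA"]], 3L)
    expect_equal(res$perPosition[[1]][["AAG"]], 1L)
    expect_equal(s$nonSynCount[1], 1L)
    expect_equal(s$wtClass[1], "most")
    # codon 2: GGA=1, GGT=2, GGC=1; one gap; WT neither max nor strict min
    expect_equal(s$gapCount[2], 1L)
    expect_equal(s$wtClass[2], "intermediate")
    # codon 3: TTA=3, CTG=1, CTA=1 -> most
    expect_equal(s$wtClass[3], "most")

    # independent exhaustive tally of codon 2
    hom <- aln[2:6, 4:6]
    codons <- apply(hom, 1, paste, collapse = "")
    codons <- codons[grepl("^[ACGT]{3}$", codons)]
    codons <- codons[translateCodons(codons) == "G"]
    tab <- table(codons)
    expect_equal(res$perPosition[[2]][sort(names(tab))],
                 setNames(as.integer(tab[sort(names(tab))]),
                          sort(names(tab))))
})

test_that("conservation classes honour strict-extremum tie-breaking", {
    aln <- toyAlignmentMatrix(c(wt = "AAA", h1 = "AAA", h2 = "AAG"))
    res <- codonConservation(aln, "wt")
    expect_equal(res$summary$wtClass, "intermediate")  # 1-1 tie

    allSame <- toyAlignmentMatrix(c(wt = "AAAGAA", h1 = "AAAGAA",
                                    h2 = "AAAGAA"))
    res2 <- codonConservation(allSame, "wt")
    expect_equal(res2$summary$wtClass, c("most", "most"))
    expect_equal(res2$summary$wtFraction, c(1, 1))

    # WT codon absent from the homologs: strict minimum -> least
    res3 <- codonConservation(toyAlignmentMatrix(
        c(wt = "AAA", h1 = "AAG", h2 = "AAG")), "wt")
    expect_equal(res3$summary$wtClass, "least")
})

test_that("classification is invariant to homolog row order and duplicates", {
    rows <- c(wt = "AAAGGATTA", h1 = "AAAGGATTA", h2 = "AAAGGTCTG",
              h3 = "AAGGGTTTA", h4 = "AAAG--CTA", h5 = "AACGGCTTA")
    a <- codonConservation(toyAlignmentMatrix(rows), "wt")
    b <- codonConservation(toyAlignmentMatrix(rows[c(1, 6, 3, 5, 2, 4)]),
                           "wt")
    expect_equal(a$summary$wtClass, b$summary$wtClass)
    # duplicating a homolog of the majority codon cannot demote a strict max
    dup <- toyAlignmentMatrix(c(rows, h6 = unname(rows["h1"])))
    d <- codonConservation(dup, "wt")
    expect_false(any(a$summary$wtClass == "most" &
                         d$summary$wtClass == "least"))
})

test_that("frame and gap violations are rejected", {
    expect_error(codonConservation(toyAlignmentMatrix(
        c(wt = "AAAA", h1 = "AAAA")), "wt"), "frame")
    expect_error(codonConservation(toyAlignmentMatrix(
        c(wt = "A-AAAA", h1 = "AAAAAA")), "wt"), "ungapped")
    expect_error(codonConservation(toyAlignmentMatrix(
        c(wt = "AAA", h1 = "AAA")), "nope"), "not found")
})

test_that("residue conservation is the percent-identity of each column", {
    aln <- toyAlignmentMatrix(c(wt = "MKV", h1 = "MKV", h2 = "MAV",
                                h3 = "M-V", h4 = "MAI"))
    rc <- residueConservation(aln, "wt")
    expect_equal(rc[1], 100)
    expect_equal(rc[2], 100 * 1 / 3)  # K matches 1 of 3 non-gap residues
    expect_equal(rc[3], 75)
    allGap <- toyAlignmentMatrix(c(wt = "MK", h1 = "M-", h2 = "M-"))
    expect_true(is.na(residueConservation(allGap, "wt")[2]))
})

test_that("class fractions summarise to a unit composition", {
    aln <- toyAlignmentMatrix(c(wt = "AAAGGATTA", h1 = "AAAGGATTA",
                                h2 = "AAAGGTCTG", h3 = "AAGGGTTTA",
                                h4 = "AAAG--CTA", h5 = "AACGGCTTA"))
    res <- codonConservation(aln, "wt")
    frac <- conservedCodonSummary(res)
    expect_equal(sum(frac), 1)
    expect_equal(unname(frac["most"]), 2 / 3)
    expect_error(conservedCodonSummary(
        list(summary = data.frame(wtClass = NA_character_))), "no classified")
})

test_that("alignment files round-trip through the readers", {
    fa <- tempfile(fileext = ".fasta")
    writeLines(c(">wt", "AAAGGATTA", ">h1", "AAAGGTCTG"), fa)
    m <- readAlignment(fa, "fasta", "dna")
    expect_equal(rownames(m), c("wt", "h1"))
    expect_equal(paste(m["h1", ], collapse = ""), "AAAGGTCTG")
})
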