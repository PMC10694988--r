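test_that("GC change of synonymous substitutions is computed and bounded", {
    expect_identical(deltaGC("AAA", "AAG"), -1L)
    expect_identical(deltaGC("GTC", "GTG"), 0L)
    expect_identical(deltaGC("AAG", "AAG"), 0L)
    expect_error(deltaGC("AXA", "AAA"), "invalid")
    # |dGC| <= 3 over every synonymous pair in the code
    gc <- Biostrings::GENETIC_CODE
    for (codon in names(gc)[gc != "*"]) {
        for (syn in synonymousCodons(codon)) {
            expect_lte(abs(deltaGC(syn, codon)), 3)
        }
    }
})

test_that("relative codon usage is a usage-table ratio", {
    expect_equal(relCodonUsage("AAA", "AAG", toyUsage()), 2)
    expect_equal(relCodonUsage("AAG", "AAG", toyUsage()), 1)
    expect_error(relCodonUsage("AAA", "GGG"), "synonymous")
    # reciprocal under argument swap
    u <- codonUsageTable()
    expect_equal(relCodonUsage("CTA", "CTG", u) * relCodonUsage("CTG", "CTA", u),
                 1)
})

test_that("RCU degree of variation mirrors the score-fold machinery", {
    expect_equal(degreeOfVariation(c(0.5, 2, 4), rep(1, 3)), c(0, 0, 1))
    expect_equal(degreeOfVariation(0.25, 7), 0)
})

test_that("CAI equals an independent product-domain oracle", {
    w <- caiWeights(codonUsageTable())
    expect_true(all(w > 0 & w <= 1))
    # the most-used synonym of every amino acid carries weight 1
    aa <- translateCodons(names(w))
    expect_true(all(tapply(w, aa, max) == 1))

    # two-codon toy: weights 0.25 and 1 -> geometric mean 0.5
    expect_equal(cai(c("CTA", "CTG"),
                     weights = c(CTA = 0.25, CTG = 1)), 0.5)
    # gene of maximal-weight codons only
    expect_equal(cai(c("CTG", "CTG", "AAA"),
                     weights = c(CTG = 1, AAA = 1)), 1)
    expect_error(cai(c("ATG", "TAA"), weights = w), "stop codon")

    # oracle equivalence on random 50-codon genes
    set.seed(12)
    sense <- names(w)
    for (i in 1:5) {
        gene <- sample(sense, 50, replace = TRUE)
        oracle <- prod(w[gene])^(1 / 50)
        expect_equal(cai(gene, w), oracle, tolerance = 1e-12)
    }
})

test_that("CAI ratios compare two genes and invert under swap", {
    w <- caiWeights()
    a <- c("CTG", "AAA", "GAA")
    b <- c("CTA", "AAG", "GAG")
    expect_equal(caiRatio(a, a, w), 1)
    expect_equal(caiRatio(a, b, w) * caiRatio(b, a, w), 1)
    expect_gt(caiRatio(a, b, w), 1)  # a is the optimal-codon gene
})

test_that("relative tRNA abundance sums multi-tRNA decoders", {
    trna <- data.frame(codon = c("CTA", "CTA", "CTG"),
                       anticodon = c("x", "y", "z"),
                       fraction_percent = c(1.0, 2.0, 1.5))
    expect_equal(relTrnaAbundance("CTA", "CTG", trna), 2)
    expect_equal(relTrnaAbundance("CTG", "CTG", trna), 1)
    expect_error(relTrnaAbundance("CTC", "CTG", trna), "absent")
    # packaged table: reciprocal property
    expect_equal(relTrnaAbundance("GAA", "GAG") *
                     relTrnaAbundance("GAG", "GAA"), 1)
})

test_that("tAI weights reproduce a hand-computed toy table", {
    toy <- data.frame(amino_acid = c("F", "K"),
                      anticodon = c("GAA", "TTT"), tgcn = c(2, 4))
    w <- taiWeights(toy)
    # raw: TTC (WC with GAA) = 2; TTT (G:U) = (1-0.41)*2 = 1.18
    #      AAA (WC with TTT) = 4; AAG (U:G) = (1-0.68)*4 = 1.28; max = 4
    expect_equal(unname(w["AAA"]), 1)
    expect_equal(unname(w["TTC"]), 0.5)
    expect_equal(unname(w["TTT"]), 1.18 / 4)
    expect_equal(unname(w["AAG"]), 1.28 / 4)
    # codons unreadable from the toy table get the nonzero geometric mean
    gm <- exp(mean(log(c(2, 1.18, 4, 1.28) / 4)))
    expect_equal(unname(w["GGG"]), gm)
    expect_error(taiWeights(toy[0, ]), "empty")

    expect_equal(tai(c("TTT", "AAA"), w), sqrt(1.18 / 4))
    expect_equal(tai("AAA", w), 1)
})

test_that("packaged tAI weights are normalised and usable gene-wide", {
    w <- taiWeights()
    expect_equal(max(w), 1)
    expect_true(all(w > 0 & w <= 1))
    gene <- randomSynGene(30, seed = 5)
    expect_true(tai(gene, w) > 0 && tai(gene, w) <= 1)
})

test_that("wobble-base composition tallies third positions", {
    expect_equal(wobbleBase("AAA"), "A")
    comp <- wobbleComposition(c("AAA", "AAT", "AAG", "AAG"))
    expect_equal(comp$count, c(1L, 0L, 2L, 1L))
    expect_equal(sum(comp$fraction), 1)
    empty <- wobbleComposition(character(0))
    expect_true(all(empty$count == 0) && all(empty$fraction == 0))
})

test_that("hydropathy profiles use the Kyte-Doolittle scale", {
    expect_equal(hydropathyProfile("AAAA"), rep(1.8, 4))
    p <- hydropathyProfile("MKIV", window = 7)  # window >= length: mean
    kd <- kyteDoolittleScale()
    expect_equal(p, rep(mean(kd[c("M", "K", "I", "V")]), 4))
    expect_error(hydropathyProfile("AZ"), "unknown residue")
    expect_error(hydropathyProfile("AAA", window = 0), "window")
})

test_that("covariate table combines the per-variant metrics", {
    gene <- c("ATG", "AAG", "CTG")
    variants <- enumerateSynonymousLibrary(gene)
    cv <- covariateTable(gene, variants)
    expect_equal(nrow(cv), 1 + 5)  # AAG -> AAA, CTG -> 5 leucine codons
    k4 <- cv[cv$label == "K2_AAA", ]
    u <- codonUsageTable()
    expect_equal(k4$deltaGc, -1L)
    expect_equal(k4$rcu, relCodonUsage("AAA", "AAG", u))
    # gene-level CAI of the single-substitution mutant
    wts <- caiWeights(u)
    mutGene <- c("ATG", "AAA", "CTG")
    expect_equal(k4$caiMut, cai(mutGene, wts))
    expect_equal(k4$caiWt, cai(gene, wts))
    expect_error(covariateTable(gene, data.frame(position = 9,
                                                 wtCodon = "AAG",
                                                 mutCodon = "AAA")),
                 "outside")
})
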