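test_that("ratios and enrichment scores follow the fraction algebra", {
    expect_equal(deepseqRatio(0.25, 0.5), 0.5)
    expect_equal(deepseqRatio(0, 0.5), 0)   # depleted variant
    expect_equal(deepseqRatio(0.3, 0.3), 1)
    expect_error(deepseqRatio(0.1, 0), "filterByResistantDepth")
    expect_error(enrichmentScore(0.5, 0), "reference")
})

test_that("a single variant against WT reproduces the hand-computed score", {
    # resistant mut=100, WT=100; sensitive mut=50, WT=150:
    # ES = (0.25/0.5)/(0.75/0.5) = 1/3
    counts <- list(res_rep1 = c(100, 100), res_rep2 = c(100, 100),
                   sen_rep1 = c(50, 150), sen_rep2 = c(50, 150),
                   relE_rep1 = c(100, 100), relE_rep2 = c(100, 100))
    se <- makeExperiment(counts, position = c(4, 4), wtCodon = "AAG",
                         mutCodon = c("AAA", "AAG"), isRef = c(FALSE, TRUE))
    sc <- scoreVariants(se)
    expect_equal(sc["K4_AAA", "esCcdB"], 1 / 3)
    expect_equal(sc["K4_AAA", "esRelE"], 1)
})

test_that("the reference variant scores exactly 1 in every condition", {
    se <- simulateSynScreen(nCodons = 15, depth = 1e4, seed = 11)
    sc <- scoreVariants(se)
    ref <- which(sc$isRef)
    for (col in c("esCcdBRep1", "esCcdBRep2", "esRelERep1", "esRelERep2",
                  "esCcdB", "esRelE")) {
        expect_identical(sc[ref, col], 1)
    }
})

test_that("scores are invariant to library-wide depth rescaling", {
    se <- makeExperiment(
        list(res_rep1 = c(40, 60, 100), res_rep2 = c(45, 70, 90),
             sen_rep1 = c(10, 80, 100), sen_rep2 = c(15, 85, 95),
             relE_rep1 = c(70, 20, 100), relE_rep2 = c(75, 30, 105)),
        position = c(2, 2, 2), wtCodon = "CTG",
        mutCodon = c("CTA", "CTC", "CTG"), isRef = c(FALSE, FALSE, TRUE))
    sc1 <- scoreVariants(se)
    rescaled <- se
    cnt <- SummarizedExperiment::assay(se, "counts")
    cnt[, "sen_rep1"] <- cnt[, "sen_rep1"] * 13L
    cnt[, "res_rep2"] <- cnt[, "res_rep2"] * 5L
    SummarizedExperiment::assay(rescaled, "counts") <- cnt
    sc2 <- scoreVariants(rescaled)
    expect_equal(sc2$esCcdB, sc1$esCcdB)
    expect_equal(sc2$esRelE, sc1$esRelE)
})

test_that("reference dropout in a selective condition is an error", {
    counts <- list(res_rep1 = c(100, 100), res_rep2 = c(100, 100),
                   sen_rep1 = c(50, 0), sen_rep2 = c(50, 10),
                   relE_rep1 = c(10, 10), relE_rep2 = c(10, 10))
    se <- makeExperiment(counts, position = c(4, 4), wtCodon = "AAG",
                         mutCodon = c("AAA", "AAG"), isRef = c(FALSE, TRUE))
    expect_error(scoreVariants(se), "zero reads")
})

test_that("phenotype classification uses strict thresholds", {
    cls <- classifyPhenotype(c(0.42, 2.0, 1.0, 0.7, 1.8),
                             c(0.35, 1.5, 1.0, 0.5, 2.0))
    expect_equal(cls$phenotype[1], "H+D")   # the archetypal hyperactive
    expect_equal(cls$phenotype[2], "I+R")
    expect_equal(cls$activityClass[3], "intermediate")
    expect_equal(cls$regulationClass[3], "neutral")
    expect_equal(cls$phenotype[3], "neutral")
    # boundary scores are not called
    expect_equal(cls$activityClass[4], "intermediate")
    expect_equal(cls$activityClass[5], "intermediate")
})

test_that("classification is monotone in the toxin score", {
    es <- sort(runif(50, 0.1, 3))
    cls <- classifyPhenotype(es, rep(2, 50))$activityClass
    ranks <- match(cls, c("hyperactive", "intermediate", "inactive"))
    expect_true(all(diff(ranks) >= 0))
})

test_that("degree of variation is anchored at the per-position minimiser", {
    expect_equal(degreeOfVariation(c(0.5, 2, 4), c(1, 1, 1)), c(0, 0, 1))
    expect_equal(degreeOfVariation(5, 1), 0)  # singleton position
    # ES = 1 present: its fold distance 1 is the minimum
    expect_equal(degreeOfVariation(c(1, 4), c(1, 1)), c(0, 2))
    expect_warning(dv <- degreeOfVariation(c(0, 2), c(1, 1)), "excluded")
    expect_true(is.na(dv[1]))
    # every position attains 0 and all values are non-negative
    set.seed(9)
    scores <- exp(rnorm(60))
    pos <- sample(1:12, 60, replace = TRUE)
    dv <- degreeOfVariation(scores, pos)
    expect_true(all(dv >= -1e-12))
    mins <- tapply(dv, pos, min)
    expect_true(all(abs(mins) < 1e-12))
})

test_that("k-means boundaries separate well-separated score clusters", {
    set.seed(4)
    es <- c(exp(rnorm(40, log(0.3), 0.15)),
            exp(rnorm(40, log(1.0), 0.15)),
            exp(rnorm(40, log(3.0), 0.15)))
    b <- kmeansThresholds(es, k = 3, seed = 1)
    expect_length(b, 2)
    expect_lt(b[1], 1)
    expect_gt(b[2], 1)
    expect_error(kmeansThresholds(es, k = 1), "k must be")
    expect_error(kmeansThresholds(c(1, 1, 1, 2), k = 3), "distinct")
})

test_that("re-referencing rescores the library against a named variant", {
    se <- simulateSynScreen(nCodons = 15, depth = 1e5, seed = 21)
    sc <- scoreVariants(se)
    target <- sc$label[!sc$isRef][3]
    sc2 <- scoreVariants(se, referenceLabel = target)
    expect_identical(sc2[target, "esCcdB"], 1)
    # within each replicate, rescoring divides every score by the new
    # anchor's original per-replicate score
    common <- intersect(rownames(sc), rownames(sc2))
    expect_equal(sc2[common, "esCcdBRep1"],
                 sc[common, "esCcdBRep1"] / sc[target, "esCcdBRep1"])
    expect_equal(sc2[common, "esRelERep2"],
                 sc[common, "esRelERep2"] / sc[target, "esRelERep2"])
})

test_that("geometric replicate averaging is available", {
    se <- simulateSynScreen(nCodons = 10, depth = 1e4, seed = 31)
    sa <- scoreVariants(se, average = "arithmetic")
    sg <- scoreVariants(se, average = "geometric")
    expect_equal(sg$esCcdB, sqrt(sa$esCcdBRep1 * sa$esCcdBRep2))
})
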