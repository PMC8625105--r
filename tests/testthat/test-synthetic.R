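smallConfig <- function(seed, ...) {
    synthConfig(nSites = 3L,
                siteHabitats = c(A = "estuarine-inshore-reef", B = "lagoon",
                                 C = "riverine"),
                nOtus = c(25L, 25L, 10L), t = c(15L, 15L, 3L),
                poolSize = 40L, nPhyla = 5L, seed = seed, ...)
}

test_that("generated taxonomies have the requested shape and determinism", {
    tax <- generateTaxonomy(10, 3, seed = 1)
    df <- taxonomyData(tax)
    expect_equal(nrow(df), 10L)
    expect_equal(length(unique(df$phylum)), 3L)

    expect_identical(taxonomyData(generateTaxonomy(10, 3, seed = 1)), df)
    expect_false(identical(taxonomyData(generateTaxonomy(10, 3, seed = 2)),
                           df))

    expect_error(generateTaxonomy(10, 0, seed = 1), class = "eemBadSize")
    expect_error(generateTaxonomy(3, 5, seed = 1), class = "eemBadSize")
})

test_that("generated communities are valid integer count tables", {
    cfg <- smallConfig(seed = 5)
    gen <- generateCommunity(cfg, 1)
    cts <- counts(gen$community)
    expect_true(all(cts >= 0))
    expect_true(all(cts == round(cts)))
    expect_equal(dim(cts), c(25L, 15L))
    expect_identical(habitat(gen$community), "estuarine-inshore-reef")
    # truth bundle carries the coupling graph
    expect_true(all(c("source", "target", "strength") %in%
                    colnames(gen$edges)))
    expect_error(generateCommunity(cfg, 9), class = "eemBadSize")
})

test_that("the generator does not disturb the caller's RNG stream", {
    set.seed(123); before <- rnorm(3)
    set.seed(123); invisible(generateCommunity(smallConfig(seed = 5), 1))
    after <- rnorm(3)
    expect_identical(before, after)
})

test_that("mean-abundance tail exponent is recovered (generator/fitter loop)", {
    errs <- vapply(1:5, function(s) {
        cfg <- synthConfig(nSites = 1L, siteHabitats = c(S = "x"),
                           archetypes = list(x = habitatArchetype(
                               2.5, 1.5, couplingDensity = 0)),
                           nOtus = 2000L, t = 3L, poolSize = 2000L,
                           nPhyla = 5L, seed = s)
        m <- generateCommunity(cfg, 1)$means
        abs(fitPowerlaw(m, "fixed", xmin = cfg$minMean)@exponent - 2.5)
    }, numeric(1))
    expect_lte(median(errs), 0.1)
})

test_that("Taylor exponent is recovered from generated dynamics", {
    cfg <- synthConfig(nSites = 1L, siteHabitats = c(S = "x"),
                       archetypes = list(x = habitatArchetype(
                           2.5, 1.7, couplingDensity = 0)),
                       nOtus = 200L, t = 100L, poolSize = 200L,
                       nPhyla = 5L, seed = 11)
    tf <- taylorExponent(generateCommunity(cfg, 1)$community)
    expect_lt(abs(tf@nu - 1.7), 0.1)
})

test_that("uncoupled OTU pairs look like the surrogate null", {
    below <- unlist(lapply(c(17L, 27L), function(s) {
        cfg <- synthConfig(nSites = 1L, siteHabitats = c(S = "x"),
                           archetypes = list(x = habitatArchetype(
                               2.2, 1.5, couplingDensity = 0)),
                           nOtus = 8L, t = 500L, poolSize = 8L, nPhyla = 2L,
                           seed = s)
        cts <- counts(generateCommunity(cfg, 1)$community)
        set.seed(s + 1L)
        pairs <- expand.grid(seq_len(8), seq_len(8))   # all ordered pairs
        pairs <- as.matrix(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
        vapply(seq_len(nrow(pairs)), function(k) {
            x <- cts[pairs[k, 1], ]; y <- cts[pairs[k, 2], ]
            est <- transferEntropy(x, y)
            est < quantile(teSurrogates(x, y, n = 60), 0.95)
        }, logical(1))
    }))
    expect_gte(mean(below), 0.9)
})

test_that("coupled pairs carry more forward than reverse information", {
    cfg <- synthConfig(nSites = 1L, siteHabitats = c(S = "x"),
                       archetypes = list(x = habitatArchetype(
                           2.2, 1.5, couplingDensity = 0.1,
                           couplingStrength = 0.7, lambdaScale = 1)),
                       nOtus = 10L, t = 300L, poolSize = 10L, nPhyla = 2L,
                       seed = 19)
    gen <- generateCommunity(cfg, 1)
    cts <- counts(gen$community)
    strong <- gen$edges[gen$edges$strength > 0.4, ]
    # targets hit by a single strong edge: forward TE should dominate
    strong <- strong[!duplicated(strong$target) &
                     !strong$target %in% strong$source, ]
    expect_gt(nrow(strong), 0)
    fwd <- vapply(seq_len(nrow(strong)), function(k)
        transferEntropy(cts[strong$source[k], ], cts[strong$target[k], ]),
        numeric(1))
    rev <- vapply(seq_len(nrow(strong)), function(k)
        transferEntropy(cts[strong$target[k], ], cts[strong$source[k], ]),
        numeric(1))
    expect_gt(mean(fwd > rev), 0.6)
})

test_that("study generation is deterministic and validates sizes", {
    cfg <- smallConfig(seed = 42)
    g1 <- generateStudy(cfg)
    g2 <- generateStudy(cfg)
    expect_identical(lapply(communities(g1$study), counts),
                     lapply(communities(g2$study), counts))
    expect_identical(taxonomyData(g1$taxonomy), taxonomyData(g2$taxonomy))
    expect_equal(length(communities(g1$study)), 3L)
    expect_identical(vapply(communities(g1$study), siteId, character(1)),
                     c("A", "B", "C"))

    expect_error(synthConfig(nSites = 0L, siteHabitats = character(0),
                             seed = 1),
                 class = "eemBadSize")
    expect_error(smallConfig(seed = NULL), class = "eemBadConfig")
    expect_error(habitatArchetype(0.9, 1.5), class = "eemBadConfig")
    expect_error(habitatArchetype(2, 2.5), class = "eemBadConfig")
})
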