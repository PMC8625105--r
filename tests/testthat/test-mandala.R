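test_that("axis rescaling divides by the observed maximum", {
    r <- rescaleAxis(c(2.39, 4.14, 14.82))
    expect_equal(as.numeric(r), c(0.1613, 0.2794, 1.0), tolerance = 1e-3)
    expect_equal(max(r), 1)
    expect_equal(attr(r, "xmax"), 14.82)

    expect_equal(as.numeric(rescaleAxis(7)), 1)
    expect_error(rescaleAxis(c(0, 0)), class = "eemBadValues")
    expect_error(rescaleAxis(c(1, NaN)), class = "eemNonFinite")
})

test_that("ternary coordinates normalize to unit sum in fixed axis order", {
    tc <- ternaryCoordinates(1, 1, 1)
    expect_equal(as.numeric(tc), rep(1 / 3, 3))

    tc2 <- ternaryCoordinates(0.5, 0.25, 0.25)
    expect_equal(as.numeric(tc2), c(0.5, 0.25, 0.25))

    tc3 <- ternaryCoordinates(1, 0, 0)
    expect_equal(as.numeric(tc3), c(1, 0, 0))
    expect_identical(colnames(tc), c("tern_D", "tern_lambda", "tern_epsilon"))

    expect_error(ternaryCoordinates(0, 0, 0), class = "eemBadValues")
    expect_error(ternaryCoordinates(-1, 1, 1), class = "eemBadValues")

    # idempotence on its own output
    set.seed(2)
    a <- runif(10); b <- runif(10); c <- runif(10)
    t1 <- ternaryCoordinates(a, b, c)
    t2 <- ternaryCoordinates(t1[, 1], t1[, 2], t1[, 3])
    expect_equal(unname(t2), unname(t1), tolerance = 1e-12)
    expect_true(all(abs(rowSums(t1) - 1) < 1e-9))
})

test_that("optimality divergence has the optimal vertex at zero and is monotone", {
    expect_equal(optimalityDivergence(1, 0, 0), 0)
    expect_equal(optimalityDivergence(1, 1, 0), 1)
    expect_equal(optimalityDivergence(0, 1, 1), sqrt(3))

    g <- seq(0, 1, by = 0.25)
    grid <- expand.grid(D = g, lam = g, eps = g)
    div <- optimalityDivergence(grid$D, grid$lam, grid$eps)
    eps <- 1e-12
    # increasing lambda_s or epsilon_s never decreases divergence
    expect_true(all(optimalityDivergence(grid$D, grid$lam + 0.1, grid$eps)
                    >= div - eps))
    expect_true(all(optimalityDivergence(grid$D, grid$lam, grid$eps + 0.1)
                    >= div - eps))
    # increasing D_s (toward 1) never increases it
    expect_true(all(optimalityDivergence(pmin(grid$D + 0.1, 1), grid$lam,
                                         grid$eps) <= div + eps))
})

test_that("identical sites land on identical Mandala points", {
    set.seed(61)
    cts <- makeCounts(8, 12, values = rpois(96, 30))
    c1 <- CommunityTable(cts, "S1", "lagoon")
    c2 <- CommunityTable(cts, "S2", "lagoon")
    tax <- makeTaxonomy(rownames(cts),
                        phylum = rep(c("P1", "P2"), each = 4),
                        genus = paste0("G", 1:8))
    m <- communityMandala(StudySet(list(c1, c2), tax))
    pts <- mandalaPoints(m)
    expect_equal(pts$divergence[1], pts$divergence[2])
    expect_equal(pts[1, c("D_raw", "lambda_raw", "epsilon_raw")],
                 pts[2, c("D_raw", "lambda_raw", "epsilon_raw")],
                 ignore_attr = TRUE)
    # rescaled maxima are exactly 1
    expect_equal(max(pts$D_s), 1)
    expect_equal(max(pts$lambda_s), 1)
    expect_equal(max(pts$epsilon_s), 1)
    # audit trail: maxima reproduce raw values exactly
    expect_equal(pts$D_s * axisMaxima(m)["D"], pts$D_raw,
                 ignore_attr = TRUE)
})

test_that("a degenerate site is flagged without affecting the others", {
    set.seed(67)
    good <- CommunityTable(makeCounts(8, 12, rpois(96, 30)), "G", "lagoon")
    flat <- CommunityTable(makeCounts(4, 12, rep(5, 48),
                                      ids = paste0("OTU_", 1:4)),
                           "F", "riverine")
    tax <- makeTaxonomy(paste0("OTU_", 1:8),
                        phylum = rep(c("P1", "P2"), 4),
                        genus = paste0("G", 1:8))
    m <- communityMandala(StudySet(list(good, flat), tax))
    pts <- mandalaPoints(m)
    expect_match(pts$flags[pts$site == "F"], "missing-lambda")
    expect_true(is.na(pts$divergence[pts$site == "F"]))
    expect_true(is.finite(pts$divergence[pts$site == "G"]))

    expect_error(communityMandala(new("StudySet", communities = list(),
                                      taxonomies = list())))
})

test_that("phylum Mandala excludes single-OTU phyla with an explicit flag", {
    set.seed(71)
    cts <- makeCounts(9, 14, values = rpois(126, 25))
    comm <- CommunityTable(cts, "S1", "lagoon")
    tax <- makeTaxonomy(rownames(cts),
                        phylum = c(rep("Big1", 4), rep("Big2", 4), "Lone"),
                        genus = paste0("G", 1:9))
    m <- phylumMandala(comm, tax, mandalaConfig(nMin = 5L))
    pts <- mandalaPoints(m)
    lone <- pts[pts$phylum %in% "Lone", ]
    expect_match(lone$flags, "single-otu")
    expect_match(lone$flags, "missing-lambda")
    expect_true(is.na(lone$tern_D))           # excluded from the ternary
    expect_equal(sum(pts$scope == "community"), 1L)
    expect_equal(sum(pts$scope == "phylum"), 3L)
})

test_that("phylum Mandala counts points when all phyla are calculable", {
    set.seed(73)
    n <- 15
    cts <- makeCounts(n, 16, values = rpois(16 * n, 40))
    comm <- CommunityTable(cts, "S1", "lagoon")
    tax <- makeTaxonomy(rownames(cts), phylum = rep(paste0("P", 1:5), 3),
                        genus = paste0("G", 1:n))
    m <- phylumMandala(comm, tax, mandalaConfig(nMin = 5L))
    pts <- mandalaPoints(m)
    expect_equal(nrow(pts), 6L)               # 5 phyla + community average
    # phylum means reported alongside the community point (no equality claim)
    ph <- pts[pts$scope == "phylum", ]
    expect_true(all(is.finite(ph$epsilon_raw)))
})

test_that("MandalaSet serialization round-trips points and maxima", {
    set.seed(79)
    cts <- makeCounts(8, 12, values = rpois(96, 30))
    tax <- makeTaxonomy(rownames(cts), phylum = rep(c("P1", "P2"), 4),
                        genus = paste0("G", 1:8))
    m <- communityMandala(StudySet(
        list(CommunityTable(cts, "A", "lagoon"),
             CommunityTable(cts + 1, "B", "riverine")), tax))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeMandalaSet(m, path, seed = 7)
    back <- read.delim(path)
    expect_equal(nrow(back), 2L)
    expect_equal(back$D_raw, mandalaPoints(m)$D_raw)
    side <- jsonlite::read_json(paste0(path, ".json"))
    expect_equal(side$axis_maxima$D, unname(axisMaxima(m)["D"]))
    expect_equal(side$seed, 7)
})

test_that("figures are rendered deterministically", {
    set.seed(83)
    cts <- makeCounts(8, 12, values = rpois(96, 30))
    tax <- makeTaxonomy(rownames(cts), phylum = rep(c("P1", "P2"), 4),
                        genus = paste0("G", 1:8))
    m <- communityMandala(StudySet(
        list(CommunityTable(cts, "A", "lagoon"),
             CommunityTable(cts + 2, "B", "riverine")), tax))
    f1 <- withr::local_tempfile(fileext = ".svg")
    f2 <- withr::local_tempfile(fileext = ".svg")
    renderMandala(m, f1)
    renderMandala(m, f2)
    expect_gt(file.size(f1), 0)
    expect_identical(readLines(f1), readLines(f2))

    p1 <- withr::local_tempfile(fileext = ".svg")
    renderPairwise(m, p1)
    expect_gt(file.size(p1), 0)
})
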