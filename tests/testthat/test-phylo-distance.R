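test_that("hand-counted taxonomy-tree distances are exact", {
    # two OTUs identical through genus: tip -> genus -> tip = 2
    tax <- makeTaxonomy(c("A", "B"), phylum = "P1", genus = "G1")
    d <- tipDistanceMatrix(buildTaxonomyTree(tax, c("A", "B")))
    expect_equal(d["A", "B"], 2)

    # sharing only kingdom: 6 edges up + 6 edges down = 12
    tax2 <- TaxonomyTable(data.frame(
        otu_id = c("A", "B"), kingdom = "Bacteria",
        phylum = c("P1", "P2"), class = c("C1", "C2"),
        order = c("O1", "O2"), family = c("F1", "F2"),
        genus = c("G1", "G2")))
    d2 <- tipDistanceMatrix(buildTaxonomyTree(tax2, c("A", "B")))
    expect_equal(d2["A", "B"], 12)

    # 3 tips: two under one genus, one diverging just below the shared
    # phylum (5 edges up + 5 edges down) -> {2, 10, 10}
    tax3 <- TaxonomyTable(data.frame(
        otu_id = c("A", "B", "C"), kingdom = "Bacteria",
        phylum = c("P1", "P1", "P1"), class = c("C1", "C1", "C2"),
        order = c("O1", "O1", "O2"), family = c("F1", "F1", "F2"),
        genus = c("G1", "G1", "G2")))
    d3 <- tipDistanceMatrix(buildTaxonomyTree(tax3, c("A", "B", "C")))
    expect_equal(d3["A", "B"], 2)
    expect_equal(d3["A", "C"], 10)
    expect_equal(d3["B", "C"], 10)
    expect_true(isSymmetric(d3))
    expect_true(all(diag(d3) == 0))
})

test_that("single-OTU sites give a one-tip tree and no distance matrix", {
    tax <- makeTaxonomy("A", phylum = "P1")
    tree <- buildTaxonomyTree(tax, "A")
    expect_equal(length(tree$tip.label), 1L)
    expect_error(tipDistanceMatrix(tree), class = "eemTooFewTips")
    expect_error(buildTaxonomyTree(tax, c("A", "ZZZ")),
                 class = "eemDuplicateId")
})

test_that("unassigned ranks become lineage-specific placeholders", {
    # both unassigned at genus, same family -> still distance 4 (sibling
    # placeholder), but unassigned under DIFFERENT families must not merge
    tax <- TaxonomyTable(data.frame(
        otu_id = c("A", "B", "C"), kingdom = "Bacteria", phylum = "P1",
        class = "C1", order = "O1", family = c("F1", "F1", "F2"),
        genus = c(UNASSIGNED, UNASSIGNED, UNASSIGNED)))
    d <- tipDistanceMatrix(buildTaxonomyTree(tax, c("A", "B", "C")))
    expect_equal(d["A", "B"], 2)   # same placeholder genus under F1
    expect_equal(d["A", "C"], 6)   # placeholders under F1 vs F2 stay apart
                                   # (paths meet at the shared order node)
    # uniform tip depth: all tips 7 edges from the root
    tree <- buildTaxonomyTree(tax, c("A", "B", "C"))
    root <- length(tree$tip.label) + 1L
    depth <- ape::node.depth.edgelength(tree)
    expect_true(all(depth[seq_along(tree$tip.label)] == 7))
})

test_that("star tree has all pairwise distances 2", {
    tree <- ape::read.tree(text = "(A:1,B:1,C:1,D:1)root;")
    d <- tipDistanceMatrix(tree)
    expect_true(all(d[upper.tri(d)] == 2))
})

test_that("tip distances match independent oracles on random taxonomies", {
    for (seed in 1:4) {
        n <- c(20, 60, 120, 200)[seed]
        tax <- generateTaxonomy(n, max(3, n %/% 20), seed = seed)
        ids <- otuIds(tax)
        tree <- buildTaxonomyTree(tax, ids)
        d <- tipDistanceMatrix(tree)[ids, ids]
        expect_equal(d, taxonomyDistanceOracle(tax, ids))
        expect_equal(d, pathWalkOracle(tree)[ids, ids])
    }
})

test_that("effective distance D is the mean over unordered pairs", {
    d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    expect_equal(effectiveDistance(d), 10 / 3)

    d2 <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("A", "B"),
                                                      c("A", "B")))
    expect_equal(effectiveDistance(d2), 7)

    dc <- matrix(3, 4, 4); diag(dc) <- 0
    dimnames(dc) <- list(letters[1:4], letters[1:4])
    expect_equal(effectiveDistance(dc), 3)

    expect_error(effectiveDistance(matrix(0, 1, 1)), class = "eemNoPairs")
})

test_that("D is invariant to tip ordering", {
    tax <- generateTaxonomy(40, 5, seed = 99)
    ids <- otuIds(tax)
    d1 <- effectiveDistance(tipDistanceMatrix(buildTaxonomyTree(tax, ids)))
    d2 <- effectiveDistance(tipDistanceMatrix(buildTaxonomyTree(tax,
                                                               rev(ids))))
    expect_equal(d1, d2)
})

test_that("per-phylum distance matches brute-force pair enumeration", {
    tax <- TaxonomyTable(data.frame(
        otu_id = c("A", "B", "C", "D"), kingdom = "Bacteria",
        phylum = c("P1", "P1", "P2", "P2"), class = c("C1", "C1", "C2", "C3"),
        order = c("O1", "O1", "O2", "O3"),
        family = c("F1", "F2", "F3", "F4"),
        genus = c("G1", "G2", "G3", "G4")))
    d <- tipDistanceMatrix(buildTaxonomyTree(tax, c("A", "B", "C", "D")))

    # between convention: i in P1, j in P2
    between <- c(d["A", "C"], d["A", "D"], d["B", "C"], d["B", "D"])
    p1 <- phylumDistance(d, tax, "P1", "between")
    expect_equal(p1$Dp, mean(between))
    expect_equal(p1$nPairs, 4)

    # all_others: adds the within-P1 pair once
    p1a <- phylumDistance(d, tax, "P1", "all_others")
    expect_equal(p1a$Dp, mean(c(between, d["A", "B"])))
    expect_equal(p1a$nPairs, 5)

    expect_error(phylumDistance(d, tax, "P9"), class = "eemPhylumAbsent")
})

test_that("single-phylum community gives Dp = D under all_others", {
    tax <- makeTaxonomy(c("A", "B", "C"), phylum = "P1",
                        genus = c("G1", "G2", "G3"))
    d <- tipDistanceMatrix(buildTaxonomyTree(tax, c("A", "B", "C")))
    expect_equal(phylumDistance(d, tax, "P1", "all_others")$Dp,
                 effectiveDistance(d))
    expect_error(phylumDistance(d, tax, "P1", "between"),
                 class = "eemNoPairs")
})

test_that("pair-count-weighted mean of Dp equals D when pairs partition", {
    # one OTU per phylum: between-phylum pairs cover every pair (twice)
    tax <- TaxonomyTable(data.frame(
        otu_id = paste0("O", 1:5), kingdom = "Bacteria",
        phylum = paste0("P", 1:5), class = paste0("C", 1:5),
        order = paste0("Or", 1:5), family = paste0("F", 1:5),
        genus = paste0("G", 1:5)))
    d <- tipDistanceMatrix(buildTaxonomyTree(tax, paste0("O", 1:5)))
    s <- distanceSummary(d, tax, "between")
    w <- s$perPhylum$n_pairs
    expect_equal(sum(s$perPhylum$Dp * w) / sum(w), s$D)
})

test_that("merging lineages at a shallower rank never decreases distance", {
    mk <- function(L) {   # two OTUs sharing exactly L leading ranks
        vals <- lapply(seq_along(TAXONOMY_RANKS), function(k)
            if (k <= L) rep(paste0("T", k), 2) else paste0("T", k, c("a", "b")))
        names(vals) <- TAXONOMY_RANKS
        TaxonomyTable(data.frame(otu_id = c("A", "B"), vals))
    }
    dist <- vapply(0:6, function(L) {
        tipDistanceMatrix(buildTaxonomyTree(mk(L), c("A", "B")))["A", "B"]
    }, numeric(1))
    expect_true(all(diff(dist) < 0))          # deeper sharing, shorter path
    expect_equal(dist, 2 * (7 - 0:6))
})

test_that("newick export writes placeholder labels", {
    tax <- TaxonomyTable(data.frame(
        otu_id = c("A", "B"), kingdom = "Bacteria", phylum = "P1",
        class = "C1", order = "O1", family = "F1",
        genus = c(UNASSIGNED, "G1")))
    tree <- buildTaxonomyTree(tax, c("A", "B"))
    path <- withr::local_tempfile(fileext = ".nwk")
    writeTaxonomyTree(tree, path)
    nwk <- readLines(path)
    expect_match(nwk, "genus__unassigned__F1")
    expect_silent(ape::read.tree(path))
})
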