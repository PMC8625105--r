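## Taxonomy-rank trees and effective phylogenetic distances.
##
## Trees are built from ranked taxonomy (not sequences): a chain
## root -> kingdom -> phylum -> class -> order -> family -> genus -> tip for
## every OTU, with shared lineage prefixes merged and every edge of length 1
## (one rank step). Unassigned ranks become placeholder nodes unique to their
## parent lineage, so tips always sit at uniform depth 7 and sites with
## poorer annotation do not get systematically shorter distances.

.sanitizeLabel <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Build a taxonomy-rank tree for the OTUs observed at a site
#'
#' @param taxonomy a [TaxonomyTable-class] covering all requested OTUs.
#' @param otuIds OTU ids observed at the site (tree tips).
#' @return an [ape::read.tree()]-style `phylo` object, rooted, with unit
#'   branch lengths, tips labelled by OTU id and internal nodes by taxon
#'   name. Placeholder nodes for unassigned ranks are labelled
#'   `<rank>__unassigned__<parent>`.
#' @export
buildTaxonomyTree <- function(taxonomy, otuIds) {
    stopifnot(is(taxonomy, "TaxonomyTable"))
    df <- taxonomy@data
    miss <- setdiff(otuIds, df$otu_id)
    if (length(miss))
        stopEem("eemDuplicateId", "unknown otu_id(s): %s",
                paste(head(miss, 5L), collapse = ", "))
    if (length(otuIds) == 0L)
        stopEem("eemEmptyTable", "no OTUs supplied")
    df <- df[match(otuIds, df$otu_id), , drop = FALSE]

    # resolve lineages: unassigned cells get placeholder labels chained from
    # their parent so identical "unassigned" under different parents stay apart
    lineages <- matrix("", nrow = nrow(df), ncol = length(TAXONOMY_RANKS))
    for (k in seq_along(TAXONOMY_RANKS)) {
        raw <- .sanitizeLabel(df[[TAXONOMY_RANKS[k]]])
        parent <- if (k == 1L) rep("root", nrow(df)) else lineages[, k - 1L]
        ph <- raw == UNASSIGNED
        raw[ph] <- paste0(TAXONOMY_RANKS[k], "__unassigned__", parent[ph])
        lineages[, k] <- raw
    }

    # recursive newick assembly over the (merged-prefix) lineage table
    build <- function(rows, depth) {
        if (depth > length(TAXONOMY_RANKS))
            return(paste0(.sanitizeLabel(df$otu_id[rows]), ":1",
                          collapse = ","))
        groups <- split(rows, factor(lineages[rows, depth],
                                     levels = unique(lineages[rows, depth])))
        paste(vapply(names(groups), function(g) {
            sprintf("(%s)%s:1", build(groups[[g]], depth + 1L), g)
        }, character(1)), collapse = ",")
    }
    newick <- sprintf("(%s)root;", build(seq_len(nrow(df)), 1L))
    ape::read.tree(text = newick)
}

#' Patristic distances between all tips of a tree
#'
#' Sum of branch lengths along the unique path between each pair of tips.
#'
#' @param tree a `phylo` object with at least two tips.
#' @return symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @export
tipDistanceMatrix <- function(tree) {
    if (!inherits(tree, "phylo"))
        stopEem("eemBadConfig", "tree must be a phylo object")
    if (length(tree$tip.label) < 2L)
        stopEem("eemTooFewTips", "need >= 2 tips for a distance matrix (have %d)",
                length(tree$tip.label))
    stats::cophenetic(tree)
}

#' Effective phylogenetic distance of a community
#'
#' The mean patristic distance over the n unordered distinct tip pairs,
#' D = (1/n) sum d_ij — an average, in contrast to the conventional summed
#' phylogenetic distance, so it is comparable across communities of
#' different richness.
#'
#' @param distances a symmetric tip-distance matrix (see
#'   [tipDistanceMatrix()]).
#' @return the mean pairwise distance D.
#' @export
effectiveDistance <- function(distances) {
    distances <- as.matrix(distances)
    if (nrow(distances) < 2L)
        stopEem("eemNoPairs", "no tip pairs: distance matrix has %d rows",
                nrow(distances))
    mean(distances[upper.tri(distances)])
}

#' Per-phylum effective phylogenetic distance
#'
#' Mean patristic distance over the pairs attributed to a phylum p. Two pair
#' conventions are supported:
#' \describe{
#'   \item{`"between"`}{(default) pairs (i, j) with i in p and j outside p —
#'     how unrelated the phylum is to the rest of the community.}
#'   \item{`"all_others"`}{unordered pairs with at least one member in p,
#'     including same-phylum pairs.}
#' }
#'
#' @param distances tip-distance matrix.
#' @param taxonomy a [TaxonomyTable-class] covering the matrix's tips.
#' @param phylum phylum label.
#' @param pairs pair convention, see Details.
#' @return list with `Dp` (mean distance) and `nPairs`.
#' @export
phylumDistance <- function(distances, taxonomy, phylum,
                           pairs = c("between", "all_others")) {
    pairs <- match.arg(pairs)
    distances <- as.matrix(distances)
    tips <- rownames(distances)
    df <- taxonomy@data
    members <- intersect(tips, df$otu_id[df$phylum == phylum])
    if (length(members) == 0L)
        stopEem("eemPhylumAbsent", "phylum '%s' has no OTUs among the tips",
                phylum)
    others <- setdiff(tips, members)
    if (pairs == "between") {
        if (length(others) == 0L)
            stopEem("eemNoPairs",
                    "phylum '%s' covers every tip; no between-phylum pairs",
                    phylum)
        vals <- as.vector(distances[members, others, drop = FALSE])
    } else {
        between <- as.vector(distances[members, others, drop = FALSE])
        within <- distances[members, members, drop = FALSE]
        vals <- c(between, within[upper.tri(within)])
        if (length(vals) == 0L)
            stopEem("eemNoPairs", "phylum '%s' is a single tip with no partners",
                    phylum)
    }
    list(Dp = mean(vals), nPairs = length(vals))
}

#' Community and per-phylum distance summary
#'
#' @param distances tip-distance matrix for one site.
#' @param taxonomy a [TaxonomyTable-class].
#' @param pairs pair convention for [phylumDistance()].
#' @return list with `D`, `nPairs`, and `perPhylum` (data.frame of phylum,
#'   Dp, n_pairs; phyla without admissible pairs get NA and are kept).
#' @export
distanceSummary <- function(distances, taxonomy,
                            pairs = c("between", "all_others")) {
    pairs <- match.arg(pairs)
    distances <- as.matrix(distances)
    tips <- rownames(distances)
    df <- taxonomy@data
    phyla <- sort(unique(df$phylum[df$otu_id %in% tips]))
    per <- lapply(phyla, function(p)
        tryCatch(phylumDistance(distances, taxonomy, p, pairs),
                 eemError = function(e) list(Dp = NA_real_, nPairs = 0L)))
    list(D = effectiveDistance(distances),
         nPairs = nrow(distances) * (nrow(distances) - 1L) / 2L,
         perPhylum = data.frame(phylum = phyla,
                                Dp = vapply(per, `[[`, numeric(1), "Dp"),
                                n_pairs = vapply(per, `[[`, numeric(1),
                                                 "nPairs")))
}

#' Export a taxonomy tree as newick
#'
#' @param tree a `phylo` object from [buildTaxonomyTree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTaxonomyTree <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' Write a distance summary as TSV
#'
#' @param summary result of [distanceSummary()].
#' @param site site label for the output rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistanceSummary <- function(summary, site, path) {
    df <- rbind(
        data.frame(site = site, scope = "community", phylum = NA_character_,
                   distance = summary$D, n_pairs = summary$nPairs),
        data.frame(site = site, scope = "phylum",
                   phylum = summary$perPhylum$phylum,
                   distance = summary$perPhylum$Dp,
                   n_pairs = summary$perPhylum$n_pairs))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
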