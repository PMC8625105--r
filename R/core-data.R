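## Readers, writers and validation for abundance and taxonomy tables.

#' Construct a CommunityTable
#'
#' @param counts numeric matrix of non-negative integer read counts, OTUs in
#'   rows (rownames = OTU ids) and time points in columns (colnames = ordered
#'   time labels). Row/column order is preserved as given.
#' @param siteId single site label.
#' @param habitat single habitat-class label.
#' @return a validated [CommunityTable-class].
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("OTU_", 1:3), c("t1", "t2")))
#' CommunityTable(m, "S1", "riverine")
#' @export
CommunityTable <- function(counts, siteId, habitat) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    new("CommunityTable", siteId = as.character(siteId),
        habitat = as.character(habitat), counts = counts)
}

#' Construct a TaxonomyTable
#'
#' Blank or NA cells are replaced by the reserved [UNASSIGNED] token.
#'
#' @param data data.frame with columns `otu_id` and the six ranks of
#'   [TAXONOMY_RANKS], in order.
#' @return a validated [TaxonomyTable-class].
#' @export
TaxonomyTable <- function(data) {
    data <- as.data.frame(data, stringsAsFactors = FALSE)
    if (!"otu_id" %in% colnames(data))
        stopEem("eemMissingColumn", "taxonomy is missing the otu_id column")
    ranksPresent <- intersect(colnames(data), TAXONOMY_RANKS)
    if (!identical(ranksPresent, TAXONOMY_RANKS[seq_along(ranksPresent)]) ||
        length(ranksPresent) != length(TAXONOMY_RANKS))
        stopEem("eemRankOrder",
                "taxonomy ranks must be exactly %s, in that order (got: %s)",
                paste(TAXONOMY_RANKS, collapse = ", "),
                paste(setdiff(colnames(data), "otu_id"), collapse = ", "))
    if (anyDuplicated(data$otu_id))
        stopEem("eemDuplicateId", "duplicate otu_id: %s",
                paste(unique(data$otu_id[duplicated(data$otu_id)]),
                      collapse = ", "))
    data <- data[, c("otu_id", TAXONOMY_RANKS)]
    for (r in TAXONOMY_RANKS) {
        col <- as.character(data[[r]])
        col[is.na(col) | !nzchar(trimws(col))] <- UNASSIGNED
        data[[r]] <- col
    }
    data$otu_id <- as.character(data$otu_id)
    rownames(data) <- NULL
    new("TaxonomyTable", data = data)
}

#' Construct a StudySet
#'
#' @param communities list of [CommunityTable-class] objects, one per site.
#' @param taxonomies a single [TaxonomyTable-class] shared by all sites, or a
#'   list of one per site.
#' @return a validated [StudySet-class].
#' @export
StudySet <- function(communities, taxonomies) {
    if (is(taxonomies, "TaxonomyTable"))
        taxonomies <- rep(list(taxonomies), length(communities))
    new("StudySet", communities = communities, taxonomies = taxonomies)
}

## ---- accessors ----

#' @rdname accessors
#' @export
setMethod("otuIds", "CommunityTable", function(x) rownames(x@counts))

#' @rdname accessors
#' @export
setMethod("otuIds", "TaxonomyTable", function(x) x@data$otu_id)

#' @rdname accessors
#' @export
setMethod("otuIds", "TEMatrix", function(x) x@otuIds)

#' @rdname accessors
#' @export
setMethod("timeLabels", "CommunityTable", function(x) colnames(x@counts))

#' @rdname accessors
#' @export
setMethod("siteId", "CommunityTable", function(x) x@siteId)

#' @rdname accessors
#' @export
setMethod("habitat", "CommunityTable", function(x) x@habitat)

#' @rdname accessors
#' @export
setMethod("counts", "CommunityTable", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("taxonomyData", "TaxonomyTable", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("communities", "StudySet", function(x) x@communities)

#' @rdname accessors
#' @export
setMethod("taxonomies", "StudySet", function(x) x@taxonomies)

#' @export
setMethod("dim", "CommunityTable", function(x) dim(x@counts))

setMethod("show", "CommunityTable", function(object) {
    cat(sprintf("CommunityTable: site %s (%s)\n", object@siteId,
                object@habitat))
    cat(sprintf("  %d OTUs x %d time points; total reads %g\n",
                nrow(object@counts), ncol(object@counts),
                sum(object@counts)))
})

setMethod("show", "TaxonomyTable", function(object) {
    cat(sprintf("TaxonomyTable: %d OTUs, %d phyla\n", nrow(object@data),
                length(unique(object@data$phylum))))
})

setMethod("show", "StudySet", function(object) {
    ids <- vapply(object@communities, siteId, character(1))
    cat(sprintf("StudySet: %d sites (%s)\n", length(ids),
                paste(ids, collapse = ", ")))
})

## ---- abundance I/O ----

#' Read an abundance table
#'
#' Reads a site's OTU-by-time abundance table from a TSV file (header row of
#' time labels, first column of OTU ids) or a BIOM v1 (JSON) file; the dialect
#' is chosen by extension (`.biom` for BIOM, anything else is TSV). Row and
#' column order is preserved from the file; counts are coerced to integers.
#'
#' @param path file path.
#' @param siteId,habitat labels attached to the resulting table.
#' @return a [CommunityTable-class].
#' @export
readAbundanceTable <- function(path, siteId, habitat) {
    if (!file.exists(path))
        stopEem("eemMissingFile", "abundance file not found: %s", path)
    if (grepl("\\.biom$", path, ignore.case = TRUE)) {
        counts <- .readBiomCounts(path)
    } else {
        counts <- .readAbundanceTsv(path)
    }
    if (nrow(counts) == 0L)
        stopEem("eemEmptyTable", "abundance table has no OTU rows: %s", path)
    if (anyDuplicated(rownames(counts)))
        stopEem("eemDuplicateId", "duplicate OTU id in %s: %s", path,
                paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                      collapse = ", "))
    CommunityTable(counts, siteId, habitat)
}

.readAbundanceTsv <- function(path) {
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
    if (ncol(raw) < 2L)
        stopEem("eemEmptyTable", "abundance TSV has no time columns: %s", path)
    ids <- raw[[1L]]
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    if (nrow(cells) == 0L)
        stopEem("eemEmptyTable", "abundance table has no OTU rows: %s", path)
    num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
    bad <- which(is.na(num), arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stopEem("eemParseError",
                "non-numeric cell '%s' at OTU '%s', time column '%s' in %s",
                cells[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                colnames(cells)[bad[1L, 2L]], path)
    dimnames(num) <- list(ids, colnames(cells))
    round(num)
}

.readBiomCounts <- function(path) {
    if (!requireNamespace("biomformat", quietly = TRUE))
        stopEem("eemBadConfig",
                "reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    storage.mode(m) <- "double"
    m
}

#' Write an abundance table as TSV
#'
#' Inverse of [readAbundanceTable()] for the TSV dialect: bit-exact round
#' trip of counts and labels.
#'
#' @param x a [CommunityTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(x, path) {
    stopifnot(is(x, "CommunityTable"))
    df <- data.frame(otu_id = otuIds(x), x@counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## ---- taxonomy I/O ----

#' Read a taxonomy table
#'
#' TSV with columns `otu_id`, `kingdom`, `phylum`, `class`, `order`,
#' `family`, `genus`. Blank cells are replaced by the reserved
#' "unassigned" token.
#'
#' @param path file path.
#' @return a [TaxonomyTable-class].
#' @export
readTaxonomy <- function(path) {
    if (!file.exists(path))
        stopEem("eemMissingFile", "taxonomy file not found: %s", path)
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "", na.strings = NULL)
    TaxonomyTable(raw)
}

#' Write a taxonomy table as TSV
#'
#' @param x a [TaxonomyTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTaxonomy <- function(x, path) {
    stopifnot(is(x, "TaxonomyTable"))
    utils::write.table(x@data, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## ---- subsetting & helpers ----

#' Restrict a community to the OTUs of one phylum
#'
#' The time axis is unchanged; OTU order is preserved.
#'
#' @param table a [CommunityTable-class].
#' @param taxonomy a [TaxonomyTable-class] covering the table's OTUs.
#' @param phylum phylum label to keep.
#' @return a [CommunityTable-class] with only that phylum's OTUs.
#' @export
subsetByPhylum <- function(table, taxonomy, phylum) {
    stopifnot(is(table, "CommunityTable"), is(taxonomy, "TaxonomyTable"))
    df <- taxonomy@data
    if (!phylum %in% df$phylum)
        stopEem("eemPhylumAbsent", "phylum '%s' not present in taxonomy",
                phylum)
    keep <- otuIds(table) %in% df$otu_id[df$phylum == phylum]
    if (!any(keep))
        stopEem("eemPhylumAbsent",
                "phylum '%s' has no OTUs in community %s", phylum,
                siteId(table))
    CommunityTable(table@counts[keep, , drop = FALSE], table@siteId,
                   table@habitat)
}

#' Relative abundance for display
#'
#' Column-wise proportions (each time point sums to 1). For plotting only:
#' every analysis in this package runs on raw counts.
#'
#' @param x a [CommunityTable-class].
#' @return numeric matrix of proportions with the same dimnames.
#' @export
relativeAbundance <- function(x) {
    stopifnot(is(x, "CommunityTable"))
    tot <- colSums(x@counts)
    tot[tot == 0] <- 1
    sweep(x@counts, 2L, tot, "/")
}
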