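## S4 classes for the Mandala pipeline.

#' Taxonomic ranks used throughout the package, in fixed order
#'
#' Taxonomy tables must carry exactly these ranks, in this order; trees built
#' from taxonomy have one level per rank plus a root and the OTU tips.
#' @export
TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Reserved token for missing taxonomic assignments
#' @export
UNASSIGNED <- "unassigned"

#' CommunityTable: one site's OTU-by-time abundance matrix
#'
#' Raw read counts for a single site. Rows are OTUs, columns are ordered time
#' points (opaque labels; only their order matters). Counts stay raw
#' throughout the pipeline; use [relativeAbundance()] for display only.
#'
#' @slot siteId single site label.
#' @slot habitat single habitat-class label (free-form, e.g. "riverine").
#' @slot counts non-negative integer matrix, OTU ids as rownames and time
#'   labels as colnames.
#' @export
setClass("CommunityTable",
    representation(siteId = "character", habitat = "character",
                   counts = "matrix"))

setValidity("CommunityTable", function(object) {
    cts <- object@counts
    if (length(object@siteId) != 1L || is.na(object@siteId))
        return("siteId must be a single non-NA label")
    if (length(object@habitat) != 1L || is.na(object@habitat))
        return("habitat must be a single non-NA label")
    if (nrow(cts) < 1L) return("counts must have at least one OTU row")
    if (ncol(cts) < 1L) return("counts must have at least one time point")
    if (is.null(rownames(cts))) return("counts must carry OTU ids as rownames")
    if (anyDuplicated(rownames(cts)))
        return("duplicate OTU ids in counts rownames")
    if (is.null(colnames(cts))) return("counts must carry time labels")
    if (!is.numeric(cts) || any(!is.finite(cts)))
        return("counts must be finite numeric values")
    if (any(cts < 0)) return("counts must be non-negative")
    if (any(cts != round(cts))) return("counts must be integers (raw reads)")
    TRUE
})

#' TaxonomyTable: ranked lineages keyed by OTU id
#'
#' One row per OTU; columns are `otu_id` plus the six ranks of
#' [TAXONOMY_RANKS]. Missing assignments hold the reserved [UNASSIGNED]
#' token — they are never dropped, so tree construction can place them
#' explicitly.
#'
#' @slot data data.frame with columns otu_id, kingdom, ..., genus.
#' @export
setClass("TaxonomyTable", representation(data = "data.frame"))

setValidity("TaxonomyTable", function(object) {
    df <- object@data
    if (!identical(colnames(df), c("otu_id", TAXONOMY_RANKS)))
        return(sprintf("columns must be otu_id followed by ranks %s in order",
                       paste(TAXONOMY_RANKS, collapse = ", ")))
    if (nrow(df) < 1L) return("taxonomy must have at least one OTU")
    if (anyDuplicated(df$otu_id)) return("duplicate otu_id entries")
    if (any(vapply(df, function(col) any(is.na(col) | col == ""), logical(1))))
        return("cells must be taxon names or the 'unassigned' token, not blank/NA")
    TRUE
})

#' StudySet: the multi-site study container
#'
#' A list of (CommunityTable, TaxonomyTable) pairs, one per site. Site ids
#' must be unique and every OTU observed at a site must be present in that
#' site's taxonomy.
#'
#' @slot communities list of [CommunityTable-class] objects.
#' @slot taxonomies list of [TaxonomyTable-class] objects, parallel to
#'   `communities` (may share one underlying master taxonomy).
#' @export
setClass("StudySet",
    representation(communities = "list", taxonomies = "list"))

setValidity("StudySet", function(object) {
    if (length(object@communities) < 1L) return("study must contain sites")
    if (length(object@communities) != length(object@taxonomies))
        return("one taxonomy per community is required")
    ok <- vapply(object@communities, is, logical(1), "CommunityTable")
    if (!all(ok)) return("communities must be CommunityTable objects")
    ok <- vapply(object@taxonomies, is, logical(1), "TaxonomyTable")
    if (!all(ok)) return("taxonomies must be TaxonomyTable objects")
    ids <- vapply(object@communities, function(x) x@siteId, character(1))
    if (anyDuplicated(ids)) return("site ids must be unique")
    for (k in seq_along(ids)) {
        missing <- setdiff(rownames(object@communities[[k]]@counts),
                           object@taxonomies[[k]]@data$otu_id)
        if (length(missing))
            return(sprintf("site %s: OTUs missing from taxonomy: %s",
                           ids[k], paste(head(missing, 3L), collapse = ", ")))
    }
    TRUE
})

#' TEMatrix: directed transfer-entropy matrix for one community
#'
#' Entry (i, j) is the transfer entropy TE(X_i -> X_j) in bits. The diagonal
#' is undefined and stored as NA. The matrix is generally asymmetric; raw
#' (possibly slightly negative) estimates are preserved.
#'
#' @slot otuIds OTU labels in matrix order.
#' @slot values numeric matrix of TE estimates in bits, NA diagonal.
#' @export
setClass("TEMatrix", representation(otuIds = "character", values = "matrix"))

setValidity("TEMatrix", function(object) {
    v <- object@values
    n <- length(object@otuIds)
    if (!all(dim(v) == c(n, n))) return("values must be n_otu x n_otu")
    off <- v[row(v) != col(v)]
    if (any(!is.finite(off))) return("off-diagonal entries must be finite")
    TRUE
})

#' ExceedanceCurve: empirical P(Y >= y)
#'
#' @slot y sorted distinct sample values, ascending.
#' @slot p exceedance probability at each y, non-increasing, p[1] == 1.
#' @export
setClass("ExceedanceCurve", representation(y = "numeric", p = "numeric"))

setValidity("ExceedanceCurve", function(object) {
    if (length(object@y) != length(object@p)) return("y and p lengths differ")
    if (is.unsorted(object@y, strictly = TRUE)) return("y must be strictly ascending")
    if (any(diff(object@p) > 0)) return("p must be non-increasing")
    if (abs(object@p[1] - 1) > 1e-12) return("p at the smallest y must be 1")
    TRUE
})

#' TailFit: a fitted exceedance-tail model
#'
#' Maximum-likelihood fit of a tail family above a lower cutoff `xmin`.
#' For `family = "powerlaw"` the exponent is the density exponent epsilon
#' (> 1); for `family = "exponential"` it is the rate lambda (> 0) of a
#' shifted exponential on y >= xmin.
#'
#' @slot family "powerlaw" or "exponential".
#' @slot exponent epsilon or lambda at the MLE.
#' @slot xmin lower cutoff, in units of the data.
#' @slot nTail number of observations >= xmin used in the fit.
#' @slot loglik log-likelihood at the MLE.
#' @slot ks Kolmogorov-Smirnov distance between fitted and empirical tail.
#' @export
setClass("TailFit",
    representation(family = "character", exponent = "numeric",
                   xmin = "numeric", nTail = "integer",
                   loglik = "numeric", ks = "numeric"))

setValidity("TailFit", function(object) {
    if (!object@family %in% c("powerlaw", "exponential"))
        return("family must be 'powerlaw' or 'exponential'")
    if (object@family == "powerlaw" && object@exponent <= 1)
        return("power-law density exponent must exceed 1")
    if (object@family == "exponential" && object@exponent <= 0)
        return("exponential rate must be positive")
    if (object@nTail < 1L) return("empty tail")
    TRUE
})

#' TaylorFit: Taylor's-law fluctuation-scaling fit
#'
#' Slope nu of the ordinary least-squares regression of log2(variance) on
#' log2(mean) across OTUs, using the population (divide-by-n) variance of
#' each abundance series.
#'
#' @slot nu slope (dimensionless).
#' @slot intercept intercept in log2 units.
#' @slot r2 coefficient of determination.
#' @slot nPoints OTUs used.
#' @slot nExcluded OTUs dropped for zero mean or zero variance.
#' @export
setClass("TaylorFit",
    representation(nu = "numeric", intercept = "numeric", r2 = "numeric",
                   nPoints = "integer", nExcluded = "integer"))

setValidity("TaylorFit", function(object) {
    if (!is.finite(object@nu)) return("nu must be finite")
    if (object@nPoints < 3L) return("at least 3 points are required")
    TRUE
})

#' MandalaSet: a set of Mandala points sharing common axis maxima
#'
#' Each row of `points` is one community or one phylum with raw axis values
#' (D, lambda, epsilon, and nu for reference), values rescaled by the common
#' per-axis maximum, barycentric ternary coordinates, the divergence from the
#' optimal vertex, and flags for axes that could not be computed.
#'
#' @slot points data.frame; see [communityMandala()] for columns.
#' @slot axisMaxima named numeric (D, lambda, epsilon) used for rescaling.
#' @slot config list of analysis settings used (audit trail).
#' @export
setClass("MandalaSet",
    representation(points = "data.frame", axisMaxima = "numeric",
                   config = "list"))

setValidity("MandalaSet", function(object) {
    need <- c("scope", "site", "phylum", "habitat", "D_raw", "lambda_raw",
              "epsilon_raw", "nu", "D_s", "lambda_s", "epsilon_s",
              "tern_D", "tern_lambda", "tern_epsilon", "divergence", "flags")
    if (!all(need %in% colnames(object@points)))
        return(sprintf("points is missing columns: %s",
                       paste(setdiff(need, colnames(object@points)),
                             collapse = ", ")))
    if (!all(c("D", "lambda", "epsilon") %in% names(object@axisMaxima)))
        return("axisMaxima must name D, lambda and epsilon")
    TRUE
})
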