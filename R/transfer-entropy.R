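## Directed interaction inference by transfer entropy with a box-kernel
## plug-in estimator (history 1, kernel half-width 0.5 sd by default).

#' Z-normalize an abundance series
#'
#' Centers to mean 0 and scales to sample standard deviation 1, so that the
#' kernel half-width of [transferEntropy()] is expressed in sd units. A
#' constant series cannot be scaled: it is returned as all zeros with
#' attribute `zeroVariance = TRUE`, and the caller decides what that means
#' (transfer entropy treats it as 0 bits).
#'
#' @param x numeric series of length >= 2.
#' @return normalized numeric series; attribute `zeroVariance` is TRUE for
#'   constant input, FALSE otherwise.
#' @examples
#' normalizeSeries(c(1, 2, 3))
#' @export
normalizeSeries <- function(x) {
    if (length(x) < 2L)
        stopEem("eemShortSeries", "need at least 2 observations, got %d",
                length(x))
    if (any(!is.finite(x)))
        stopEem("eemNonFinite", "series contains non-finite values")
    s <- stats::sd(x)
    if (s == 0) {
        out <- rep(0, length(x))
        attr(out, "zeroVariance") <- TRUE
        return(out)
    }
    out <- (x - mean(x)) / s
    attr(out, "zeroVariance") <- FALSE
    out
}

#' Transfer entropy between two abundance series
#'
#' Plug-in estimate of the directed information flow from `source` to
#' `target`,
#' \deqn{TE_{X \to Y} = \sum p(y_t, y_{t-1}, x_{t-1})
#'   \log_2 \frac{p(y_t \mid y_{t-1}, x_{t-1})}{p(y_t \mid y_{t-1})},}
#' with probabilities estimated by a box kernel (Heaviside, max-norm) of
#' half-width `kernelWidth` on the z-normalized series: each probability is
#' the fraction of embedded sample points within the closed ball of that
#' radius around the query point, in the relevant 1-, 2- and 3-dimensional
#' embedding spaces. The sum runs over the t-1 embedded observations.
#' Deterministic; returned in bits.
#'
#' The raw plug-in value can be slightly negative (estimator noise); it is
#' returned as-is — flooring at zero is the caller's choice. If either series
#' is constant the estimate is 0 bits by convention (no uncertainty to
#' reduce).
#'
#' @param source,target numeric series of equal length t >= 3.
#' @param history target history length; the supported estimator uses 1
#'   (other values are accepted but flagged experimental).
#' @param kernelWidth kernel half-width (closed-ball radius) in sd units
#'   after normalization.
#' @return transfer entropy estimate in bits.
#' @export
transferEntropy <- function(source, target, history = 1L,
                            kernelWidth = 0.5) {
    if (length(source) != length(target))
        stopEem("eemLengthMismatch",
                "source (%d) and target (%d) lengths differ",
                length(source), length(target))
    t <- length(source)
    if (t < 3L)
        stopEem("eemShortSeries",
                "transfer entropy needs t >= 3 observations, got %d", t)
    if (any(!is.finite(source)) || any(!is.finite(target)))
        stopEem("eemNonFinite", "series contain non-finite values")
    history <- as.integer(history)
    if (history != 1L)
        warnEem("eemExperimental",
                "history length %d is experimental; the supported estimator uses 1",
                history)
    if (history < 1L || t - history < 2L)
        stopEem("eemShortSeries", "history %d too long for t = %d", history, t)
    zs <- normalizeSeries(source)
    zt <- normalizeSeries(target)
    if (attr(zs, "zeroVariance") || attr(zt, "zeroVariance"))
        return(0)
    .teKernelCpp(as.numeric(zs), as.numeric(zt), history, kernelWidth)
}

#' Permutation-surrogate transfer-entropy estimates
#'
#' Null distribution for [transferEntropy()] obtained by randomly permuting
#' the source series (destroying its temporal alignment with the target)
#' and re-estimating. Used for significance checks in validation; the
#' package applies no surrogate correction to pipeline estimates.
#'
#' @param source,target numeric series of equal length t >= 3.
#' @param n number of surrogates.
#' @param history,kernelWidth as in [transferEntropy()].
#' @return numeric vector of `n` surrogate TE estimates (bits).
#' @export
teSurrogates <- function(source, target, n = 100L, history = 1L,
                         kernelWidth = 0.5) {
    zs <- normalizeSeries(source)
    zt <- normalizeSeries(target)
    if (attr(zs, "zeroVariance") || attr(zt, "zeroVariance"))
        return(rep(0, n))
    perms <- vapply(seq_len(n), function(i) sample(as.numeric(zs)),
                    numeric(length(zs)))
    .teSurrogatesCpp(perms, as.numeric(zt), as.integer(history), kernelWidth)
}

#' Pairwise transfer entropy within a community
#'
#' Fills TE(X_i -> X_j) for every ordered OTU pair of a community. Zero-
#' variance (constant) OTUs give 0 bits in both directions; the diagonal is
#' NA. The estimator has no internal randomness: repeated calls on the same
#' community give identical matrices.
#'
#' @param community a [CommunityTable-class] with t >= 3 time points (a
#'   short-series warning is emitted for t < 10).
#' @param history,kernelWidth as in [transferEntropy()].
#' @return a [TEMatrix-class] in bits.
#' @export
pairwiseTE <- function(community, history = 1L, kernelWidth = 0.5) {
    stopifnot(is(community, "CommunityTable"))
    cts <- counts(community)
    t <- ncol(cts)
    if (t < 3L)
        stopEem("eemShortSeries",
                "site %s: transfer entropy needs t >= 3 time points, got %d",
                siteId(community), t)
    if (t < 10L)
        warnEem("eemShortSeriesWarning",
                "site %s: short series (t = %d); interaction estimates will be noisy",
                siteId(community), t)
    history <- as.integer(history)
    if (history != 1L)
        warnEem("eemExperimental",
                "history length %d is experimental; the supported estimator uses 1",
                history)
    sds <- apply(cts, 1L, stats::sd)
    zeroVar <- sds == 0
    z <- t(cts)                         # t x n
    z <- sweep(z, 2L, rowMeans(cts), "-")
    z[, !zeroVar] <- sweep(z[, !zeroVar, drop = FALSE], 2L, sds[!zeroVar],
                           "/")
    z[, zeroVar] <- 0
    vals <- .teMatrixCpp(z, zeroVar, history, kernelWidth)
    dimnames(vals) <- list(otuIds(community), otuIds(community))
    new("TEMatrix", otuIds = otuIds(community), values = vals)
}

#' @rdname accessors
#' @export
setMethod("teValues", "TEMatrix", function(x) x@values)

setMethod("show", "TEMatrix", function(object) {
    off <- object@values[row(object@values) != col(object@values)]
    cat(sprintf("TEMatrix: %d OTUs; off-diagonal TE in [%.4g, %.4g] bits\n",
                length(object@otuIds), min(off), max(off)))
})

#' Flatten a TEMatrix to the values used for tail fitting
#'
#' Pools all directed off-diagonal estimates, floors negatives at 0 (the
#' exceedance machinery needs non-negative support) and drops exact zeros.
#'
#' @param tem a [TEMatrix-class].
#' @return numeric vector of positive TE values (bits).
#' @export
teFitValues <- function(tem) {
    stopifnot(is(tem, "TEMatrix"))
    v <- tem@values[row(tem@values) != col(tem@values)]
    v <- pmax(v, 0)
    v[v > 0]
}

#' Write a TEMatrix to disk
#'
#' @param tem a [TEMatrix-class].
#' @param path output path.
#' @param format `"edges"` for a (source_id, target_id, te_bits) TSV edge
#'   list, `"matrix"` for a square TSV, `"graphml"` for GraphML (requires
#'   igraph).
#' @return `path`, invisibly.
#' @export
writeTEMatrix <- function(tem, path, format = c("edges", "matrix",
                                                "graphml")) {
    stopifnot(is(tem, "TEMatrix"))
    format <- match.arg(format)
    v <- tem@values
    if (format == "matrix") {
        df <- data.frame(otu_id = tem@otuIds, v, check.names = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else if (format == "edges") {
        idx <- which(row(v) != col(v), arr.ind = TRUE)
        df <- data.frame(source_id = tem@otuIds[idx[, 1L]],
                         target_id = tem@otuIds[idx[, 2L]],
                         te_bits = v[idx])
        df <- df[order(df$source_id, df$target_id), ]
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        if (!requireNamespace("igraph", quietly = TRUE))
            stopEem("eemBadConfig", "GraphML export requires igraph")
        w <- v
        w[is.na(w)] <- 0
        g <- igraph::graph_from_adjacency_matrix(w, mode = "directed",
                                                 weighted = "te_bits")
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}
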