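## The Eco-Evo Mandala: assemble (D, lambda, epsilon) per community or
## phylum, rescale each axis to its observed maximum, project to ternary
## coordinates, and score divergence from the theoretically optimal vertex
## (high D, low lambda, low epsilon).

#' Analysis settings for the Mandala pipeline
#'
#' Defaults reproduce the reference estimator settings throughout: transfer
#' entropy with history length 1 and box-kernel half-width 0.5 normalized
#' units; tail fits with a KS-scanned cutoff for abundances and a fixed
#' cutoff (minimum positive value) for TE values; at least 8 tail points per
#' fit; a log-likelihood margin of 2 for family selection; between-phylum
#' pairs for Dp.
#'
#' @param history TE target history length.
#' @param kernelWidth TE box-kernel half-width in sd units.
#' @param nMin minimum tail observations for an admissible fit.
#' @param familyThreshold log-likelihood margin for [selectFamily()].
#' @param abundanceXminPolicy xmin policy for abundance fits.
#' @param teXminPolicy xmin policy for TE fits.
#' @param pairConvention Dp pair set, `"between"` or `"all_others"`.
#' @param abundancePooling `"pooled"` fits epsilon to all (OTU, time) counts;
#'   `"otu_means"` fits it to per-OTU time means.
#' @return a named list of settings (class `mandalaConfig`).
#' @export
mandalaConfig <- function(history = 1L, kernelWidth = 0.5, nMin = 8L,
                          familyThreshold = 2,
                          abundanceXminPolicy = c("ks_scan", "fixed"),
                          teXminPolicy = c("fixed", "ks_scan"),
                          pairConvention = c("between", "all_others"),
                          abundancePooling = c("pooled", "otu_means")) {
    cfg <- list(history = as.integer(history), kernelWidth = kernelWidth,
                nMin = as.integer(nMin), familyThreshold = familyThreshold,
                abundanceXminPolicy = match.arg(abundanceXminPolicy),
                teXminPolicy = match.arg(teXminPolicy),
                pairConvention = match.arg(pairConvention),
                abundancePooling = match.arg(abundancePooling))
    class(cfg) <- "mandalaConfig"
    cfg
}

#' Rescale an axis by its maximum
#'
#' Each value is divided by the maximum of the series (x / xmax), so the
#' largest observation maps to exactly 1. NAs are carried through (their
#' presence marks axes that could not be computed) but at least one finite
#' positive value is required.
#'
#' @param values numeric axis values across the plotted entities.
#' @return rescaled values in (0, 1], same length; attribute `xmax` records
#'   the maximum used.
#' @export
rescaleAxis <- function(values) {
    if (any(is.nan(values)))
        stopEem("eemNonFinite", "axis values contain NaN")
    finite <- values[is.finite(values)]
    if (length(finite) == 0L || max(finite) <= 0)
        stopEem("eemBadValues",
                "axis rescaling needs at least one positive finite value")
    xmax <- max(finite)
    out <- values / xmax
    attr(out, "xmax") <- xmax
    out
}

#' Barycentric ternary coordinates
#'
#' Normalizes a rescaled (D, lambda, epsilon) triplet to unit sum. Axis order
#' is fixed as (D, lambda, epsilon), read counter-clockwise around the
#' triangle.
#'
#' @param D_s,lambda_s,epsilon_s rescaled axis values (vectors of equal
#'   length), all >= 0 and not all zero.
#' @return matrix with columns tern_D, tern_lambda, tern_epsilon summing to 1
#'   per row.
#' @export
ternaryCoordinates <- function(D_s, lambda_s, epsilon_s) {
    m <- cbind(tern_D = D_s, tern_lambda = lambda_s, tern_epsilon = epsilon_s)
    if (any(m[is.finite(m)] < 0))
        stopEem("eemBadValues", "ternary components must be non-negative")
    tot <- rowSums(m)
    if (any(!is.na(tot) & tot == 0))
        stopEem("eemBadValues", "all-zero triplet cannot be placed on the ternary")
    m / tot
}

#' Divergence from the optimal vertex
#'
#' Euclidean distance, in rescaled (D_s, lambda_s, epsilon_s) space, from the
#' theoretically optimal state (1, 0, 0): maximal phylogenetic dissimilarity
#' with maximally scale-free (low-rate, low-exponent) abundance and
#' interaction distributions. 0 at the optimum; increases with lambda_s or
#' epsilon_s and decreases as D_s approaches 1.
#'
#' @param D_s,lambda_s,epsilon_s rescaled axis values.
#' @return non-negative divergence, NA where any component is missing.
#' @export
optimalityDivergence <- function(D_s, lambda_s, epsilon_s) {
    sqrt((D_s - 1)^2 + lambda_s^2 + epsilon_s^2)
}

## shared assembly: raw axis rows -> MandalaSet
.assembleMandala <- function(pts, config) {
    maxOrNa <- function(v) {
        f <- v[is.finite(v)]
        if (length(f)) max(f) else NA_real_
    }
    maxima <- c(D = maxOrNa(pts$D_raw), lambda = maxOrNa(pts$lambda_raw),
                epsilon = maxOrNa(pts$epsilon_raw))
    pts$D_s <- pts$D_raw / maxima["D"]
    pts$lambda_s <- pts$lambda_raw / maxima["lambda"]
    pts$epsilon_s <- pts$epsilon_raw / maxima["epsilon"]
    complete <- is.finite(pts$D_s) & is.finite(pts$lambda_s) &
        is.finite(pts$epsilon_s)
    tern <- matrix(NA_real_, nrow(pts), 3L,
                   dimnames = list(NULL, c("tern_D", "tern_lambda",
                                           "tern_epsilon")))
    if (any(complete))
        tern[complete, ] <- ternaryCoordinates(pts$D_s[complete],
                                               pts$lambda_s[complete],
                                               pts$epsilon_s[complete])
    pts <- cbind(pts, tern)
    pts$divergence <- ifelse(complete,
                             optimalityDivergence(pts$D_s, pts$lambda_s,
                                                  pts$epsilon_s),
                             NA_real_)
    rownames(pts) <- NULL
    new("MandalaSet", points = pts, axisMaxima = maxima,
        config = unclass(config))
}

.axisRow <- function(scope, site, phylum, habitat) {
    data.frame(scope = scope, site = site, phylum = phylum, habitat = habitat,
               D_raw = NA_real_, lambda_raw = NA_real_,
               epsilon_raw = NA_real_, nu = NA_real_, flags = "",
               stringsAsFactors = FALSE)
}

.addFlag <- function(flags, flag) {
    ifelse(nzchar(flags), paste(flags, flag, sep = ";"), flag)
}

## epsilon from abundances; lambda from TE values; both may refuse
.fitAxes <- function(cts, tem, config) {
    out <- list(epsilon = NA_real_, lambda = NA_real_, flags = character(0))
    abund <- if (config$abundancePooling == "pooled") as.vector(cts)
             else rowMeans(cts)
    eps <- tryCatch(fitPowerlaw(abund, config$abundanceXminPolicy,
                                nMin = config$nMin),
                    eemError = function(e) NULL)
    if (is.null(eps)) out$flags <- c(out$flags, "missing-epsilon")
    else out$epsilon <- eps@exponent
    if (!is.null(tem)) {
        tev <- teFitValues(tem)
        lam <- tryCatch(fitExponential(tev, config$teXminPolicy,
                                       nMin = config$nMin),
                        eemError = function(e) NULL)
        if (is.null(lam)) out$flags <- c(out$flags, "missing-lambda")
        else out$lambda <- lam@exponent
    } else out$flags <- c(out$flags, "missing-lambda")
    out$epsilonFit <- eps
    if (!is.null(tem)) out$lambdaFit <- lam
    out
}

#' Community-level Mandala for a multi-site study
#'
#' For each site: epsilon from the power-law fit of pooled abundances, lambda
#' from the exponential fit of pooled pairwise transfer-entropy values, D
#' from the taxonomy-rank tree, and nu (Taylor's law, reported alongside but
#' not a Mandala axis). Axes are then rescaled by their maxima across sites,
#' projected to ternary coordinates, and scored for divergence from the
#' optimal vertex. Sites where a fit refuses are retained with an explicit
#' flag (e.g. `missing-lambda`) and excluded from the ternary projection,
#' never silently dropped.
#'
#' @param study a [StudySet-class].
#' @param config a [mandalaConfig()].
#' @return a [MandalaSet-class] with one point per site.
#' @export
communityMandala <- function(study, config = mandalaConfig()) {
    stopifnot(is(study, "StudySet"))
    comms <- communities(study)
    if (length(comms) == 0L)
        stopEem("eemEmptyStudy", "study contains no sites")
    rows <- vector("list", length(comms))
    for (k in seq_along(comms)) {
        comm <- comms[[k]]
        tax <- taxonomies(study)[[k]]
        row <- .axisRow("community", siteId(comm), NA_character_,
                        habitat(comm))
        tem <- tryCatch(pairwiseTE(comm, config$history, config$kernelWidth),
                        eemError = function(e) NULL)
        ax <- .fitAxes(counts(comm), tem, config)
        row$epsilon_raw <- ax$epsilon
        row$lambda_raw <- ax$lambda
        for (f in ax$flags) row$flags <- .addFlag(row$flags, f)
        if (length(otuIds(comm)) >= 2L) {
            tree <- buildTaxonomyTree(tax, otuIds(comm))
            row$D_raw <- effectiveDistance(tipDistanceMatrix(tree))
        } else row$flags <- .addFlag(row$flags, "missing-D")
        tf <- tryCatch(taylorExponent(comm), eemError = function(e) NULL)
        if (!is.null(tf)) row$nu <- tf@nu
        rows[[k]] <- row
    }
    .assembleMandala(do.call(rbind, rows), config)
}

#' Phylum-level Mandala for one site
#'
#' For each phylum present at the site: epsilon from the phylum-restricted
#' abundance fit, lambda from the phylum-restricted TE fit, and Dp from the
#' site's taxonomy tree. Only phyla for which all three axes are calculable
#' receive ternary coordinates; the others are retained with flags (a phylum
#' with a single OTU has no TE pairs, so lambda is never calculable for it).
#' A community-average point over the whole site is included.
#'
#' @param community a [CommunityTable-class].
#' @param taxonomy a [TaxonomyTable-class].
#' @param config a [mandalaConfig()].
#' @return a [MandalaSet-class] with one point per phylum plus one
#'   community point.
#' @export
phylumMandala <- function(community, taxonomy, config = mandalaConfig()) {
    stopifnot(is(community, "CommunityTable"), is(taxonomy, "TaxonomyTable"))
    ids <- otuIds(community)
    df <- taxonomyData(taxonomy)
    phyla <- sort(unique(df$phylum[df$otu_id %in% ids]))
    if (length(phyla) < 1L)
        stopEem("eemPhylumAbsent", "no phyla found for site %s",
                siteId(community))
    dmat <- if (length(ids) >= 2L)
        tipDistanceMatrix(buildTaxonomyTree(taxonomy, ids)) else NULL

    rows <- vector("list", length(phyla) + 1L)
    for (k in seq_along(phyla)) {
        p <- phyla[k]
        row <- .axisRow("phylum", siteId(community), p, habitat(community))
        sub <- subsetByPhylum(community, taxonomy, p)
        tem <- if (length(otuIds(sub)) >= 2L)
            tryCatch(suppressWarnings(
                pairwiseTE(sub, config$history, config$kernelWidth)),
                eemError = function(e) NULL)
            else NULL
        if (length(otuIds(sub)) < 2L)
            row$flags <- .addFlag(row$flags, "single-otu")
        ax <- .fitAxes(counts(sub), tem, config)
        row$epsilon_raw <- ax$epsilon
        row$lambda_raw <- ax$lambda
        for (f in ax$flags) row$flags <- .addFlag(row$flags, f)
        if (!is.null(dmat)) {
            dp <- tryCatch(phylumDistance(dmat, taxonomy, p,
                                          config$pairConvention),
                           eemError = function(e) NULL)
            if (!is.null(dp)) row$D_raw <- dp$Dp
            else row$flags <- .addFlag(row$flags, "missing-D")
        } else row$flags <- .addFlag(row$flags, "missing-D")
        tf <- tryCatch(taylorExponent(sub), eemError = function(e) NULL)
        if (!is.null(tf)) row$nu <- tf@nu
        rows[[k]] <- row
    }

    crow <- .axisRow("community", siteId(community), NA_character_,
                     habitat(community))
    tem <- tryCatch(suppressWarnings(
        pairwiseTE(community, config$history, config$kernelWidth)),
        eemError = function(e) NULL)
    ax <- .fitAxes(counts(community), tem, config)
    crow$epsilon_raw <- ax$epsilon
    crow$lambda_raw <- ax$lambda
    for (f in ax$flags) crow$flags <- .addFlag(crow$flags, f)
    if (!is.null(dmat)) crow$D_raw <- effectiveDistance(dmat)
    tf <- tryCatch(taylorExponent(community), eemError = function(e) NULL)
    if (!is.null(tf)) crow$nu <- tf@nu
    rows[[length(phyla) + 1L]] <- crow

    pts <- do.call(rbind, rows)
    if (!any(with(pts, scope == "phylum" & is.finite(D_raw) &
                       is.finite(lambda_raw) & is.finite(epsilon_raw))))
        stopEem("eemTooFewPoints",
                "site %s: no phylum has all three axes calculable",
                siteId(community))
    .assembleMandala(pts, config)
}

#' @rdname accessors
#' @export
setMethod("mandalaPoints", "MandalaSet", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("axisMaxima", "MandalaSet", function(x) x@axisMaxima)

setMethod("show", "MandalaSet", function(object) {
    pts <- object@points
    cat(sprintf("MandalaSet: %d points (%d on the ternary)\n", nrow(pts),
                sum(is.finite(pts$divergence))))
    cat(sprintf("  axis maxima: D = %.4g, lambda = %.4g, epsilon = %.4g\n",
                object@axisMaxima["D"], object@axisMaxima["lambda"],
                object@axisMaxima["epsilon"]))
})

#' Serialize a MandalaSet
#'
#' Writes the point table as TSV and a JSON sidecar (same path with
#' `.json` appended) holding the axis maxima and analysis settings, so any
#' rescaled value can be audited back to its raw value.
#'
#' @param set a [MandalaSet-class].
#' @param path output TSV path.
#' @param seed optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
writeMandalaSet <- function(set, path, seed = NULL) {
    stopifnot(is(set, "MandalaSet"))
    cols <- c("scope", "site", "phylum", "habitat", "D_raw", "lambda_raw",
              "epsilon_raw", "nu", "D_s", "lambda_s", "epsilon_s", "tern_D",
              "tern_lambda", "tern_epsilon", "divergence", "flags")
    utils::write.table(set@points[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sidecar <- list(axis_maxima = as.list(set@axisMaxima),
                    config = set@config)
    if (!is.null(seed)) sidecar$seed <- seed
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
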