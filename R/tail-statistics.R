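## Exceedance distributions, maximum-likelihood tail fits (power law epsilon,
## exponential rate lambda) and Taylor's-law fluctuation scaling (nu).

#' Empirical exceedance curve P(Y >= y)
#'
#' For each distinct sample value y, the fraction of observations greater
#' than or equal to y. Ties collapse to one point; the curve starts at 1.
#'
#' @param values numeric sample with at least one positive value;
#'   non-positive values are dropped (exceedance tails are defined on
#'   positive support).
#' @return an [ExceedanceCurve-class].
#' @examples
#' exceedance(c(3, 1, 2))
#' @export
exceedance <- function(values) {
    values <- values[is.finite(values) & values > 0]
    if (length(values) == 0L)
        stopEem("eemEmptyTable", "no positive values to form an exceedance curve")
    n <- length(values)
    y <- sort(unique(values))
    # count of observations >= y, via the sorted sample
    srt <- sort(values)
    p <- (n - findInterval(y, srt, left.open = TRUE)) / n
    new("ExceedanceCurve", y = y, p = p)
}

setMethod("show", "ExceedanceCurve", function(object) {
    cat(sprintf("ExceedanceCurve: %d distinct values, y in [%g, %g]\n",
                length(object@y), min(object@y), max(object@y)))
})

.tailOf <- function(values, xmin, nMin, what) {
    tail <- values[values >= xmin]
    if (length(tail) < nMin)
        stopEem("eemTooFewTail",
                "%s: only %d tail observations >= xmin = %g (need >= %d)",
                what, length(tail), xmin, nMin)
    tail
}

.ksDistance <- function(tailSorted, fittedCdf) {
    n <- length(tailSorted)
    Fhat <- fittedCdf(tailSorted)
    max(abs(seq_len(n) / n - Fhat), abs((seq_len(n) - 1) / n - Fhat))
}

.plFitAt <- function(values, xmin, nMin) {
    tail <- sort(.tailOf(values, xmin, nMin, "power-law fit"))
    n <- length(tail)
    slnr <- sum(log(tail / xmin))
    if (slnr == 0)
        stopEem("eemZeroSpread",
                "all tail values equal xmin = %g; power-law exponent undefined",
                xmin)
    eps <- 1 + n / slnr
    loglik <- n * log(eps - 1) - n * log(xmin) - eps * slnr
    ks <- .ksDistance(tail, function(y) 1 - (y / xmin)^(-(eps - 1)))
    list(exponent = eps, xmin = xmin, nTail = n, loglik = loglik, ks = ks)
}

.expFitAt <- function(values, xmin, nMin) {
    tail <- sort(.tailOf(values, xmin, nMin, "exponential fit"))
    n <- length(tail)
    spread <- mean(tail) - xmin
    if (spread <= 0)
        stopEem("eemZeroSpread",
                "tail mean equals xmin = %g; exponential rate undefined", xmin)
    lambda <- 1 / spread
    loglik <- n * log(lambda) - lambda * sum(tail - xmin)
    ks <- .ksDistance(tail, function(y) 1 - exp(-lambda * (y - xmin)))
    list(exponent = lambda, xmin = xmin, nTail = n, loglik = loglik, ks = ks)
}

.xminCandidates <- function(values, nMin) {
    y <- sort(unique(values))
    nTail <- length(values) - findInterval(y, sort(values),
                                           left.open = TRUE)
    y[nTail >= nMin]
}

.fitTail <- function(values, family, xminPolicy, xmin, nMin) {
    values <- values[is.finite(values) & values > 0]
    if (length(values) == 0L)
        stopEem("eemEmptyTable", "no positive values to fit")
    fitAt <- if (family == "powerlaw") .plFitAt else .expFitAt
    if (xminPolicy == "fixed") {
        if (is.null(xmin)) xmin <- min(values)
        fit <- fitAt(values, xmin, nMin)
    } else {
        cands <- .xminCandidates(values, nMin)
        if (length(cands) == 0L)
            stopEem("eemTooFewTail",
                    "no xmin candidate leaves >= %d tail observations", nMin)
        fits <- lapply(cands, function(xm)
            tryCatch(fitAt(values, xm, nMin), eemError = function(e) NULL))
        keep <- !vapply(fits, is.null, logical(1))
        fits <- fits[keep]
        if (length(fits) == 0L)
            stopEem("eemZeroSpread", "no admissible xmin candidate")
        ks <- vapply(fits, `[[`, numeric(1), "ks")
        fit <- fits[[which.min(ks)]]  # ties: which.min takes the smallest xmin
    }
    new("TailFit", family = family, exponent = fit$exponent, xmin = fit$xmin,
        nTail = as.integer(fit$nTail), loglik = fit$loglik, ks = fit$ks)
}

#' Maximum-likelihood power-law tail fit
#'
#' Fits the Zipfian (power-law) tail of the exceedance distribution,
#' P(Y >= y) ~ y^{-(epsilon - 1)} for y >= xmin, i.e. density exponent
#' epsilon. The continuous MLE is closed-form:
#' epsilon = 1 + n / sum(log(y_i / xmin)) over the n tail observations.
#'
#' With `xminPolicy = "ks_scan"` the cutoff is chosen among the observed
#' values to minimize the Kolmogorov-Smirnov distance between the fitted and
#' empirical tail (standard power-law practice for heavy-tailed data with a
#' noisy head); `"fixed"` uses `xmin` as given (default: the minimum positive
#' observation).
#'
#' @param values positive sample (non-positive values are dropped).
#' @param xminPolicy `"fixed"` or `"ks_scan"`.
#' @param xmin lower cutoff for the fixed policy; ignored by the scan.
#' @param nMin minimum number of tail observations for an admissible fit.
#' @return a [TailFit-class] with `family = "powerlaw"`.
#' @examples
#' fitPowerlaw(c(2, 4, 8), xminPolicy = "fixed", xmin = 2, nMin = 3)
#' @export
fitPowerlaw <- function(values, xminPolicy = c("ks_scan", "fixed"),
                        xmin = NULL, nMin = 8L) {
    .fitTail(values, "powerlaw", match.arg(xminPolicy), xmin,
             as.integer(nMin))
}

#' Maximum-likelihood exponential tail fit
#'
#' Fits a shifted exponential P(Y >= y) = exp(-lambda (y - xmin)) for
#' y >= xmin. The MLE is closed-form: lambda = 1 / (mean(tail) - xmin).
#'
#' @inheritParams fitPowerlaw
#' @return a [TailFit-class] with `family = "exponential"`.
#' @examples
#' fitExponential(c(1, 2, 3), xminPolicy = "fixed", xmin = 1, nMin = 3)
#' @export
fitExponential <- function(values, xminPolicy = c("fixed", "ks_scan"),
                           xmin = NULL, nMin = 8L) {
    .fitTail(values, "exponential", match.arg(xminPolicy), xmin,
             as.integer(nMin))
}

setMethod("show", "TailFit", function(object) {
    sym <- if (object@family == "powerlaw") "epsilon" else "lambda"
    cat(sprintf("TailFit (%s): %s = %.4g, xmin = %.4g, n_tail = %d, ks = %.4g, loglik = %.4g\n",
                object@family, sym, object@exponent, object@xmin,
                object@nTail, object@ks, object@loglik))
})

#' Choose between power-law and exponential tail families
#'
#' Fits both families above one common cutoff and compares log-likelihoods
#' on that common tail. By default (`xminPolicy = "fixed"`) the cutoff is
#' the minimum positive observation, so the families are compared over the
#' full positive support: a cutoff scanned to optimize one family's fit
#' truncates the sample to a short tail segment where the two families are
#' locally indistinguishable and the comparison loses essentially all power.
#' `xminPolicy = "ks_scan"` instead reuses the KS-scanned power-law cutoff
#' for both fits (the tail-only comparison). The verdict is
#' `"inconclusive"` when the absolute log-likelihood difference is below
#' `threshold` or when either fit refuses (too few tail observations).
#'
#' @param values positive sample.
#' @param nMin minimum tail size for an admissible fit.
#' @param threshold log-likelihood difference (natural-log units) below which
#'   the families are considered indistinguishable.
#' @param xminPolicy `"fixed"` (common cutoff at the minimum positive value)
#'   or `"ks_scan"` (common cutoff from the power-law KS scan).
#' @return list with `verdict` ("powerlaw", "exponential" or
#'   "inconclusive"), `delta_loglik` (power-law minus exponential; NA when a
#'   fit refused), `powerlaw` and `exponential` ([TailFit-class] or NULL),
#'   and `xmin`.
#' @export
selectFamily <- function(values, nMin = 8L, threshold = 2,
                         xminPolicy = c("fixed", "ks_scan")) {
    xminPolicy <- match.arg(xminPolicy)
    pl <- tryCatch(fitPowerlaw(values, xminPolicy, nMin = nMin),
                   eemError = function(e) NULL)
    if (is.null(pl))
        return(list(verdict = "inconclusive", delta_loglik = NA_real_,
                    powerlaw = NULL, exponential = NULL, xmin = NA_real_))
    ex <- tryCatch(fitExponential(values, "fixed", xmin = pl@xmin,
                                  nMin = nMin),
                   eemError = function(e) NULL)
    if (is.null(ex))
        return(list(verdict = "inconclusive", delta_loglik = NA_real_,
                    powerlaw = pl, exponential = NULL, xmin = pl@xmin))
    delta <- pl@loglik - ex@loglik
    verdict <- if (abs(delta) < threshold) "inconclusive"
               else if (delta > 0) "powerlaw" else "exponential"
    list(verdict = verdict, delta_loglik = delta, powerlaw = pl,
         exponential = ex, xmin = pl@xmin)
}

#' Taylor's-law exponent
#'
#' Fluctuation scaling <x^2> ~ <x>^nu: ordinary least squares of
#' log2(variance) on log2(mean), one point per OTU, where the variance is
#' the population (divide-by-n) variance of the series, Var = E[X^2] -
#' (E[X])^2. OTUs with zero mean or zero variance carry no information about
#' the scaling and are excluded (their count is reported).
#'
#' @param table a [CommunityTable-class] (or any phylum-restricted subset),
#'   or a plain OTU-by-time numeric matrix.
#' @return a [TaylorFit-class].
#' @export
taylorExponent <- function(table) {
    m <- if (is(table, "CommunityTable")) counts(table) else as.matrix(table)
    mu <- rowMeans(m)
    v <- rowMeans(m^2) - mu^2
    keep <- mu > 0 & v > 0
    if (sum(keep) < 3L)
        stopEem("eemTooFewPoints",
                "Taylor regression needs >= 3 OTUs with positive mean and variance (have %d)",
                sum(keep))
    lx <- log2(mu[keep]); ly <- log2(v[keep])
    fit <- stats::lm.fit(cbind(1, lx), ly)
    resid <- fit$residuals
    r2 <- if (stats::var(ly) == 0) 1 else 1 - sum(resid^2) / sum((ly - mean(ly))^2)
    new("TaylorFit", nu = unname(fit$coefficients[2L]),
        intercept = unname(fit$coefficients[1L]), r2 = r2,
        nPoints = as.integer(sum(keep)),
        nExcluded = as.integer(sum(!keep)))
}

setMethod("show", "TaylorFit", function(object) {
    cat(sprintf("TaylorFit: nu = %.4g (r2 = %.3f, %d OTUs, %d excluded)\n",
                object@nu, object@r2, object@nPoints, object@nExcluded))
})

#' Write a table of tail fits as TSV
#'
#' @param fits data.frame with columns scope, site, phylum, quantity, family,
#'   exponent, xmin, n_tail, ks, loglik (as assembled by the pipeline).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFitReport <- function(fits, path) {
    need <- c("scope", "site", "phylum", "quantity", "family", "exponent",
              "xmin", "n_tail", "ks", "loglik")
    if (!all(need %in% colnames(fits)))
        stopEem("eemBadConfig", "fit report is missing columns: %s",
                paste(setdiff(need, colnames(fits)), collapse = ", "))
    utils::write.table(fits[, need], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
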