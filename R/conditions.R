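## Classed conditions so callers can distinguish failure modes programmatically.
## Every user-facing error in the package goes through stopEem() with a class
## from the list below; tests and the pipeline match on these classes.

.eemError <- function(class, message, call = sys.call(-1)) {
    structure(
        class = c(class, "eemError", "error", "condition"),
        list(message = message, call = call)
    )
}

stopEem <- function(class, fmt, ...) {
    stop(.eemError(class, sprintf(fmt, ...), call = sys.call(-1)))
}

warnEem <- function(class, fmt, ...) {
    warning(warningCondition(sprintf(fmt, ...),
                             class = c(class, "eemWarning")))
}

# Error classes in use:
#   eemMissingFile       input file does not exist
#   eemParseError        non-numeric / malformed cell in an abundance table
#   eemDuplicateId       duplicated OTU identifier
#   eemEmptyTable        table with no OTU rows (or no usable values)
#   eemMissingColumn     required column absent
#   eemRankOrder         taxonomy ranks present but in the wrong order
#   eemPhylumAbsent      requested phylum not present
#   eemLengthMismatch    series of unequal length
#   eemShortSeries       time series too short (t < 3)
#   eemNonFinite         NA/NaN/Inf where finite values are required
#   eemZeroVariance      constant series where spread is required
#   eemTooFewTail        fewer tail observations than n_min
#   eemZeroSpread        degenerate sample (all values equal)
#   eemTooFewPoints      fewer usable points than a regression needs
#   eemTooFewTips        tree with fewer than two tips
#   eemNoPairs           empty distance matrix
#   eemBadValues         axis/triplet values outside the admissible range
#   eemEmptyStudy        study with no sites
#   eemBadConfig         invalid or unknown configuration entry
#   eemBadSize           invalid generator size parameter
# Warning classes:
#   eemShortSeriesWarning   3 <= t < 10: estimates will be noisy
#   eemExperimental         non-default estimator settings
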