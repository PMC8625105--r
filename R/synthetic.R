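## Synthetic multi-site bacterioplankton communities with controlled tail
## exponents, Taylor coupling and directed lag-1 interaction graphs. The
## defaults emulate the shape of a seven-site reef/river monitoring study:
## four habitat classes, monthly series of length 3-17, heavy-tailed mean
## abundances with Taylor-scaled variance. Every pipeline stage has a
## ground-truth recovery test against this generator.

#' Habitat archetype parameters for the synthetic generator
#'
#' @param epsilonTrue power-law density exponent of mean abundances (> 1).
#' @param nuTrue Taylor's-law exponent in [1, 2] (fluctuation scaling of
#'   abundance variance against mean).
#' @param couplingDensity fraction of ordered OTU pairs carrying a directed
#'   lag-1 interaction.
#' @param couplingStrength mean mixing weight of an interaction (0-1).
#' @param lambdaScale rate controlling how quickly interaction strengths
#'   decay; higher values give weaker, faster-decaying interactions and thus
#'   a larger fitted exponential rate on the TE distribution.
#' @return named list of archetype parameters.
#' @export
habitatArchetype <- function(epsilonTrue, nuTrue, couplingDensity = 0.05,
                             couplingStrength = 0.5, lambdaScale = 5) {
    if (epsilonTrue <= 1)
        stopEem("eemBadConfig", "epsilonTrue must exceed 1")
    if (nuTrue < 1 || nuTrue > 2)
        stopEem("eemBadConfig", "nuTrue must lie in [1, 2]")
    if (couplingDensity < 0 || couplingDensity > 1)
        stopEem("eemBadConfig", "couplingDensity must lie in [0, 1]")
    if (couplingStrength < 0 || couplingStrength >= 1)
        stopEem("eemBadConfig", "couplingStrength must lie in [0, 1)")
    list(epsilonTrue = epsilonTrue, nuTrue = nuTrue,
         couplingDensity = couplingDensity,
         couplingStrength = couplingStrength, lambdaScale = lambdaScale)
}

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a seven-site study spanning four habitat classes with
#' monthly series of length 3 to 17, a shared OTU pool, and archetype
#' parameters spanning the ranges reported for such communities (density
#' exponents roughly 1.7-2.9, Taylor exponents 1.5-1.7), at a problem size
#' small enough for routine testing.
#'
#' @param nSites number of sites.
#' @param archetypes named list of [habitatArchetype()] entries.
#' @param siteHabitats character vector (length nSites) mapping each site to
#'   an archetype name; names are used as site ids.
#' @param nOtus integer vector (length nSites): OTUs observed per site.
#' @param t integer vector (length nSites): time-series length per site
#'   (>= 3).
#' @param poolSize size of the master OTU pool shared across sites.
#' @param nPhyla phyla in the master taxonomy.
#' @param noiseCv lognormal jitter (sd in log space) on each OTU's variance
#'   target.
#' @param minMean lower cutoff of the Pareto law for mean abundances (reads).
#' @param seed mandatory integer seed.
#' @return a validated `synthConfig` list.
#' @export
synthConfig <- function(nSites = 7L,
                        archetypes = list(
                            "estuarine-inshore-reef" = habitatArchetype(
                                1.9, 1.6, 0.08, 0.35, 8),
                            "lagoon" = habitatArchetype(2.3, 1.55, 0.05,
                                                        0.45, 6),
                            "marine-inshore-reef" = habitatArchetype(
                                2.6, 1.5, 0.05, 0.5, 4),
                            "riverine" = habitatArchetype(1.75, 1.7, 0.10,
                                                          0.6, 2.5)),
                        siteHabitats = c(
                            TT1 = "estuarine-inshore-reef",
                            TT2 = "estuarine-inshore-reef",
                            TT3 = "estuarine-inshore-reef",
                            TT4 = "lagoon",
                            FI = "marine-inshore-reef",
                            RI = "marine-inshore-reef",
                            TR = "riverine"),
                        nOtus = c(180L, 190L, 185L, 170L, 110L, 90L, 12L),
                        t = c(15L, 17L, 17L, 15L, 10L, 9L, 3L),
                        poolSize = 240L,
                        nPhyla = 12L,
                        noiseCv = 0.2,
                        minMean = 5,
                        seed = NULL) {
    if (is.null(seed))
        stopEem("eemBadConfig", "synthConfig requires an explicit seed")
    nSites <- as.integer(nSites)
    if (nSites < 1L)
        stopEem("eemBadSize", "nSites must be >= 1 (got %d)", nSites)
    if (length(siteHabitats) != nSites)
        stopEem("eemBadConfig", "siteHabitats must have one entry per site")
    if (is.null(names(siteHabitats)))
        names(siteHabitats) <- paste0("S", seq_len(nSites))
    if (!all(siteHabitats %in% names(archetypes)))
        stopEem("eemBadConfig", "unknown archetype(s): %s",
                paste(setdiff(siteHabitats, names(archetypes)),
                      collapse = ", "))
    nOtus <- rep_len(as.integer(nOtus), nSites)
    t <- rep_len(as.integer(t), nSites)
    if (any(t < 3L))
        stopEem("eemBadConfig", "every site needs t >= 3 time points")
    if (any(nOtus < 1L))
        stopEem("eemBadSize", "every site needs at least one OTU")
    if (as.integer(poolSize) < max(nOtus))
        stopEem("eemBadSize", "poolSize must cover the largest site")
    cfg <- list(nSites = nSites, archetypes = archetypes,
                siteHabitats = siteHabitats, nOtus = nOtus, t = t,
                poolSize = as.integer(poolSize), nPhyla = as.integer(nPhyla),
                noiseCv = noiseCv, minMean = minMean,
                seed = as.integer(seed))
    class(cfg) <- "synthConfig"
    cfg
}

## ---- taxonomy ----

.generateTaxonomyImpl <- function(nOtus, nPhyla) {
    otu <- paste0("OTU_", seq_len(nOtus))
    # heavy-tailed phylum sizes: Zipf weights, each phylum seeded with one OTU
    w <- (seq_len(nPhyla))^-1
    phylum <- c(seq_len(nPhyla),
                sample(seq_len(nPhyla), nOtus - nPhyla, replace = TRUE,
                       prob = w))
    labels <- list(kingdom = rep("Bacteria", nOtus),
                   phylum = paste0("Phylum_", phylum))
    # nested hierarchy with bounded branching below phylum
    parent <- labels$phylum
    for (rank in TAXONOMY_RANKS[3:6]) {
        child <- character(nOtus)
        for (g in unique(parent)) {
            idx <- which(parent == g)
            k <- sample(1:3, 1L)
            child[idx] <- paste0(g, "_", substr(rank, 1L, 1L),
                                 sample(seq_len(k), length(idx),
                                        replace = TRUE))
        }
        labels[[rank]] <- child
        parent <- child
    }
    TaxonomyTable(data.frame(otu_id = otu, labels,
                             stringsAsFactors = FALSE))
}

#' Generate a synthetic taxonomy
#'
#' OTUs are assigned to phyla with heavy-tailed (Zipf-weighted) sizes; lower
#' ranks form a random nested hierarchy with 1-3 children per node.
#' Deterministic for a fixed seed.
#'
#' @param nOtus number of OTUs.
#' @param nPhyla number of phyla (1 <= nPhyla <= nOtus).
#' @param seed integer seed.
#' @return a [TaxonomyTable-class].
#' @export
generateTaxonomy <- function(nOtus, nPhyla, seed) {
    nOtus <- as.integer(nOtus); nPhyla <- as.integer(nPhyla)
    if (nPhyla < 1L || nOtus < 1L || nPhyla > nOtus)
        stopEem("eemBadSize",
                "need 1 <= nPhyla <= nOtus (got nPhyla = %d, nOtus = %d)",
                nPhyla, nOtus)
    withSeed(seed, .generateTaxonomyImpl(nOtus, nPhyla))
}

## ---- abundance dynamics ----

# Pareto means, Taylor-scaled lognormal fluctuations, directed lag-1 mixing.
.generateCommunityImpl <- function(arch, nOtu, t, noiseCv, minMean, otuIds,
                                   siteId, habitat) {
    eps <- arch$epsilonTrue
    m <- minMean * stats::runif(nOtu)^(-1 / (eps - 1))   # inverse-CDF Pareto
    # variance target Var = m^nu, jittered in log space
    vTarget <- m^arch$nuTrue * exp(stats::rnorm(nOtu, 0, noiseCv))
    sigma2 <- log1p(vTarget / m^2)    # lognormal: Var = m^2 (e^{s2} - 1)
    sigma <- sqrt(sigma2)
    z <- matrix(stats::rnorm(nOtu * t), nOtu, t)
    base <- m * exp(sigma * z - sigma2 / 2)

    # directed lag-1 coupling on a random graph of the requested density
    nPairs <- nOtu * (nOtu - 1L)
    nEdges <- round(arch$couplingDensity * nPairs)
    edges <- data.frame(source = integer(0), target = integer(0),
                        strength = numeric(0))
    x <- base
    if (nEdges > 0L && nOtu >= 2L && t >= 2L) {
        pick <- sample(nPairs, nEdges)
        src <- ((pick - 1L) %% nOtu) + 1L
        tgt <- ((pick - 1L) %/% nOtu) + 1L
        bump <- tgt >= src
        tgt[bump] <- tgt[bump] + 1L      # skip the diagonal
        # strengths ~ Exp(rate = lambdaScale / couplingStrength): higher
        # lambdaScale means weaker couplings, hence smaller TE values and a
        # larger fitted exponential rate on the TE distribution
        s <- stats::rexp(nEdges, rate = arch$lambdaScale /
                                        arch$couplingStrength)
        s <- pmin(0.95, pmax(s, 0.02))
        for (e in seq_len(nEdges)) {
            i <- src[e]; j <- tgt[e]
            x[j, 2:t] <- (1 - s[e]) * x[j, 2:t] +
                s[e] * (m[j] / m[i]) * x[i, 1:(t - 1L)]
        }
        edges <- data.frame(source = otuIds[src], target = otuIds[tgt],
                            strength = s)
    }
    cts <- pmax(round(x), 0)
    dimnames(cts) <- list(otuIds, paste0("t", seq_len(t)))
    list(community = CommunityTable(cts, siteId, habitat),
         edges = edges, means = stats::setNames(m, otuIds),
         params = arch)
}

#' Generate one synthetic community
#'
#' Mean abundances are drawn from a Pareto law with density exponent
#' `epsilonTrue`; per-time counts are lognormal around each mean with the
#' variance tuned to the Taylor target Var = mean^nuTrue (then rounded to
#' non-negative integers); a random directed coupling graph imposes lag-1
#' dependence of the given density and strength. The true edge list is
#' returned for interaction-inference validation.
#'
#' @param config a [synthConfig()].
#' @param siteIndex which site (1-based) to generate.
#' @return list with `community` (a [CommunityTable-class]), `edges` (true
#'   directed coupling edge list with strengths), `means` (true mean
#'   abundances) and `params` (the archetype used).
#' @export
generateCommunity <- function(config, siteIndex) {
    stopifnot(inherits(config, "synthConfig"))
    siteIndex <- as.integer(siteIndex)
    if (siteIndex < 1L || siteIndex > config$nSites)
        stopEem("eemBadSize", "siteIndex %d outside 1..%d", siteIndex,
                config$nSites)
    arch <- config$archetypes[[config$siteHabitats[siteIndex]]]
    n <- config$nOtus[siteIndex]
    withSeed(deriveSeed(config$seed, siteIndex),
             .generateCommunityImpl(arch, n, config$t[siteIndex],
                                    config$noiseCv, config$minMean,
                                    paste0("OTU_", seq_len(n)),
                                    names(config$siteHabitats)[siteIndex],
                                    config$siteHabitats[siteIndex]))
}

#' Generate a synthetic multi-site study
#'
#' Builds a master taxonomy over the shared OTU pool, then one community per
#' site (each site observes a random subset of the pool, generated under its
#' habitat archetype). Fully deterministic for a fixed seed.
#'
#' @param config a [synthConfig()].
#' @return list with `study` (a [StudySet-class]), `taxonomy` (the master
#'   [TaxonomyTable-class]) and `truth` (per-site generating parameters,
#'   true coupling edges and true means).
#' @export
generateStudy <- function(config) {
    stopifnot(inherits(config, "synthConfig"))
    taxonomy <- generateTaxonomy(config$poolSize, config$nPhyla, config$seed)
    pool <- otuIds(taxonomy)
    comms <- vector("list", config$nSites)
    truth <- vector("list", config$nSites)
    for (k in seq_len(config$nSites)) {
        arch <- config$archetypes[[config$siteHabitats[k]]]
        ids <- withSeed(deriveSeed(config$seed, 1000L + k),
                        sort(sample(pool, config$nOtus[k])))
        gen <- withSeed(deriveSeed(config$seed, k),
                        .generateCommunityImpl(arch, config$nOtus[k],
                                               config$t[k], config$noiseCv,
                                               config$minMean, ids,
                                               names(config$siteHabitats)[k],
                                               config$siteHabitats[k]))
        comms[[k]] <- gen$community
        truth[[k]] <- list(site = names(config$siteHabitats)[k],
                           habitat = config$siteHabitats[[k]],
                           params = gen$params, edges = gen$edges,
                           means = gen$means)
    }
    names(truth) <- names(config$siteHabitats)
    list(study = StudySet(comms, taxonomy), taxonomy = taxonomy,
         truth = truth)
}
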