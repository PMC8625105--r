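## Full pipeline: inputs (files or the synthetic generator) -> transfer
## entropy -> tail fits -> phylogenetic distances -> Mandala, with a strict
## config schema and a reproducibility manifest.

.schema <- list(
    top = c("input", "synth", "te", "fit", "phylo", "output_dir", "seed",
            "log_level", "figures"),
    input = c("abundance", "taxonomy", "site_id", "habitat"),
    te = c("history", "kernel_width"),
    fit = c("abundance_xmin_policy", "te_xmin_policy", "n_min",
            "family_threshold"),
    phylo = c("pair_convention"),
    synth = c("n_sites", "archetypes", "site_habitats", "n_otus", "t",
              "pool_size", "n_phyla", "noise_cv", "min_mean", "seed"),
    archetype = c("epsilon_true", "nu_true", "coupling_density",
                  "coupling_strength", "lambda_scale"))

.checkKeys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
        stopEem("eemBadConfig", "unknown config key%s in %s: %s",
                if (length(unknown) > 1L) "s" else "", where,
                paste(unknown, collapse = ", "))
}

#' Read and validate a pipeline run configuration
#'
#' YAML with a strict schema: unknown keys raise an error naming the key.
#' Either `input` (a list of sites with `abundance`, `taxonomy`, `site_id`,
#' `habitat`) or `synth` (fields of [synthConfig()], snake_case) must be
#' present. Defaults for the `te`, `fit` and `phylo` blocks are the reference
#' settings of [mandalaConfig()] (history 1, kernel width 0.5 normalized
#' units, n_min 8, KS-scanned abundance cutoff, fixed TE cutoff,
#' between-phylum pairs).
#'
#' @param path YAML file path, or an already-parsed list.
#' @return validated config list (class `runConfig`).
#' @export
readRunConfig <- function(path) {
    cfg <- if (is.character(path)) {
        if (!file.exists(path))
            stopEem("eemMissingFile", "config file not found: %s", path)
        yaml::read_yaml(path)
    } else as.list(path)
    .checkKeys(cfg, .schema$top, "top level")
    if (is.null(cfg$input) && is.null(cfg$synth))
        stopEem("eemBadConfig", "config needs an 'input' or 'synth' block")
    if (!is.null(cfg$input))
        for (k in seq_along(cfg$input)) {
            .checkKeys(cfg$input[[k]], .schema$input,
                       sprintf("input[%d]", k))
            need <- setdiff(.schema$input, names(cfg$input[[k]]))
            if (length(need))
                stopEem("eemBadConfig", "input[%d] is missing: %s", k,
                        paste(need, collapse = ", "))
        }
    if (!is.null(cfg$synth)) {
        .checkKeys(cfg$synth, .schema$synth, "synth")
        for (a in names(cfg$synth$archetypes))
            .checkKeys(cfg$synth$archetypes[[a]], .schema$archetype,
                       sprintf("synth archetype '%s'", a))
    }
    if (!is.null(cfg$te)) .checkKeys(cfg$te, .schema$te, "te")
    if (!is.null(cfg$fit)) .checkKeys(cfg$fit, .schema$fit, "fit")
    if (!is.null(cfg$phylo)) .checkKeys(cfg$phylo, .schema$phylo, "phylo")
    cfg$te <- utils::modifyList(list(history = 1L, kernel_width = 0.5),
                                as.list(cfg$te))
    cfg$fit <- utils::modifyList(list(abundance_xmin_policy = "ks_scan",
                                      te_xmin_policy = "fixed", n_min = 8L,
                                      family_threshold = 2),
                                 as.list(cfg$fit))
    cfg$phylo <- utils::modifyList(list(pair_convention = "between"),
                                   as.list(cfg$phylo))
    if (is.null(cfg$figures)) cfg$figures <- TRUE
    if (is.null(cfg$log_level)) cfg$log_level <- "info"
    class(cfg) <- "runConfig"
    cfg
}

.configToMandala <- function(cfg) {
    mandalaConfig(history = cfg$te$history, kernelWidth = cfg$te$kernel_width,
                  nMin = cfg$fit$n_min,
                  familyThreshold = cfg$fit$family_threshold,
                  abundanceXminPolicy = cfg$fit$abundance_xmin_policy,
                  teXminPolicy = cfg$fit$te_xmin_policy,
                  pairConvention = cfg$phylo$pair_convention)
}

.synthFromConfig <- function(cfg) {
    s <- cfg$synth
    seed <- if (!is.null(s$seed)) s$seed else cfg$seed
    args <- list(seed = seed)
    if (!is.null(s$n_sites)) args$nSites <- s$n_sites
    if (!is.null(s$archetypes))
        args$archetypes <- lapply(s$archetypes, function(a)
            habitatArchetype(a$epsilon_true, a$nu_true,
                             a$coupling_density %||% 0.05,
                             a$coupling_strength %||% 0.5,
                             a$lambda_scale %||% 5))
    if (!is.null(s$site_habitats)) args$siteHabitats <- unlist(s$site_habitats)
    if (!is.null(s$n_otus)) args$nOtus <- unlist(s$n_otus)
    if (!is.null(s$t)) args$t <- unlist(s$t)
    if (!is.null(s$pool_size)) args$poolSize <- s$pool_size
    if (!is.null(s$n_phyla)) args$nPhyla <- s$n_phyla
    if (!is.null(s$noise_cv)) args$noiseCv <- s$noise_cv
    if (!is.null(s$min_mean)) args$minMean <- s$min_mean
    do.call(synthConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.logMsg <- function(cfg, level, fmt, ...) {
    if (identical(cfg$log_level, "quiet")) return(invisible())
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the full Mandala pipeline
#'
#' Reads (or synthesizes) the study, computes pairwise transfer entropy, tail
#' fits, Taylor exponents and phylogenetic distances per site, assembles the
#' community-level and per-site phylum-level Mandalas, and writes all
#' artifacts to the output directory:
#' \itemize{
#'   \item `te_<site>.tsv` — TE edge lists;
#'   \item `fits.tsv` — tail-fit report (community and phylum scope);
#'   \item `distances.tsv` — D and per-phylum Dp per site;
#'   \item `mandala_community.tsv` (+ `.json` sidecar) and
#'     `mandala_phylum_<site>.tsv` — Mandala point tables;
#'   \item `mandala.svg`, `pairwise.svg` — figures (unless `figures: false`);
#'   \item `manifest.json` — config echo, seed, package version and per-site
#'     flags; together with the seed it reproduces the run bit-exactly.
#' }
#'
#' @param config a YAML path or list accepted by [readRunConfig()].
#' @param outDir output directory (created if needed); overrides the
#'   config's `output_dir`.
#' @return invisibly, a list with the `study`, the community `mandala`, the
#'   per-site phylum mandalas, the fit report and the manifest.
#' @export
runPipeline <- function(config, outDir = NULL) {
    cfg <- if (inherits(config, "runConfig")) config else readRunConfig(config)
    outDir <- outDir %||% cfg$output_dir %||%
        stopEem("eemBadConfig", "no output directory given")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    mcfg <- .configToMandala(cfg)

    siteWarnings <- list()
    if (!is.null(cfg$synth)) {
        scfg <- .synthFromConfig(cfg)
        gen <- generateStudy(scfg)
        study <- gen$study
        writeTaxonomy(gen$taxonomy, file.path(outDir, "taxonomy.tsv"))
        for (comm in communities(study))
            writeAbundanceTable(comm, file.path(outDir,
                sprintf("abundance_%s.tsv", siteId(comm))))
        jsonlite::write_json(
            lapply(gen$truth, function(tr)
                list(site = tr$site, habitat = tr$habitat,
                     params = tr$params, n_edges = nrow(tr$edges))),
            file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
    } else {
        comms <- lapply(cfg$input, function(s)
            readAbundanceTable(s$abundance, s$site_id, s$habitat))
        taxs <- lapply(cfg$input, function(s) readTaxonomy(s$taxonomy))
        study <- StudySet(comms, taxs)
    }

    fitRows <- list(); distPaths <- character(0)
    for (k in seq_along(communities(study))) {
        comm <- communities(study)[[k]]
        tax <- taxonomies(study)[[k]]
        sid <- siteId(comm)
        warns <- character(0)
        tem <- withCallingHandlers(
            tryCatch(pairwiseTE(comm, mcfg$history, mcfg$kernelWidth),
                     eemError = function(e) NULL),
            eemWarning = function(w) {
                warns <<- c(warns, conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        siteWarnings[[sid]] <- warns
        if (!is.null(tem))
            writeTEMatrix(tem, file.path(outDir, sprintf("te_%s.tsv", sid)),
                          "edges")
        for (quantity in c("abundance", "te")) {
            vals <- if (quantity == "abundance") as.vector(counts(comm))
                    else if (!is.null(tem)) teFitValues(tem) else numeric(0)
            policy <- if (quantity == "abundance")
                mcfg$abundanceXminPolicy else mcfg$teXminPolicy
            for (family in c("powerlaw", "exponential")) {
                fitFun <- if (family == "powerlaw") fitPowerlaw
                          else fitExponential
                fit <- tryCatch(fitFun(vals, policy, nMin = mcfg$nMin),
                                eemError = function(e) NULL)
                if (!is.null(fit))
                    fitRows[[length(fitRows) + 1L]] <- data.frame(
                        scope = "community", site = sid,
                        phylum = NA_character_, quantity = quantity,
                        family = family, exponent = fit@exponent,
                        xmin = fit@xmin, n_tail = fit@nTail, ks = fit@ks,
                        loglik = fit@loglik)
            }
        }
        if (length(otuIds(comm)) >= 2L) {
            dmat <- tipDistanceMatrix(buildTaxonomyTree(tax, otuIds(comm)))
            ds <- distanceSummary(dmat, tax, mcfg$pairConvention)
            p <- file.path(outDir, sprintf("distances_%s.tsv", sid))
            writeDistanceSummary(ds, sid, p)
            distPaths <- c(distPaths, p)
        }
        .logMsg(cfg, "info", "site %s done (%d OTUs, t = %d)", sid,
                nrow(counts(comm)), ncol(counts(comm)))
    }
    fits <- if (length(fitRows)) do.call(rbind, fitRows) else
        data.frame(scope = character(0), site = character(0),
                   phylum = character(0), quantity = character(0),
                   family = character(0), exponent = numeric(0),
                   xmin = numeric(0), n_tail = integer(0), ks = numeric(0),
                   loglik = numeric(0))
    writeFitReport(fits, file.path(outDir, "fits.tsv"))

    mandala <- suppressWarnings(communityMandala(study, mcfg))
    writeMandalaSet(mandala, file.path(outDir, "mandala_community.tsv"),
                    seed = cfg$seed)
    phylumSets <- list()
    for (k in seq_along(communities(study))) {
        comm <- communities(study)[[k]]
        ps <- tryCatch(suppressWarnings(
            phylumMandala(comm, taxonomies(study)[[k]], mcfg)),
            eemError = function(e) NULL)
        if (!is.null(ps)) {
            writeMandalaSet(ps, file.path(outDir,
                sprintf("mandala_phylum_%s.tsv", siteId(comm))))
            phylumSets[[siteId(comm)]] <- ps
        } else {
            siteWarnings[[siteId(comm)]] <- c(
                siteWarnings[[siteId(comm)]],
                "phylum-level Mandala not calculable")
        }
    }
    if (isTRUE(cfg$figures)) {
        tryCatch({
            renderMandala(mandala, file.path(outDir, "mandala.svg"))
            renderPairwise(mandala, file.path(outDir, "pairwise.svg"))
        }, eemError = function(e)
            .logMsg(cfg, "warn", "figures skipped: %s", conditionMessage(e)))
    }

    manifest <- list(
        package_version = as.character(utils::packageVersion("EcoMandala")),
        seed = cfg$seed,
        config = unclass(cfg),
        sites = lapply(stats::setNames(nm = names(siteWarnings)),
                       function(s) list(warnings = siteWarnings[[s]])),
        flags = stats::setNames(mandala@points$flags, mandala@points$site))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    .logMsg(cfg, "info", "pipeline complete: %s", outDir)
    invisible(list(study = study, mandala = mandala,
                   phylumMandalas = phylumSets, fits = fits,
                   manifest = manifest))
}
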