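## Fixtures and independent oracles shared across the suite.

makeCounts <- function(n, t, values = NULL, ids = paste0("OTU_", seq_len(n)),
                       times = paste0("t", seq_len(t))) {
    if (is.null(values)) values <- seq_len(n * t)
    matrix(values, n, t, dimnames = list(ids, times))
}

makeCommunity <- function(n = 3, t = 4, values = NULL, site = "S1",
                          hab = "riverine", ...) {
    CommunityTable(makeCounts(n, t, values, ...), site, hab)
}

## quick taxonomy builder: lineage columns default to per-OTU unique genera
## under shared upper ranks
makeTaxonomy <- function(otu, phylum, class = NULL, order = NULL,
                         family = NULL, genus = NULL,
                         kingdom = rep("Bacteria", length(otu))) {
    n <- length(otu)
    TaxonomyTable(data.frame(
        otu_id = otu, kingdom = kingdom,
        phylum = rep_len(phylum, n),
        class = if (is.null(class)) paste0(rep_len(phylum, n), "_c") else rep_len(class, n),
        order = if (is.null(order)) paste0(rep_len(phylum, n), "_o") else rep_len(order, n),
        family = if (is.null(family)) paste0(rep_len(phylum, n), "_f") else rep_len(family, n),
        genus = if (is.null(genus)) paste0("g_", otu) else rep_len(genus, n),
        stringsAsFactors = FALSE))
}

## Independent oracle 1: closed-form patristic distance on uniform-depth
## taxonomy trees. Tips sit 7 edges below the root (kingdom..genus + tip);
## two OTUs sharing exactly L leading ranks are 2 * (7 - L) apart. An
## unassigned cell matches another unassigned cell only while the full
## preceding lineage matches, which the prefix rule captures automatically.
taxonomyDistanceOracle <- function(taxonomy, ids) {
    df <- taxonomyData(taxonomy)
    df <- df[match(ids, df$otu_id), ]
    ranks <- as.matrix(df[, TAXONOMY_RANKS])
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        same <- ranks[i, ] == ranks[j, ]
        L <- if (all(same)) 6L else which.min(same) - 1L
        d[i, j] <- 2 * (7 - L)
    }
    d
}

## Independent oracle 2: brute-force path walk over the phylo edge list
## (breadth-first from each tip, summing branch lengths).
pathWalkOracle <- function(tree) {
    nTip <- length(tree$tip.label)
    nNode <- nTip + tree$Nnode
    adj <- vector("list", nNode)
    for (e in seq_len(nrow(tree$edge))) {
        a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
        w <- tree$edge.length[e]
        adj[[a]] <- rbind(adj[[a]], c(b, w))
        adj[[b]] <- rbind(adj[[b]], c(a, w))
    }
    d <- matrix(0, nTip, nTip,
                dimnames = list(tree$tip.label, tree$tip.label))
    for (start in seq_len(nTip)) {
        dist <- rep(NA_real_, nNode)
        dist[start] <- 0
        queue <- start
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            for (k in seq_len(NROW(adj[[v]]))) {
                u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
                if (is.na(dist[u])) {
                    dist[u] <- dist[v] + w
                    queue <- c(queue, u)
                }
            }
        }
        d[start, ] <- dist[seq_len(nTip)]
    }
    d
}

## Independent oracle 3: discrete plug-in transfer entropy from contingency
## counts of symbolized series (for two-level processes the box kernel with
## half-width < half the level separation must reproduce this exactly).
discreteTEOracle <- function(x, y) {
    t <- length(x)
    yt <- y[2:t]; ytm <- y[1:(t - 1)]; xtm <- x[1:(t - 1)]
    n <- t - 1
    key3 <- paste(yt, ytm, xtm)
    key2t <- paste(yt, ytm)
    key2p <- paste(ytm, xtm)
    key1 <- paste(ytm)
    c3 <- table(key3); c2t <- table(key2t); c2p <- table(key2p)
    c1 <- table(key1)
    sum(vapply(seq_len(n), function(i) {
        log2(c3[[key3[i]]] * c1[[key1[i]]] /
             (c2t[[key2t[i]]] * c2p[[key2p[i]]]))
    }, numeric(1))) / n
}

## Independent oracle 4: numeric likelihood maximizer for the tail families.
numericPowerlawMLE <- function(tail, xmin) {
    ll <- function(eps) length(tail) * log(eps - 1) -
        length(tail) * log(xmin) - eps * sum(log(tail / xmin))
    stats::optimize(ll, c(1 + 1e-9, 60), maximum = TRUE,
                    tol = 1e-10)$maximum
}

numericExponentialMLE <- function(tail, xmin) {
    ll <- function(lam) length(tail) * log(lam) - lam * sum(tail - xmin)
    stats::optimize(ll, c(1e-9, 1e4), maximum = TRUE, tol = 1e-10)$maximum
}

## inverse-CDF samplers used as generating oracles
rParetoOracle <- function(n, eps, xmin) xmin * runif(n)^(-1 / (eps - 1))
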