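## Interactome integration: resampling edge enrichment, connected
## components of induced subgraphs, node metrics (degree, stress
## centrality, neighborhood connectivity) and group contrasts.

#' Resampling edge enrichment of a node set
#'
#' Observed statistic: the number of retained edges with both endpoints in
#' the node set. The null redraws uniform node sets of equal size from the
#' whole graph, `nResample` times; the expected edge count is the null
#' mean and `p = (1 + #(null >= observed)) / (nResample + 1)`. A
#' degree-stratified null (`stratifyDegree = TRUE`) redraws within degree
#' tertiles, since hub-rich sets inflate counts.
#'
#' @param graph an [Interactome-class].
#' @param nodeSet character vector of node ids.
#' @param nResample number of resampled sets (default 999).
#' @param seed integer seed.
#' @param stratifyDegree draw null sets within degree tertiles.
#' @return list with `observed`, `expected` (null mean), `p`, `nodeSet`
#'   size actually used.
#' @export
edgeEnrichment <- function(graph, nodeSet, nResample = 999, seed = 1,
                           stratifyDegree = FALSE) {
    stopifnot(is(graph, "Interactome"))
    g <- graph@graph
    nodes <- igraph::V(g)$name
    nodeSet <- intersect(unique(nodeSet), nodes)
    if (length(nodeSet) < 2) {
        warning("node set smaller than 2: observed 0, p = 1")
        return(list(observed = 0L, expected = 0, p = 1,
                    nNodes = length(nodeSet)))
    }
    el <- igraph::as_edgelist(g, names = TRUE)
    inSet <- function(set) sum(el[, 1] %in% set & el[, 2] %in% set)
    obs <- inSet(nodeSet)
    set.seed(seed)
    k <- length(nodeSet); n <- length(nodes)
    if (stratifyDegree) {
        deg <- igraph::degree(g)
        strat <- cut(rank(deg, ties.method = "first"), 3, labels = FALSE)
        kPer <- tabulate(strat[match(nodeSet, nodes)], 3)
        draw <- function() unlist(lapply(1:3, function(s) {
            pool <- nodes[strat == s]
            pool[sample.int(length(pool), min(kPer[s], length(pool)))]
        }))
    } else {
        draw <- function() nodes[sample.int(n, k)]
    }
    nullCounts <- vapply(seq_len(nResample), function(b) inSet(draw()),
                         numeric(1))
    list(observed = obs, expected = mean(nullCounts),
         p = (1 + sum(nullCounts >= obs)) / (nResample + 1),
         nNodes = k)
}

#' Connected components of an induced subgraph
#'
#' @param graph an [Interactome-class].
#' @param nodeSet node ids; defaults to all nodes.
#' @return list with `components` (list of node-id vectors, size
#'   descending; only components with at least one edge) and `isolated`
#'   (nodes of the set without any edge inside the set).
#' @export
graphComponents <- function(graph, nodeSet = NULL) {
    stopifnot(is(graph, "Interactome"))
    g <- graph@graph
    if (is.null(nodeSet)) nodeSet <- igraph::V(g)$name
    nodeSet <- intersect(unique(nodeSet), igraph::V(g)$name)
    sub <- igraph::induced_subgraph(g, nodeSet)
    comp <- igraph::components(sub)
    groups <- split(igraph::V(sub)$name, comp$membership)
    sizes <- lengths(groups)
    isolated <- sort(unlist(groups[sizes == 1], use.names = FALSE))
    groups <- groups[sizes > 1]
    groups <- groups[order(-lengths(groups),
                           vapply(groups, function(x) sort(x)[1],
                                  character(1)))]
    list(components = unname(lapply(groups, sort)),
         isolated = if (is.null(isolated)) character(0) else isolated)
}

# shortest-path counts from every source (unweighted BFS, Brandes-style
# sigma accumulation); returns list(dist, sigma) matrices
.shortestPathCounts <- function(adj) {
    n <- length(adj)
    dist <- matrix(Inf, n, n)
    sigma <- matrix(0, n, n)
    for (s in seq_len(n)) {
        ds <- rep(Inf, n); sg <- numeric(n)
        ds[s] <- 0; sg[s] <- 1
        frontier <- s
        while (length(frontier)) {
            nxt <- integer(0)
            for (v in frontier) {
                for (w in adj[[v]]) {
                    if (is.infinite(ds[w])) {
                        ds[w] <- ds[v] + 1
                        nxt <- c(nxt, w)
                    }
                    if (ds[w] == ds[v] + 1) sg[w] <- sg[w] + sg[v]
                }
            }
            frontier <- unique(nxt)
        }
        dist[s, ] <- ds; sigma[s, ] <- sg
    }
    list(dist = dist, sigma = sigma)
}

#' Node metrics: degree, stress centrality, neighborhood connectivity
#'
#' Degree is the incident edge count. Stress centrality of `v` counts, over
#' unordered node pairs `(s, t)` with `s != v != t`, every distinct
#' shortest path passing through `v` (Shimbel stress; ordered-pair counting
#' would exactly double the values - set `pairs = "ordered"` for that
#' convention). Neighborhood connectivity is the mean degree of a node's
#' neighbors (`NA` for isolated nodes). Disconnected graphs are handled
#' per component.
#'
#' @param graph an [Interactome-class] or igraph object.
#' @param pairs `"unordered"` (default) or `"ordered"` stress counting.
#' @return data.frame: `node`, `label`, `degree`, `stress`,
#'   `neighborhoodConnectivity`.
#' @export
nodeMetrics <- function(graph, pairs = c("unordered", "ordered")) {
    pairs <- match.arg(pairs)
    g <- if (is(graph, "Interactome")) graph@graph else graph
    n <- igraph::vcount(g)
    nodes <- igraph::V(g)$name
    deg <- igraph::degree(g)
    adj <- igraph::as_adj_list(g)
    adj <- lapply(adj, as.integer)
    sp <- .shortestPathCounts(adj)
    stress <- numeric(n)
    for (v in seq_len(n)) {
        dv <- sp$dist[, v]
        through <- outer(dv, dv, "+") == sp$dist &
            is.finite(sp$dist)
        through[v, ] <- FALSE; through[, v] <- FALSE
        diag(through) <- FALSE
        cnt <- outer(sp$sigma[, v], sp$sigma[v, ]) * through
        stress[v] <- sum(cnt) / 2
    }
    if (pairs == "ordered") stress <- stress * 2
    nc <- vapply(seq_len(n), function(v) {
        nb <- adj[[v]]
        if (!length(nb)) NA_real_ else mean(deg[nb])
    }, numeric(1))
    lab <- igraph::V(g)$label
    data.frame(node = nodes,
               label = if (is.null(lab)) NA_character_ else lab,
               degree = as.integer(deg), stress = stress,
               neighborhoodConnectivity = nc,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Contrast node-metric distributions between two node groups
#'
#' Two-sided Wilcoxon rank-sum and two-sample Kolmogorov-Smirnov tests of
#' each metric between two groups of nodes, with the direction of the
#' median difference.
#'
#' @param metrics data.frame from [nodeMetrics()].
#' @param groups named character vector (node -> group) or a column name in
#'   `metrics` (default `"label"`).
#' @param levels the two group labels to contrast (default: the two most
#'   frequent).
#' @param tests subset of `c("wilcoxon", "ks")`.
#' @return data.frame: `metric`, `test`, `p`, `medianDiff` (first level
#'   minus second).
#' @export
compareGroups <- function(metrics, groups = "label", levels = NULL,
                          tests = c("wilcoxon", "ks")) {
    tests <- match.arg(tests, several.ok = TRUE)
    grp <- if (is.character(groups) && length(groups) == 1L)
        metrics[[groups]] else unname(groups[metrics$node])
    if (is.null(levels)) {
        tab <- sort(table(grp), decreasing = TRUE)
        if (length(tab) < 2) stop("need two groups")
        levels <- names(tab)[1:2]
    }
    g1 <- grp == levels[1]; g2 <- grp == levels[2]
    if (!sum(g1) || !sum(g2)) stop("both groups must be non-empty")
    if (sum(g1) < 3 || sum(g2) < 3)
        warning("group smaller than 3: exact small-sample tests")
    cols <- c("degree", "stress", "neighborhoodConnectivity")
    out <- list()
    for (m in cols) {
        x <- metrics[[m]][g1]; y <- metrics[[m]][g2]
        x <- x[is.finite(x)]; y <- y[is.finite(y)]
        md <- median(x) - median(y)
        if ("wilcoxon" %in% tests) {
            p <- suppressWarnings(wilcox.test(x, y)$p.value)
            if (is.na(p)) p <- 1   # fully tied distributions
            out[[length(out) + 1L]] <- data.frame(
                metric = m, test = "wilcoxon", p = p, medianDiff = md)
        }
        if ("ks" %in% tests) {
            p <- suppressWarnings(ks.test(x, y)$p.value)
            out[[length(out) + 1L]] <- data.frame(
                metric = m, test = "ks", p = p, medianDiff = md)
        }
    }
    do.call(rbind, out)
}
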