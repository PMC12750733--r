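.mkGraph <- function(edges, nodes = NULL) {
    interactome(data.frame(node_a = edges[, 1], node_b = edges[, 2],
                           score = 0.9, stringsAsFactors = FALSE),
                nodes = nodes)
}

test_that("interactome construction enforces the 0.400 score cutoff", {
    ed <- data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "d"),
                     score = c(0.85, 0.400, 0.399))
    g <- interactome(ed, nodes = letters[1:4])
    expect_equal(igraph::ecount(asIgraph(g)), 2)   # 0.399 dropped, 0.400 kept
    expect_true(all(igraph::E(asIgraph(g))$score >= 0.4))
})

test_that("edge enrichment hits its boundaries and detects the planted module", {
    sim <- simulateInteractome(80, 0.05, sprintf("n%03d", 1:8),
                               sprintf("n%03d", 9:16),
                               plantedEdgeProb = 0.9, seed = 5)
    allN <- igraph::V(asIgraph(sim$graph))$name
    ee <- edgeEnrichment(sim$graph, allN, nResample = 49, seed = 1)
    expect_equal(ee$observed, igraph::ecount(asIgraph(sim$graph)))
    expect_equal(ee$p, 1)

    mod <- edgeEnrichment(sim$graph, sprintf("n%03d", 1:16),
                          nResample = 499, seed = 2)
    expect_lt(mod$p, 0.01)

    expect_warning(tiny <- edgeEnrichment(sim$graph, "n001",
                                          nResample = 9, seed = 1),
                   "smaller than 2")
    expect_equal(tiny$p, 1)

    # observed count equals an independent induced-subgraph edge total
    sub <- igraph::induced_subgraph(asIgraph(sim$graph),
                                    sprintf("n%03d", 1:16))
    expect_equal(mod$observed, igraph::ecount(sub))
})

test_that("components match a flood-fill oracle and report isolated nodes", {
    g <- .mkGraph(cbind(c("a", "b", "x"), c("b", "c", "y")),
                  nodes = c("a", "b", "c", "d", "x", "y"))
    comp <- graphComponents(g)
    expect_equal(comp$components[[1]], c("a", "b", "c"))
    expect_equal(comp$components[[2]], c("x", "y"))
    expect_equal(comp$isolated, "d")

    edgeless <- graphComponents(g, c("a", "d"))
    expect_length(edgeless$components, 0)
    expect_setequal(edgeless$isolated, c("a", "d"))

    set.seed(31)
    for (r in 1:5) {
        nsim <- simulateInteractome(30, 0.08, character(0), character(0),
                                    seed = 300 + r)
        got <- graphComponents(nsim$graph)
        el <- igraph::as_edgelist(asIgraph(nsim$graph))
        oracle <- floodComponents(el, igraph::V(asIgraph(nsim$graph))$name)
        oracle <- lapply(oracle, sort)
        oracle <- oracle[lengths(oracle) > 1]
        oracle <- oracle[order(-lengths(oracle),
                               vapply(oracle, `[`, character(1), 1))]
        expect_equal(got$components, unname(oracle))
    }
})

test_that("degree, stress and neighborhood connectivity have their closed forms", {
    path <- .mkGraph(cbind(c("A", "B"), c("B", "C")))
    m <- nodeMetrics(path)
    expect_equal(m$stress[m$node == "B"], 1)
    expect_equal(m$stress[m$node %in% c("A", "C")], c(0, 0))
    expect_equal(m$degree[m$node == "B"], 2L)

    star <- .mkGraph(cbind("hub", paste0("leaf", 1:5)))
    ms <- nodeMetrics(star)
    expect_equal(ms$stress[ms$node == "hub"], choose(5, 2))
    expect_equal(ms$neighborhoodConnectivity[ms$node == "leaf1"], 5)
    expect_equal(ms$neighborhoodConnectivity[ms$node == "hub"], 1)

    # ordered-pair convention exactly doubles stress
    mo <- nodeMetrics(star, pairs = "ordered")
    expect_equal(mo$stress, ms$stress * 2)

    # complete graph: all stress zero
    cg <- .mkGraph(t(combn(letters[1:5], 2)))
    expect_true(all(nodeMetrics(cg)$stress == 0))
})

test_that("stress matches exhaustive geodesic enumeration on small graphs", {
    set.seed(77)
    for (r in 1:20) {
        nsim <- simulateInteractome(8, 0.35, character(0), character(0),
                                    seed = 700 + r)
        g <- asIgraph(nsim$graph)
        got <- nodeMetrics(nsim$graph)
        expect_equal(got$stress, bruteStress(g), tolerance = 1e-12)
        expect_equal(got$degree, unname(igraph::degree(g)))
    }
})

test_that("group contrasts detect shifts and tolerate ties", {
    set.seed(42)
    m <- data.frame(node = sprintf("v%02d", 1:40),
                    label = rep(c("CE", "DE_up_female"), each = 20),
                    degree = c(rpois(20, 12) + 10, rpois(20, 12)),
                    stress = c(rnorm(20, 30, 3), rnorm(20, 20, 3)),
                    neighborhoodConnectivity = rep(4, 40))
    out <- compareGroups(m, levels = c("CE", "DE_up_female"))
    wilD <- out$p[out$metric == "degree" & out$test == "wilcoxon"]
    expect_lt(wilD, 0.01)
    expect_gt(out$medianDiff[out$metric == "degree" &
                             out$test == "wilcoxon"], 0)
    # tied constant metric still yields a finite p
    ncP <- out$p[out$metric == "neighborhoodConnectivity"]
    expect_true(all(is.finite(ncP)))

    same <- m
    same$degree <- rep(1:20, 2)
    sameOut <- compareGroups(same, levels = c("CE", "DE_up_female"))
    expect_gt(sameOut$p[sameOut$metric == "degree" &
                        sameOut$test == "wilcoxon"], 0.9)
})
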