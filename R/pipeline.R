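## End-to-end orchestration on synthetic inputs: expression ->
## (orthogroup filter -> convergence -> codon selection -> rate
## covariation) -> lncRNA hits -> network, with one config and one master
## seed fanning out deterministically to the stages.

#' Default pipeline configuration
#'
#' Every analysis threshold keeps its standard value (sex-bias 0.70,
#' CPM 2, deposition probability 0.95, orthogroup minima 15 species / 4 DUI
#' species, hit filters 100 bp / 0.5 coverage / 90 percent identity, 100 bp
#' flank, interaction score 0.400, 50 random taggings of 10 species).
#' Synthetic problem sizes are desk-scale: they keep the full run in
#' minutes while leaving every planted signal detectable; see the package
#' vignette for the rationale behind each generator default.
#'
#' @param masterSeed integer master seed; all stage seeds derive from it.
#' @return nested configuration list.
#' @export
defaultConfig <- function(masterSeed = 1) {
    list(
        masterSeed = masterSeed,
        expression = list(nFeatures = 15826, nSamples = 8,
                          deFrac = 0.016, lfcMean = 2, dispersion = 0.1,
                          biasThreshold = 0.70, minCpm = 2, q = 0.95,
                          nNull = 1e5),
        evolution = list(nGenes = 120, cladeSizes = c(2, 2, 2, 2, 1, 1),
                         nSpecies = 36, constrainedFrac = 0.2,
                         acceleratedFrac = 0.05, rateMultiplier = 0.3,
                         lognormalNoiseSd = 0.2, missingFrac = 0.1,
                         minSpecies = 15, minForeground = 4,
                         nPerm = 199, alpha = 0.05,
                         nRandom = 50, randomTagSize = 10,
                         pairWeighting = "mrca_depth"),
        selection = list(maxGenes = 10, nCodons = 200, maxTaxa = 12,
                         omegaBg = 0.5, omegaFgConstrained = 0.1,
                         kappa = 2, alphaLrt = 0.05),
        erc = list(ercFrac = 0.3, ercConstrainedWeight = 8,
                   deviationSd = 0.6, minShared = 10, alpha = 0.05,
                   nDeMapped = 30),
        lncrna = list(nGenes = 200, nFocal = 20, nLncrnas = 10,
                      hitsPerLncrna = 20, focalGeneBias = 10,
                      minLen = 100, minCov = 0.5, minIdent = 90,
                      flank = 100, nResample = 999),
        network = list(nNodes = 300, nDe = 40, nCe = 40,
                       backgroundEdgeProb = 0.01, plantedEdgeProb = 0.12,
                       minScore = 0.400, nResample = 999))
}

# deterministic seed schedule: masterSeed fans out to one seed per stage
.stageSeeds <- function(masterSeed) {
    set.seed(masterSeed)
    setNames(sample.int(2^30, 10),
             c("counts", "bias", "tree", "genes", "codon", "mito",
               "convergence", "hits", "network", "misc"))
}

#' Run the full synthetic pipeline
#'
#' Generates every input with planted ground truth, runs all analysis
#' stages in the fixed order, and returns a report bundle: per-stage
#' tables, the 2x2 overlap tests (rate-covariation among convergently
#' evolving genes; DE among convergence-tested genes), network enrichment
#' and metric contrasts, and a flat numeric summary. Deterministic given
#' the master seed. With `outputDir` set, per-stage TSVs, the YAML config
#' echo, and a JSON summary are written.
#'
#' @param config configuration list from [defaultConfig()] (possibly
#'   modified), or a path to a YAML file with the same structure.
#' @param outputDir optional output directory.
#' @param verbose print stage progress (default `TRUE`).
#' @return report list (invisibly when `outputDir` is set).
#' @export
runPipeline <- function(config = defaultConfig(), outputDir = NULL,
                        verbose = TRUE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    def <- defaultConfig(config$masterSeed %||na% 1)
    config <- utils::modifyList(def, config)
    seeds <- .stageSeeds(config$masterSeed)
    say <- function(...) if (verbose) message(...)
    report <- list(config = config, seeds = as.list(seeds))

    ## ---- expression stage -------------------------------------------
    say("expression: simulating counts and testing deposition")
    ce <- config$expression
    sim <- simulateCounts(nFeatures = ce$nFeatures, nSamples = ce$nSamples,
                          deFrac = ce$deFrac, lfcMean = ce$lfcMean,
                          dispersion = ce$dispersion,
                          seed = seeds[["counts"]])
    set.seed(seeds[["bias"]])
    opRatios <- lapply(sexRatio(sim$counts), function(s)
        pmin(pmax(s + rnorm(3, 0, 0.03), 0), 1))
    labels <- vapply(opRatios, classifySexBias, character(1),
                     threshold = ce$biasThreshold)
    expr <- expressionStage(sim$counts, minCpm = ce$minCpm, q = ce$q,
                            nNull = ce$nNull, seed = seeds[["counts"]])
    res <- expr$results
    deCalled <- res$feature_id[res$called]
    deAndCor <- res$feature_id[res$called & !is.na(res$p_rho) &
                               res$p_rho < 0.05]
    truthDe <- sim$truth$feature_id[sim$truth$is_de]
    report$expression <- list(
        sampleSheet = data.frame(
            sample = colnames(counts(sim$counts)),
            sexRatio = sexRatio(sim$counts),
            bias = biasLabel(sim$counts), operatorLabel = labels),
        results = res, truth = sim$truth,
        nRetained = length(expr$retained),
        deCalled = deCalled, deAndCorrelated = deAndCor,
        recall = if (length(truthDe))
            mean(intersect(truthDe, res$feature_id) %in% deCalled)
        else NA_real_)

    ## ---- evolution: trees, orthogroup filter, convergence -----------
    say("evolution: species tree, gene trees, orthogroup filter")
    cv <- config$evolution
    spTree <- makeSpeciesTree(cv$nSpecies, cv$cladeSizes,
                              seed = seeds[["tree"]])
    dev <- simulateRateDeviations(spTree, sd = config$erc$deviationSd,
                                  seed = seeds[["mito"]])
    gsim <- simulateGeneTrees(spTree, cv$nGenes, cv$constrainedFrac,
                              rateMultiplier = cv$rateMultiplier,
                              lognormalNoiseSd = cv$lognormalNoiseSd,
                              missingFrac = cv$missingFrac,
                              seed = seeds[["genes"]],
                              acceleratedFrac = cv$acceleratedFrac,
                              ercFrac = config$erc$ercFrac,
                              ercDeviations = dev,
                              ercConstrainedWeight =
                                  config$erc$ercConstrainedWeight,
                              minSpecies = cv$minSpecies,
                              minForeground = cv$minForeground)
    ogf <- ogFilterStage(gsim$trees, foregroundTips(spTree),
                         minSpecies = cv$minSpecies,
                         minForeground = cv$minForeground)
    trees <- ogf$trees
    say("convergence: scanning ", length(trees), " retained genes")
    conv <- convergenceScan(trees, spTree, nPerm = cv$nPerm,
                            pairWeighting = cv$pairWeighting,
                            seed = seeds[["convergence"]])
    constrained <- conv$gene_id[conv$direction == "constrained" &
                                conv$p < cv$alpha]
    accelerated <- conv$gene_id[conv$direction == "accelerated" &
                                conv$p < cv$alpha]
    say("convergence: control harness (", cv$nRandom, " random taggings)")
    ctrl <- controlScan(trees, spTree, nRandom = cv$nRandom,
                        randomTagSize = cv$randomTagSize,
                        alpha = cv$alpha, nPerm = cv$nPerm,
                        pairWeighting = cv$pairWeighting,
                        seed = seeds[["convergence"]])
    report$evolution <- list(
        speciesTree = spTree, ogReport = ogf$report, convergence = conv,
        constrained = constrained, accelerated = accelerated,
        truth = gsim$truth, controls = ctrl)

    ## ---- codon selection on constrained candidates -------------------
    cs <- config$selection
    selGenes <- head(constrained, cs$maxGenes)
    say("selection: branch-model LRT on ", length(selGenes), " genes")
    truthCls <- setNames(gsim$truth$convergence_class, gsim$truth$gene_id)
    selRows <- list()
    for (g in selGenes) {
        gt <- trees[[g]]
        tips <- tipLabels(gt)
        fg <- intersect(foregroundTips(gt), tips)
        if (length(tips) > cs$maxTaxa) {
            keep <- c(fg, head(setdiff(tips, fg),
                               max(cs$maxTaxa - length(fg), 2)))
            gt <- pruneTo(gt, keep)
        }
        wFg <- if (truthCls[[g]] == "constrained") cs$omegaFgConstrained
               else cs$omegaBg
        aln <- simulateCodonAlignment(gt, cs$nCodons,
                                      omegaBg = cs$omegaBg, omegaFg = wFg,
                                      kappa = cs$kappa,
                                      seed = seeds[["codon"]] +
                                          match(g, selGenes))
        fit <- branchModelLrt(aln, gt, seed = seeds[["codon"]])
        selRows[[g]] <- cbind(gene_id = g, fit)
    }
    sel <- if (length(selRows))
        do.call(rbind, c(selRows, list(make.row.names = FALSE)))
    else NULL
    ceGenes <- if (!is.null(sel))
        sel$gene_id[sel$converged & sel$p < cs$alphaLrt &
                    sel$deltaOmega < 0] else character(0)
    report$selection <- list(results = sel, ceGenes = ceGenes)

    ## ---- mito-nuclear rate covariation -------------------------------
    say("rate covariation: mito tree regression and 2x2 enrichment")
    cerc <- config$erc
    mito <- simulateMitoTree(spTree, dev, seed = seeds[["mito"]])
    erc <- ercScan(trees, mito, spTree, minShared = cerc$minShared)
    ercSig <- erc$gene_id[!is.na(erc$p) & erc$p < cerc$alpha]
    universe <- names(trees)
    # convergently constrained set stands in for the CE focal set in the
    # 2x2 (the LRT stage only scores a capped subset)
    ceFocal <- intersect(constrained, universe)
    ercEnrich <- if (length(ceFocal))
        enrichment2x2(ceFocal, intersect(ercSig, universe), universe,
                      method = "chi_square") else NULL
    set.seed(seeds[["misc"]])
    deMapped <- sample(universe, min(cerc$nDeMapped, length(universe)))
    deCeOverlap <- enrichment2x2(intersect(deMapped, universe),
                                 ceFocal, universe,
                                 method = "fisher_exact")
    report$erc <- list(results = erc, significant = ercSig,
                       enrichmentAmongCE = ercEnrich,
                       deMapped = deMapped, deCeOverlap = deCeOverlap,
                       mitoTree = mito)

    ## ---- lncRNA hits --------------------------------------------------
    say("lncRNA hits: containment and focal-gene enrichment")
    cl <- config$lncrna
    gi <- simulateGeneIntervals(cl$nGenes, focalGenes = cl$nFocal,
                                seed = seeds[["hits"]])
    hsim <- simulateHitTable(gi, cl$nLncrnas, cl$hitsPerLncrna,
                             focalGeneBias = cl$focalGeneBias,
                             seed = seeds[["hits"]])
    kept <- filterHits(hsim$hits, minLen = cl$minLen, minCov = cl$minCov,
                       minIdent = cl$minIdent)
    assigned <- annotateContainment(kept, gi, flank = cl$flank)
    hitEnr <- hitEnrichment(assigned, gi$gene_id[gi$focal], gi$gene_id,
                            nResample = cl$nResample,
                            seed = seeds[["hits"]])
    report$lncrna <- list(intervals = gi, hits = hsim$hits,
                          kept = kept, assigned = assigned,
                          truth = hsim$truth, enrichment = hitEnr)

    ## ---- network integration ------------------------------------------
    say("network: planted-module enrichment and node metrics")
    cn <- config$network
    nodes <- sprintf("n%03d", seq_len(cn$nNodes))
    set.seed(seeds[["network"]])
    setA <- sample(nodes, cn$nDe)
    setB <- sample(setdiff(nodes, setA), cn$nCe)
    nsim <- simulateInteractome(cn$nNodes, cn$backgroundEdgeProb,
                                setA, setB,
                                plantedEdgeProb = cn$plantedEdgeProb,
                                seed = seeds[["network"]],
                                minScore = cn$minScore)
    moduleSet <- union(setA, setB)
    edgeEnr <- edgeEnrichment(nsim$graph, moduleSet,
                              nResample = cn$nResample,
                              seed = seeds[["network"]])
    comps <- graphComponents(nsim$graph, moduleSet)
    largest <- if (length(comps$components)) comps$components[[1]]
               else character(0)
    metrics <- nodeMetrics(igraph::induced_subgraph(asIgraph(nsim$graph),
                                                    largest))
    contrasts <- if (length(unique(metrics$label[
        metrics$label %in% c("CE", "DE_up_female")])) == 2)
        compareGroups(metrics, levels = c("CE", "DE_up_female"))
    else NULL
    report$network <- list(graph = nsim$graph, truth = nsim$truth,
                           edgeEnrichment = edgeEnr,
                           components = comps, metrics = metrics,
                           contrasts = contrasts)

    ## ---- summary -------------------------------------------------------
    tr <- gsim$truth
    conTruth <- tr$gene_id[tr$convergence_class == "constrained"]
    nullTruth <- tr$gene_id[tr$convergence_class == "null"]
    scored <- conv$gene_id
    report$summary <- list(
        n_features_retained = length(expr$retained),
        n_de_called = length(deCalled),
        n_de_and_correlated = length(deAndCor),
        de_recall = mean(intersect(truthDe, res$feature_id) %in% deCalled),
        de_null_call_rate = mean(
            res$called[res$feature_id %in%
                       sim$truth$feature_id[!sim$truth$is_de]]),
        n_og_retained = length(trees),
        n_constrained = length(constrained),
        n_accelerated = length(accelerated),
        constrained_recall = mean(intersect(conTruth, scored) %in%
                                  constrained),
        constrained_false_sign = mean(
            conv$direction[conv$gene_id %in% conTruth] == "accelerated"),
        null_lowp_rate = mean(conv$p[conv$gene_id %in% nullTruth] <
                              cv$alpha),
        true_tagging_rank = ctrl$trueRank,
        n_ce = length(ceGenes),
        median_delta_omega = if (!is.null(sel))
            median(sel$deltaOmega[sel$converged]) else NA_real_,
        erc_among_ce_p = if (!is.null(ercEnrich)) ercEnrich$p
                         else NA_real_,
        de_ce_overlap_p = deCeOverlap$p,
        hit_enrichment_p = hitEnr$p,
        edge_observed = edgeEnr$observed,
        edge_expected = edgeEnr$expected,
        edge_enrichment_p = edgeEnr$p,
        largest_component = length(largest),
        n_components = length(comps$components))
    if (!is.null(outputDir)) {
        .writeReport(report, outputDir)
        return(invisible(report))
    }
    report
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

# deterministic on-disk report: per-stage TSVs + config echo + JSON summary
.writeReport <- function(report, outputDir) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(...) file.path(outputDir, ...)
    yaml::write_yaml(report$config, fp("config.yaml"))
    writeTsv(report$expression$sampleSheet, fp("sample_sheet.tsv"))
    writeTsv(report$expression$results, fp("expression_results.tsv"))
    writeTsv(report$evolution$ogReport, fp("og_filter.tsv"))
    writeTsv(report$evolution$convergence, fp("convergence.tsv"))
    writeTsv(report$evolution$controls$summary, fp("control_summary.tsv"))
    pv <- report$evolution$controls$pValues
    writeTsv(cbind(gene_id = rownames(pv), as.data.frame(pv)),
             fp("control_pvalues.tsv"))
    if (!is.null(report$selection$results))
        writeTsv(report$selection$results, fp("selection.tsv"))
    if (!is.null(report$erc$results))
        writeTsv(report$erc$results, fp("erc.tsv"))
    writeTsv(report$lncrna$assigned, fp("lncrna_assigned_hits.tsv"))
    writeTsv(report$network$metrics, fp("network_metrics.tsv"))
    if (!is.null(report$network$contrasts))
        writeTsv(report$network$contrasts, fp("network_contrasts.tsv"))
    cat(writeNewick(report$evolution$speciesTree),
        file = fp("species_tree.nwk"), sep = "\n")
    jsonlite::write_json(report$summary, fp("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(outputDir)
}
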