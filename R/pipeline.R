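# End-to-end orchestration on a simulated (or equivalently structured)
# study, plus the machine-readable run report.

#' Run the full LoF association pipeline on a simulated study
#'
#' Executes every stage in order: harmonize annotator calls and classify
#' consensus; hard-call genotypes and run the variant QC cascade; prune
#' related subjects; collapse retained variants to gene carrier sets; clean
#' the trait streams and aggregate medians; run the Box-Cox/IRLS gene-trait
#' scan; run the expression-trait scan on the genotype-significant genes;
#' assess concordance, tally it, and apply the GO keyword filter.
#'
#' @param sim a [LofStudySim-class].
#' @param alphaGenotype genotype-scan significance threshold (default 0.1).
#' @param alphaExpression expression-scan threshold (default 0.05).
#' @param minCarriers minimum carriers with trait data (default 3).
#' @param probThreshold genotype-probability hard-call threshold.
#' @param piHatThreshold relatedness pruning threshold.
#' @param pruneSeed seed for the random pair-member removal (defaults to
#'   the simulation seed + 1000).
#' @param jacobian include the Box-Cox Jacobian in lambda selection.
#' @return list with every stage output: harmonized, consensus, hardCalled,
#'   qc, pruning, carrierSet, traitProfiles, genotypeScan, expressionScan,
#'   concordance, tally, goFilter, report.
#' @examples
#' \donttest{
#' sim <- simulateStudy(simConfig(nSubjects = 150, nGenes = 30,
#'                                nExpressionSamples = 80, seed = 3))
#' res <- runLofPipeline(sim)
#' res$tally
#' }
#' @export
runLofPipeline <- function(sim, alphaGenotype = 0.1, alphaExpression = 0.05,
                           minCarriers = 3L, probThreshold = 0.95,
                           piHatThreshold = 0.2, pruneSeed = NULL,
                           jacobian = TRUE) {
  if (!is(sim, "LofStudySim"))
    stop("sim must be a LofStudySim", call. = FALSE)
  cfg <- sim@config
  if (is.null(pruneSeed)) pruneSeed <- cfg@seed + 1000L

  harmonized <- harmonizeCalls(sim@calls)
  consensus <- consensusClassify(harmonized)
  hardCalled <- hardCallGenotypes(sim@genotypes$carrier,
                                  sim@genotypes$probability,
                                  threshold = probThreshold)
  qc <- applyVariantQC(sim@variants, consensus, hardCalled,
                       sim@transcripts)
  pruning <- pruneRelatives(sim@cohort$subject_id, sim@relatedness,
                            threshold = piHatThreshold, seed = pruneSeed)
  carrierSet <- collapseToGenes(qc$retained, hardCalled$carrier,
                                pruning$retained)
  traitProfiles <- traitQC(sim@measurements, sim@medications,
                           cfg@traits, cfg@medicationEffects)
  covariates <- sim@cohort[sim@cohort$subject_id %in% pruning$retained, ]
  genotypeScan <- runGeneTraitScan(carrierSet, traitProfiles, covariates,
                                   alpha = alphaGenotype,
                                   minCarriers = minCarriers,
                                   jacobian = jacobian)
  candidates <- unique(genotypeScan$associations$gene[
    genotypeScan$associations$significant])
  expressionScan <- runTissueScan(sim@expression, candidates,
                                  traits = cfg@traits$trait,
                                  alpha = alphaExpression)
  concordance <- assessConcordance(genotypeScan$associations,
                                   expressionScan,
                                   alphaGenotype = alphaGenotype,
                                   alphaExpression = alphaExpression)
  tally <- tallyConcordance(concordance)
  concPairs <- concordance[concordance$verdict == "concordant", ,
                           drop = FALSE]
  goRes <- goFilter(concPairs, sim@goAnnotations)

  out <- list(harmonized = harmonized, consensus = consensus,
              hardCalled = hardCalled, qc = qc, pruning = pruning,
              carrierSet = carrierSet, traitProfiles = traitProfiles,
              genotypeScan = genotypeScan, expressionScan = expressionScan,
              concordance = concordance, tally = tally, goFilter = goRes)
  out$report <- buildReport(out)
  out
}

#' Assemble the run report
#'
#' A single JSON-serializable summary of every stage: variant counts per
#' filter, trait-QC exclusion counts, tested/significant association
#' counts, concordance tallies and the GO-filter pass list. Reruns of the
#' same simulation and configuration produce an identical report.
#'
#' @param stages the stage list produced inside [runLofPipeline()];
#'   required elements: qc, pruning, carrierSet, traitProfiles,
#'   genotypeScan, expressionScan, concordance, tally, goFilter.
#' @return nested list; serialize with [jsonlite::write_json()].
#' @export
buildReport <- function(stages) {
  need <- c("qc", "pruning", "carrierSet", "traitProfiles", "genotypeScan",
            "expressionScan", "concordance", "tally", "goFilter")
  miss <- setdiff(need, names(stages))
  if (length(miss))
    stop("missing stage output: ", paste(miss, collapse = ", "),
         call. = FALSE)
  exc <- exclusions(stages$traitProfiles)
  excCounts <- if (nrow(exc)) as.list(table(exc$reason)) else list()
  gs <- stages$genotypeScan
  es <- stages$expressionScan
  list(
    variant_qc = as.list(stages$qc$counts),
    pruning = list(n_removed = length(stages$pruning$removed),
                   n_retained = length(stages$pruning$retained)),
    gene_collapse = list(
      n_genes = length(stages$carrierSet),
      mean_variants_per_gene =
        attr(stages$carrierSet, "summary")$meanVariantsPerGene),
    trait_qc = list(exclusions_by_reason = excCounts,
                    n_profiles = nrow(profiles(stages$traitProfiles))),
    genotype_scan = list(n_tested = gs$nTested,
                         n_significant = gs$nSignificant,
                         lambda = as.list(stats::setNames(
                           gs$lambdaSelection$lambda,
                           gs$lambdaSelection$trait))),
    expression_scan = list(n_fits = nrow(es),
                           n_significant = sum(es$significant)),
    concordance = as.list(stages$tally),
    go_filter = stages$goFilter$coverage)
}
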