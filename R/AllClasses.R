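#' @import methods
NULL

#' Simulation configuration
#'
#' An S4 container describing the full study regime emulated by the synthetic
#' data generator: cohort size, gene and variant structure, trait generative
#' distributions, planted gene-trait effects, medication perturbations,
#' measurement corruption rates, relatedness structure and expression tissues.
#' The seed fully determines every generated table.
#'
#' @slot nSubjects integer, cohort size (>= 10).
#' @slot nGenes integer, number of genes carrying candidate LoF variants.
#' @slot meanVariantsPerGene mean of the zero-truncated Poisson used for the
#'   per-gene variant count.
#' @slot carrierFreqRange numeric length-2, allele-frequency interval for
#'   non-planted variants; must lie inside (0, 0.02).
#' @slot plantedCarrierFreq allele frequency assigned to variants of genes
#'   carrying a planted effect.
#' @slot traits data.frame of trait generative parameters (one row per trait
#'   code: family, location, betweenSd, withinSd, ageCoef, sexCoef, unit,
#'   hardMin, hardMax).
#' @slot plantedEffects data.frame with columns gene, trait, beta (trait
#'   units), expressionDirection in {"concordant","discordant","absent"}.
#' @slot medicationEffects data.frame with columns medClass, trait, shift.
#' @slot medicationUseRate fraction of subjects prescribed each med class.
#' @slot outlierRate fraction of measurements replaced by gross outliers.
#' @slot mislabelRate fraction of measurements recorded in a wrong unit.
#' @slot measurementsPerSubject integer length-2 range of dated measurements
#'   per subject per trait.
#' @slot nRelatedPairs number of subject pairs planted above the PI-HAT
#'   relatedness threshold.
#' @slot nBackgroundPairs number of unrelated pairs reported below threshold.
#' @slot tissues character, subset of the seven expression tissues.
#' @slot nExpressionSamples samples per tissue in the expression cohort.
#' @slot expressionSlope absolute expression-trait slope for planted
#'   concordant/discordant effects.
#' @slot expressionNoiseSd residual SD of the expression-cohort trait model.
#' @slot qcPlants named integer vector: number of variants planted to fail
#'   each QC filter (info, completeness, consensus_transcript, final_exon,
#'   af, no_carrier) plus "no_consensus" (single-annotator variants).
#' @slot seed integer random seed.
#' @export
setClass("SimConfig", representation(
  nSubjects = "integer",
  nGenes = "integer",
  meanVariantsPerGene = "numeric",
  carrierFreqRange = "numeric",
  plantedCarrierFreq = "numeric",
  traits = "data.frame",
  plantedEffects = "data.frame",
  medicationEffects = "data.frame",
  medicationUseRate = "numeric",
  outlierRate = "numeric",
  mislabelRate = "numeric",
  measurementsPerSubject = "integer",
  nRelatedPairs = "integer",
  nBackgroundPairs = "integer",
  tissues = "character",
  nExpressionSamples = "integer",
  expressionSlope = "numeric",
  expressionNoiseSd = "numeric",
  qcPlants = "integer",
  seed = "integer"
))

validSimConfig <- function(object) {
  msgs <- character()
  bad <- function(m) msgs <<- c(msgs, m)
  if (length(object@nSubjects) != 1L || is.na(object@nSubjects) ||
      object@nSubjects < 10L)
    bad("nSubjects must be a single integer >= 10")
  if (length(object@nGenes) != 1L || is.na(object@nGenes) || object@nGenes < 1L)
    bad("nGenes must be a single positive integer")
  cf <- object@carrierFreqRange
  if (length(cf) != 2L || any(is.na(cf)) || cf[1] <= 0 || cf[2] >= 0.02 ||
      cf[1] > cf[2])
    bad("carrierFreqRange must be an increasing interval inside (0, 0.02)")
  if (object@plantedCarrierFreq <= 0 || object@plantedCarrierFreq >= 0.02)
    bad("plantedCarrierFreq must lie in (0, 0.02)")
  for (fld in c("medicationUseRate", "outlierRate", "mislabelRate")) {
    v <- slot(object, fld)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      bad(sprintf("%s must be a single value in [0, 1]", fld))
  }
  need <- c("trait", "family", "location", "betweenSd", "withinSd",
            "ageCoef", "sexCoef", "unit", "hardMin", "hardMax")
  if (!all(need %in% names(object@traits)))
    bad(sprintf("traits must have columns: %s", paste(need, collapse = ", ")))
  pe <- object@plantedEffects
  if (nrow(pe)) {
    if (!all(c("gene", "trait", "beta", "expressionDirection") %in% names(pe)))
      bad("plantedEffects must have columns gene, trait, beta, expressionDirection")
    else {
      if (!all(pe$trait %in% object@traits$trait))
        bad("plantedEffects refers to unconfigured trait codes")
      if (!all(pe$expressionDirection %in%
               c("concordant", "discordant", "absent")))
        bad("expressionDirection must be concordant, discordant or absent")
      geneIdx <- suppressWarnings(as.integer(sub("^G", "", pe$gene)))
      if (anyNA(geneIdx) || any(geneIdx < 1L | geneIdx > object@nGenes))
        bad("every plantedEffects gene must exist (G1..GnGenes)")
    }
  }
  if (object@nRelatedPairs * 2L > object@nSubjects)
    bad("nRelatedPairs must not exceed nSubjects/2")
  okTis <- c("AOR", "BLOOD", "LIV", "MAM", "SF", "SKLM", "VAF")
  if (length(object@tissues) < 1L || !all(object@tissues %in% okTis))
    bad("tissues must be a nonempty subset of the seven study tissues")
  if (length(object@measurementsPerSubject) != 2L ||
      any(object@measurementsPerSubject < 1L) ||
      diff(object@measurementsPerSubject) < 0L)
    bad("measurementsPerSubject must be an increasing integer range >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    bad("seed must be a single integer")
  if (length(msgs)) msgs else TRUE
}
setValidity("SimConfig", validSimConfig)

#' Simulated study container
#'
#' Holds every table produced by [simulateStudy()]: the genotyped cohort,
#' variant sites with imputation metrics, the three annotator call tables,
#' transcript/exon models, per-subject genotype-probability calls,
#' longitudinal trait measurements with medication intervals, pairwise
#' relatedness, per-tissue expression sets, GO annotations, and the truth
#' table tracing every planted effect and perturbation.
#'
#' @slot config the generating [SimConfig-class].
#' @slot cohort data.frame: subject_id, sex, age, PC1..PC5.
#' @slot variants data.frame of variant sites (variant_key, gene_id, chrom,
#'   pos, ref, alt, info_score, alt_allele_freq).
#' @slot calls named list of three annotator call data.frames (A1, A2, A3).
#' @slot transcripts data.frame transcript model (transcript_id, gene_id,
#'   exon_rank, start, end, strand).
#' @slot genotypes list with matrices `carrier` and `probability`
#'   (subjects x variants).
#' @slot measurements data.frame: subject_id, trait, value, unit, date.
#' @slot medications data.frame: subject_id, med_class, start, end.
#' @slot relatedness data.frame: id_a, id_b, pi_hat.
#' @slot expression named list per tissue: list(expr = genes x samples matrix,
#'   samples = covariate/trait data.frame).
#' @slot goAnnotations data.frame: gene_id, go_id, term_name, aspect.
#' @slot truth named list: plantedEffects, qcPlants, measurementFlags,
#'   relatedPairs, expectedConcordance.
#' @export
setClass("LofStudySim", representation(
  config = "SimConfig",
  cohort = "data.frame",
  variants = "data.frame",
  calls = "list",
  transcripts = "data.frame",
  genotypes = "list",
  measurements = "data.frame",
  medications = "data.frame",
  relatedness = "data.frame",
  expression = "list",
  goAnnotations = "data.frame",
  truth = "list"
))

#' Gene-level carrier sets
#'
#' The result of collapsing retained LoF variants to the gene level: for each
#' gene, the retained variant keys and the set of subjects carrying at least
#' one of them. Genes without carriers are dropped at construction.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot variantsByGene named list (by gene) of retained variant keys.
#' @slot carriersByGene named list (by gene) of carrier subject ids.
#' @export
setClass("GeneCarrierSet", representation(
  geneIds = "character",
  variantsByGene = "list",
  carriersByGene = "list"
))

setValidity("GeneCarrierSet", function(object) {
  msgs <- character()
  if (!identical(names(object@variantsByGene), object@geneIds) ||
      !identical(names(object@carriersByGene), object@geneIds))
    msgs <- c(msgs, "variantsByGene and carriersByGene must be named by geneIds")
  if (any(lengths(object@carriersByGene) == 0L))
    msgs <- c(msgs, "zero-carrier genes must be dropped")
  if (length(msgs)) msgs else TRUE
})

#' QC'd per-subject trait medians
#'
#' Output of [traitQC()]: one median value per subject per trait computed from
#' measurements surviving the mislabel, medication and outlier filters, plus
#' the full exclusion accounting (each excluded measurement carries exactly
#' one first-cause reason).
#'
#' @slot profiles data.frame: subject_id, trait, median_value, n_used.
#' @slot exclusions data.frame of excluded measurements with a `reason`
#'   column in {"mislabel","medication","outlier"}.
#' @slot summary data.frame of per-trait measurement and subject counts
#'   before and after each filter.
#' @export
setClass("TraitProfileSet", representation(
  profiles = "data.frame",
  exclusions = "data.frame",
  summary = "data.frame"
))

setValidity("TraitProfileSet", function(object) {
  msgs <- character()
  if (nrow(object@profiles) && any(object@profiles$n_used < 1L))
    msgs <- c(msgs, "every profile must use at least one measurement")
  if (nrow(object@exclusions) &&
      !all(object@exclusions$reason %in% c("mislabel", "medication", "outlier")))
    msgs <- c(msgs, "unknown exclusion reason")
  if (length(msgs)) msgs else TRUE
})
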