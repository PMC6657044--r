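#' Default generative parameters for the ten cardiovascular traits
#'
#' One row per trait: generative family (`lognormal` for the right-skewed
#' lipid/glycaemic/inflammatory traits, `normal` for blood pressures and
#' HbA1c), cohort-median location, between-subject and within-subject
#' (measurement) spread on the family's parameter scale (log scale for
#' lognormal traits), age/sex effects on the same scale, the expected
#' recording unit and a hard physiological plausibility range.
#'
#' @return data.frame of per-trait generative and QC parameters.
#' @export
defaultTraitConfig <- function() {
  tr <- rbind(
    data.frame(trait = "glucose",      family = "lognormal", location = 95,
               betweenSd = 0.16, withinSd = 0.08, ageCoef = 0.030, sexCoef = 0.020,
               unit = "mg/dL", hardMin = 20,  hardMax = 600),
    data.frame(trait = "hba1c",        family = "normal",    location = 5.6,
               betweenSd = 0.50, withinSd = 0.20, ageCoef = 0.100, sexCoef = 0.050,
               unit = "%",     hardMin = 3,   hardMax = 20),
    data.frame(trait = "cholesterol",  family = "lognormal", location = 190,
               betweenSd = 0.15, withinSd = 0.06, ageCoef = 0.030, sexCoef = -0.020,
               unit = "mg/dL", hardMin = 60,  hardMax = 500),
    data.frame(trait = "ldl",          family = "lognormal", location = 112,
               betweenSd = 0.20, withinSd = 0.08, ageCoef = 0.030, sexCoef = -0.020,
               unit = "mg/dL", hardMin = 20,  hardMax = 400),
    data.frame(trait = "hdl",          family = "lognormal", location = 50,
               betweenSd = 0.20, withinSd = 0.08, ageCoef = 0.010, sexCoef = 0.100,
               unit = "mg/dL", hardMin = 10,  hardMax = 150),
    data.frame(trait = "triglycerides", family = "lognormal", location = 120,
               betweenSd = 0.35, withinSd = 0.12, ageCoef = 0.030, sexCoef = -0.050,
               unit = "mg/dL", hardMin = 20,  hardMax = 1500),
    data.frame(trait = "hscrp",        family = "lognormal", location = 2,
               betweenSd = 0.60, withinSd = 0.20, ageCoef = 0.050, sexCoef = 0.050,
               unit = "mg/L",  hardMin = 0.05, hardMax = 100),
    data.frame(trait = "dbp",          family = "normal",    location = 76,
               betweenSd = 8,    withinSd = 4,    ageCoef = 1.5,   sexCoef = 1,
               unit = "mmHg",  hardMin = 30,  hardMax = 150),
    data.frame(trait = "sbp",          family = "normal",    location = 122,
               betweenSd = 12,   withinSd = 6,    ageCoef = 3,     sexCoef = 2,
               unit = "mmHg",  hardMin = 50,  hardMax = 260),
    data.frame(trait = "wbc",          family = "lognormal", location = 7,
               betweenSd = 0.22, withinSd = 0.10, ageCoef = 0,     sexCoef = 0,
               unit = "10^3/uL", hardMin = 1, hardMax = 50)
  )
  rownames(tr) <- NULL
  tr
}

#' Default planted gene-trait effects
#'
#' Twenty planted effects over the ten traits: effect sizes of roughly
#' 1.3-2 between-subject SDs on the natural trait scale, alternating sign,
#' with 14 concordant, 3 discordant and 3 absent expression counterparts.
#'
#' @return data.frame with columns gene, trait, beta, expressionDirection,
#'   tissue (tissue designated to carry the expression-trait correlation).
#' @export
defaultPlantedEffects <- function() {
  pe <- rbind(
    data.frame(gene = "G1",  trait = "glucose",       beta = -24,  dir = "concordant"),
    data.frame(gene = "G2",  trait = "glucose",       beta = 26,   dir = "concordant"),
    data.frame(gene = "G3",  trait = "hba1c",         beta = -0.9, dir = "concordant"),
    data.frame(gene = "G4",  trait = "hba1c",         beta = 0.9,  dir = "discordant"),
    data.frame(gene = "G5",  trait = "cholesterol",   beta = -44,  dir = "concordant"),
    data.frame(gene = "G6",  trait = "cholesterol",   beta = 46,   dir = "concordant"),
    data.frame(gene = "G7",  trait = "ldl",           beta = -40,  dir = "concordant"),
    data.frame(gene = "G8",  trait = "ldl",           beta = 38,   dir = "absent"),
    data.frame(gene = "G9",  trait = "hdl",           beta = -16,  dir = "concordant"),
    data.frame(gene = "G10", trait = "hdl",           beta = 16,   dir = "concordant"),
    data.frame(gene = "G11", trait = "triglycerides", beta = -68,  dir = "concordant"),
    data.frame(gene = "G12", trait = "triglycerides", beta = 72,   dir = "discordant"),
    data.frame(gene = "G13", trait = "hscrp",         beta = 2.4,  dir = "concordant"),
    data.frame(gene = "G14", trait = "hscrp",         beta = -1.4, dir = "absent"),
    data.frame(gene = "G15", trait = "dbp",           beta = -13,  dir = "concordant"),
    data.frame(gene = "G16", trait = "dbp",           beta = 13,   dir = "concordant"),
    data.frame(gene = "G17", trait = "sbp",           beta = -20,  dir = "concordant"),
    data.frame(gene = "G18", trait = "sbp",           beta = 20,   dir = "discordant"),
    data.frame(gene = "G19", trait = "wbc",           beta = -2.4, dir = "concordant"),
    data.frame(gene = "G20", trait = "wbc",           beta = 2.4,  dir = "absent")
  )
  names(pe)[names(pe) == "dir"] <- "expressionDirection"
  tissues <- c("AOR", "BLOOD", "LIV", "MAM", "SF", "SKLM", "VAF")
  pe$tissue <- tissues[(seq_len(nrow(pe)) - 1L) %% length(tissues) + 1L]
  rownames(pe) <- NULL
  pe
}

#' Default medication effect table
#'
#' Three medication classes and their additive shifts on affected traits,
#' emulating lipid-lowering, antihypertensive and glucose-lowering therapy.
#'
#' @return data.frame with columns medClass, trait, shift.
#' @export
defaultMedicationEffects <- function() {
  rbind(
    data.frame(medClass = "statin",           trait = "ldl",           shift = -35),
    data.frame(medClass = "statin",           trait = "cholesterol",   shift = -40),
    data.frame(medClass = "antihypertensive", trait = "sbp",           shift = -14),
    data.frame(medClass = "antihypertensive", trait = "dbp",           shift = -9),
    data.frame(medClass = "antidiabetic",     trait = "glucose",       shift = -25),
    data.frame(medClass = "antidiabetic",     trait = "hba1c",         shift = -0.8)
  )
}

defaultQcPlants <- function() {
  c(info = 10L, completeness = 8L, consensus_transcript = 6L,
    final_exon = 12L, af = 7L, no_carrier = 5L, no_consensus = 15L)
}

#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig-class]. The defaults define the package's
#' reference study regime: a cohort of 2000 genotyped subjects, 200 genes
#' carrying rare LoF variants (allele frequencies mostly below 0.5%), ten
#' skewed EMR traits measured longitudinally, 20 planted gene-trait effects
#' with concordant/discordant/absent expression counterparts in a 500-sample
#' seven-tissue expression cohort, medication perturbation, low-rate outlier
#' and unit-mislabel corruption, and 20 directly related subject pairs.
#'
#' @param nSubjects cohort size (>= 10).
#' @param nGenes number of genes.
#' @param meanVariantsPerGene mean of the zero-truncated Poisson variant count.
#' @param carrierFreqRange allele-frequency interval for non-planted variants,
#'   inside (0, 0.02).
#' @param plantedCarrierFreq allele frequency for variants of planted-effect
#'   genes (chosen so planted genes comfortably clear the 3-carrier rule).
#' @param traits trait generative table, see [defaultTraitConfig()].
#' @param plantedEffects planted effect table, see [defaultPlantedEffects()].
#' @param medicationEffects medication shift table.
#' @param medicationUseRate per-class fraction of subjects medicated.
#' @param outlierRate,mislabelRate measurement corruption rates in [0, 1].
#' @param measurementsPerSubject integer range of measurements per
#'   subject-trait.
#' @param nRelatedPairs,nBackgroundPairs relatedness pairs above/below the
#'   PI-HAT threshold.
#' @param tissues expression tissues to simulate.
#' @param nExpressionSamples samples per expression tissue.
#' @param expressionSlope absolute planted expression-trait slope.
#' @param expressionNoiseSd residual SD of the expression-cohort trait model.
#' @param qcPlants named integer vector of per-filter planted QC failures.
#' @param seed integer seed; fully determines all outputs.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSubjects = 200, nGenes = 20, seed = 1)
#' cfg
#' @export
simConfig <- function(nSubjects = 2000L,
                      nGenes = 200L,
                      meanVariantsPerGene = 1.3,
                      carrierFreqRange = c(5e-4, 6e-3),
                      plantedCarrierFreq = 8e-3,
                      traits = defaultTraitConfig(),
                      plantedEffects = defaultPlantedEffects(),
                      medicationEffects = defaultMedicationEffects(),
                      medicationUseRate = 0.2,
                      outlierRate = 0.01,
                      mislabelRate = 0.005,
                      measurementsPerSubject = c(2L, 6L),
                      nRelatedPairs = 20L,
                      nBackgroundPairs = 50L,
                      tissues = c("AOR", "BLOOD", "LIV", "MAM", "SF", "SKLM", "VAF"),
                      nExpressionSamples = 500L,
                      expressionSlope = 0.4,
                      expressionNoiseSd = 1,
                      qcPlants = defaultQcPlants(),
                      seed = 1L) {
  if (is.null(plantedEffects))
    plantedEffects <- defaultPlantedEffects()[0, ]
  if (nrow(plantedEffects) && is.null(plantedEffects$tissue)) {
    plantedEffects$tissue <-
      tissues[(seq_len(nrow(plantedEffects)) - 1L) %% length(tissues) + 1L]
  }
  obj <- new("SimConfig",
             nSubjects = as.integer(nSubjects),
             nGenes = as.integer(nGenes),
             meanVariantsPerGene = as.numeric(meanVariantsPerGene),
             carrierFreqRange = as.numeric(carrierFreqRange),
             plantedCarrierFreq = as.numeric(plantedCarrierFreq),
             traits = traits,
             plantedEffects = plantedEffects,
             medicationEffects = medicationEffects,
             medicationUseRate = as.numeric(medicationUseRate),
             outlierRate = as.numeric(outlierRate),
             mislabelRate = as.numeric(mislabelRate),
             measurementsPerSubject = as.integer(measurementsPerSubject),
             nRelatedPairs = as.integer(nRelatedPairs),
             nBackgroundPairs = as.integer(nBackgroundPairs),
             tissues = tissues,
             nExpressionSamples = as.integer(nExpressionSamples),
             expressionSlope = as.numeric(expressionSlope),
             expressionNoiseSd = as.numeric(expressionNoiseSd),
             qcPlants = qcPlants,
             seed = as.integer(seed))
  msg <- validSimConfig(obj)
  if (!isTRUE(msg))
    stop("invalid simulation configuration: ", paste(msg, collapse = "; "),
         call. = FALSE)
  obj
}
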