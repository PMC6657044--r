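# Synthetic study generator: cohort, variants + annotator calls, EMR trait
# streams, relatedness, multi-tissue expression, GO annotations, truth table.
#
# Each generator draws from its own seed stream (config seed + fixed offset)
# so that simulateStudy() is bit-identical under a given config and each
# component is individually reproducible. The caller's RNG state is restored.

withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.seedOffsets <- c(cohort = 0L, variants = 1L, relatedness = 2L, traits = 3L,
                  expression = 4L, go = 5L)

checkConfig <- function(config) {
  if (!is(config, "SimConfig"))
    stop("config must be a SimConfig object", call. = FALSE)
  msg <- validSimConfig(config)
  if (!isTRUE(msg))
    stop("invalid simulation configuration: ", paste(msg, collapse = "; "),
         call. = FALSE)
  invisible(config)
}

#' Simulate the genotyped cohort
#'
#' Draws the subject table: id, sex (0 = female, 1 = male), age in years
#' (uniform 30-80) and five standard-normal genotype principal components.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns subject_id, sex, age, PC1..PC5.
#' @examples
#' co <- simulateCohort(simConfig(nSubjects = 100, nGenes = 20, seed = 1))
#' head(co)
#' @export
simulateCohort <- function(config) {
  checkConfig(config)
  n <- config@nSubjects
  withSeed(config@seed + .seedOffsets[["cohort"]], {
    data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      sex = stats::rbinom(n, 1L, 0.5),
      age = round(stats::runif(n, 30, 80)),
      PC1 = stats::rnorm(n), PC2 = stats::rnorm(n), PC3 = stats::rnorm(n),
      PC4 = stats::rnorm(n), PC5 = stats::rnorm(n),
      stringsAsFactors = FALSE)
  })
}

# Deterministic gene/transcript models: gene g sits on chrom ((g-1) %% 22)+1
# at base position ((g-1) %/% 22)*1e4 + 1 with three 200-bp exons; strand
# alternates. Both transcripts carry all three exons, so the middle genomic
# exon is never final in transcription order on either strand.
geneModel <- function(g) {
  base <- ((g - 1L) %/% 22L) * 10000L + 1L
  list(gene_id = paste0("G", g),
       chrom = as.character(((g - 1L) %% 22L) + 1L),
       base = base,
       strand = if (g %% 2L == 1L) "+" else "-",
       exons = rbind(c(base, base + 199L),
                     c(base + 500L, base + 699L),
                     c(base + 1000L, base + 1199L)))
}

buildTranscripts <- function(nGenes) {
  out <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    gm <- geneModel(g)
    # transcription-order ranks: genomic order on "+", reversed on "-"
    rk <- if (gm$strand == "+") 1:3 else 3:1
    for (tx in c(".1", ".2")) {
      out[[g]] <- rbind(out[[g]], data.frame(
        transcript_id = paste0("T", g, tx),
        gene_id = gm$gene_id,
        exon_rank = rk,
        start = gm$exons[, 1], end = gm$exons[, 2],
        strand = gm$strand, stringsAsFactors = FALSE))
    }
  }
  do.call(rbind, out)
}

# Annotator vocabularies: canonical class -> raw label per annotator.
.rawA1 <- c(frameshift = "frameshift_indel", stop_gained = "stop_gained",
            splice_disrupting = "splice_site")
.rawA2 <- c(frameshift = "frameshift substitution", stop_gained = "stopgain",
            splice_disrupting = "exonic;splicing")
.rawA3 <- c(frameshift = "FRAME_SHIFT", stop_gained = "STOP_GAINED",
            splice_disrupting = "SPLICE_SITE_ACCEPTOR")

#' Simulate variant sites, annotator calls, transcripts and genotypes
#'
#' Generates rare LoF variant sites per gene (zero-truncated Poisson counts),
#' per-site imputation INFO scores and allele frequencies, dominant carrier
#' status with per-call genotype probabilities, three annotator call tables
#' in annotator-specific vocabularies, and the transcript/exon models.
#' A configured number of additional variants is planted to fail each QC
#' filter exactly once (recorded in the truth table): low INFO, low site
#' completeness, no shared LoF transcript between annotators, final-exon
#' position, high allele frequency, zero carriers, and single-annotator
#' (non-consensus) calls.
#'
#' @param config a [SimConfig-class].
#' @param cohort output of [simulateCohort()].
#' @param annotatorMissProb per-annotator probability that a true LoF is
#'   reported as a non-LoF outcome (unmapped label or failing qualifier).
#' @return list with elements `variants`, `calls` (list A1/A2/A3),
#'   `transcripts`, `genotypes` (list of subject x variant `carrier` and
#'   `probability` matrices) and `qcPlants` (truth data.frame).
#' @export
simulateVariants <- function(config, cohort, annotatorMissProb = 0.1) {
  checkConfig(config)
  n <- nrow(cohort)
  nGenes <- config@nGenes
  pe <- config@plantedEffects
  plantedGenes <- unique(pe$gene)
  plantedIdx <- as.integer(sub("^G", "", plantedGenes))

  withSeed(config@seed + .seedOffsets[["variants"]], {
    nv <- 1L + stats::rpois(nGenes, max(config@meanVariantsPerGene - 1, 0))
    geneOfVariant <- rep(seq_len(nGenes), nv)

    qp <- config@qcPlants
    plantFilters <- rep(names(qp), qp)
    # planted QC failures live on genes without planted trait effects
    hostPool <- setdiff(seq_len(nGenes), plantedIdx)
    if (length(plantFilters) > 0L && length(hostPool) == 0L)
      stop("no genes available to host planted QC failures", call. = FALSE)
    hostGene <- if (length(plantFilters))
      sample(hostPool, length(plantFilters), replace = TRUE) else integer()

    allGene <- c(geneOfVariant, hostGene)
    allPlant <- c(rep(NA_character_, length(geneOfVariant)), plantFilters)
    nVar <- length(allGene)

    # position: middle exon unless the plant requires the final exon
    pos <- integer(nVar); chrom <- character(nVar)
    offs <- integer(nGenes)   # per-gene running offset keeps positions unique
    for (i in seq_len(nVar)) {
      g <- allGene[i]
      gm <- geneModel(g)
      off <- offs[g]; offs[g] <- off + 2L
      chrom[i] <- gm$chrom
      if (identical(allPlant[i], "final_exon")) {
        fe <- if (gm$strand == "+") gm$exons[3, ] else gm$exons[1, ]
        pos[i] <- fe[1] + off
      } else {
        pos[i] <- gm$exons[2, 1] + off
      }
    }
    key <- paste(chrom, pos, "A", "T", sep = ":")

    af <- ifelse(allGene %in% plantedIdx,
                 config@plantedCarrierFreq,
                 stats::runif(nVar, config@carrierFreqRange[1],
                              config@carrierFreqRange[2]))
    af[allPlant %in% "af"] <- stats::runif(sum(allPlant %in% "af"),
                                           0.021, 0.04)
    af[allPlant %in% "no_carrier"] <- stats::runif(
      sum(allPlant %in% "no_carrier"), 1e-4, 5e-4)

    info <- stats::runif(nVar, 0.75, 1)
    info[allPlant %in% "info"] <- stats::runif(sum(allPlant %in% "info"),
                                               0.05, 0.3)

    trueClass <- sample(c("frameshift", "stop_gained", "splice_disrupting"),
                        nVar, replace = TRUE)

    variants <- data.frame(
      variant_key = key, gene_id = paste0("G", allGene),
      chrom = chrom, pos = pos, ref = "A", alt = "T",
      true_class = trueClass, info_score = info, alt_allele_freq = af,
      planted_filter = allPlant, stringsAsFactors = FALSE)

    # genotypes: dominant carrier status, ascertained as segregating (every
    # non-"no_carrier" site has >= 1 carrier); carrier calls are confident
    # (probability >= 0.96) so hard-calling never erases a site's carriers.
    carrier <- matrix(0L, n, nVar,
                      dimnames = list(cohort$subject_id, key))
    probability <- matrix(stats::runif(n * nVar, 0.95, 1), n, nVar,
                          dimnames = list(cohort$subject_id, key))
    lowIdx <- which(stats::runif(n * nVar) < 0.02)
    probability[lowIdx] <- stats::runif(length(lowIdx), 0.5, 0.9499)
    for (i in seq_len(nVar)) {
      if (identical(allPlant[i], "no_carrier")) next
      carriers <- which(stats::runif(n) < 2 * af[i])
      if (length(carriers) == 0L) carriers <- sample.int(n, 1L)
      carrier[carriers, i] <- 1L
      probability[carriers, i] <- stats::runif(length(carriers), 0.96, 1)
    }
    for (i in which(allPlant %in% "completeness")) {
      k <- ceiling(0.15 * n)
      nonCar <- which(carrier[, i] == 0L)
      low <- sample(nonCar, min(k, length(nonCar)))
      probability[low, i] <- stats::runif(length(low), 0.5, 0.9)
    }

    # annotator call tables
    mkCalls <- function() list(A1 = NULL, A2 = NULL, A3 = NULL)
    rowsA1 <- list(); rowsA2 <- list(); rowsA3 <- list()
    for (i in seq_len(nVar)) {
      g <- allGene[i]; cls <- trueClass[i]
      tx <- paste0("T", g, c(".1", ".2"))
      plant <- allPlant[i]
      deterministic <- !is.na(plant)
      if (identical(plant, "no_consensus")) {
        rowsA1[[length(rowsA1) + 1L]] <- data.frame(
          variant_key = key[i], transcript_id = tx,
          raw_effect = .rawA1[[cls]], full_effect = "full",
          stringsAsFactors = FALSE)
        rowsA2[[length(rowsA2) + 1L]] <- data.frame(
          variant_key = key[i], transcript_id = tx,
          raw_effect = "nonsynonymous SNV", stringsAsFactors = FALSE)
        next
      }
      if (identical(plant, "consensus_transcript")) {
        # two annotators agree the variant is LoF but never on a shared
        # transcript
        rowsA1[[length(rowsA1) + 1L]] <- data.frame(
          variant_key = key[i], transcript_id = tx[1],
          raw_effect = .rawA1[[cls]], full_effect = "full",
          stringsAsFactors = FALSE)
        rowsA2[[length(rowsA2) + 1L]] <- data.frame(
          variant_key = key[i], transcript_id = tx[2],
          raw_effect = .rawA2[[cls]], stringsAsFactors = FALSE)
        next
      }
      missA1 <- !deterministic && stats::runif(1) < annotatorMissProb
      missA2 <- !deterministic && stats::runif(1) < annotatorMissProb
      missA3 <- !deterministic && stats::runif(1) < annotatorMissProb
      rowsA1[[length(rowsA1) + 1L]] <- if (missA1) {
        if (stats::runif(1) < 0.5)
          data.frame(variant_key = key[i], transcript_id = tx,
                     raw_effect = "missense", full_effect = "full",
                     stringsAsFactors = FALSE)
        else
          data.frame(variant_key = key[i], transcript_id = tx,
                     raw_effect = .rawA1[[cls]], full_effect = "partial",
                     stringsAsFactors = FALSE)
      } else data.frame(variant_key = key[i], transcript_id = tx,
                        raw_effect = .rawA1[[cls]], full_effect = "full",
                        stringsAsFactors = FALSE)
      rowsA2[[length(rowsA2) + 1L]] <- data.frame(
        variant_key = key[i], transcript_id = tx,
        raw_effect = if (missA2) "nonsynonymous SNV" else .rawA2[[cls]],
        stringsAsFactors = FALSE)
      rowsA3[[length(rowsA3) + 1L]] <- data.frame(
        variant_key = key[i], transcript_id = tx,
        raw_effect = .rawA3[[cls]],
        impact = if (missA3) "MODERATE" else "HIGH",
        biotype = "protein-coding", stringsAsFactors = FALSE)
    }
    calls <- list(A1 = do.call(rbind, rowsA1),
                  A2 = do.call(rbind, rowsA2),
                  A3 = do.call(rbind, rowsA3))

    qcPlantTruth <- variants[!is.na(variants$planted_filter),
                             c("variant_key", "planted_filter")]
    names(qcPlantTruth) <- c("variant_key", "filter")
    rownames(qcPlantTruth) <- NULL

    list(variants = variants, calls = calls,
         transcripts = buildTranscripts(nGenes),
         genotypes = list(carrier = carrier, probability = probability),
         qcPlants = qcPlantTruth)
  })
}

#' Simulate pairwise relatedness estimates
#'
#' Plants the configured number of subject pairs with PI-HAT drawn above the
#' direct-relatedness threshold (uniform 0.25-0.55) plus background pairs
#' below it (uniform 0.01-0.15); the pair table is deduplicated.
#'
#' @param config a [SimConfig-class].
#' @param cohort output of [simulateCohort()].
#' @return list(pairs = data.frame(id_a, id_b, pi_hat),
#'   relatedPairs = truth data.frame of the planted pairs).
#' @export
simulateRelatedness <- function(config, cohort) {
  checkConfig(config)
  withSeed(config@seed + .seedOffsets[["relatedness"]], {
    ids <- cohort$subject_id
    nr <- config@nRelatedPairs
    rel <- if (nr > 0L) {
      picked <- sample(ids, 2L * nr)
      data.frame(id_a = pmin(picked[seq_len(nr) * 2L - 1L],
                             picked[seq_len(nr) * 2L]),
                 id_b = pmax(picked[seq_len(nr) * 2L - 1L],
                             picked[seq_len(nr) * 2L]),
                 pi_hat = stats::runif(nr, 0.25, 0.55),
                 stringsAsFactors = FALSE)
    } else data.frame(id_a = character(), id_b = character(),
                      pi_hat = numeric())
    nb <- config@nBackgroundPairs
    bg <- if (nb > 0L) {
      a <- sample(ids, nb, replace = TRUE)
      b <- sample(ids, nb, replace = TRUE)
      ok <- a != b
      data.frame(id_a = pmin(a[ok], b[ok]), id_b = pmax(a[ok], b[ok]),
                 pi_hat = stats::runif(sum(ok), 0.01, 0.15),
                 stringsAsFactors = FALSE)
    } else rel[0, ]
    pairs <- rbind(rel, bg)
    pairs <- pairs[!duplicated(pairs[, c("id_a", "id_b")]), ]
    rownames(pairs) <- NULL
    list(pairs = pairs, relatedPairs = rel)
  })
}

.altUnits <- c("mg/dL" = "mmol/L", "%" = "mmol/mol", "mmHg" = "kPa",
               "mg/L" = "nmol/L", "10^3/uL" = "10^9/L")
.altFactors <- c("mg/dL" = 1 / 18, "%" = 10.93, "mmHg" = 1 / 7.5,
                 "mg/L" = 9.52, "10^3/uL" = 1)

#' Simulate longitudinal EMR trait streams and medication intervals
#'
#' Each subject receives dated measurements per trait drawn from the trait's
#' generative family with between- and within-subject variation and age/sex
#' effects; carriers of a planted (gene, trait) effect have their latent mean
#' shifted by the configured effect. Legitimate values are winsorized at 3.6
#' cohort MADs from the trait median (physiological plausibility), so the
#' downstream 4-MAD outlier rule fires only on planted outliers. Medication
#' intervals additively shift in-interval measurements of affected traits;
#' unit mislabels and gross outliers are injected at the configured rates on
#' measurements not already medication-affected, so every perturbed
#' measurement has exactly one cause, recorded in the truth flags.
#'
#' @param config a [SimConfig-class].
#' @param cohort output of [simulateCohort()].
#' @param carriersByGene named list: gene id -> carrier subject ids (raw
#'   carrier status, before hard-calling).
#' @return list(measurements, medications, measurementFlags).
#' @export
simulateTraitStreams <- function(config, cohort, carriersByGene) {
  checkConfig(config)
  n <- nrow(cohort)
  tr <- config@traits
  pe <- config@plantedEffects
  withSeed(config@seed + .seedOffsets[["traits"]], {
    # medication intervals
    medClasses <- unique(config@medicationEffects$medClass)
    medRows <- list()
    for (mc in medClasses) {
      users <- which(stats::runif(n) < config@medicationUseRate)
      if (!length(users)) next
      start <- sample(0:1200, length(users), replace = TRUE)
      dur <- sample(300:2000, length(users), replace = TRUE)
      end <- start + dur
      end[stats::runif(length(users)) < 0.1] <- NA_integer_
      medRows[[mc]] <- data.frame(
        subject_id = cohort$subject_id[users], med_class = mc,
        start = start, end = end, stringsAsFactors = FALSE)
    }
    medications <- if (length(medRows)) do.call(rbind, medRows) else
      data.frame(subject_id = character(), med_class = character(),
                 start = integer(), end = integer())
    rownames(medications) <- NULL

    ageZ <- (cohort$age - 55) / 15
    sexN <- cohort$sex
    kRange <- config@measurementsPerSubject
    nMeas <- sample(kRange[1]:kRange[2], n, replace = TRUE)

    measList <- list()
    flagList <- list()
    midCounter <- 0L
    for (ti in seq_len(nrow(tr))) {
      trait <- tr$trait[ti]
      shift <- numeric(n)
      peT <- pe[pe$trait == trait, , drop = FALSE]
      for (j in seq_len(nrow(peT))) {
        carr <- carriersByGene[[peT$gene[j]]]
        idx <- match(carr, cohort$subject_id)
        idx <- idx[!is.na(idx)]
        shift[idx] <- shift[idx] + peT$beta[j]
      }
      if (tr$family[ti] == "lognormal") {
        latent <- exp(log(tr$location[ti]) + tr$ageCoef[ti] * ageZ +
                        tr$sexCoef[ti] * sexN +
                        stats::rnorm(n, 0, tr$betweenSd[ti])) + shift
        latent <- pmax(latent, tr$hardMin[ti] * 1.05)
        vals <- rep(latent, nMeas) *
          exp(stats::rnorm(sum(nMeas), 0, tr$withinSd[ti]))
      } else {
        latent <- tr$location[ti] + tr$ageCoef[ti] * ageZ +
          tr$sexCoef[ti] * sexN + stats::rnorm(n, 0, tr$betweenSd[ti]) + shift
        vals <- rep(latent, nMeas) + stats::rnorm(sum(nMeas), 0,
                                                  tr$withinSd[ti])
      }
      subj <- rep(cohort$subject_id, nMeas)
      dates <- sample(0:2500, length(vals), replace = TRUE)

      # winsorize legitimate values at 3.6 cohort MADs
      med0 <- stats::median(vals)
      mad0 <- stats::mad(vals)
      vals <- pmin(pmax(vals, med0 - 3.6 * mad0), med0 + 3.6 * mad0)
      vals <- pmax(vals, tr$hardMin[ti] * 1.01)

      unit <- rep(tr$unit[ti], length(vals))
      mid <- sprintf("M%07d", midCounter + seq_along(vals))
      midCounter <- midCounter + length(vals)

      # medication perturbation
      mcAff <- config@medicationEffects[
        config@medicationEffects$trait == trait, , drop = FALSE]
      medFlag <- rep(FALSE, length(vals))
      for (j in seq_len(nrow(mcAff))) {
        iv <- medications[medications$med_class == mcAff$medClass[j], ,
                          drop = FALSE]
        if (!nrow(iv)) next
        m <- merge(data.frame(i = seq_along(vals), subject_id = subj,
                              date = dates, stringsAsFactors = FALSE),
                   iv, by = "subject_id")
        hit <- m$date >= m$start & (is.na(m$end) | m$date <= m$end)
        idx <- unique(m$i[hit])
        if (length(idx)) {
          # treated values stay inside the plausibility floor
          vals[idx] <- pmax(vals[idx] + mcAff$shift[j], tr$hardMin[ti] * 1.02)
          medFlag[idx] <- TRUE
        }
      }

      # mislabels and outliers on untouched measurements only
      free <- which(!medFlag)
      misSel <- free[stats::runif(length(free)) < config@mislabelRate]
      free2 <- setdiff(free, misSel)
      outSel <- free2[stats::runif(length(free2)) < config@outlierRate]
      if (length(misSel)) {
        unit[misSel] <- .altUnits[[tr$unit[ti]]]
        vals[misSel] <- vals[misSel] * .altFactors[[tr$unit[ti]]]
      }
      if (length(outSel)) {
        # gross errors that still pass the field's recordable range
        vals[outSel] <- pmin(med0 + stats::runif(length(outSel), 5, 8) * mad0,
                             tr$hardMax[ti] * 0.98)
      }

      measList[[trait]] <- data.frame(
        measurement_id = mid, subject_id = subj, trait = trait,
        value = vals, unit = unit, date = dates, stringsAsFactors = FALSE)
      fl <- character(length(vals))
      fl[medFlag] <- "medication"
      fl[misSel] <- "mislabel"
      fl[outSel] <- "outlier"
      keep <- fl != ""
      flagList[[trait]] <- data.frame(
        measurement_id = mid[keep], subject_id = subj[keep],
        trait = rep(trait, sum(keep)), flag = fl[keep],
        stringsAsFactors = FALSE)
    }
    measurements <- do.call(rbind, measList)
    rownames(measurements) <- NULL
    measurementFlags <- do.call(rbind, flagList)
    rownames(measurementFlags) <- NULL
    list(measurements = measurements, medications = medications,
         measurementFlags = measurementFlags)
  })
}

#' Simulate per-tissue expression sets with planted trait correlations
#'
#' For each configured tissue, draws an expression-cohort sample set (age,
#' sex, BMI), an iid standard-normal gene x sample expression matrix, and
#' trait values built from covariates plus, for planted effects designated to
#' that tissue, a slope on the gene's expression whose sign encodes the
#' configured relationship: `concordant` effects get a slope of sign opposite
#' to the genotype effect, `discordant` the same sign, `absent` zero. Slopes
#' and residual SDs scale with each trait's natural between-subject SD.
#'
#' @param config a [SimConfig-class].
#' @return list(expression = per-tissue list(expr, samples),
#'   expressionSlopes = truth data.frame(gene, trait, tissue, slope)).
#' @export
simulateExpression <- function(config) {
  checkConfig(config)
  tr <- config@traits
  pe <- config@plantedEffects
  sdNat <- ifelse(tr$family == "lognormal", tr$location * tr$betweenSd,
                  tr$betweenSd)
  names(sdNat) <- tr$trait
  geneIdsAll <- paste0("G", seq_len(config@nGenes))
  plantedIdx <- as.integer(sub("^G", "", unique(pe$gene)))

  withSeed(config@seed + .seedOffsets[["expression"]], {
    ns <- config@nExpressionSamples
    slopeRows <- list()
    expression <- list()
    for (k in seq_along(config@tissues)) {
      tis <- config@tissues[k]
      samples <- data.frame(
        sample_id = sprintf("%s_%04d", tis, seq_len(ns)),
        age = round(stats::runif(ns, 40, 75)),
        sex = stats::rbinom(ns, 1L, 0.7),
        bmi = round(stats::rnorm(ns, 27.5, 4), 1),
        stringsAsFactors = FALSE)
      dropIdx <- setdiff(which(seq_len(config@nGenes) %% 37L == k %% 37L),
                         plantedIdx)
      genes <- geneIdsAll[setdiff(seq_len(config@nGenes), dropIdx)]
      expr <- matrix(stats::rnorm(length(genes) * ns), length(genes), ns,
                     dimnames = list(genes, samples$sample_id))
      ageZ <- (samples$age - 55) / 10
      bmiZ <- (samples$bmi - 27.5) / 4
      for (ti in seq_len(nrow(tr))) {
        trait <- tr$trait[ti]
        s <- sdNat[[trait]]
        y <- tr$location[ti] + 0.3 * s * ageZ + 0.2 * s * samples$sex +
          0.25 * s * bmiZ +
          stats::rnorm(ns, 0, config@expressionNoiseSd * s)
        peT <- pe[pe$trait == trait & pe$tissue == tis, , drop = FALSE]
        for (j in seq_len(nrow(peT))) {
          dirn <- peT$expressionDirection[j]
          slope <- if (dirn == "concordant") -sign(peT$beta[j]) *
            config@expressionSlope * s
          else if (dirn == "discordant") sign(peT$beta[j]) *
            config@expressionSlope * s
          else 0
          if (slope != 0 && peT$gene[j] %in% genes)
            y <- y + slope * expr[peT$gene[j], ]
          slopeRows[[length(slopeRows) + 1L]] <- data.frame(
            gene = peT$gene[j], trait = trait, tissue = tis, slope = slope,
            stringsAsFactors = FALSE)
        }
        samples[[trait]] <- y
      }
      expression[[tis]] <- list(expr = expr, samples = samples)
    }
    list(expression = expression,
         expressionSlopes = if (length(slopeRows)) do.call(rbind, slopeRows)
         else data.frame(gene = character(), trait = character(),
                         tissue = character(), slope = numeric()))
  })
}

.goRelevant <- data.frame(
  go_id = c("GO:0006006", "GO:0008203", "GO:0006641", "GO:0006631",
            "GO:0008217"),
  term_name = c("glucose metabolic process", "cholesterol metabolic process",
                "triglyceride metabolic process",
                "fatty acid metabolic process",
                "regulation of blood pressure"),
  stringsAsFactors = FALSE)

.goTraitTerm <- c(glucose = "GO:0006006", hba1c = "GO:0006006",
                  cholesterol = "GO:0008203", ldl = "GO:0008203",
                  hdl = "GO:0008203", triglycerides = "GO:0006641",
                  hscrp = "GO:0006631", dbp = "GO:0008217",
                  sbp = "GO:0008217", wbc = "GO:0006631")

.goIrrelevant <- data.frame(
  go_id = c("GO:0006281", "GO:0007155", "GO:0006412", "GO:0016192",
            "GO:0006396", "GO:0007165"),
  term_name = c("DNA repair", "cell adhesion", "translation",
                "vesicle-mediated transport", "RNA processing",
                "signal transduction"),
  stringsAsFactors = FALSE)

#' Simulate GO biological-process annotations
#'
#' Genes with planted trait effects receive a CVD-relevant biological-process
#' term matched to the trait domain; of the remaining genes roughly 80% get
#' one to three generic BP terms and the rest only a molecular-function
#' annotation (no BP term), so stage-1 GO coverage is exercised.
#'
#' @param config a [SimConfig-class].
#' @return data.frame(gene_id, go_id, term_name, aspect).
#' @export
simulateGoAnnotations <- function(config) {
  checkConfig(config)
  pe <- config@plantedEffects
  withSeed(config@seed + .seedOffsets[["go"]], {
    rows <- list()
    for (j in seq_len(nrow(pe))) {
      gid <- .goTraitTerm[[pe$trait[j]]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = pe$gene[j], go_id = gid,
        term_name = .goRelevant$term_name[.goRelevant$go_id == gid],
        aspect = "P", stringsAsFactors = FALSE)
    }
    others <- setdiff(paste0("G", seq_len(config@nGenes)), unique(pe$gene))
    for (g in others) {
      if (stats::runif(1) < 0.8) {
        k <- sample(1:3, 1L)
        pick <- sample(nrow(.goIrrelevant), k)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, go_id = .goIrrelevant$go_id[pick],
          term_name = .goIrrelevant$term_name[pick], aspect = "P",
          stringsAsFactors = FALSE)
        if (stats::runif(1) < 0.03) {
          pick2 <- sample(nrow(.goRelevant), 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, go_id = .goRelevant$go_id[pick2],
            term_name = .goRelevant$term_name[pick2], aspect = "P",
            stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, go_id = "GO:0005515", term_name = "protein binding",
          aspect = "F", stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out[, c("gene_id", "go_id")]), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete study with known ground truth
#'
#' Runs every generator in a fixed order and assembles a [LofStudySim-class]
#' whose truth table traces each planted gene-trait effect (with its true
#' carrier list and expected concordance verdict), each planted QC failure,
#' each perturbed measurement and each planted related pair.
#'
#' @param config a [SimConfig-class]; the same config and seed reproduce the
#'   object bit-identically.
#' @return a [LofStudySim-class].
#' @examples
#' sim <- simulateStudy(simConfig(nSubjects = 120, nGenes = 25,
#'                                nExpressionSamples = 60, seed = 7))
#' sim
#' @export
simulateStudy <- function(config) {
  checkConfig(config)
  co <- simulateCohort(config)
  vg <- simulateVariants(config, co)
  rel <- simulateRelatedness(config, co)

  # raw carrier sets per gene drive the planted trait shifts
  carrier <- vg$genotypes$carrier
  geneOf <- vg$variants$gene_id[match(colnames(carrier),
                                      vg$variants$variant_key)]
  carriersByGene <- lapply(split(seq_len(ncol(carrier)), geneOf), function(ix) {
    rownames(carrier)[rowSums(carrier[, ix, drop = FALSE]) > 0L]
  })

  ts <- simulateTraitStreams(config, co, carriersByGene)
  ex <- simulateExpression(config)
  go <- simulateGoAnnotations(config)

  pe <- config@plantedEffects
  expectedVerdict <- ifelse(pe$expressionDirection == "concordant",
                            "concordant",
                            ifelse(pe$expressionDirection == "discordant",
                                   "discordant", "untested"))
  peTruth <- cbind(pe, expectedVerdict = expectedVerdict,
                   nCarriers = vapply(pe$gene, function(g)
                     length(carriersByGene[[g]]), integer(1)))
  rownames(peTruth) <- NULL

  truth <- list(
    plantedEffects = peTruth,
    plantedCarriers = carriersByGene[unique(pe$gene)],
    qcPlants = vg$qcPlants,
    measurementFlags = ts$measurementFlags,
    relatedPairs = rel$relatedPairs,
    expressionSlopes = ex$expressionSlopes)

  new("LofStudySim", config = config, cohort = co,
      variants = vg$variants, calls = vg$calls,
      transcripts = vg$transcripts, genotypes = vg$genotypes,
      measurements = ts$measurements, medications = ts$medications,
      relatedness = rel$pairs, expression = ex$expression,
      goAnnotations = go, truth = truth)
}
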