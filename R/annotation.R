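# Consensus LoF classification: vocabulary harmonization across the three
# annotators, the >=2-of-3 transcript-agreement rule, genotype-probability
# hard-calling, the variant QC cascade with per-filter accounting,
# relatedness pruning and gene-level collapsing.

#' Default annotator vocabulary mapping
#'
#' Maps each annotator's raw effect labels to the canonical LoF classes
#' (frameshift, stop_gained, splice_disrupting) and states the
#' annotator-specific qualifier rules: A1 (VAT-style) calls must carry a
#' "full" predicted effect; A3 (SnpEff-style) calls must have "HIGH" impact
#' and "protein-coding" transcript biotype. The mapping is configuration:
#' pass a modified copy to [harmonizeCalls()] to track vocabulary drift.
#'
#' @return named list with one entry per annotator (A1, A2, A3).
#' @export
lofVocabulary <- function() {
  list(
    A1 = list(map = c("frameshift_indel" = "frameshift",
                      "stop_gained" = "stop_gained",
                      "splice_site" = "splice_disrupting"),
              requireFullEffect = TRUE),
    A2 = list(map = c("frameshift substitution" = "frameshift",
                      "stopgain" = "stop_gained",
                      "exonic;splicing" = "splice_disrupting")),
    A3 = list(map = c("FRAME_SHIFT" = "frameshift",
                      "STOP_GAINED" = "stop_gained",
                      "SPLICE_SITE_ACCEPTOR" = "splice_disrupting",
                      "SPLICE_SITE_DONOR" = "splice_disrupting"),
              impact = "HIGH", biotype = "protein-coding")
  )
}

#' Harmonize raw annotator call tables into canonical LoF calls
#'
#' Emits one canonical call per (annotator, variant, transcript) for calls
#' whose raw effect maps into the canonical LoF set and whose
#' annotator-specific qualifiers pass. Calls with unmapped labels or failing
#' qualifiers are dropped and counted, never fatal.
#'
#' @param calls named list of annotator call data.frames. Required columns:
#'   variant_key, transcript_id, raw_effect; A1 additionally full_effect,
#'   A3 additionally impact and biotype.
#' @param vocabulary mapping configuration, see [lofVocabulary()].
#' @return data.frame(annotator, variant_key, transcript_id,
#'   canonical_effect) with a `dropped` attribute: per-annotator counts of
#'   calls dropped for unmapped labels or failed qualifiers.
#' @examples
#' a1 <- data.frame(variant_key = "1:501:A:T", transcript_id = "T1.1",
#'                  raw_effect = "stop_gained", full_effect = "full")
#' harmonizeCalls(list(A1 = a1))
#' @export
harmonizeCalls <- function(calls, vocabulary = lofVocabulary()) {
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    stop("calls must be a named list of annotator tables", call. = FALSE)
  unknown <- setdiff(names(calls), names(vocabulary))
  if (length(unknown))
    stop("unknown annotator id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- list()
  dropped <- list()
  for (ann in names(calls)) {
    tab <- calls[[ann]]
    if (is.null(tab) || nrow(tab) == 0L) {
      dropped[[ann]] <- c(unmapped = 0L, qualifier = 0L)
      next
    }
    if (any(!nzchar(tab$raw_effect)) || anyNA(tab$raw_effect))
      stop("empty raw_effect in annotator ", ann, call. = FALSE)
    voc <- vocabulary[[ann]]
    canon <- unname(voc$map[tab$raw_effect])
    mapped <- !is.na(canon)
    qualOk <- rep(TRUE, nrow(tab))
    if (isTRUE(voc$requireFullEffect))
      qualOk <- qualOk & tab$full_effect == "full"
    if (!is.null(voc$impact))
      qualOk <- qualOk & tab$impact == voc$impact
    if (!is.null(voc$biotype))
      qualOk <- qualOk & tab$biotype == voc$biotype
    keep <- mapped & qualOk
    dropped[[ann]] <- c(unmapped = sum(!mapped),
                        qualifier = sum(mapped & !qualOk))
    if (any(keep))
      out[[ann]] <- data.frame(
        annotator = ann, variant_key = tab$variant_key[keep],
        transcript_id = tab$transcript_id[keep],
        canonical_effect = canon[keep], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(annotator = character(), variant_key = character(),
               transcript_id = character(), canonical_effect = character())
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Consensus classification of harmonized calls
#'
#' A variant has annotator consensus when at least two of the three
#' annotators call it LoF; the `consensus` flag additionally requires the
#' agreeing annotators to share at least one transcript ("shared_transcripts"
#' lists every transcript with canonical LoF calls from two or more distinct
#' annotators). Adding calls can only add consensus, never revoke it.
#'
#' @param harmonized output of [harmonizeCalls()].
#' @return data.frame per variant_key: n_annotators, any_two (>= 2
#'   annotators, any transcript), shared_transcripts (comma-joined),
#'   consensus (>= 2 annotators on a common transcript), canonical_effects.
#' @export
consensusClassify <- function(harmonized) {
  if (nrow(harmonized) == 0L)
    return(data.frame(variant_key = character(), n_annotators = integer(),
                      any_two = logical(), shared_transcripts = character(),
                      consensus = logical(), canonical_effects = character()))
  byVar <- split(harmonized, harmonized$variant_key)
  rows <- lapply(byVar, function(d) {
    nAnn <- length(unique(d$annotator))
    txAnn <- tapply(d$annotator, d$transcript_id,
                    function(a) length(unique(a)))
    shared <- sort(names(txAnn)[txAnn >= 2L])
    data.frame(
      variant_key = d$variant_key[1],
      n_annotators = nAnn,
      any_two = nAnn >= 2L,
      shared_transcripts = paste(shared, collapse = ","),
      consensus = length(shared) > 0L,
      canonical_effects = paste(sort(unique(d$canonical_effect)),
                                collapse = ","),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Hard-call genotypes at a probability threshold
#'
#' Calls with genotype probability below the threshold become missing; site
#' completeness is the fraction of non-missing calls per variant.
#'
#' @param carrier integer subject x variant matrix of dominant carrier
#'   status (0/1).
#' @param probability numeric matrix of per-call genotype probabilities,
#'   same shape.
#' @param threshold probability below which a call is set missing
#'   (default 0.95; a call at exactly the threshold is retained).
#' @return list(carrier = matrix with NA for masked calls,
#'   completeness = named per-variant fraction of confident calls).
#' @export
hardCallGenotypes <- function(carrier, probability, threshold = 0.95) {
  if (!all(dim(carrier) == dim(probability)))
    stop("carrier and probability matrices must have identical shape",
         call. = FALSE)
  if (any(probability < 0 | probability > 1, na.rm = TRUE))
    stop("genotype probabilities must lie in [0, 1]", call. = FALSE)
  masked <- probability < threshold
  hc <- carrier
  hc[masked] <- NA_integer_
  completeness <- colMeans(!is.na(hc))
  list(carrier = hc, completeness = completeness)
}

#' Final-exon status of a position on one transcript
#'
#' TRUE when the position falls inside the transcript's 3'-most exon in
#' transcription order (the exon with the highest exon_rank), strand-aware
#' because exon_rank is given in transcription order. A position inside the
#' transcript span but in no exon is reported FALSE with a logged anomaly.
#'
#' @param pos 1-based genomic position.
#' @param transcriptExons data.frame rows for one transcript with columns
#'   exon_rank, start, end (1-based inclusive).
#' @return logical scalar.
#' @examples
#' tx <- data.frame(exon_rank = 1:3, start = c(100, 300, 500),
#'                  end = c(199, 399, 599))
#' isFinalExon(550, tx)   # TRUE
#' isFinalExon(150, tx)   # FALSE
#' @export
isFinalExon <- function(pos, transcriptExons) {
  if (nrow(transcriptExons) < 1L)
    stop("transcript must have at least one exon", call. = FALSE)
  inExon <- pos >= transcriptExons$start & pos <= transcriptExons$end
  if (!any(inExon)) {
    message("position ", pos, " falls in no exon of the transcript; ",
            "reported as not-in-final-exon")
    return(FALSE)
  }
  fin <- which.max(transcriptExons$exon_rank)
  pos >= transcriptExons$start[fin] && pos <= transcriptExons$end[fin]
}

# for one variant: TRUE if every supporting transcript places it in that
# transcript's final exon (vacuously FALSE when no transcript is supplied)
allSupportingFinal <- function(pos, transcriptIds, transcripts) {
  if (length(transcriptIds) == 0L) return(FALSE)
  all(vapply(transcriptIds, function(tid) {
    te <- transcripts[transcripts$transcript_id == tid, , drop = FALSE]
    if (nrow(te) == 0L) stop("unknown transcript: ", tid, call. = FALSE)
    isFinalExon(pos, te)
  }, logical(1)))
}

#' Apply the variant QC cascade
#'
#' Evaluates the filters in the study's order on the consensus-eligible pool
#' (variants called LoF by at least two annotators): imputation INFO score
#' strictly above `infoMin`; site completeness at least `completenessMin`;
#' consensus on at least one shared transcript; not located in the final
#' exon of every consensus-supporting transcript; alternate allele frequency
#' strictly below `afMax`; and at least one carrier after hard-calling.
#' A variant may fail several filters but is removed once; both per-filter
#' and unique-removal counts are reported.
#'
#' @param variants data.frame with columns variant_key, gene_id, pos,
#'   info_score, alt_allele_freq.
#' @param consensusTab output of [consensusClassify()].
#' @param hardCalled output of [hardCallGenotypes()].
#' @param transcripts transcript model data.frame (transcript_id, gene_id,
#'   exon_rank, start, end, strand).
#' @param infoMin,completenessMin,afMax filter thresholds.
#' @return list(retained = variant data.frame with pass/fail filter_status
#'   columns for retained variants, filterStatus = the same columns for the
#'   whole eligible pool, counts = named vector of per-filter fail counts
#'   plus n_eligible, n_not_consensus_pool, unique_removed, n_retained).
#' @export
applyVariantQC <- function(variants, consensusTab, hardCalled, transcripts,
                           infoMin = 0.3, completenessMin = 0.9,
                           afMax = 0.02) {
  need <- c("variant_key", "gene_id", "pos", "info_score", "alt_allele_freq")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variants table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (m in c("info_score", "alt_allele_freq")) {
    bad <- variants$variant_key[!is.finite(variants[[m]])]
    if (length(bad))
      stop("variant ", bad[1], " has missing metric ", m, call. = FALSE)
  }
  cs <- consensusTab[match(variants$variant_key, consensusTab$variant_key), ]
  eligible <- !is.na(cs$any_two) & cs$any_two
  pool <- variants[eligible, , drop = FALSE]
  poolCs <- cs[eligible, , drop = FALSE]

  compl <- hardCalled$completeness[pool$variant_key]
  bad <- pool$variant_key[is.na(compl)]
  if (length(bad))
    stop("variant ", bad[1], " has missing metric completeness",
         call. = FALSE)
  carrierCounts <- colSums(hardCalled$carrier[, pool$variant_key,
                                              drop = FALSE] == 1L,
                           na.rm = TRUE)

  sharedList <- strsplit(poolCs$shared_transcripts, ",", fixed = TRUE)
  sharedList <- lapply(sharedList, function(x) x[nzchar(x)])

  failInfo <- !(pool$info_score > infoMin)
  failCompl <- compl < completenessMin
  failConsTx <- !poolCs$consensus
  failFinal <- mapply(function(p, tids) allSupportingFinal(p, tids,
                                                           transcripts),
                      pool$pos, sharedList)
  failAf <- !(pool$alt_allele_freq < afMax)
  failCarrier <- carrierCounts == 0L

  failAny <- failInfo | failCompl | failConsTx | failFinal | failAf |
    failCarrier
  status <- data.frame(
    variant_key = pool$variant_key,
    info = ifelse(failInfo, "fail", "pass"),
    completeness = ifelse(failCompl, "fail", "pass"),
    consensus_transcript = ifelse(failConsTx, "fail", "pass"),
    final_exon = ifelse(failFinal, "fail", "pass"),
    af = ifelse(failAf, "fail", "pass"),
    carrier = ifelse(failCarrier, "fail", "pass"),
    stringsAsFactors = FALSE)

  retained <- cbind(pool[!failAny, , drop = FALSE],
                    status[!failAny, -1, drop = FALSE])
  rownames(retained) <- NULL
  counts <- c(n_input = nrow(variants),
              n_not_consensus_pool = sum(!eligible),
              n_eligible = nrow(pool),
              info = sum(failInfo), completeness = sum(failCompl),
              consensus_transcript = sum(failConsTx),
              final_exon = sum(failFinal), af = sum(failAf),
              no_carrier = sum(failCarrier),
              unique_removed = sum(failAny),
              n_retained = sum(!failAny))
  list(retained = retained, filterStatus = status, counts = counts)
}

#' Prune directly related subjects
#'
#' Processes deduplicated pairs with PI-HAT above the threshold in
#' lexicographic (id_a, id_b) order; for each pair whose members are both
#' still retained, one member is removed uniformly at random under the seed.
#' Pairs already broken by an earlier removal are skipped, so the retained
#' set contains no pair above the threshold.
#'
#' @param subjects character vector of subject ids.
#' @param pairs data.frame(id_a, id_b, pi_hat).
#' @param threshold PI-HAT above which a pair counts as directly related.
#' @param seed integer seed for the random member choice (caller RNG state
#'   is preserved); NULL uses the current RNG stream.
#' @return list(retained, removed) character vectors.
#' @export
pruneRelatives <- function(subjects, pairs, threshold = 0.2, seed = NULL) {
  if (nrow(pairs)) {
    if (any(pairs$id_a == pairs$id_b))
      stop("self-pair in relatedness table", call. = FALSE)
    a <- pmin(pairs$id_a, pairs$id_b)
    b <- pmax(pairs$id_a, pairs$id_b)
    pairs <- data.frame(id_a = a, id_b = b, pi_hat = pairs$pi_hat,
                        stringsAsFactors = FALSE)
    pairs <- pairs[!duplicated(pairs[, c("id_a", "id_b")]), , drop = FALSE]
    pairs <- pairs[order(pairs$id_a, pairs$id_b), , drop = FALSE]
  }
  doPrune <- function() {
    retained <- subjects
    removed <- character()
    for (i in seq_len(nrow(pairs))) {
      if (pairs$pi_hat[i] <= threshold) next
      ab <- c(pairs$id_a[i], pairs$id_b[i])
      if (!all(ab %in% retained)) next
      drop <- ab[sample.int(2L, 1L)]
      retained <- setdiff(retained, drop)
      removed <- c(removed, drop)
    }
    list(retained = retained, removed = removed)
  }
  if (is.null(seed)) doPrune() else withSeed(seed, doPrune())
}

#' Collapse retained variants to gene-level carrier sets
#'
#' A subject carries a gene's LoF burden when it carries at least one
#' retained variant of that gene (hard-called dosage >= 1). Carrier sets are
#' restricted to the retained subjects; genes without carriers are dropped.
#' Summary distributions (variants per gene, LoF genes per person) are
#' attached as the `summary` attribute.
#'
#' @param retainedVariants data.frame with variant_key and gene_id for
#'   QC-retained variants; variants without a gene are logged and skipped.
#' @param carrier hard-called subject x variant carrier matrix.
#' @param subjects subject ids retained after relatedness pruning.
#' @return a [GeneCarrierSet-class] with a `summary` attribute.
#' @export
collapseToGenes <- function(retainedVariants, carrier, subjects) {
  noGene <- is.na(retainedVariants$gene_id) |
    !nzchar(retainedVariants$gene_id)
  if (any(noGene)) {
    message(sum(noGene), " retained variant(s) without gene assignment ",
            "skipped")
    retainedVariants <- retainedVariants[!noGene, , drop = FALSE]
  }
  carrier <- carrier[rownames(carrier) %in% subjects, , drop = FALSE]
  byGene <- split(retainedVariants$variant_key, retainedVariants$gene_id)
  carriersByGene <- lapply(byGene, function(keys) {
    sub <- carrier[, keys, drop = FALSE]
    rownames(sub)[rowSums(sub == 1L, na.rm = TRUE) > 0L]
  })
  keep <- lengths(carriersByGene) > 0L
  genes <- sort(names(byGene)[keep])
  obj <- new("GeneCarrierSet", geneIds = genes,
             variantsByGene = byGene[genes],
             carriersByGene = carriersByGene[genes])
  perPerson <- table(unlist(carriersByGene[genes], use.names = FALSE))
  attr(obj, "summary") <- list(
    variantsPerGene = lengths(byGene[genes]),
    lofGenesPerPerson = as.integer(perPerson),
    meanVariantsPerGene = mean(lengths(byGene[genes])))
  obj
}
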