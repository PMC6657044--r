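# Shared fixtures: a down-scaled study config, hand-built annotator call
# tables in each annotator's vocabulary, and tiny transcript models.

smallConfig <- function(seed = 1, nExpressionSamples = 80L, ...) {
  simConfig(nSubjects = 200L, nGenes = 30L,
            nExpressionSamples = nExpressionSamples,
            nRelatedPairs = 5L, nBackgroundPairs = 10L, seed = seed, ...)
}

# canonical-vocabulary raw call rows for one variant on given transcripts
rawCallA1 <- function(key, tx, effect = "stop_gained", full = "full") {
  data.frame(variant_key = key, transcript_id = tx, raw_effect = effect,
             full_effect = full, stringsAsFactors = FALSE)
}
rawCallA2 <- function(key, tx, effect = "stopgain") {
  data.frame(variant_key = key, transcript_id = tx, raw_effect = effect,
             stringsAsFactors = FALSE)
}
rawCallA3 <- function(key, tx, effect = "STOP_GAINED", impact = "HIGH",
                      biotype = "protein-coding") {
  data.frame(variant_key = key, transcript_id = tx, raw_effect = effect,
             impact = impact, biotype = biotype, stringsAsFactors = FALSE)
}

# three-exon transcript model; exon_rank follows transcription order
makeTranscript <- function(tid, gene = "G1", strand = "+",
                           exonStarts = c(100, 300, 500),
                           exonEnds = c(199, 399, 599)) {
  rk <- if (strand == "+") seq_along(exonStarts) else rev(seq_along(exonStarts))
  data.frame(transcript_id = tid, gene_id = gene, exon_rank = rk,
             start = exonStarts, end = exonEnds, strand = strand,
             stringsAsFactors = FALSE)
}

# least-squares oracle via the normal equations
normalEquations <- function(y, X) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

expect_no_related_pair <- function(retained, pairs, threshold = 0.2) {
  hot <- pairs[pairs$pi_hat > threshold, , drop = FALSE]
  both <- hot$id_a %in% retained & hot$id_b %in% retained
  expect_false(any(both))
}
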