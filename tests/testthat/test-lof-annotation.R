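# Annotator harmonization, consensus classification, hard-calling,
# final-exon logic, the QC cascade, relatedness pruning and gene collapse.

test_that("harmonization respects vocabularies and qualifier rules", {
  calls <- list(
    A1 = rbind(rawCallA1("v1", "T1"),
               rawCallA1("v2", "T1", full = "partial"),
               rawCallA1("v3", "T1", effect = "frameshift_indel"),
               rawCallA1("v4", "T1", effect = "missense")),
    A2 = rbind(rawCallA2("v1", "T1"),
               rawCallA2("v5", "T1", effect = "nonsynonymous SNV"),
               rawCallA2("v6", "T1", effect = "exonic;splicing")),
    A3 = rbind(rawCallA3("v1", "T1"),
               rawCallA3("v7", "T1", impact = "MODERATE"),
               rawCallA3("v8", "T1", biotype = "lincRNA"),
               rawCallA3("v9", "T1", effect = "SPLICE_SITE_DONOR")))
  h <- harmonizeCalls(calls)
  expect_setequal(h$variant_key[h$annotator == "A1"], c("v1", "v3"))
  expect_equal(h$canonical_effect[h$variant_key == "v3"], "frameshift")
  expect_equal(h$canonical_effect[h$variant_key == "v6"],
               "splice_disrupting")
  expect_equal(h$canonical_effect[h$variant_key == "v9"],
               "splice_disrupting")
  expect_false("v2" %in% h$variant_key)  # partial effect
  expect_false("v7" %in% h$variant_key)  # MODERATE impact
  expect_false("v8" %in% h$variant_key)  # non-coding biotype
  dropped <- attr(h, "dropped")
  expect_equal(unname(dropped$A1["unmapped"]), 1L)
  expect_equal(unname(dropped$A1["qualifier"]), 1L)
  expect_equal(unname(dropped$A2["unmapped"]), 1L)
  expect_equal(unname(dropped$A3["qualifier"]), 2L)
  expect_error(harmonizeCalls(list(VEP = rawCallA1("v1", "T1"))),
               "unknown annotator")
})

test_that("consensus needs two annotators on a shared transcript", {
  h <- harmonizeCalls(list(A1 = rawCallA1("v", "T1"),
                           A2 = rawCallA2("v", "T1")))
  cs <- consensusClassify(h)
  expect_true(cs$consensus)
  expect_equal(cs$shared_transcripts, "T1")

  h2 <- harmonizeCalls(list(A1 = rawCallA1("v", "T1"),
                            A2 = rawCallA2("v", "T2")))
  cs2 <- consensusClassify(h2)
  expect_true(cs2$any_two)
  expect_false(cs2$consensus)

  h3 <- harmonizeCalls(list(A1 = rawCallA1("v", "T1")))
  cs3 <- consensusClassify(h3)
  expect_false(cs3$any_two)
  expect_false(cs3$consensus)
})

test_that("consensus over annotator subsets on one transcript needs >= 2", {
  mk <- list(A1 = function(k) rawCallA1(k, "T1"),
             A2 = function(k) rawCallA2(k, "T1"),
             A3 = function(k) rawCallA3(k, "T1"))
  for (mask in 0:7) {
    anns <- c("A1", "A2", "A3")[bitwAnd(mask, c(1L, 2L, 4L)) > 0L]
    if (length(anns) == 0L) next
    calls <- lapply(anns, function(a) mk[[a]]("v"))
    names(calls) <- anns
    cs <- consensusClassify(harmonizeCalls(calls))
    expect_equal(cs$consensus, length(anns) >= 2L,
                 info = paste(anns, collapse = "+"))
  }
})

test_that("adding an annotator call never revokes consensus", {
  set.seed(42)
  for (rep in 1:25) {
    nA <- sample(1:3, 1)
    anns <- sample(c("A1", "A2", "A3"), nA)
    txOf <- function() sample(c("T1", "T2"), sample(1:2, 1))
    calls <- lapply(anns, function(a) {
      tx <- txOf()
      switch(a, A1 = rawCallA1("v", tx), A2 = rawCallA2("v", tx),
             A3 = rawCallA3("v", tx))
    })
    names(calls) <- anns
    before <- consensusClassify(harmonizeCalls(calls))$consensus
    extra <- setdiff(c("A1", "A2", "A3"), anns)
    if (length(extra)) {
      a <- extra[1]
      calls[[a]] <- switch(a, A1 = rawCallA1("v", c("T1", "T2")),
                           A2 = rawCallA2("v", c("T1", "T2")),
                           A3 = rawCallA3("v", c("T1", "T2")))
    } else {
      calls[["A1"]] <- rbind(calls[["A1"]], rawCallA1("v", c("T1", "T2")))
    }
    after <- consensusClassify(harmonizeCalls(calls))$consensus
    expect_true(!before || after)
  }
})

test_that("hard-calling masks below the probability threshold", {
  carrier <- matrix(c(1L, 0L, 1L, 0L), 2, 2,
                    dimnames = list(c("s1", "s2"), c("v1", "v2")))
  prob <- matrix(c(0.94, 0.95, 0.99, 0.50), 2, 2,
                 dimnames = dimnames(carrier))
  hc <- hardCallGenotypes(carrier, prob)
  expect_true(is.na(hc$carrier["s1", "v1"]))   # 0.94 < 0.95 -> missing
  expect_equal(hc$carrier["s2", "v1"], 0L)     # exactly 0.95 retained
  expect_equal(unname(hc$completeness), c(0.5, 0.5))
  prob2 <- prob; prob2[1, 1] <- 1.2
  expect_error(hardCallGenotypes(carrier, prob2), "\\[0, 1\\]")
})

test_that("completeness is the non-missing fraction", {
  n <- 100
  carrier <- matrix(0L, n, 1, dimnames = list(sprintf("s%d", 1:n), "v"))
  prob <- matrix(0.99, n, 1, dimnames = dimnames(carrier))
  prob[1:8, 1] <- 0.5
  hc <- hardCallGenotypes(carrier, prob)
  expect_equal(unname(hc$completeness), 0.92)
})

test_that("final-exon status is strand-aware", {
  plus <- makeTranscript("Tp", strand = "+")
  expect_true(isFinalExon(550, plus))
  expect_false(isFinalExon(150, plus))
  expect_false(isFinalExon(350, plus))
  # minus strand: the exon with the smallest genomic start is transcribed last
  minus <- makeTranscript("Tm", strand = "-", exonStarts = c(100, 300),
                          exonEnds = c(200, 400))
  expect_true(isFinalExon(150, minus))
  expect_false(isFinalExon(350, minus))
  expect_message(res <- isFinalExon(250, plus), "no exon")
  expect_false(res)
})

test_that("variant QC applies each filter at the stated boundary", {
  tx <- makeTranscript("T1")
  mkVar <- function(key, pos = 350, info = 0.9, af = 0.001) {
    data.frame(variant_key = key, gene_id = "G1", pos = pos,
               info_score = info, alt_allele_freq = af,
               stringsAsFactors = FALSE)
  }
  variants <- rbind(mkVar("ok"), mkVar("lowinfo", info = 0.25),
                    mkVar("edgeinfo", info = 0.3),
                    mkVar("highaf", af = 0.025),
                    mkVar("finalexon", pos = 550))
  h <- harmonizeCalls(list(
    A1 = rawCallA1(variants$variant_key, "T1"),
    A2 = rawCallA2(variants$variant_key, "T1")))
  cs <- consensusClassify(h)
  n <- 50
  carrier <- matrix(0L, n, nrow(variants),
                    dimnames = list(sprintf("s%d", 1:n),
                                    variants$variant_key))
  carrier[1, ] <- 1L
  prob <- matrix(0.99, n, nrow(variants), dimnames = dimnames(carrier))
  hc <- hardCallGenotypes(carrier, prob)
  qc <- applyVariantQC(variants, cs, hc, tx)
  st <- qc$filterStatus
  expect_equal(st$info[st$variant_key == "lowinfo"], "fail")
  expect_equal(st$info[st$variant_key == "edgeinfo"], "fail") # strictly > 0.3
  expect_equal(st$af[st$variant_key == "highaf"], "fail")
  expect_equal(st$final_exon[st$variant_key == "finalexon"], "fail")
  expect_equal(qc$retained$variant_key, "ok")
  expect_equal(unname(qc$counts["unique_removed"]), 4L)
})

test_that("final-exon failure requires every supporting transcript", {
  # T1 places the variant in its final exon, T2 does not
  tx <- rbind(makeTranscript("T1", exonStarts = c(100, 500),
                             exonEnds = c(199, 599)),
              makeTranscript("T2", exonStarts = c(100, 500, 700),
                             exonEnds = c(199, 599, 799)))
  variants <- data.frame(variant_key = "v", gene_id = "G1", pos = 550,
                         info_score = 0.9, alt_allele_freq = 0.001,
                         stringsAsFactors = FALSE)
  carrier <- matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "v"))
  prob <- matrix(0.99, 3, 1, dimnames = dimnames(carrier))
  hc <- hardCallGenotypes(carrier, prob)
  # both annotators support both transcripts: T2 rescues the variant
  h <- harmonizeCalls(list(A1 = rawCallA1("v", c("T1", "T2")),
                           A2 = rawCallA2("v", c("T1", "T2"))))
  qc <- applyVariantQC(variants, consensusClassify(h), hc, tx)
  expect_equal(qc$filterStatus$final_exon, "pass")
  # support restricted to T1 only: now every supporting transcript is final
  h1 <- harmonizeCalls(list(A1 = rawCallA1("v", "T1"),
                            A2 = rawCallA2("v", "T1")))
  qc1 <- applyVariantQC(variants, consensusClassify(h1), hc, tx)
  expect_equal(qc1$filterStatus$final_exon, "fail")
})

test_that("retained set is the conjunction of filters (order-insensitive)", {
  sim <- simulateStudy(smallConfig(seed = 12))
  h <- harmonizeCalls(sim@calls)
  cs <- consensusClassify(h)
  hc <- hardCallGenotypes(sim@genotypes$carrier, sim@genotypes$probability)
  qc <- applyVariantQC(sim@variants, cs, hc, sim@transcripts)
  st <- qc$filterStatus
  allPass <- rowSums(st[, -1] == "fail") == 0L
  expect_setequal(qc$retained$variant_key, st$variant_key[allPass])
})

test_that("relatedness pruning removes one member per related pair", {
  pairs <- data.frame(id_a = "A", id_b = "B", pi_hat = 0.3)
  pr <- pruneRelatives(c("A", "B", "C"), pairs, seed = 1)
  expect_length(pr$removed, 1L)
  expect_true(pr$removed %in% c("A", "B"))
  expect_true("C" %in% pr$retained)

  below <- data.frame(id_a = "A", id_b = "B", pi_hat = 0.15)
  pr2 <- pruneRelatives(c("A", "B"), below, seed = 1)
  expect_length(pr2$removed, 0L)

  expect_error(pruneRelatives("A", data.frame(id_a = "A", id_b = "A",
                                              pi_hat = 0.5)), "self-pair")
})

test_that("a relatedness chain leaves no retained pair, both branches", {
  pairs <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"),
                      pi_hat = c(0.3, 0.4))
  for (s in 1:20) {
    pr <- pruneRelatives(c("A", "B", "C"), pairs, seed = s)
    expect_no_related_pair(pr$retained, pairs)
    expect_gte(length(pr$removed), 1L)
    expect_lte(length(pr$removed), 2L)
  }
})

test_that("gene collapse unions carriers and honors pruning", {
  carrier <- matrix(c(1L, 0L, 0L,
                      1L, 1L, 0L), 3, 2,
                    dimnames = list(c("s1", "s2", "s3"), c("v1", "v2")))
  prob <- matrix(0.99, 3, 2, dimnames = dimnames(carrier))
  hc <- hardCallGenotypes(carrier, prob)
  rv <- data.frame(variant_key = c("v1", "v2"), gene_id = "G1",
                   stringsAsFactors = FALSE)
  gcs <- collapseToGenes(rv, hc$carrier, c("s1", "s2", "s3"))
  expect_setequal(carriersOf(gcs, "G1"), c("s1", "s2"))
  # carrier s1 pruned away
  gcs2 <- collapseToGenes(rv, hc$carrier, c("s2", "s3"))
  expect_setequal(carriersOf(gcs2, "G1"), "s2")
  # missing gene assignment is skipped, not fatal
  rv2 <- rbind(rv, data.frame(variant_key = "v3", gene_id = NA))
  expect_message(collapseToGenes(rv2, hc$carrier, c("s1", "s2")),
                 "without gene")
})

test_that("collapse conserves carriers across genes on synthetic data", {
  sim <- simulateStudy(smallConfig(seed = 13))
  hc <- hardCallGenotypes(sim@genotypes$carrier, sim@genotypes$probability)
  rv <- sim@variants[, c("variant_key", "gene_id")]
  gcs <- collapseToGenes(rv, hc$carrier, rownames(hc$carrier))
  for (g in sample(geneIds(gcs), 5)) {
    keys <- variantsOf(gcs, g)
    manual <- rownames(hc$carrier)[
      rowSums(hc$carrier[, keys, drop = FALSE] == 1L, na.rm = TRUE) > 0L]
    expect_setequal(carriersOf(gcs, g), manual)
  }
})
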