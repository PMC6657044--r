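# Opposite-sign concordance rule, tallies, GO keyword filter and report.

mkGeno <- function(gene, trait, beta, p = 0.01) {
  data.frame(gene = gene, trait = trait, p_value = p,
             beta_untransformed = beta, stringsAsFactors = FALSE)
}
mkExpr <- function(gene, trait, tissue, beta, p = 0.01) {
  data.frame(gene = gene, trait = trait, tissue = tissue, beta = beta,
             p_value = p, stringsAsFactors = FALSE)
}

test_that("the two worked sign examples evaluate as concordant", {
  # LoF lowers glucose, liver expression positively tracks glucose
  c1 <- assessConcordance(mkGeno("DGAT2", "glucose", -19, p = 0.049),
                          mkExpr("DGAT2", "glucose", "LIV", 0.56,
                                 p = 0.024))
  expect_equal(c1$verdict, "concordant")
  expect_equal(c1$concordant_tissues, "LIV")
  # LoF raises glucose, skeletal-muscle expression negatively tracks it
  c2 <- assessConcordance(mkGeno("ACOT11", "glucose", 40, p = 0.059),
                          mkExpr("ACOT11", "glucose", "SKLM", -0.28,
                                 p = 0.040))
  expect_equal(c2$verdict, "concordant")
})

test_that("concordance holds exactly when the signs differ", {
  for (sg in c(-1, 1)) for (se in c(-1, 1)) {
    cc <- assessConcordance(mkGeno("G", "t", sg * 2),
                            mkExpr("G", "t", "LIV", se * 0.5))
    expect_equal(cc$verdict == "concordant", sg * se < 0)
  }
})

test_that("concordance is symmetric under a joint sign flip", {
  set.seed(20)
  for (rep in 1:20) {
    bg <- rnorm(1); be <- rnorm(1)
    if (bg == 0 || be == 0) next
    v1 <- assessConcordance(mkGeno("G", "t", bg),
                            mkExpr("G", "t", "AOR", be))$verdict
    v2 <- assessConcordance(mkGeno("G", "t", -bg),
                            mkExpr("G", "t", "AOR", -be))$verdict
    expect_equal(v1, v2)
  }
})

test_that("missing expression support gives verdict untested; zero beta errors", {
  cc <- assessConcordance(mkGeno("G", "t", -2),
                          mkExpr("G", "t", "LIV", 0.5, p = 0.2))
  expect_equal(cc$verdict, "untested")
  expect_error(assessConcordance(mkGeno("G", "t", 0),
                                 mkExpr("G", "t", "LIV", 0.5)),
               "zero genotype beta")
  expect_error(assessConcordance(mkGeno("G", "t", -2),
                                 mkExpr("G", "t", "LIV", 0)),
               "zero expression beta")
})

test_that("tightening the expression threshold never makes discordant concordant", {
  set.seed(21)
  for (rep in 1:20) {
    e <- do.call(rbind, lapply(1:5, function(i)
      mkExpr("G", "t", c("AOR", "LIV", "MAM", "SF", "SKLM")[i],
             rnorm(1), p = runif(1, 0, 0.1))))
    g <- mkGeno("G", "t", rnorm(1))
    if (g$beta_untransformed == 0) next
    vLoose <- assessConcordance(g, e, alphaExpression = 0.08)$verdict
    vTight <- assessConcordance(g, e, alphaExpression = 0.02)$verdict
    if (vLoose == "discordant") expect_false(vTight == "concordant")
  }
})

test_that("tallies count genes, pairs and tissue triples", {
  cc <- assessConcordance(
    mkGeno("G1", "glucose", -2),
    rbind(mkExpr("G1", "glucose", "LIV", 0.5),
          mkExpr("G1", "glucose", "AOR", 0.3)))
  expect_equal(unname(tallyConcordance(cc)), c(1L, 1L, 2L))
  empty <- assessConcordance(mkGeno("G", "t", 1)[0, ],
                             mkExpr("G", "t", "LIV", 1)[0, ])
  expect_equal(unname(tallyConcordance(empty)), c(0L, 0L, 0L))
})

test_that("tallies match brute-force set construction on random tables", {
  set.seed(22)
  tissues <- c("AOR", "BLOOD", "LIV", "MAM", "SF", "SKLM", "VAF")
  for (rep in 1:30) {
    genes <- paste0("G", 1:8)
    traits <- c("glucose", "ldl", "sbp")
    g <- do.call(rbind, lapply(1:12, function(i)
      mkGeno(sample(genes, 1), sample(traits, 1),
             sample(c(-1, 1), 1) * runif(1, 0.1, 2),
             p = runif(1, 0, 0.2))))
    g <- g[!duplicated(g[, c("gene", "trait")]), ]
    e <- do.call(rbind, lapply(1:40, function(i)
      mkExpr(sample(genes, 1), sample(traits, 1), sample(tissues, 1),
             sample(c(-1, 1), 1) * runif(1, 0.05, 1),
             p = runif(1, 0, 0.1))))
    e <- e[!duplicated(e[, c("gene", "trait", "tissue")]), ]
    cc <- assessConcordance(g, e)
    got <- tallyConcordance(cc)
    # brute force over the raw tables
    gs <- g[g$p_value < 0.1, ]
    es <- e[e$p_value < 0.05, ]
    concPairs <- character(); concGenes <- character(); triples <- 0L
    for (i in seq_len(nrow(gs))) {
      ei <- es[es$gene == gs$gene[i] & es$trait == gs$trait[i], ]
      opp <- sign(ei$beta) != sign(gs$beta_untransformed[i])
      if (nrow(ei) && any(opp)) {
        concPairs <- c(concPairs, paste(gs$gene[i], gs$trait[i]))
        concGenes <- c(concGenes, gs$gene[i])
        triples <- triples + sum(opp)
      }
    }
    expect_equal(unname(got), c(length(unique(concGenes)),
                                length(unique(concPairs)), triples))
  }
})

test_that("GO keyword filter passes domain terms and reports coverage", {
  go <- data.frame(
    gene_id = c("ACOT11", "X1", "X2"),
    go_id = c("GO:0006631", "GO:0006281", "GO:0005515"),
    term_name = c("fatty acid metabolic process", "DNA repair",
                  "protein binding"),
    aspect = c("P", "P", "F"), stringsAsFactors = FALSE)
  pairs <- data.frame(gene = c("ACOT11", "X1", "X2"),
                      trait = c("glucose", "glucose", "ldl"),
                      stringsAsFactors = FALSE)
  gf <- goFilter(pairs, go)
  r <- gf$results
  expect_true(r$passed[r$gene == "ACOT11"])     # domain-level match
  expect_false(r$passed[r$gene == "X1"])        # irrelevant BP term
  expect_false(r$passed[r$gene == "X2"])        # no BP annotation at all
  expect_equal(gf$coverage$n_with_bp, 2L)       # X2 outside the numerator
  expect_equal(gf$coverage$fraction_with_bp, 2 / 3)
  expect_error(goFilter(pairs, go, keywords = character()), "nonempty")
})

test_that("malformed GO records are skipped, not fatal", {
  go <- data.frame(gene_id = c("G1", ""), go_id = c("GO:1", "GO:2"),
                   term_name = c("cholesterol metabolic process", "x"),
                   aspect = c("P", "P"), stringsAsFactors = FALSE)
  expect_message(gf <- goFilter(data.frame(gene = "G1", trait = "ldl"), go),
                 "malformed")
  expect_true(gf$results$passed)
})

test_that("the report is complete, deterministic and JSON-serializable", {
  sim <- simulateStudy(smallConfig(seed = 40))
  r1 <- suppressMessages(runLofPipeline(sim))
  r2 <- suppressMessages(runLofPipeline(sim))
  expect_identical(r1$report, r2$report)
  js <- jsonlite::toJSON(r1$report, auto_unbox = TRUE, digits = NA)
  expect_true(jsonlite::validate(js))
  broken <- r1[setdiff(names(r1), c("tally", "report"))]
  expect_error(buildReport(broken), "tally")
})
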