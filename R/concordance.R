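# Integration of genotype-level and expression-level evidence: the
# opposite-sign concordance rule, unique gene / gene-trait /
# gene-trait-tissue tallies, and the GO biological-process keyword filter.

#' Default CVD-metabolic GO keyword set
#'
#' A single global keyword list applied to biological-process term names
#' (case-insensitive substring match), covering the blood-pressure,
#' glycaemic and lipid domains of the ten study traits. Matching is at the
#' domain level rather than per-trait: a fatty-acid term is accepted for a
#' glucose association.
#'
#' @return character vector of keywords.
#' @export
cvdGoKeywords <- function() {
  c("blood pressure", "glucose", "glucagon", "insulin", "cholesterol",
    "triglyceride", "lipid", "fatty acid", "lipoprotein")
}

#' Assess genotype/expression concordance per gene-trait
#'
#' LoF carriage and low expression are assumed to act in the same
#' direction, so a gene-trait pair is concordant when at least one
#' significant tissue association has an expression beta of sign opposite
#' to the genotype beta (a negative LoF effect with a positive
#' expression-trait slope, or vice versa), regardless of which tissue.
#' Significant gene-traits with no significant expression row are
#' `untested`; discordant pairs are retained with verdict `discordant`.
#'
#' @param genotypeTab genotype association table with columns gene, trait,
#'   p_value, beta_untransformed (see [runGeneTraitScan()]).
#' @param expressionTab expression association table with columns gene,
#'   trait, tissue, beta, p_value (see [runTissueScan()]).
#' @param alphaGenotype,alphaExpression significance thresholds applied to
#'   the two tables (defaults 0.1 and 0.05).
#' @return data.frame(gene, trait, beta_genotype, p_genotype,
#'   n_significant_tissues, concordant_tissues (comma-joined), verdict).
#'   A `tissueDetail` attribute holds one row per significant
#'   gene-trait-tissue with its concordance flag.
#' @export
assessConcordance <- function(genotypeTab, expressionTab,
                              alphaGenotype = 0.1,
                              alphaExpression = 0.05) {
  g <- genotypeTab[genotypeTab$p_value < alphaGenotype, , drop = FALSE]
  e <- expressionTab[expressionTab$p_value < alphaExpression, , drop = FALSE]
  if (nrow(g) && any(g$beta_untransformed == 0))
    stop("zero genotype beta on a significant row: sign undefined",
         call. = FALSE)
  if (nrow(e) && any(e$beta == 0))
    stop("zero expression beta on a significant row: sign undefined",
         call. = FALSE)
  detail <- list()
  rows <- lapply(seq_len(nrow(g)), function(i) {
    gi <- g[i, ]
    ei <- e[e$gene == gi$gene & e$trait == gi$trait, , drop = FALSE]
    if (nrow(ei) == 0L) {
      return(data.frame(gene = gi$gene, trait = gi$trait,
                        beta_genotype = gi$beta_untransformed,
                        p_genotype = gi$p_value,
                        n_significant_tissues = 0L,
                        concordant_tissues = "",
                        verdict = "untested", stringsAsFactors = FALSE))
    }
    conc <- sign(gi$beta_untransformed) * sign(ei$beta) < 0
    detail[[length(detail) + 1L]] <<- data.frame(
      gene = gi$gene, trait = gi$trait, tissue = ei$tissue,
      beta_genotype = gi$beta_untransformed, beta_expression = ei$beta,
      p_expression = ei$p_value, concordant = conc,
      stringsAsFactors = FALSE)
    data.frame(gene = gi$gene, trait = gi$trait,
               beta_genotype = gi$beta_untransformed,
               p_genotype = gi$p_value,
               n_significant_tissues = nrow(ei),
               concordant_tissues = paste(sort(ei$tissue[conc]),
                                          collapse = ","),
               verdict = if (any(conc)) "concordant" else "discordant",
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), trait = character(),
               beta_genotype = numeric(), p_genotype = numeric(),
               n_significant_tissues = integer(),
               concordant_tissues = character(), verdict = character())
  rownames(out) <- NULL
  attr(out, "tissueDetail") <- if (length(detail)) do.call(rbind, detail)
  else data.frame(gene = character(), trait = character(),
                  tissue = character(), beta_genotype = numeric(),
                  beta_expression = numeric(), p_expression = numeric(),
                  concordant = logical())
  out
}

#' Tally concordant genes, gene-trait pairs and gene-trait-tissue triples
#'
#' @param concordance output of [assessConcordance()].
#' @return named integer vector: genes (unique concordant genes), pairs
#'   (concordant gene-trait pairs), triples (concordant gene-trait-tissue
#'   combinations). Always triples >= pairs >= genes.
#' @export
tallyConcordance <- function(concordance) {
  conc <- concordance[concordance$verdict == "concordant", , drop = FALSE]
  tisLists <- strsplit(conc$concordant_tissues, ",", fixed = TRUE)
  c(genes = length(unique(conc$gene)),
    pairs = nrow(conc),
    triples = sum(vapply(tisLists, function(x) sum(nzchar(x)), integer(1))))
}

#' GO biological-process keyword filter for target nomination
#'
#' Stage 1 reports, among the concordant genes, those with at least one
#' biological-process annotation of any kind (coverage). Stage 2 passes
#' gene-traits whose gene has at least one BP term name matching any
#' keyword, case-insensitive substring, with the whole keyword set applied
#' globally rather than per trait.
#'
#' @param concordantPairs data.frame with columns gene and trait (typically
#'   the concordant rows of [assessConcordance()]).
#' @param goAnnotations data.frame(gene_id, go_id, term_name, aspect);
#'   BP terms have aspect "P". Records with missing fields are skipped and
#'   logged.
#' @param keywords keyword set, see [cvdGoKeywords()].
#' @return list(results = data.frame(gene, trait, matched_terms, passed),
#'   coverage = list(n_genes, n_with_bp, fraction_with_bp, n_passed_genes,
#'   n_passed_pairs)).
#' @export
goFilter <- function(concordantPairs, goAnnotations,
                     keywords = cvdGoKeywords()) {
  if (length(keywords) == 0L)
    stop("keyword configuration must be nonempty", call. = FALSE)
  need <- c("gene_id", "go_id", "term_name", "aspect")
  ok <- stats::complete.cases(goAnnotations[, need]) &
    rowSums(goAnnotations[, need] == "" | is.na(goAnnotations[, need])) == 0L
  if (any(!ok))
    message(sum(!ok), " malformed GO record(s) skipped")
  go <- goAnnotations[ok, , drop = FALSE]
  bp <- go[go$aspect %in% c("P", "BP"), , drop = FALSE]

  genes <- unique(concordantPairs$gene)
  hasBp <- genes %in% bp$gene_id

  matchedByGene <- lapply(genes, function(g) {
    terms <- bp[bp$gene_id == g, , drop = FALSE]
    if (nrow(terms) == 0L) return(character())
    hit <- vapply(terms$term_name, function(tn)
      any(vapply(keywords, function(kw)
        grepl(kw, tn, ignore.case = TRUE, fixed = FALSE), logical(1))),
      logical(1))
    if (!any(hit)) return(character())
    unique(paste0(terms$go_id[hit], " (", terms$term_name[hit], ")"))
  })
  names(matchedByGene) <- genes

  results <- data.frame(
    gene = concordantPairs$gene, trait = concordantPairs$trait,
    matched_terms = vapply(concordantPairs$gene, function(g)
      paste(matchedByGene[[g]], collapse = "; "), character(1)),
    passed = vapply(concordantPairs$gene, function(g)
      length(matchedByGene[[g]]) > 0L, logical(1)),
    stringsAsFactors = FALSE)
  rownames(results) <- NULL
  list(results = results,
       coverage = list(
         n_genes = length(genes),
         n_with_bp = sum(hasBp),
         fraction_with_bp = if (length(genes)) mean(hasBp) else NA_real_,
         n_passed_genes = length(unique(results$gene[results$passed])),
         n_passed_pairs = sum(results$passed)))
}
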