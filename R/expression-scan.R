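# Multi-tissue expression-trait association: CPM-based expressed-gene
# filtering (when starting from raw counts) and per-gene OLS of
# trait ~ expression + age + sex + BMI.

#' Filter genes by the counts-per-million expression rule
#'
#' A gene is removed when its CPM (count x 1e6 / library size, via
#' [edgeR::cpm()]) is below 1 in more than 90% of samples; a gene at exactly
#' 90% is retained. The rule is invariant to uniform scaling of library
#' sizes.
#'
#' @param counts nonnegative integer gene x sample count matrix.
#' @param cpmMin CPM detection threshold (default 1).
#' @param maxLowFraction largest tolerated fraction of below-threshold
#'   samples (default 0.9, strict inequality).
#' @return character vector of retained gene names.
#' @export
cpmFilter <- function(counts, cpmMin = 1, maxLowFraction = 0.9) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  libSize <- colSums(counts)
  if (any(libSize == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libSize == 0], collapse = ", "),
         call. = FALSE)
  cpm <- edgeR::cpm(counts)
  lowFrac <- rowMeans(cpm < cpmMin)
  rownames(counts)[lowFrac <= maxLowFraction]
}

#' Association between one gene's expression and a clinical trait
#'
#' Ordinary least squares of trait on expression with age, sex and BMI as
#' covariates; samples with any missing value are dropped and counted. The
#' reported beta and two-sided p-value belong to the expression coefficient.
#'
#' @param expr numeric expression values (one gene across samples).
#' @param trait numeric trait values.
#' @param age,sex,bmi sample covariates.
#' @return list(beta, p_value, n, nDropped).
#' @export
fitExpressionTrait <- function(expr, trait, age, sex, bmi) {
  d <- data.frame(trait = trait, expr = expr, age = age, sex = sex,
                  bmi = bmi)
  complete <- stats::complete.cases(d)
  d <- d[complete, , drop = FALSE]
  if (nrow(d) < 6L)
    stop("need at least 6 complete samples", call. = FALSE)
  for (col in c("expr", "age", "sex", "bmi"))
    if (length(unique(d[[col]])) == 1L)
      stop("rank deficiency: column constant: ", col, call. = FALSE)
  fit <- stats::lm(trait ~ expr + age + sex + bmi, data = d)
  sm <- summary(fit)$coefficients
  list(beta = unname(sm["expr", "Estimate"]),
       p_value = unname(sm["expr", "Pr(>|t|)"]),
       n = nrow(d), nDropped = sum(!complete))
}

#' Scan candidate genes against traits across tissues
#'
#' For every tissue, every candidate gene present in that tissue's matrix
#' and every trait column, fits [fitExpressionTrait()] and records one
#' gene-trait-tissue row. Genes absent from a tissue are skipped and logged.
#'
#' @param expression named per-tissue list: list(expr = gene x sample
#'   normalized matrix, samples = data.frame with sample_id, age, sex, bmi
#'   and one column per trait), as produced by [simulateExpression()].
#' @param candidates character vector of gene ids (typically the
#'   genotype-scan significant set).
#' @param traits trait codes to test; default every configured trait column
#'   present in the sample tables.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame(gene, trait, tissue, beta, p_value, n, significant).
#' @export
runTissueScan <- function(expression, candidates, traits = NULL,
                          alpha = 0.05) {
  rows <- list()
  for (tis in names(expression)) {
    ex <- expression[[tis]]
    samp <- ex$samples
    if (is.null(traits)) {
      traits <- setdiff(names(samp), c("sample_id", "age", "sex", "bmi"))
    }
    absent <- setdiff(candidates, rownames(ex$expr))
    if (length(absent))
      message(length(absent), " candidate gene(s) absent from tissue ",
              tis, ": ", paste(utils::head(absent, 3L), collapse = ", "),
              if (length(absent) > 3L) " ..." else "")
    for (gene in intersect(candidates, rownames(ex$expr))) {
      ev <- ex$expr[gene, samp$sample_id]
      for (trait in intersect(traits, names(samp))) {
        ft <- fitExpressionTrait(ev, samp[[trait]], samp$age, samp$sex,
                                 samp$bmi)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, trait = trait, tissue = tis, beta = ft$beta,
          p_value = ft$p_value, n = ft$n,
          significant = ft$p_value < alpha, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), trait = character(), tissue = character(),
               beta = numeric(), p_value = numeric(), n = integer(),
               significant = logical())
  rownames(out) <- NULL
  out
}
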