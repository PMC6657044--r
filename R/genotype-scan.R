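# Gene-trait association scan: per-trait Box-Cox selection on the
# covariates-only model, transformed-scale test of the gene carrier term,
# and untransformed re-estimation of the effect size.

buildCovariateMatrix <- function(covariates) {
  need <- c("sex", "age", "PC1", "PC2", "PC3", "PC4", "PC5")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("covariates table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cbind(`(Intercept)` = 1,
        as.matrix(covariates[, need, drop = FALSE]))
}

#' Scan genes for carrier-trait association
#'
#' For every trait: (1) positive responses are enforced by an additive
#' offset when the trait medians include non-positive values (logged in the
#' lambda table); (2) the Box-Cox parameter is selected on the
#' covariates-only model ([selectLambda()]); (3) for every gene with at
#' least `minCarriers` carriers having the trait, the transformed trait is
#' regressed on carrier status + sex + age + PC1..PC5 by Gaussian IRLS and
#' the two-sided p-value of the carrier coefficient is recorded; (4) the
#' effect size beta and its t-statistic are re-estimated without response
#' transformation, so beta is in trait units.
#'
#' @param carrierSet a [GeneCarrierSet-class] (carriers already restricted
#'   to retained subjects).
#' @param traitProfiles a [TraitProfileSet-class] or its profiles
#'   data.frame.
#' @param covariates data.frame(subject_id, sex, age, PC1..PC5); only
#'   subjects present here are analyzed, so relatedness pruning is applied
#'   by passing the pruned cohort.
#' @param alpha significance threshold on the transformed-scale p
#'   (default 0.1, uncorrected).
#' @param minCarriers minimum carriers with trait data (default 3).
#' @param grid,jacobian passed to [selectLambda()].
#' @return list(associations = data.frame(gene, trait, n_carriers, n, lambda,
#'   p_value, beta_untransformed, t_stat, significant),
#'   lambdaSelection = per-trait data.frame(trait, lambda, offset, n),
#'   nTested, nSignificant).
#' @export
runGeneTraitScan <- function(carrierSet, traitProfiles, covariates,
                             alpha = 0.1, minCarriers = 3L,
                             grid = seq(-2, 2, by = 0.5), jacobian = TRUE) {
  prof <- if (is(traitProfiles, "TraitProfileSet")) profiles(traitProfiles)
  else traitProfiles
  rows <- list()
  lamRows <- list()
  for (trait in unique(prof$trait)) {
    pt <- prof[prof$trait == trait, , drop = FALSE]
    idx <- match(pt$subject_id, covariates$subject_id)
    keep <- !is.na(idx)
    pt <- pt[keep, , drop = FALSE]
    cv <- covariates[idx[keep], , drop = FALSE]
    y <- pt$median_value
    offset <- 0
    if (any(y <= 0)) {
      offset <- 1 - min(y)
      message("trait ", trait, ": shifting response by ", signif(offset, 4),
              " to enforce positivity before Box-Cox")
      y <- y + offset
    }
    X0 <- buildCovariateMatrix(cv)
    sel <- selectLambda(y, X0[, -1, drop = FALSE], grid = grid,
                        jacobian = jacobian)
    lamRows[[trait]] <- data.frame(trait = trait, lambda = sel$lambda,
                                   offset = offset, n = length(y),
                                   stringsAsFactors = FALSE)
    z <- boxcoxTransform(y, sel$lambda)
    yRaw <- pt$median_value
    for (gene in geneIds(carrierSet)) {
      carr <- as.numeric(pt$subject_id %in% carriersOf(carrierSet, gene))
      nc <- sum(carr)
      if (nc < minCarriers) next
      X <- cbind(X0[, 1, drop = FALSE], gene = carr, X0[, -1, drop = FALSE])
      fitT <- fitIRLS(z, X)
      p <- unname(fitT$pvalue["gene"])
      fitU <- fitIRLS(yRaw, X)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, trait = trait, n_carriers = nc, n = length(y),
        lambda = sel$lambda, p_value = p,
        beta_untransformed = unname(fitU$coefficients["gene"]),
        t_stat = unname(fitU$tstat["gene"]),
        significant = p < alpha, stringsAsFactors = FALSE)
    }
  }
  assoc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), trait = character(),
               n_carriers = integer(), n = integer(), lambda = numeric(),
               p_value = numeric(), beta_untransformed = numeric(),
               t_stat = numeric(), significant = logical())
  rownames(assoc) <- NULL
  list(associations = assoc,
       lambdaSelection = do.call(rbind, lamRows),
       nTested = nrow(assoc), nSignificant = sum(assoc$significant))
}
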