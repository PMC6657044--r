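#' Accessors for study containers
#'
#' Accessor generics for the S4 containers: `cohort()`, `variantTable()`,
#' `truthTable()` and `simConfigOf()` for [LofStudySim-class];
#' `geneIds()`, `carriersOf()` and `variantsOf()` for [GeneCarrierSet-class];
#' `profiles()`, `exclusions()` and `qcSummary()` for [TraitProfileSet-class].
#'
#' @param x the container object.
#' @param gene a gene identifier (for `carriersOf`/`variantsOf`).
#' @return The requested slot content; `carriersOf` and `variantsOf` return a
#'   character vector for one gene.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))
#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("simConfigOf", function(x) standardGeneric("simConfigOf"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("carriersOf", function(x, gene) standardGeneric("carriersOf"))
#' @rdname accessors
#' @export
setGeneric("variantsOf", function(x, gene) standardGeneric("variantsOf"))
#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname accessors
#' @export
setGeneric("qcSummary", function(x) standardGeneric("qcSummary"))

#' @rdname accessors
setMethod("cohort", "LofStudySim", function(x) x@cohort)
#' @rdname accessors
setMethod("variantTable", "LofStudySim", function(x) x@variants)
#' @rdname accessors
setMethod("truthTable", "LofStudySim", function(x) x@truth)
#' @rdname accessors
setMethod("simConfigOf", "LofStudySim", function(x) x@config)

#' @rdname accessors
setMethod("geneIds", "GeneCarrierSet", function(x) x@geneIds)
#' @rdname accessors
setMethod("carriersOf", "GeneCarrierSet", function(x, gene) {
  if (!gene %in% x@geneIds) stop("unknown gene: ", gene)
  x@carriersByGene[[gene]]
})
#' @rdname accessors
setMethod("variantsOf", "GeneCarrierSet", function(x, gene) {
  if (!gene %in% x@geneIds) stop("unknown gene: ", gene)
  x@variantsByGene[[gene]]
})

#' @describeIn GeneCarrierSet number of genes with at least one carrier.
#' @param x a `GeneCarrierSet`.
#' @export
setMethod("length", "GeneCarrierSet", function(x) length(x@geneIds))

#' @rdname accessors
setMethod("profiles", "TraitProfileSet", function(x) x@profiles)
#' @rdname accessors
setMethod("exclusions", "TraitProfileSet", function(x) x@exclusions)
#' @rdname accessors
setMethod("qcSummary", "TraitProfileSet", function(x) x@summary)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSubjects, "subjects,", object@nGenes, "genes,",
      nrow(object@traits), "traits,", nrow(object@plantedEffects),
      "planted effects\n")
  cat("  tissues:", paste(object@tissues, collapse = ", "),
      "| seed:", object@seed, "\n")
})

setMethod("show", "LofStudySim", function(object) {
  cat("LofStudySim:", nrow(object@cohort), "subjects,",
      nrow(object@variants), "variants,",
      nrow(object@measurements), "trait measurements,",
      length(object@expression), "expression tissues\n")
})

setMethod("show", "GeneCarrierSet", function(object) {
  nc <- lengths(object@carriersByGene)
  cat("GeneCarrierSet:", length(object@geneIds), "genes;",
      sum(lengths(object@variantsByGene)), "retained variants; carriers/gene",
      if (length(nc)) sprintf("median %s, max %s", stats::median(nc), max(nc))
      else "none", "\n")
})

setMethod("show", "TraitProfileSet", function(object) {
  cat("TraitProfileSet:", nrow(object@profiles), "subject-trait medians;",
      nrow(object@exclusions), "excluded measurements\n")
  if (nrow(object@exclusions))
    print(table(object@exclusions$reason))
})
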