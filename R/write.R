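# Plain-text serialization of a simulated study: minimal VCF for variant
# sites, headered TSVs for everything else, JSON for the truth table.

writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated study to a directory
#'
#' Serializes every table of a [LofStudySim-class] as plain text: the
#' variant sites as a minimal VCF (INFO fields INFO_SCORE, AF,
#' COMPLETENESS is computed downstream and not stored), the genotype
#' carrier/probability calls as a long-format TSV, the three annotator call
#' tables, the transcript models, measurements, medications, relatedness,
#' per-tissue expression matrices with sample covariates, GO annotations,
#' and the truth table as JSON.
#'
#' @param sim a [LofStudySim-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(sim, dir) {
  if (!is(sim, "LofStudySim"))
    stop("sim must be a LofStudySim", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add <- function(f) files <<- c(files, f)

  # minimal VCF
  v <- sim@variants
  vcf <- file.path(dir, "variants.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=INFO_SCORE,Number=1,Type=Float,Description=\"Imputation INFO score\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tINFO_SCORE=%.4f;AF=%.6f;GENE=%s",
                  v$chrom, v$pos, v$variant_key, v$ref, v$alt,
                  v$info_score, v$alt_allele_freq, v$gene_id)
  writeLines(c(hdr, body), vcf)
  add(vcf)

  # long-format genotype calls
  gt <- sim@genotypes
  long <- data.frame(
    subject_id = rep(rownames(gt$carrier), ncol(gt$carrier)),
    variant_key = rep(colnames(gt$carrier), each = nrow(gt$carrier)),
    carrier = as.integer(gt$carrier),
    probability = round(as.numeric(gt$probability), 4))
  f <- file.path(dir, "genotypes.tsv"); writeTsv(long, f); add(f)

  for (ann in names(sim@calls)) {
    f <- file.path(dir, sprintf("calls_%s.tsv", ann))
    writeTsv(sim@calls[[ann]], f); add(f)
  }
  for (nm in c("cohort", "transcripts", "measurements", "medications",
               "relatedness", "goAnnotations")) {
    f <- file.path(dir, paste0(
      switch(nm, goAnnotations = "go_annotations", nm), ".tsv"))
    writeTsv(slot(sim, nm), f); add(f)
  }
  for (tis in names(sim@expression)) {
    ex <- sim@expression[[tis]]
    f <- file.path(dir, sprintf("expression_%s.tsv", tis))
    writeTsv(data.frame(gene_id = rownames(ex$expr),
                        round(ex$expr, 5), check.names = FALSE), f)
    add(f)
    f <- file.path(dir, sprintf("expression_samples_%s.tsv", tis))
    writeTsv(ex$samples, f); add(f)
  }
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(sim@truth, f, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  add(f)
  invisible(files)
}

#' Read back the tables of a serialized simulation
#'
#' Re-parses the files written by [writeSimulation()] into plain tables and
#' matrices (the minimal VCF included), for pipelines starting from files
#' rather than a live [LofStudySim-class].
#'
#' @param dir directory written by [writeSimulation()].
#' @return named list: variants, genotypes (carrier/probability matrices),
#'   calls, cohort, transcripts, measurements, medications, relatedness,
#'   expression, goAnnotations, truth.
#' @export
readSimulationTables <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  vcfLines <- readLines(file.path(dir, "variants.vcf"))
  body <- vcfLines[!startsWith(vcfLines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(parts, `[[`, character(1), 8L)
  getInfo <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    sub(paste0(key, "="), "", m)
  }
  variants <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
    variant_key = vapply(parts, `[[`, character(1), 3L),
    ref = vapply(parts, `[[`, character(1), 4L),
    alt = vapply(parts, `[[`, character(1), 5L),
    info_score = as.numeric(getInfo("INFO_SCORE")),
    alt_allele_freq = as.numeric(getInfo("AF")),
    gene_id = getInfo("GENE"),
    stringsAsFactors = FALSE)

  long <- rd("genotypes.tsv")
  subjects <- unique(long$subject_id)
  keys <- unique(long$variant_key)
  carrier <- matrix(long$carrier, nrow = length(subjects),
                    dimnames = list(subjects, keys))
  probability <- matrix(long$probability, nrow = length(subjects),
                        dimnames = list(subjects, keys))

  callFiles <- list.files(dir, pattern = "^calls_.*\\.tsv$")
  calls <- lapply(callFiles, rd)
  names(calls) <- sub("^calls_(.*)\\.tsv$", "\\1", callFiles)

  tisFiles <- list.files(dir, pattern = "^expression_samples_.*\\.tsv$")
  tissues <- sub("^expression_samples_(.*)\\.tsv$", "\\1", tisFiles)
  expression <- lapply(tissues, function(tis) {
    em <- rd(sprintf("expression_%s.tsv", tis))
    expr <- as.matrix(em[, -1, drop = FALSE])
    rownames(expr) <- em$gene_id
    samples <- rd(sprintf("expression_samples_%s.tsv", tis))
    colnames(expr) <- samples$sample_id
    list(expr = expr, samples = samples)
  })
  names(expression) <- tissues

  list(variants = variants,
       genotypes = list(carrier = carrier, probability = probability),
       calls = calls, cohort = rd("cohort.tsv"),
       transcripts = rd("transcripts.tsv"),
       measurements = rd("measurements.tsv"),
       medications = rd("medications.tsv"),
       relatedness = rd("relatedness.tsv"),
       expression = expression,
       goAnnotations = rd("go_annotations.tsv"),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
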