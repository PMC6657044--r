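# EMR trait-stream QC: mislabel -> medication -> outlier filters, then a
# single median per subject per trait, with full exclusion accounting.

checkMeasurements <- function(measurements) {
  need <- c("subject_id", "trait", "value", "unit", "date")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurements table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(measurements)
}

#' Filter mislabeled measurements
#'
#' A measurement is mislabeled when its recorded unit differs from the
#' trait's expected unit, or its value is non-finite or outside the trait's
#' hard plausibility range.
#'
#' @param measurements data.frame(subject_id, trait, value, unit, date).
#' @param traitConfig data.frame with columns trait, unit, hardMin, hardMax
#'   (see [defaultTraitConfig()]); every measured trait must be configured.
#' @return list(kept, excluded) data.frames; `excluded` gains
#'   reason = "mislabel".
#' @export
filterMislabels <- function(measurements, traitConfig) {
  checkMeasurements(measurements)
  unconfigured <- setdiff(unique(measurements$trait), traitConfig$trait)
  if (length(unconfigured))
    stop("no trait configuration for: ",
         paste(unconfigured, collapse = ", "), call. = FALSE)
  idx <- match(measurements$trait, traitConfig$trait)
  bad <- measurements$unit != traitConfig$unit[idx] |
    !is.finite(measurements$value) |
    measurements$value < traitConfig$hardMin[idx] |
    measurements$value > traitConfig$hardMax[idx]
  excluded <- measurements[bad, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "mislabel"
  else excluded$reason <- character()
  list(kept = measurements[!bad, , drop = FALSE], excluded = excluded)
}

#' Filter medication-affected measurements
#'
#' A measurement is excluded when its date lies inside [start, end]
#' (end-inclusive; a missing end means an ongoing prescription) of any
#' interval of the same subject whose medication class affects the measured
#' trait. Disease-driven exclusions use the same mechanism via pseudo-classes.
#'
#' @param measurements data.frame(subject_id, trait, value, unit, date).
#' @param medications data.frame(subject_id, med_class, start, end).
#' @param medMap data.frame(medClass, trait): which traits each class
#'   affects (see [defaultMedicationEffects()]; the shift column is ignored).
#' @return list(kept, excluded) with reason = "medication" on exclusions.
#' @export
filterMedicationAffected <- function(measurements, medications, medMap) {
  checkMeasurements(measurements)
  if (nrow(medications) &&
      any(!is.na(medications$end) & medications$start > medications$end))
    stop("medication interval with start > end", call. = FALSE)
  bad <- rep(FALSE, nrow(measurements))
  if (nrow(medications) && nrow(medMap)) {
    key <- paste(medMap$medClass, medMap$trait, sep = "\r")
    m <- merge(cbind(measurements[, c("subject_id", "trait", "date")],
                     i = seq_len(nrow(measurements))),
               medications, by = "subject_id")
    if (nrow(m)) {
      affected <- paste(m$med_class, m$trait, sep = "\r") %in% key
      hit <- affected & m$date >= m$start & (is.na(m$end) | m$date <= m$end)
      bad[unique(m$i[hit])] <- TRUE
    }
  }
  excluded <- measurements[bad, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "medication"
  else excluded$reason <- character()
  list(kept = measurements[!bad, , drop = FALSE], excluded = excluded)
}

#' Filter outlier measurements
#'
#' Default rule: per trait, exclude values farther than `nMad` scaled median
#' absolute deviations (stats::mad, normal-consistent) from the cohort-wide
#' median of the surviving measurements. A zero MAD (e.g. all values equal)
#' excludes nothing.
#'
#' @param measurements measurements surviving the earlier filters.
#' @param nMad multiplier of the scaled MAD (default 4).
#' @return list(kept, excluded) with reason = "outlier" on exclusions.
#' @export
filterOutliers <- function(measurements, nMad = 4) {
  checkMeasurements(measurements)
  bad <- rep(FALSE, nrow(measurements))
  for (trait in unique(measurements$trait)) {
    sel <- measurements$trait == trait
    v <- measurements$value[sel]
    m <- stats::median(v)
    s <- stats::mad(v)
    if (s > 0)
      bad[sel] <- abs(v - m) > nMad * s
  }
  excluded <- measurements[bad, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "outlier"
  else excluded$reason <- character()
  list(kept = measurements[!bad, , drop = FALSE], excluded = excluded)
}

#' Clean trait streams and aggregate to per-subject medians
#'
#' Applies the filters in order (mislabel, then medication, then outlier on
#' the survivors, so each excluded measurement carries exactly one
#' first-cause reason) and reduces each subject's surviving measurements to
#' a single median per trait (an even count averages the two middle values).
#' Subjects with no surviving measurement for a trait are omitted for that
#' trait.
#'
#' @param measurements data.frame(subject_id, trait, value, unit, date);
#'   an optional measurement_id column is carried through the exclusions.
#' @param medications data.frame(subject_id, med_class, start, end).
#' @param traitConfig per-trait units and hard ranges
#'   (see [defaultTraitConfig()]).
#' @param medMap data.frame(medClass, trait) of trait-affecting classes.
#' @param nMad outlier rule multiplier (default 4).
#' @return a [TraitProfileSet-class].
#' @export
traitQC <- function(measurements, medications, traitConfig,
                    medMap = defaultMedicationEffects(), nMad = 4) {
  checkMeasurements(measurements)
  s1 <- filterMislabels(measurements, traitConfig)
  s2 <- filterMedicationAffected(s1$kept, medications, medMap)
  s3 <- filterOutliers(s2$kept, nMad = nMad)
  exclusions <- rbind(s1$excluded, s2$excluded, s3$excluded)
  rownames(exclusions) <- NULL

  kept <- s3$kept
  prof <- if (nrow(kept)) {
    agg <- stats::aggregate(value ~ subject_id + trait, data = kept,
                            FUN = stats::median)
    cnt <- stats::aggregate(value ~ subject_id + trait, data = kept,
                            FUN = length)
    names(agg)[3] <- "median_value"
    agg$n_used <- cnt$value[match(paste(agg$subject_id, agg$trait),
                                  paste(cnt$subject_id, cnt$trait))]
    agg[order(agg$trait, agg$subject_id), ]
  } else data.frame(subject_id = character(), trait = character(),
                    median_value = numeric(), n_used = integer())
  rownames(prof) <- NULL

  traits <- unique(measurements$trait)
  summary <- do.call(rbind, lapply(traits, function(tr) {
    n0 <- sum(measurements$trait == tr)
    n1 <- sum(s1$kept$trait == tr)
    n2 <- sum(s2$kept$trait == tr)
    n3 <- sum(kept$trait == tr)
    data.frame(trait = tr,
               n_measurements = n0,
               after_mislabel = n1, after_medication = n2,
               after_outlier = n3,
               n_subjects = length(unique(
                 measurements$subject_id[measurements$trait == tr])),
               n_subjects_final = length(unique(
                 kept$subject_id[kept$trait == tr])),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  new("TraitProfileSet", profiles = prof, exclusions = exclusions,
      summary = summary)
}
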