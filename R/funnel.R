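# The filtering funnel: partition each strain's transcriptome into
# antisense, soluble, secreted, bitopic-membrane and polytopic-membrane.

#' Localization classes
#' @return character vector of the five funnel classes, in funnel order.
#' @export
localization_classes <- function() {
  c("ANTISENSE_NONCODING", "SOLUBLE", "SECRETED",
    "BITOPIC_MEMBRANE", "POLYTOPIC_MEMBRANE")
}

MEMBRANE_CLASSES <- c("BITOPIC_MEMBRANE", "POLYTOPIC_MEMBRANE")
TRAFFICKED_CLASSES <- c("SECRETED", MEMBRANE_CLASSES)

#' Classify a transcript's localization from its topology profile
#'
#' Antisense transcripts are non-coding by definition. Otherwise, with
#' k = non-cleaved TM count of the representative protein: k = 0 with a
#' signal peptide is SECRETED (trafficked but completely released); k = 0
#' without one is SOLUBLE; k = 1 is BITOPIC_MEMBRANE; k >= 2 is
#' POLYTOPIC_MEMBRANE. Transcripts lacking any topology profile are binned
#' SOLUBLE (keeping the partition total) and flagged `no_profile`.
#'
#' @param profile a [topology_profile()] or `NULL` when the protein has no
#'   profile.
#' @param antisense logical antisense flag for the transcript.
#' @return character class; attribute `no_profile` set when defaulted.
#' @export
classify_localization <- function(profile, antisense = FALSE) {
  if (isTRUE(antisense)) return("ANTISENSE_NONCODING")
  if (is.null(profile))
    return(structure("SOLUBLE", no_profile = TRUE))
  k <- noncleaved_tm_count(profile)
  if (k >= 2L) "POLYTOPIC_MEMBRANE"
  else if (k == 1L) "BITOPIC_MEMBRANE"
  else if (profile$sp_present) "SECRETED"
  else "SOLUBLE"
}

#' Funnel summary per strain
#'
#' Counts and fractions-of-total at each funnel level: total transcripts,
#' trafficked (secreted + bitopic + polytopic; signal peptide and/or TM),
#' membrane (bitopic + polytopic), with bitopic reported separately.
#' Antisense transcripts stay in the denominator but never in the trafficked
#' numerator.
#'
#' @param records data frame with columns `strain` and `localization`.
#' @return data frame (strain, level, count, fraction).
#' @export
funnel_counts <- function(records) {
  strains <- unique(records$strain)
  rows <- lapply(strains, function(s) {
    loc <- records$localization[records$strain == s]
    total <- length(loc)
    lv <- c(total = total,
            antisense = sum(loc == "ANTISENSE_NONCODING"),
            soluble = sum(loc == "SOLUBLE"),
            secreted = sum(loc == "SECRETED"),
            bitopic = sum(loc == "BITOPIC_MEMBRANE"),
            polytopic = sum(loc == "POLYTOPIC_MEMBRANE"),
            trafficked = sum(loc %in% TRAFFICKED_CLASSES),
            membrane = sum(loc %in% MEMBRANE_CLASSES))
    data.frame(strain = s, level = names(lv), count = unname(lv),
               fraction = if (total > 0) unname(lv) / total else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
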