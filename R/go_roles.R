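# GO-keyword role binning for membrane proteins, with strict precedence.

#' Functional roles, in precedence order
#' @return character vector: TRANSPORT > SENSING_SIGNALING > CATALYSIS >
#'   OTHER > UNKNOWN.
#' @export
role_levels <- function() {
  c("TRANSPORT", "SENSING_SIGNALING", "CATALYSIS", "OTHER", "UNKNOWN")
}

#' Assign a functional role from GO term names
#'
#' Case-insensitive keyword matching on GO term text, applied in strict
#' precedence: any term containing "transport", "symport" or "v-type atpase"
#' gives TRANSPORT; else "receptor", "signal" or "sensor" gives
#' SENSING_SIGNALING; else a term whose final whitespace-delimited word ends
#' in "ase" gives CATALYSIS; else any annotation at all gives OTHER; no
#' annotation gives UNKNOWN. A protein with multiple matching functions is
#' binned only once, at the highest-precedence role (so e.g. an ABC
#' transporter with both transport and ATPase annotations is TRANSPORT).
#' The "-ase" rule is a blunt suffix test on the final word; rare false
#' positives such as "...base" are accepted by design.
#'
#' @param go_names character vector of GO term names for one protein (may be
#'   empty).
#' @return one of [role_levels()].
#' @export
assign_role <- function(go_names) {
  go_names <- go_names[!is.na(go_names) & nzchar(go_names)]
  if (!length(go_names)) return("UNKNOWN")
  x <- tolower(go_names)
  if (any(ci_detect(x, c("transport", "symport", "v-type atpase"))))
    return("TRANSPORT")
  if (any(ci_detect(x, c("receptor", "signal", "sensor"))))
    return("SENSING_SIGNALING")
  last_word <- vapply(strsplit(trimws(x), "\\s+"),
                      function(w) w[length(w)], "")
  if (any(grepl("ase$", last_word))) return("CATALYSIS")
  "OTHER"
}

#' Role distribution over membrane proteins, per strain
#'
#' @param records data frame with columns `strain` and `role`, one row per
#'   membrane protein.
#' @return data frame (strain, role, count, percent); percentages are over
#'   each strain's membrane proteins and sum to 100 up to rounding. Empty
#'   input returns an empty table with a warning.
#' @export
role_distribution <- function(records) {
  if (!nrow(records)) {
    warning("no membrane proteins; role distribution is empty")
    return(data.frame(strain = character(0), role = character(0),
                      count = integer(0), percent = numeric(0)))
  }
  strains <- unique(records$strain)
  rows <- lapply(strains, function(s) {
    rl <- factor(records$role[records$strain == s], levels = role_levels())
    ct <- table(rl)
    data.frame(strain = s, role = names(ct), count = as.integer(ct),
               percent = 100 * as.integer(ct) / sum(ct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
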