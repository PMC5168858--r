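# Per-protein topology profiles: signal-peptide call + ordered transmembrane
# segments, from standard predictor output dialects or a built-in
# hydrophobicity fallback.

#' Construct a topology profile
#'
#' @param protein_id protein identifier.
#' @param sp_present logical, signal peptide predicted.
#' @param cleavage_after residue index of the last signal-peptide residue
#'   (`NA` when no SP).
#' @param tm_starts,tm_ends 1-based inclusive residue coordinates of
#'   transmembrane segments, sorted and non-overlapping.
#' @param sources character vector of predictor labels.
#' @param flags optional character vector of provenance flags.
#' @return object of class `topology_profile`.
#' @export
topology_profile <- function(protein_id, sp_present = FALSE,
                             cleavage_after = NA_integer_,
                             tm_starts = integer(0), tm_ends = integer(0),
                             sources = character(0), flags = character(0)) {
  if (length(tm_starts) != length(tm_ends))
    stop_input("tm_starts/tm_ends length mismatch for %s", protein_id)
  if (length(tm_starts)) {
    o <- order(tm_starts, tm_ends)
    tm_starts <- as.integer(tm_starts[o]); tm_ends <- as.integer(tm_ends[o])
    if (any(tm_ends < tm_starts))
      stop_input("segment end before start for %s", protein_id)
  }
  if (isTRUE(sp_present) && (is.na(cleavage_after) || cleavage_after < 1))
    stop_input("SP present but cleavage_after < 1 for %s", protein_id)
  structure(list(protein_id = protein_id, sp_present = isTRUE(sp_present),
                 cleavage_after = as.integer(cleavage_after),
                 tm_starts = tm_starts, tm_ends = tm_ends,
                 sources = sources, flags = flags),
            class = "topology_profile")
}

#' @export
print.topology_profile <- function(x, ...) {
  cat(sprintf("<topology_profile %s> SP=%s%s, %d TM segment(s) [%s]\n",
              x$protein_id, x$sp_present,
              if (x$sp_present) sprintf(" (cleaved after %d)", x$cleavage_after) else "",
              length(x$tm_starts), paste(x$sources, collapse = ",")))
  invisible(x)
}

parse_segments <- function(txt) {
  m <- gregexpr("(\\d+)-(\\d+)", txt)[[1]]
  if (m[1] == -1) return(list(starts = integer(0), ends = integer(0)))
  seg <- regmatches(txt, gregexpr("(\\d+)-(\\d+)", txt))[[1]]
  parts <- strsplit(seg, "-", fixed = TRUE)
  list(starts = as.integer(vapply(parts, `[`, "", 1)),
       ends = as.integer(vapply(parts, `[`, "", 2)))
}

parse_error <- function(path, lineno, msg) {
  stop_input("parse error in %s line %d: %s", path, lineno, msg)
}

read_tmhmm_short <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) parse_error(path, i, "expected 6 tab fields (TMHMM short)")
    id <- f[1]
    predhel <- suppressWarnings(as.integer(sub("(?i)^predhel=", "", f[5], perl = TRUE)))
    topo <- sub("(?i)^topology=", "", f[6], perl = TRUE)
    if (is.na(predhel)) parse_error(path, i, "unreadable PredHel field")
    seg <- parse_segments(topo)
    if (length(seg$starts) != predhel)
      parse_error(path, i, sprintf("PredHel=%d but %d segments in topology",
                                   predhel, length(seg$starts)))
    out[[id]] <- topology_profile(id, FALSE, NA, seg$starts, seg$ends, "tmhmm")
  }
  out
}

read_signalp_short <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) < 10) parse_error(path, i, "expected >= 10 fields (SignalP short)")
    id <- f[1]
    sp <- toupper(f[10]) == "Y"
    ymax_pos <- suppressWarnings(as.integer(f[5]))
    if (sp && (is.na(ymax_pos) || ymax_pos < 2))
      parse_error(path, i, "SP=Y but unreadable cleavage position")
    out[[id]] <- topology_profile(id, sp,
                                  if (sp) ymax_pos - 1L else NA_integer_,
                                  sources = "signalp")
  }
  out
}

read_phobius_short <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (toupper(f[1]) %in% c("SEQENCE", "SEQUENCE")) next  # header
    if (length(f) < 4) parse_error(path, i, "expected 4 fields (Phobius short)")
    id <- f[1]
    tmn <- suppressWarnings(as.integer(f[2]))
    sp <- toupper(f[3]) == "Y"
    pred <- f[4]
    if (is.na(tmn)) parse_error(path, i, "unreadable TM count")
    cleav <- NA_integer_
    body <- pred
    if (sp) {
      m <- regmatches(pred, regexec("^n\\d+-\\d+c(\\d+)/\\d+", pred))[[1]]
      if (length(m) < 2) parse_error(path, i, "SP=Y but no n..c../.. signal region")
      cleav <- as.integer(m[2])
      body <- sub("^n\\d+-\\d+c\\d+/\\d+", "", pred)
    }
    seg <- parse_segments(body)
    if (length(seg$starts) != tmn)
      parse_error(path, i, sprintf("TM=%d but %d segments in prediction",
                                   tmn, length(seg$starts)))
    out[[id]] <- topology_profile(id, sp, cleav, seg$starts, seg$ends, "phobius")
  }
  out
}

#' Read topology predictor output files
#'
#' Parses TMHMM short, SignalP short-tabular or Phobius short-tabular output
#' into per-protein profile fragments. Proteins absent from a file get no
#' profile (they are not defaulted).
#'
#' @param paths character vector of files, all in the same dialect.
#' @param dialect one of `"tmhmm-short"`, `"signalp-short"`, `"phobius-short"`.
#' @return named list of [topology_profile()] fragments.
#' @export
read_topology_files <- function(paths,
                                dialect = c("tmhmm-short", "signalp-short",
                                            "phobius-short")) {
  dialect <- match.arg(dialect)
  reader <- switch(dialect,
                   "tmhmm-short" = read_tmhmm_short,
                   "signalp-short" = read_signalp_short,
                   "phobius-short" = read_phobius_short)
  out <- list()
  for (p in paths) out <- c(out, reader(p))
  out
}

#' Kyte-Doolittle hydropathy scale
#' @return named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Fallback topology prediction by sliding-window hydropathy
#'
#' Mean Kyte-Doolittle hydropathy over a sliding window; maximal runs of
#' above-threshold windows become transmembrane segments (each segment is the
#' union of the window spans in its run). A segment starting within the first
#' 30 residues that is followed within 10 residues by a small residue
#' (A/G/S/T/C, the typical position just before a cleavage site) is
#' additionally reported as a signal-peptide candidate, with the cleavage
#' placed after that small residue. This is a deliberately simple stand-in
#' that lets the pipeline run without external predictor output; it does not
#' reproduce the TMHMM/SignalP probabilistic models.
#'
#' @param aa_sequence protein string.
#' @param protein_id identifier recorded in the profile.
#' @param window sliding-window width in residues (default 19).
#' @param threshold mean-hydropathy cutoff for a window (default 1.6).
#' @return a [topology_profile()]; for sequences shorter than `window` an
#'   empty profile flagged `"too_short"`.
#' @export
predict_topology_fallback <- function(aa_sequence, protein_id = "protein",
                                      window = 19L, threshold = 1.6) {
  aa <- strsplit(toupper(aa_sequence), "")[[1]]
  L <- length(aa)
  if (L < window)
    return(topology_profile(protein_id, sources = "kd-fallback",
                            flags = "too_short"))
  kd <- kyte_doolittle()
  h <- unname(kd[aa]); h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
  # strict ">" with a small epsilon so windows sitting exactly on the
  # threshold resolve identically regardless of summation order
  above <- means > threshold + 1e-9
  tm_starts <- integer(0); tm_ends <- integer(0)
  if (any(above)) {
    r <- rle(above)
    pos <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      ws <- pos[j]; we <- pos[j] + r$lengths[j] - 1L
      tm_starts <- c(tm_starts, ws)
      tm_ends <- c(tm_ends, we + window - 1L)
    }
  }
  sp <- FALSE; cleav <- NA_integer_
  if (length(tm_starts) && tm_starts[1] <= 30L) {
    lim <- min(tm_ends[1] + 10L, L)
    if (tm_ends[1] < L) {
      cand <- which(aa[(tm_ends[1] + 1L):lim] %in% c("A", "G", "S", "T", "C"))
      if (length(cand)) { sp <- TRUE; cleav <- tm_ends[1] + cand[1] }
    }
  }
  topology_profile(protein_id, sp, cleav, tm_starts, tm_ends, "kd-fallback")
}

# residue-coverage interval union: merges overlapping or adjacent segments
interval_union <- function(starts, ends) {
  if (!length(starts)) return(list(starts = integer(0), ends = integer(0)))
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  us <- s[1]; ue <- e[1]; k <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] <= ue[k] + 1L) ue[k] <- max(ue[k], e[i])
    else { k <- k + 1L; us[k] <- s[i]; ue[k] <- e[i] }
  }
  list(starts = as.integer(us), ends = as.integer(ue))
}

interval_intersection <- function(profiles) {
  L <- max(c(1L, unlist(lapply(profiles, function(p) p$tm_ends))))
  cov <- rep(TRUE, L)
  for (p in profiles) {
    here <- rep(FALSE, L)
    for (i in seq_along(p$tm_starts))
      here[p$tm_starts[i]:p$tm_ends[i]] <- TRUE
    cov <- cov & here
  }
  if (!any(cov)) return(list(starts = integer(0), ends = integer(0)))
  r <- rle(cov); pos <- cumsum(c(1L, r$lengths))
  keep <- which(r$values)
  list(starts = as.integer(pos[keep]),
       ends = as.integer(pos[keep] + r$lengths[keep] - 1L))
}

#' Merge topology predictions from several predictors
#'
#' Default `"union"` mode interval-unions the transmembrane segment sets and
#' calls a signal peptide if any source does (cleavage = maximum over
#' sources), maximising sensitivity in keeping with an inclusive
#' signal-peptide-and/or-TM funnel. `"intersection"` keeps only residues
#' covered by every source (SP requires all sources; cleavage = minimum);
#' `"priority"` takes the first profile in list order. The latter two are for
#' sensitivity analysis.
#'
#' @param profiles list of [topology_profile()] objects for one protein.
#' @param mode `"union"` (default), `"intersection"` or `"priority"`.
#' @return merged [topology_profile()].
#' @export
merge_predictions <- function(profiles,
                              mode = c("union", "intersection", "priority")) {
  mode <- match.arg(mode)
  profiles <- profiles[!vapply(profiles, is.null, TRUE)]
  if (!length(profiles)) stop_input("no profiles to merge")
  ids <- unique(vapply(profiles, `[[`, "", "protein_id"))
  if (length(ids) != 1L)
    stop_input("profiles refer to different proteins: %s",
               paste(ids, collapse = ", "))
  sources <- sort(unique(unlist(lapply(profiles, `[[`, "sources"))))
  flags <- sort(unique(unlist(lapply(profiles, `[[`, "flags"))))
  if (mode == "priority") {
    p <- profiles[[1]]
    return(topology_profile(ids, p$sp_present, p$cleavage_after,
                            p$tm_starts, p$tm_ends, p$sources, p$flags))
  }
  sp_calls <- vapply(profiles, `[[`, TRUE, "sp_present")
  cleavs <- vapply(profiles, `[[`, 1L, "cleavage_after")
  if (mode == "union") {
    u <- interval_union(unlist(lapply(profiles, `[[`, "tm_starts")),
                        unlist(lapply(profiles, `[[`, "tm_ends")))
    sp <- any(sp_calls)
    cleav <- if (sp) max(cleavs[sp_calls], na.rm = TRUE) else NA_integer_
  } else {
    u <- interval_intersection(profiles)
    sp <- all(sp_calls)
    cleav <- if (sp) min(cleavs, na.rm = TRUE) else NA_integer_
  }
  topology_profile(ids, sp, cleav, u$starts, u$ends, sources, flags)
}

#' Count non-cleaved transmembrane segments
#'
#' A predicted TM segment whose start lies at or before the signal-peptide
#' cleavage site is taken to be the signal peptide itself (predictors
#' routinely call hydrophobic signal sequences as helices) and is not counted
#' as a membrane anchor. With no signal peptide, all segments count. This is
#' the TM count used for funnel classification.
#'
#' @param profile a [topology_profile()].
#' @return integer count.
#' @export
noncleaved_tm_count <- function(profile) {
  if (!profile$sp_present || is.na(profile$cleavage_after))
    return(length(profile$tm_starts))
  sum(profile$tm_starts > profile$cleavage_after)
}

#' Raw transmembrane segment count
#' @param profile a [topology_profile()].
#' @return integer count of all TM segments, before any signal-peptide
#'   discounting (the count used by the GPCR 7-9 gate).
#' @export
raw_tm_count <- function(profile) length(profile$tm_starts)

#' Flatten a list of profiles to a table
#' @param profiles named list of [topology_profile()] objects.
#' @return data frame (protein_id, sp_present, cleavage_after, tm_starts,
#'   tm_ends, sources) with comma-separated coordinate lists.
#' @export
profiles_to_table <- function(profiles) {
  data.frame(
    protein_id = vapply(profiles, `[[`, "", "protein_id"),
    sp_present = vapply(profiles, `[[`, TRUE, "sp_present"),
    cleavage_after = vapply(profiles, `[[`, 1L, "cleavage_after"),
    tm_starts = vapply(profiles, function(p) int_csv(p$tm_starts), ""),
    tm_ends = vapply(profiles, function(p) int_csv(p$tm_ends), ""),
    sources = vapply(profiles, function(p) paste(p$sources, collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}
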