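# GPCR discovery: annotation-keyword entry filter, 7-9 TM gate, N-terminal
# region delimitation and receptor-class / domain-architecture calls.

GPCR_KEYWORDS <- c("gpcr", "g-protein coupled receptor")
GPCR_CLASSES <- c("RHODOPSIN_DICTY_CAR", "CLASS_C", "UNCLASSIFIED")
GPCR_FLAGS <- c("ANF", "PECTIN_LYASE", "BETA_HELIX", "EGF_LIKE", "SBP_TYPE_II")

#' Load the GPCR signature table
#'
#' Maps InterPro accessions (and member-database signatures such as SCOP
#' superfamilies) to receptor-class calls and N-terminal architecture flags.
#' Shipped as editable TSV config.
#'
#' @param path signature TSV; default is the packaged table.
#' @return data frame (signature, id_type, kind, value).
#' @export
load_gpcr_signatures <- function(path = system.file("extdata",
                                                    "gpcr_signature_map.tsv",
                                                    package = "membraneMiner")) {
  sig <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("signature", "id_type", "kind", "value") %in% names(sig)))
  sig
}

#' Find GPCR candidates
#'
#' A protein is a candidate iff (i) any of its annotation descriptions
#' contains "GPCR" or "G-protein coupled receptor" (case-insensitive) and
#' (ii) its raw transmembrane-segment count is between 7 and 9 inclusive.
#' The gate deliberately uses the raw count, before any signal-peptide
#' discounting: the upper bound of 9 exists precisely to tolerate
#' hydrophobic signal sequences called as extra helices.
#'
#' @param annotations data frame (protein_id, text) of annotation
#'   descriptions from any source (domain descriptions, GO names, alignment
#'   subject titles).
#' @param profiles named list of [topology_profile()] objects.
#' @param tm_gate inclusive integer bounds on the raw TM count,
#'   default `c(7, 9)`.
#' @return character vector of candidate protein ids.
#' @export
find_gpcr_candidates <- function(annotations, profiles, tm_gate = c(7L, 9L)) {
  hit <- ci_detect(annotations$text, GPCR_KEYWORDS)
  kw_ids <- unique(annotations$protein_id[hit])
  keep <- vapply(kw_ids, function(id) {
    p <- profiles[[id]]
    if (is.null(p)) return(FALSE)
    k <- raw_tm_count(p)
    k >= tm_gate[1] && k <= tm_gate[2]
  }, TRUE)
  kw_ids[keep]
}

#' Delimit the N-terminal extracellular region of a GPCR candidate
#'
#' The heptahelical bundle is taken to be the 7 most C-terminal TM segments
#' (when 8-9 are predicted, the extra N-terminal helices are assumed to be
#' signal sequences); the N-terminal region runs from residue 1 to the
#' residue before the bundle's first helix. Domains belong to the region
#' only when wholly contained (domain end strictly before the bundle start).
#'
#' @param profile a [topology_profile()] with 7-9 TM segments.
#' @return list with `region_start`, `region_end` (0-length region gives
#'   `region_end = 0`) and `bundle_start`.
#' @export
delimit_n_terminal_region <- function(profile) {
  k <- raw_tm_count(profile)
  if (k < 7L) stop_input("GPCR gate violated: %d TM segments", k)
  bundle_start <- profile$tm_starts[k - 6L]
  list(region_start = 1L, region_end = bundle_start - 1L,
       bundle_start = bundle_start)
}

#' Classify a GPCR candidate and flag its N-terminal architecture
#'
#' Receptor class comes from class signatures anywhere in the protein:
#' CLASS_C for the class C (glutamate) 7TM signature, RHODOPSIN_DICTY_CAR
#' for rhodopsin-like / slime-mold cAMP-receptor signatures, else
#' UNCLASSIFIED. A protein carrying both is called CLASS_C with
#' `class_conflict = TRUE` (never silently). Architecture flags come only
#' from domains wholly inside the N-terminal extracellular region.
#'
#' @param protein_id candidate id.
#' @param domains domain-hit data frame for this protein (columns
#'   `signature_id`, `interpro_id`, `start`, `end`).
#' @param profile the candidate's [topology_profile()].
#' @param signatures a [load_gpcr_signatures()] table.
#' @return one-row data frame: protein_id, tm_count, gpcr_class,
#'   class_conflict, flags (comma-joined), n_term_start/end,
#'   n_term_domains (comma-joined signature ids), has_signal_peptide.
#' @export
classify_gpcr <- function(protein_id, domains, profile,
                          signatures = load_gpcr_signatures()) {
  reg <- delimit_n_terminal_region(profile)
  sig_of <- function(row_kind) signatures[signatures$kind == row_kind, ,
                                          drop = FALSE]
  match_sigs <- function(dom, tab) {
    if (!nrow(dom) || !nrow(tab)) return(character(0))
    hit_ip <- dom$interpro_id %in% tab$signature[tab$id_type == "interpro"]
    hit_db <- dom$signature_id %in% tab$signature[tab$id_type == "signature"]
    vals_ip <- tab$value[match(dom$interpro_id[hit_ip], tab$signature)]
    vals_db <- tab$value[match(dom$signature_id[hit_db], tab$signature)]
    c(vals_ip, vals_db)
  }
  classes <- unique(match_sigs(domains, sig_of("class")))
  conflict <- all(c("CLASS_C", "RHODOPSIN_DICTY_CAR") %in% classes)
  gclass <- if ("CLASS_C" %in% classes) "CLASS_C"
            else if ("RHODOPSIN_DICTY_CAR" %in% classes) "RHODOPSIN_DICTY_CAR"
            else "UNCLASSIFIED"
  nterm <- domains[domains$end < reg$bundle_start, , drop = FALSE]
  flags <- sort(unique(match_sigs(nterm, sig_of("flag"))))
  data.frame(protein_id = protein_id, tm_count = raw_tm_count(profile),
             gpcr_class = gclass, class_conflict = conflict,
             flags = paste(flags, collapse = ","),
             n_term_start = reg$region_start, n_term_end = reg$region_end,
             n_term_domains = paste(unique(nterm$signature_id), collapse = ","),
             has_signal_peptide = profile$sp_present,
             stringsAsFactors = FALSE)
}

#' Per-strain GPCR report
#'
#' Receptor-class counts per strain with per-strain and cross-strain totals,
#' N-terminal architecture-flag fractions, and the N-terminal region length
#' distribution (min / mean / max).
#'
#' @param candidates data frame of classified candidates with a `strain`
#'   column (rows as produced by [classify_gpcr()]).
#' @return list of data frames `classes` (strain x class counts with margin
#'   totals), `architecture` (flag, count, fraction over all candidates),
#'   `n_term_length` (per-strain min/mean/max).
#' @export
gpcr_report <- function(candidates) {
  if (!nrow(candidates)) {
    return(list(classes = data.frame(strain = character(0),
                                     gpcr_class = character(0),
                                     count = integer(0)),
                architecture = data.frame(flag = GPCR_FLAGS, count = 0L,
                                          fraction = 0),
                n_term_length = data.frame(strain = character(0),
                                           min = integer(0), mean = numeric(0),
                                           max = integer(0))))
  }
  strains <- unique(candidates$strain)
  cls <- do.call(rbind, lapply(strains, function(s) {
    v <- factor(candidates$gpcr_class[candidates$strain == s],
                levels = GPCR_CLASSES)
    ct <- table(v)
    data.frame(strain = s, gpcr_class = names(ct), count = as.integer(ct),
               stringsAsFactors = FALSE)
  }))
  # per-strain totals over classes, then cross-strain totals per class
  cls <- add_margin_totals(cls, margin_col = "gpcr_class",
                           count_col = "count", total_label = "Total")
  cls <- add_margin_totals(cls, margin_col = "strain", count_col = "count")
  n <- nrow(candidates)
  fl <- strsplit(candidates$flags, ",", fixed = TRUE)
  arch <- data.frame(flag = GPCR_FLAGS,
                     count = vapply(GPCR_FLAGS, function(f)
                       sum(vapply(fl, function(x) f %in% x, TRUE)), 1L),
                     stringsAsFactors = FALSE)
  arch$fraction <- arch$count / n
  lenq <- do.call(rbind, lapply(strains, function(s) {
    L <- candidates$n_term_end[candidates$strain == s]
    data.frame(strain = s, min = min(L), mean = mean(L), max = max(L))
  }))
  rownames(cls) <- rownames(arch) <- rownames(lenq) <- NULL
  list(classes = cls, architecture = arch, n_term_length = lenq)
}
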