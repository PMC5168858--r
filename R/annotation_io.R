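# Parsers for alignment tabular (BLAST outfmt-6 dialect) and
# InterProScan-TSV-style domain/GO annotation files.

BLAST12 <- c("query_id", "subject_id", "pct_identity", "aln_length",
             "mismatch", "gapopen", "q_start", "q_end", "s_start", "s_end",
             "e_value", "bit_score")

#' Read a BLAST-tabular alignment file
#'
#' Accepts the 12-column outfmt-6 dialect extended with `qlen` and `slen`
#' (14 columns), optionally followed by a subject-title column (15 columns),
#' or the plain 12-column dialect plus a separate two-column
#' (id, length) table covering every query and subject. Subject spans given
#' in descending coordinates are normalised ascending with
#' `s_minus_strand = TRUE` recorded.
#'
#' @param path alignment file.
#' @param length_table optional data frame (id, length) used when the file
#'   has only 12 columns.
#' @return data frame of alignment hits (one row per HSP) with columns
#'   `query_id, subject_id, pct_identity, aln_length, q_start, q_end,
#'   s_start, s_end, e_value, bit_score, q_len, s_len, subject_desc,
#'   s_minus_strand`.
#' @export
empty_alignment_table <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             e_value = numeric(0), bit_score = numeric(0),
             q_len = integer(0), s_len = integer(0),
             subject_desc = character(0), s_minus_strand = logical(0))
}

read_alignment_table <- function(path, length_table = NULL) {
  if (!any(nzchar(readLines(path, n = 5L)))) return(empty_alignment_table())
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           quote = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  nc <- ncol(raw)
  if (!nc %in% c(12L, 14L, 15L))
    stop_input("alignment table %s has %d columns; expected 12, 14 or 15",
               path, nc)
  names(raw)[1:12] <- BLAST12
  if (nc >= 14L) {
    names(raw)[13:14] <- c("q_len", "s_len")
  } else {
    if (is.null(length_table))
      stop_input("12-column alignment table %s needs a length_table", path)
    lt <- stats::setNames(as.integer(length_table[[2]]),
                          as.character(length_table[[1]]))
    raw$q_len <- unname(lt[raw$query_id])
    raw$s_len <- unname(lt[raw$subject_id])
    if (anyNA(raw$q_len) || anyNA(raw$s_len))
      stop_input("length_table is missing ids present in %s", path)
  }
  raw$subject_desc <- if (nc == 15L) raw[[15]] else ""
  for (col in c("q_start", "q_end", "s_start", "s_end", "q_len", "s_len"))
    raw[[col]] <- as.integer(raw[[col]])
  raw$e_value <- as.numeric(raw$e_value)
  raw$bit_score <- as.numeric(raw$bit_score)
  if (any(raw$e_value < 0, na.rm = TRUE) || anyNA(raw$e_value))
    stop_input("negative or unreadable E-value in %s", path)
  if (any(raw$q_len < 1) || any(raw$s_len < 1))
    stop_input("sequence lengths must be >= 1 in %s", path)
  flip <- raw$s_start > raw$s_end
  tmp <- raw$s_start[flip]
  raw$s_start[flip] <- raw$s_end[flip]
  raw$s_end[flip] <- tmp
  raw$s_minus_strand <- flip
  qflip <- raw$q_start > raw$q_end
  tmp <- raw$q_start[qflip]
  raw$q_start[qflip] <- raw$q_end[qflip]
  raw$q_end[qflip] <- tmp
  raw[, c(BLAST12[1:2], "pct_identity", "aln_length", "q_start", "q_end",
          "s_start", "s_end", "e_value", "bit_score", "q_len", "s_len",
          "subject_desc", "s_minus_strand")]
}

#' Serialize alignment hits back to 15-column tabular
#' @param hits data frame from [read_alignment_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id, hits$pct_identity,
                    hits$aln_length, 0L, 0L, hits$q_start, hits$q_end,
                    ifelse(hits$s_minus_strand, hits$s_end, hits$s_start),
                    ifelse(hits$s_minus_strand, hits$s_start, hits$s_end),
                    format(hits$e_value, scientific = TRUE),
                    hits$bit_score, hits$q_len, hits$s_len,
                    hits$subject_desc)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

GO_RE <- "GO:\\d{7}"

#' Read an InterProScan-style domain/GO annotation TSV
#'
#' Fourteen tab-separated columns, no header: protein id, md5, sequence
#' length, analysis, signature accession, signature description, start, end,
#' e-value (`-` allowed for analyses without scores), status, date, InterPro
#' accession (`-` when absent), InterPro description, GO annotations as
#' pipe-separated `GO:NNNNNNN(term name)` entries (`-` when none). Rows with
#' e-value above `max_e` are dropped (the significance gate is inclusive:
#' e-value equal to the cutoff is retained); GO entries of retained rows are
#' expanded into one annotation row per term.
#'
#' @param path annotation file.
#' @param max_e inclusive e-value cutoff (default `1e-3`).
#' @return list with elements `domains` (protein_id, signature_id,
#'   interpro_id, description, start, end, e_value), `go` (protein_id, go_id,
#'   go_name), `n_dropped` and `n_input`.
#' @export
read_domain_table <- function(path, max_e = 1e-3) {
  if (!any(nzchar(readLines(path, n = 5L))))
    return(list(domains = data.frame(protein_id = character(0),
                                     signature_id = character(0),
                                     interpro_id = character(0),
                                     description = character(0),
                                     start = integer(0), end = integer(0),
                                     e_value = numeric(0)),
                go = data.frame(protein_id = character(0),
                                go_id = character(0), go_name = character(0)),
                n_dropped = 0L, n_input = 0L))
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) != 14L)
    stop_input("domain table %s has %d columns; expected 14", path, ncol(raw))
  names(raw) <- c("protein_id", "md5", "seq_len", "analysis", "signature_id",
                  "signature_desc", "start", "end", "e_value", "status",
                  "date", "interpro_id", "interpro_desc", "go")
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad))
    stop_input("parse error in %s line %d: bad domain coordinates", path, bad[1])
  ev <- suppressWarnings(as.numeric(ifelse(raw$e_value == "-", NA, raw$e_value)))
  keep <- is.na(ev) | ev <= max_e
  n_dropped <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  start <- start[keep]; end <- end[keep]; ev <- ev[keep]
  desc <- ifelse(raw$interpro_desc != "-" & nzchar(raw$interpro_desc),
                 raw$interpro_desc, raw$signature_desc)
  domains <- data.frame(
    protein_id = raw$protein_id,
    signature_id = raw$signature_id,
    interpro_id = ifelse(raw$interpro_id == "-", NA_character_, raw$interpro_id),
    description = desc, start = start, end = end, e_value = ev,
    stringsAsFactors = FALSE)
  go_rows <- list()
  has_go <- which(raw$go != "-" & nzchar(raw$go))
  for (i in has_go) {
    entries <- strsplit(raw$go[i], "|", fixed = TRUE)[[1]]
    ids <- regmatches(entries, regexpr(GO_RE, entries))
    if (length(ids) != length(entries))
      stop_input("parse error in %s: malformed GO entry '%s'",
                 path, entries[!grepl(GO_RE, entries)][1])
    nm <- tolower(sub("\\)$", "", sub(paste0("^", GO_RE, "\\("), "", entries)))
    nm[!grepl("\\(", entries)] <- ""
    go_rows[[length(go_rows) + 1L]] <-
      data.frame(protein_id = raw$protein_id[i], go_id = ids, go_name = nm,
                 stringsAsFactors = FALSE)
  }
  go <- if (length(go_rows)) do.call(rbind, go_rows) else
    data.frame(protein_id = character(0), go_id = character(0),
               go_name = character(0), stringsAsFactors = FALSE)
  list(domains = domains, go = go,
       n_dropped = n_dropped, n_input = n_dropped + nrow(raw))
}
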