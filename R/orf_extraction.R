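# Six-frame ORF extraction and translation.
#
# Frames are numbered +1/+2/+3 on the forward strand and -1/-2/-3 on the
# reverse complement (frame -f is frame +f of the reverse complement).
# Coordinates are always 1-based inclusive on the forward strand of the
# transcript; the frame sign carries the strand.

FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

assert_frame <- function(frame) {
  if (length(frame) != 1L || is.na(frame) || !frame %in% FRAME_ORDER)
    stop_input("frame must be one of %s, got '%s'",
               paste(FRAME_ORDER, collapse = ", "), paste(frame, collapse = ","))
  as.integer(frame)
}

assert_dna <- function(x) {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad))
    stop_input("sequence contains characters outside {A,C,G,T,N}: '%s'",
               substr(x[bad][1], 1, 40))
  toupper(x)
}

# Translate a whole DNAStringSet in one frame; codons containing N become X,
# stops are rendered '*'.  Returns a character vector of aa strings.
translate_set_frame <- function(dna, frame) {
  frame <- assert_frame(frame)
  if (frame < 0) dna <- Biostrings::reverseComplement(dna)
  off <- abs(frame) - 1L
  w <- Biostrings::width(dna)
  ncod <- pmax(0L, (w - off) %/% 3L)
  sub <- Biostrings::subseq(dna, start = pmin(off + 1L, w + 1L), width = 3L * ncod)
  # fuzzy-codon resolution is an order of magnitude slower; only pay for it
  # when ambiguous bases are actually present
  if (sum(Biostrings::vcountPattern("N", sub)) == 0L)
    as.character(Biostrings::translate(sub, no.init.codon = TRUE))
  else
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Standard genetic code. Codons containing `N` translate to `X`; stop codons
#' are rendered as `*`. Frame `-f` translates frame `+f` of the reverse
#' complement, so `translate_frame(s, -1)` equals
#' `translate_frame(revcomp(s), +1)`.
#'
#' @param nt_sequence single nucleotide string over `{A,C,G,T,N}`.
#' @param frame integer in `{+1,+2,+3,-1,-2,-3}`.
#' @return amino-acid string (possibly containing `*` and `X`).
#' @export
translate_frame <- function(nt_sequence, frame) {
  stopifnot(length(nt_sequence) == 1L)
  nt_sequence <- assert_dna(nt_sequence)
  dna <- Biostrings::DNAStringSet(nt_sequence)
  translate_set_frame(dna, frame)[[1]]
}

# ORFs in one translated frame string.  Returns a list of parallel vectors
# (aa_start, aa_end in codons including the stop codon when present,
# has_start, has_stop).
orfs_in_aa <- function(aa) {
  L <- nchar(aa)
  if (L == 0L)
    return(list(aa_start = integer(0), aa_end = integer(0),
                has_start = logical(0), has_stop = logical(0)))
  ms <- gregexpr("M", aa, fixed = TRUE)[[1]]
  ms <- ms[ms > 0]
  st <- gregexpr("*", aa, fixed = TRUE)[[1]]
  st <- st[st > 0]
  out_start <- integer(0); out_end <- integer(0)
  out_has_start <- logical(0); out_has_stop <- logical(0)
  if (length(ms)) {
    # index of first stop at-or-after each M
    idx <- findInterval(ms - 1L, st) + 1L
    has_stop <- idx <= length(st)
    end <- ifelse(has_stop, st[pmin(idx, length(st))], L)
    out_start <- ms; out_end <- as.integer(end)
    out_has_start <- rep(TRUE, length(ms)); out_has_stop <- has_stop
  }
  # 5'-open-ended ORF: frame start to first stop (or frame end), only when the
  # first residue is not already a reported M-initiated start
  first <- substr(aa, 1L, 1L)
  if (first != "M") {
    s1 <- if (length(st)) st[1] else NA_integer_
    if (is.na(s1)) {
      out_start <- c(out_start, 1L); out_end <- c(out_end, L)
      out_has_start <- c(out_has_start, FALSE); out_has_stop <- c(out_has_stop, FALSE)
    } else if (s1 > 1L) {
      out_start <- c(out_start, 1L); out_end <- c(out_end, s1)
      out_has_start <- c(out_has_start, FALSE); out_has_stop <- c(out_has_stop, TRUE)
    }
  }
  list(aa_start = out_start, aa_end = out_end,
       has_start = out_has_start, has_stop = out_has_stop)
}

#' Extract all ORFs from a set of transcripts in six frames
#'
#' Reports every ATG-to-in-frame-stop ORF plus open-ended ORFs truncated by
#' the transcript ends (flagged `partial`), in all six frames, with length at
#' least `min_len_codons` codons (the terminal stop codon counts as a codon).
#' Within each transcript ORFs are sorted by descending codon count, ties
#' broken by frame (+1,+2,+3,-1,-2,-3) then ascending `nt_start`; the first
#' ORF per transcript is its representative.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   transcript sequences.
#' @param min_len_codons minimum ORF length in codons (default 50).
#' @return data frame with columns `orf_id`, `transcript_id`, `frame`,
#'   `nt_start`, `nt_end`, `n_codons`, `partial`, `aa_sequence`.
#' @export
extract_orfs_set <- function(seqs, min_len_codons = 50L) {
  if (min_len_codons < 1L) stop_input("min_len_codons must be >= 1")
  if (is.character(seqs)) {
    seqs <- vapply(seqs, assert_dna, character(1))
    dna <- Biostrings::DNAStringSet(seqs)
  } else dna <- seqs
  ids <- names(dna)
  if (is.null(ids) || anyDuplicated(ids))
    stop_input("transcripts must carry unique names")
  n <- Biostrings::width(dna)
  acc <- list(tid = list(), frame = list(), nt_start = list(),
              nt_end = list(), n_codons = list(), partial = list(),
              aaseq = list())
  j <- 0L
  for (k in seq_along(FRAME_ORDER)) {
    f <- FRAME_ORDER[k]
    aa <- translate_set_frame(dna, f)
    off <- abs(f) - 1L
    for (i in seq_along(aa)) {
      o <- orfs_in_aa(aa[[i]])
      if (!length(o$aa_start)) next
      n_codons <- o$aa_end - o$aa_start + 1L
      keep <- n_codons >= min_len_codons
      if (!any(keep)) next
      o <- lapply(o, `[`, keep); n_codons <- n_codons[keep]
      a <- off + 3L * (o$aa_start - 1L) + 1L
      b <- off + 3L * o$aa_end
      if (f > 0) { nt_start <- a; nt_end <- b
      } else { nt_start <- n[i] - b + 1L; nt_end <- n[i] - a + 1L }
      aa_end_res <- ifelse(o$has_stop, o$aa_end - 1L, o$aa_end)
      j <- j + 1L
      acc$tid[[j]] <- rep(ids[i], length(n_codons))
      acc$frame[[j]] <- rep(f, length(n_codons))
      acc$nt_start[[j]] <- nt_start
      acc$nt_end[[j]] <- nt_end
      acc$n_codons[[j]] <- n_codons
      acc$partial[[j]] <- !(o$has_start & o$has_stop)
      acc$aaseq[[j]] <- substring(aa[[i]], o$aa_start, aa_end_res)
    }
  }
  out <- if (j > 0L)
    data.frame(transcript_id = unlist(acc$tid), frame = unlist(acc$frame),
               nt_start = unlist(acc$nt_start), nt_end = unlist(acc$nt_end),
               n_codons = unlist(acc$n_codons), partial = unlist(acc$partial),
               aa_sequence = unlist(acc$aaseq), stringsAsFactors = FALSE)
  else NULL
  if (is.null(out) || !nrow(out))
    return(data.frame(orf_id = character(0), transcript_id = character(0),
                      frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), n_codons = integer(0),
                      partial = logical(0), aa_sequence = character(0)))
  key <- match(out$frame, FRAME_ORDER)
  out <- out[order(match(out$transcript_id, ids), -out$n_codons, key,
                   out$nt_start), , drop = FALSE]
  rk <- stats::ave(seq_len(nrow(out)), out$transcript_id,
                   FUN = seq_along)
  out$orf_id <- paste0(out$transcript_id, ".orf", rk)
  rownames(out) <- NULL
  out[, c("orf_id", "transcript_id", "frame", "nt_start", "nt_end",
          "n_codons", "partial", "aa_sequence")]
}

#' Extract ORFs from a single transcript
#'
#' @param sequence nucleotide string.
#' @param transcript_id transcript identifier.
#' @inheritParams extract_orfs_set
#' @return see [extract_orfs_set()].
#' @export
extract_orfs <- function(sequence, transcript_id = "transcript",
                         min_len_codons = 50L) {
  extract_orfs_set(stats::setNames(sequence, transcript_id), min_len_codons)
}

#' Representative ORF per transcript
#'
#' The longest extracted ORF (first row per transcript after the canonical
#' ordering) stands in for the transcript's protein in all downstream stages,
#' so each transcript is counted exactly once.
#'
#' @param orf_table output of [extract_orfs_set()].
#' @return one-row-per-transcript subset of `orf_table`.
#' @export
representative_orfs <- function(orf_table) {
  orf_table[!duplicated(orf_table$transcript_id), , drop = FALSE]
}

#' Flag antisense transcripts from the annotation reading frame
#'
#' A strand-specific transcript whose best annotation hit lies in a negative
#' reading frame (-1, -2, -3) is treated as a non-coding antisense transcript.
#' Transcripts without any annotation hit cannot be flagged.
#'
#' @param best_hit_frame integer vector of frames in `{-3..-1, 1..3}`; `NA`
#'   for transcripts without an annotation hit.
#' @return logical vector.
#' @export
flag_antisense <- function(best_hit_frame) {
  ok <- is.na(best_hit_frame) | best_hit_frame %in% FRAME_ORDER
  if (!all(ok))
    stop_input("invalid annotation frame: %s", best_hit_frame[!ok][1])
  !is.na(best_hit_frame) & best_hit_frame < 0
}
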