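# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package's own paths.

ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_translate <- function(nt, frame) {
  if (frame < 0) { nt <- oracle_revcomp(nt); frame <- -frame }
  off <- frame - 1
  n <- (nchar(nt) - off) %/% 3
  if (n <= 0) return("")
  aa <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(nt, off + 3 * (i - 1) + 1, off + 3 * i)
    a <- ORACLE_CODONS[cod]
    aa[i] <- if (is.na(a)) "X" else a
  }
  paste(aa, collapse = "")
}

# brute-force six-frame ORF scan: every codon position of every frame is
# tested directly; returns the canonical tuple set
oracle_orfs <- function(seq, min_len) {
  n <- nchar(seq)
  rows <- list()
  for (f in c(1, 2, 3, -1, -2, -3)) {
    aa <- oracle_translate(seq, f)
    L <- nchar(aa)
    if (L == 0) next
    ch <- strsplit(aa, "")[[1]]
    emit <- function(i, j, has_start, has_stop) {
      a <- abs(f) - 1 + 3 * (i - 1) + 1
      b <- abs(f) - 1 + 3 * j
      if (f > 0) { s <- a; e <- b } else { s <- n - b + 1; e <- n - a + 1 }
      aaseq <- if (has_stop) substr(aa, i, j - 1) else substr(aa, i, j)
      rows[[length(rows) + 1]] <<- data.frame(
        frame = f, nt_start = s, nt_end = e, n_codons = j - i + 1,
        partial = !(has_start && has_stop), aa_sequence = aaseq,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(L)) {
      if (ch[i] != "M") next
      j <- i
      while (j <= L && ch[j] != "*") j <- j + 1
      if (j <= L) { if (j - i + 1 >= min_len) emit(i, j, TRUE, TRUE) }
      else if (L - i + 1 >= min_len) emit(i, L, TRUE, FALSE)
    }
    if (ch[1] != "M") {
      j <- 1
      while (j <= L && ch[j] != "*") j <- j + 1
      if (j <= L) { if (j > 1 && j >= min_len) emit(1, j, FALSE, TRUE) }
      else if (L >= min_len) emit(1, L, FALSE, FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), nt_start = integer(0),
               nt_end = integer(0), n_codons = integer(0),
               partial = logical(0), aa_sequence = character(0))
  out[order(out$frame, out$nt_start, out$nt_end), , drop = FALSE]
}

oracle_best_hit <- function(hits, max_e = 1e-3, min_cov = 0.70) {
  best <- NULL
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    qc <- (h$q_end - h$q_start + 1) / h$q_len
    sc <- (h$s_end - h$s_start + 1) / h$s_len
    if (qc < min_cov || sc < min_cov || h$e_value > max_e) next
    if (is.null(best)) { best <- h; next }
    better <- h$e_value < best$e_value ||
      (h$e_value == best$e_value && h$bit_score > best$bit_score) ||
      (h$e_value == best$e_value && h$bit_score == best$bit_score &&
         h$subject_id < best$subject_id)
    if (better) best <- h
  }
  best
}

# independent sliding-window hydropathy recomputation (direct window means)
oracle_kd_segments <- function(aa, window = 19, threshold = 1.6) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  ch <- strsplit(aa, "")[[1]]
  L <- length(ch)
  if (L < window) return(list(starts = integer(0), ends = integer(0)))
  above <- logical(L - window + 1)
  for (i in seq_along(above)) {
    vals <- kd[ch[i:(i + window - 1)]]
    vals[is.na(vals)] <- 0
    above[i] <- mean(vals) > threshold + 1e-9
  }
  starts <- integer(0); ends <- integer(0)
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      starts <- c(starts, i); ends <- c(ends, j + window - 1)
      i <- j + 1
    } else i <- i + 1
  }
  list(starts = starts, ends = ends)
}

# residue-coverage union of intervals via an explicit boolean mask
oracle_interval_union <- function(starts, ends) {
  if (!length(starts)) return(list(starts = integer(0), ends = integer(0)))
  L <- max(ends)
  cov <- rep(FALSE, L)
  for (i in seq_along(starts)) cov[starts[i]:ends[i]] <- TRUE
  r <- rle(cov)
  pos <- cumsum(c(1, r$lengths))
  keep <- which(r$values)
  list(starts = as.integer(pos[keep]),
       ends = as.integer(pos[keep] + r$lengths[keep] - 1))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
random_protein <- function(n) paste(sample(names(oracle_kd_scale()), n,
                                           replace = TRUE), collapse = "")
oracle_kd_scale <- function() c(A = 1.8, R = -4.5, N = -3.5, D = -3.5,
                                C = 2.5, Q = -3.5, E = -3.5, G = -0.4,
                                H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                                M = 1.9, F = 2.8, P = -1.6, S = -0.8,
                                T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

random_hits <- function(n_hits, n_queries = 3) {
  data.frame(
    query_id = sample(paste0("q", seq_len(n_queries)), n_hits, replace = TRUE),
    subject_id = paste0("s", sample(100, n_hits, replace = TRUE)),
    pct_identity = runif(n_hits, 20, 95),
    aln_length = 0L,
    q_start = 1L, q_end = sample(40:100, n_hits, replace = TRUE),
    s_start = 1L, s_end = sample(40:100, n_hits, replace = TRUE),
    e_value = 10^-sample(0:12, n_hits, replace = TRUE),
    bit_score = sample(50:500, n_hits, replace = TRUE),
    q_len = 100L, s_len = 100L,
    subject_desc = "", s_minus_strand = FALSE,
    stringsAsFactors = FALSE)
}
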