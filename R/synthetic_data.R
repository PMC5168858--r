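# Synthetic strand-specific transcriptomes with planted, fully known
# classification truth, plus mock annotation files in the exact dialects the
# pipeline parsers read.  Every downstream stage is testable against the
# planted truth without any external data.

GEN_TC_CLASSES <- c(
  tc_mfs_sugar = "2.A.1.1.8",    tc_sss_sugar = "2.A.2.3.1",
  tc_sweet_sugar = "2.A.123.1.4", tc_abc_sugar = "3.A.1.1.2",
  tc_dha_drug = "2.A.1.2.16",    tc_mate_drug = "2.A.66.1.3",
  tc_abc_drug = "3.A.1.201.5",   tc_ion_channel = "1.A.1.11.1",
  tc_ptype_pump = "3.A.3.1.1",   tc_secretory = "3.A.5.8.1",
  tc_nuclear = "1.I.1.1.1",      tc_peroxisomal = "3.A.20.1.1",
  tc_organelle = "3.A.8.1.1",    tc_mito_carrier = "2.A.29.2.5",
  tc_other = "9.B.27.1.1")

GEN_GPCR_CLASSES <- list(
  gpcr_rhodopsin = list(class = "RHODOPSIN_DICTY_CAR", flags = character(0)),
  gpcr_classC_sbp = list(class = "CLASS_C", flags = "SBP_TYPE_II"),
  gpcr_classC_pectin = list(class = "CLASS_C",
                            flags = c("BETA_HELIX", "PECTIN_LYASE")),
  gpcr_classC_plain = list(class = "CLASS_C", flags = character(0)))

GEN_CLASSES <- c("soluble", "secreted", "bitopic", "polytopic", "antisense",
                 names(GEN_TC_CLASSES), names(GEN_GPCR_CLASSES))

ROLE_GO <- list(
  TRANSPORT = c("GO:0055085", "transmembrane transport"),
  SENSING_SIGNALING = c("GO:0007165", "signal transduction"),
  CATALYSIS = c("GO:0004558", "alpha-glucosidase"),
  OTHER = c("GO:0007155", "cell adhesion"))

#' Default planted-class mixture
#'
#' Proportions chosen to resemble a gut-fungal transcriptome at a glance:
#' about a fifth of transcripts trafficked, roughly a third of those fully
#' secreted, membrane proteins split between bitopic and polytopic, a small
#' antisense arm, transporters spread over every TCDB category the
#' classifier knows, and a thin tail of GPCR architectures dominated by
#' class C.
#' @return named numeric vector over the generator classes, summing to 1.
#' @export
default_class_mix <- function() {
  c(soluble = 0.66, antisense = 0.05, secreted = 0.07,
    bitopic = 0.06, polytopic = 0.06,
    tc_mfs_sugar = 0.008, tc_sss_sugar = 0.005, tc_sweet_sugar = 0.005,
    tc_abc_sugar = 0.010, tc_dha_drug = 0.006, tc_mate_drug = 0.005,
    tc_abc_drug = 0.006, tc_ion_channel = 0.007, tc_ptype_pump = 0.006,
    tc_secretory = 0.008, tc_nuclear = 0.005, tc_peroxisomal = 0.004,
    tc_organelle = 0.005, tc_mito_carrier = 0.004, tc_other = 0.004,
    gpcr_rhodopsin = 0.002, gpcr_classC_sbp = 0.005,
    gpcr_classC_pectin = 0.003, gpcr_classC_plain = 0.002)
}

#' Generator configuration
#'
#' @param n_transcripts transcripts per simulated strain (>= 1).
#' @param strain_names labels of the simulated strains.
#' @param class_mix named proportions over the generator classes (see
#'   [default_class_mix()]); must sum to 1 within 1e-9.
#' @param orf_len_range planted ORF length range in codons (stop included)
#'   for classes whose length is not dictated by their architecture.
#' @param tm_count_range TM-segment count range for generic polytopic
#'   proteins.
#' @param noise per-record corruption probability for mock annotations.
#' @param seed integer seed for the random stream.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_transcripts = 1000L,
                             strain_names = c("Neocallimastix",
                                              "Anaeromyces", "Piromyces"),
                             class_mix = default_class_mix(),
                             orf_len_range = c(120L, 400L),
                             tm_count_range = c(2L, 8L),
                             noise = 0, seed = 1L) {
  if (n_transcripts < 1L) stop_input("n_transcripts must be >= 1")
  if (!length(strain_names) || anyDuplicated(strain_names))
    stop_input("strain_names must be nonempty and unique")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% GEN_CLASSES))
    stop_input("class_mix names must be generator classes")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9)
    stop_input("class_mix proportions must be >= 0 and sum to 1 (+/- 1e-9)")
  if (length(orf_len_range) != 2L || orf_len_range[1] > orf_len_range[2] ||
      orf_len_range[1] < 60L)
    stop_input("orf_len_range must be a nonempty range of >= 60 codons")
  if (length(tm_count_range) != 2L || tm_count_range[1] > tm_count_range[2] ||
      tm_count_range[1] < 2L)
    stop_input("tm_count_range must be a nonempty range with minimum >= 2")
  if (noise < 0 || noise > 1) stop_input("noise must be in [0, 1]")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 strain_names = strain_names, class_mix = class_mix,
                 orf_len_range = as.integer(orf_len_range),
                 tm_count_range = as.integer(tm_count_range),
                 noise = noise, seed = as.integer(seed)),
            class = "generator_config")
}

POLAR_AA <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P", "H", "Y")
POLAR_W <- c(1.2, 1.2, 1.2, 1, 1, 1, 1, 1, 0.8, 0.6, 0.6, 0.6)
HYDRO_AA <- c("L", "I", "V", "F", "A")
HYDRO_W <- c(0.35, 0.2, 0.2, 0.15, 0.1)

# Polar loop/body residues with occasional hydrophobic singletons.  The
# singletons matter: codons with TA/TG at positions 2-3 (only found among
# L/I/V/M codons) are what seed stop codons in the +1-shifted reading frame,
# keeping frame-shifted open-ended ORFs from outranking the planted ORF.
# At 8% density they never push a 19-residue hydropathy window anywhere near
# the transmembrane threshold.
polar_run <- function(n) {
  res <- sample(POLAR_AA, n, replace = TRUE, prob = POLAR_W)
  k <- which(stats::runif(n) < 0.08)
  if (length(k))
    res[k] <- sample(c("L", "I", "V", "M"), length(k), replace = TRUE)
  res
}
hydro_run <- function(n) sample(HYDRO_AA, n, replace = TRUE, prob = HYDRO_W)
rint <- function(lo, hi) sample(seq.int(lo, hi), 1L)

# codon back-translation table from the standard genetic code, flattened for
# vectorised lookup: codons named "A1", "A2", ... per amino acid
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  flat <- unlist(lapply(names(by_aa), function(a)
    stats::setNames(by_aa[[a]], paste0(a, seq_along(by_aa[[a]])))))
  list(n = lengths(by_aa), flat = flat)
}

backtranslate <- function(aa, codon_tab) {
  pick <- 1L + floor(stats::runif(length(aa)) * codon_tab$n[aa])
  paste(codon_tab$flat[paste0(aa, pick)], collapse = "")
}

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# Build the protein architecture for one planted class.  Returns residues
# (character vector incl. leading M), SP call, actual TM segments (excluding
# the SP helix), and for GPCRs the N-terminal region end.
build_architecture <- function(class, cfg) {
  len <- rint(cfg$orf_len_range[1], cfg$orf_len_range[2]) - 1L  # aa length
  sp_core <- c("K", "R", hydro_run(12L), "A", "Q", "A")  # res 2..18
  res <- "M"; sp <- FALSE; cleav <- NA_integer_
  tm_s <- integer(0); tm_e <- integer(0); sp_helix <- NULL; nterm_end <- NA_integer_
  add_tm <- function(res) {
    s <- length(res) + 1L
    res <- c(res, hydro_run(21L))
    list(res = res, s = s, e = s + 20L)
  }
  add_sp <- function(res) c(res, sp_core)
  if (class %in% c("soluble", "antisense")) {
    res <- c(res, polar_run(len - 1L))
  } else if (class == "secreted") {
    res <- add_sp(res); sp <- TRUE; cleav <- 18L; sp_helix <- c(4L, 15L)
    res <- c(res, polar_run(max(40L, len - length(res))))
  } else if (class == "bitopic") {
    pre <- rint(30L, 80L)
    res <- c(res, polar_run(pre))
    t <- add_tm(res); res <- t$res; tm_s <- t$s; tm_e <- t$e
    res <- c(res, polar_run(max(30L, len - length(res))))
  } else if (class == "polytopic" || startsWith(class, "tc_")) {
    k <- if (class == "polytopic") rint(cfg$tm_count_range[1],
                                        cfg$tm_count_range[2])
         else rint(4L, 8L)
    if (class == "polytopic" && stats::runif(1) < 0.3) {
      res <- add_sp(res); sp <- TRUE; cleav <- 18L; sp_helix <- c(4L, 15L)
    }
    res <- c(res, polar_run(rint(25L, 50L)))
    for (j in seq_len(k)) {
      t <- add_tm(res); res <- t$res
      tm_s <- c(tm_s, t$s); tm_e <- c(tm_e, t$e)
      res <- c(res, polar_run(if (j < k) rint(25L, 40L) else rint(20L, 35L)))
    }
  } else if (startsWith(class, "gpcr_")) {
    if (stats::runif(1) < 0.3) {
      res <- add_sp(res); sp <- TRUE; cleav <- 18L; sp_helix <- c(4L, 15L)
    }
    res <- c(res, polar_run(rint(300L, 700L)))
    nterm_end <- length(res)
    for (j in 1:7) {
      t <- add_tm(res); res <- t$res
      tm_s <- c(tm_s, t$s); tm_e <- c(tm_e, t$e)
      res <- c(res, polar_run(if (j < 7) rint(25L, 40L) else rint(20L, 35L)))
    }
  } else stop_input("unknown generator class '%s'", class)
  list(res = res, sp = sp, cleavage_after = cleav, sp_helix = sp_helix,
       tm_starts = tm_s, tm_ends = tm_e, nterm_end = nterm_end)
}

# domain/GO/alignment plans for one transcript
plan_annotations <- function(class, id, arch, cfg) {
  plen <- length(arch$res)
  role <- NA_character_; tc <- NA_character_
  gpcr_class <- NA_character_; gpcr_flags <- character(0)
  dom <- list(); aln <- list()
  add_dom <- function(dom, sig, ipr, desc, s, e, ev, go) {
    dom[[length(dom) + 1L]] <- list(signature_id = sig, interpro_id = ipr,
                                    desc = desc, start = s, end = e,
                                    e_value = ev, go = go)
    dom
  }
  go_of <- function(role) sprintf("%s(%s)", ROLE_GO[[role]][1], ROLE_GO[[role]][2])
  add_aln <- function(aln, tag, ev, qs, qe, sl, ss, se, bits) {
    aln[[length(aln) + 1L]] <- list(
      subject_id = sprintf("gnl|TC-DB|Q%05d|%s", length(aln) + 1L, tag),
      e_value = ev, q_start = qs, q_end = qe, q_len = plen,
      s_len = sl, s_start = ss, s_end = se, bit_score = bits,
      subject_desc = "transporter component")
    aln
  }
  if (class == "soluble") {
    role <- "UNKNOWN"
    if (stats::runif(1) < 0.3)  # low-coverage decoy hit only
      aln <- add_aln(aln, "1.C.1.1.1", 1e-40, 1L, max(2L, floor(0.5 * plen)),
                     plen, 1L, max(2L, floor(0.5 * plen)), 80)
  } else if (class == "antisense") {
    dom <- add_dom(dom, "PF99001", "-", "hypothetical protein domain",
                   10L, min(60L, plen - 1L), 1e-8,
                   "GO:0005515(protein binding)")
  } else if (class == "secreted") {
    role <- "CATALYSIS"
    dom <- add_dom(dom, "PF99002", "-", "glycoside hydrolase domain",
                   30L, min(120L, plen - 1L), 1e-12, go_of("CATALYSIS"))
  } else if (class %in% c("bitopic", "polytopic")) {
    role <- sample(role_levels(), 1L,
                   prob = c(0.10, 0.15, 0.30, 0.25, 0.20))
    go <- if (role == "UNKNOWN") "-" else go_of(role)
    dom <- add_dom(dom, "PF99003", "-", "predicted membrane protein domain",
                   10L, min(60L, plen - 1L), 1e-10, go)
  } else if (startsWith(class, "tc_")) {
    role <- "TRANSPORT"; tc <- unname(GEN_TC_CLASSES[class])
    dom <- add_dom(dom, "PF99004", "-", "transporter domain",
                   10L, min(80L, plen - 1L), 1e-15, go_of("TRANSPORT"))
    ev <- 10^-rint(20L, 60L)
    aln <- add_aln(aln, tc, ev, 1L, plen, plen, 1L, plen, 300)
    # passing-coverage decoy with worse E and a different family
    aln <- add_aln(aln, "9.B.99.1.1", 1e-4, 1L, plen, plen, 1L, plen, 90)
    # strong-E decoy failing reciprocal coverage on the subject side
    aln <- add_aln(aln, "1.C.1.1.1", 1e-80, 1L, plen,
                   2L * plen, 1L, plen, 150)
  } else if (startsWith(class, "gpcr_")) {
    role <- "SENSING_SIGNALING"
    spec <- GEN_GPCR_CLASSES[[class]]
    gpcr_class <- spec$class; gpcr_flags <- spec$flags
    bundle_start <- arch$tm_starts[1]
    if (gpcr_class == "CLASS_C") {
      dom <- add_dom(dom, "PF00003", "IPR017978",
                     "GPCR, family 3 (class C, glutamate receptor-like)",
                     bundle_start, plen - 5L, 1e-25,
                     "GO:0004930(g-protein coupled receptor activity)")
    } else {
      dom <- add_dom(dom, "PF00001", "IPR017452",
                     "GPCR, rhodopsin-like, 7TM",
                     bundle_start, plen - 5L, 1e-25,
                     "GO:0004930(g-protein coupled receptor activity)")
    }
    if ("SBP_TYPE_II" %in% gpcr_flags)
      dom <- add_dom(dom, "SSF53850", "-",
                     "Periplasmic binding protein-like II",
                     30L, arch$nterm_end - 20L, 1e-18, "-")
    if ("PECTIN_LYASE" %in% gpcr_flags)
      dom <- add_dom(dom, "PF12708", "IPR011050",
                     "Pectin lyase fold/virulence factor",
                     30L, min(200L, arch$nterm_end - 60L), 1e-14, "-")
    if ("BETA_HELIX" %in% gpcr_flags)
      dom <- add_dom(dom, "PF13229", "IPR006626",
                     "Pectate lyase/parallel beta-helix repeat",
                     min(210L, arch$nterm_end - 50L), arch$nterm_end - 30L,
                     1e-9, "-")
  }
  list(role = role, tc = tc, gpcr_class = gpcr_class,
       gpcr_flags = gpcr_flags, domains = dom, alignments = aln)
}

build_transcript <- function(class, id, cfg, codon_tab) {
  arch <- build_architecture(class, cfg)
  plan <- plan_annotations(class, id, arch, cfg)
  orf_nt <- paste0(backtranslate(arch$res[-1L], codon_tab),
                   sample(c("TAA", "TAG", "TGA"), 1L))
  orf_nt <- paste0("ATG", orf_nt)
  u5 <- rint(6L, 30L); u3 <- rint(6L, 30L)
  # in-frame stop planted just upstream of ATG keeps the 5'-open partial ORF
  # from outranking the planted ORF
  seq <- paste0(rand_nt(u5), "TAA", orf_nt, rand_nt(u3))
  nt_start <- u5 + 4L
  nt_end <- nt_start + nchar(orf_nt) - 1L
  frame <- ((nt_start - 1L) %% 3L) + 1L
  n <- nchar(seq)
  if (class == "antisense") {
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    tmp <- nt_start
    nt_start <- n - nt_end + 1L
    nt_end <- n - tmp + 1L
    frame <- -frame
  }
  plen <- length(arch$res)
  tm_raw <- length(arch$tm_starts) + if (arch$sp) 1L else 0L
  tm_noncleaved <- length(arch$tm_starts)
  loc <- if (class == "antisense") "ANTISENSE_NONCODING"
    else if (tm_noncleaved >= 2L) "POLYTOPIC_MEMBRANE"
    else if (tm_noncleaved == 1L) "BITOPIC_MEMBRANE"
    else if (arch$sp) "SECRETED" else "SOLUBLE"
  truth <- list(
    transcript_id = id, class = class, localization = loc,
    go_role = plan$role, tc_id = plan$tc,
    gpcr_class = plan$gpcr_class,
    gpcr_flags = paste(sort(plan$gpcr_flags), collapse = ","),
    frame = frame, sp_present = arch$sp,
    tm_count_raw = tm_raw, tm_count_noncleaved = tm_noncleaved,
    protein_length = plen, n_term_end = arch$nterm_end,
    nt_start = nt_start, nt_end = nt_end)
  list(seq = seq, truth = truth, arch = arch, plan = plan)
}

#' Generate a synthetic multi-strain transcriptome with planted truth
#'
#' Each transcript carries one planted ORF (start codon, in-frame stop)
#' whose translated protein has the sequence features its planted class
#' implies: strongly hydrophobic 21-residue stretches for each planted TM
#' segment, an N-terminal signal-peptide-like stretch for secretory classes,
#' neither for soluble proteins; antisense transcripts carry the ORF on the
#' reverse strand. A post-generation check re-extracts ORFs and resamples
#' any transcript whose random flanks would let a competing ORF outrank the
#' planted one, so the planted ORF is always the representative. The same
#' seed gives byte-identical output.
#'
#' @param config a [generator_config()].
#' @return object of class `membrane_sim`: list with `config`, `transcripts`
#'   (named character vector), `truth` (one row per transcript, including a
#'   `strain` column), and internal annotation plans consumed by
#'   [emit_mock_annotations()].
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  codon_tab <- codons_by_aa()
  classes <- names(config$class_mix)
  seqs <- character(0); truths <- list(); archs <- list(); plans <- list()
  for (strain in config$strain_names) {
    planted <- sample(classes, config$n_transcripts, replace = TRUE,
                      prob = config$class_mix)
    for (i in seq_len(config$n_transcripts)) {
      id <- sprintf("%s_t%05d", strain, i)
      bt <- build_transcript(planted[i], id, config, codon_tab)
      bt$truth$strain <- strain
      seqs[id] <- bt$seq
      truths[[id]] <- bt$truth
      archs[[id]] <- bt$arch
      plans[[id]] <- bt$plan
    }
  }
  truth_df <- function(truths) {
    cols <- names(truths[[1]])
    out <- lapply(cols, function(cn)
      unlist(lapply(truths, `[[`, cn), use.names = FALSE))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  truth <- truth_df(truths)
  # representative-ORF check: regenerate the rare transcript whose random
  # flanks or wobble bases create a longer competing ORF; later rounds only
  # re-check the resampled transcripts
  pending <- truth$transcript_id
  for (round in 1:20) {
    orfs <- extract_orfs_set(seqs[pending], min_len_codons = 50L)
    rep_orfs <- representative_orfs(orfs)
    tr <- truth[match(pending, truth$transcript_id), , drop = FALSE]
    m <- match(pending, rep_orfs$transcript_id)
    ok <- !is.na(m) &
      rep_orfs$frame[m] == tr$frame &
      rep_orfs$nt_start[m] == tr$nt_start &
      rep_orfs$nt_end[m] == tr$nt_end &
      !rep_orfs$partial[m]
    if (all(ok)) break
    pending <- pending[!ok]
    for (id in pending) {
      row <- which(truth$transcript_id == id)
      bt <- build_transcript(truth$class[row], id, config, codon_tab)
      bt$truth$strain <- truth$strain[row]
      seqs[id] <- bt$seq
      truth[row, ] <- bt$truth[names(truth)]
      archs[[id]] <- bt$arch
      plans[[id]] <- bt$plan
    }
    if (round == 20L)
      stop("could not plant a dominant ORF after 20 rounds")
  }
  structure(list(config = config, transcripts = seqs, truth = truth,
                 archs = archs, plans = plans),
            class = "membrane_sim")
}

#' @export
print.membrane_sim <- function(x, ...) {
  cat(sprintf("<membrane_sim> %d strains x %d transcripts (seed %d)\n",
              length(x$config$strain_names), x$config$n_transcripts,
              x$config$seed))
  print(table(x$truth$class))
  invisible(x)
}

# ---- mock annotation emission -------------------------------------------

fmt_topology_string <- function(starts, ends) {
  if (!length(starts)) return("o")
  sides <- rep(c("o", "i"), length.out = length(starts) + 1L)
  paste0(paste0(sides[seq_along(starts)],
                starts, "-", ends, collapse = ""),
         sides[length(starts) + 1L])
}

#' Emit mock annotation files for a synthetic transcriptome
#'
#' Writes, per strain: transcript FASTA, TMHMM-short / Phobius-short /
#' SignalP-short topology files, a 15-column alignment table against a mock
#' TCDB (subject ids embed the planted TC tags; decoy hits plant coverage
#' and e-value failures), an InterProScan-style domain TSV (GPCR
#' architectures use the packaged signature ids), and the truth table TSV.
#' The mock TMHMM output renders a planted signal peptide as an extra
#' N-terminal helix, as the real predictor tends to; Phobius and SignalP
#' render it as a signal peptide.
#'
#' With `noise = 0` every record is consistent with the planted truth. With
#' `noise = p` each topology / alignment / domain record is independently
#' corrupted with probability p in exactly one field (a TM count, a
#' signal-peptide call, an e-value pushed across the significance cutoff, a
#' coverage span, a GO role keyword, or a signature id); corruption always
#' changes the record, and files stay parseable.
#'
#' @param sim a [generate_transcriptome()] result.
#' @param dir output directory (created if needed).
#' @param noise per-record corruption probability; defaults to the
#'   generator config.
#' @param seed seed for the corruption stream; defaults to config seed + 1.
#' @return named list of written file paths per strain, invisibly.
#' @export
emit_mock_annotations <- function(sim, dir, noise = sim$config$noise,
                                  seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "membrane_sim"))
  if (!setequal(sim$truth$transcript_id, names(sim$transcripts)))
    stop_input("truth table and transcripts disagree on ids")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  out <- list()
  other_role_go <- function(cur_go) {
    # role-changing replacement: cycle transport -> signal -> -ase -> other
    all_go <- vapply(names(ROLE_GO), function(r)
      sprintf("%s(%s)", ROLE_GO[[r]][1], ROLE_GO[[r]][2]), "")
    pool <- setdiff(all_go, cur_go)
    sample(pool, 1L)
  }
  for (strain in sim$config$strain_names) {
    ids <- sim$truth$transcript_id[sim$truth$strain == strain]
    fa <- file.path(dir, paste0(strain, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$transcripts[ids]), fa, width = 70L)
    tm_lines <- character(0); pb_lines <- character(0); sp_lines <- character(0)
    aln_rows <- list(); dom_rows <- list()
    for (id in ids) {
      a <- sim$archs[[id]]; p <- sim$plans[[id]]
      plen <- length(a$res)
      # --- TMHMM: SP rendered as an extra helix
      th_s <- c(if (a$sp) a$sp_helix[1], a$tm_starts)
      th_e <- c(if (a$sp) a$sp_helix[2], a$tm_ends)
      if (stats::runif(1) < noise) {
        if (length(th_s)) { th_s <- th_s[-length(th_s)]; th_e <- th_e[-length(th_e)] }
        else { th_s <- 50L; th_e <- 70L }
      }
      tm_lines <- c(tm_lines, sprintf(
        "%s\tlen=%d\tExpAA=%.1f\tFirst60=%.1f\tPredHel=%d\tTopology=%s",
        id, plen, 22.5 * length(th_s), 1.5, length(th_s),
        fmt_topology_string(th_s, th_e)))
      # --- Phobius: true SP + true TMs
      pb_sp <- a$sp
      if (stats::runif(1) < noise) pb_sp <- !pb_sp
      pred <- if (pb_sp)
        paste0(sprintf("n4-15c%d/%d", if (a$sp) a$cleavage_after else 18L,
                       (if (a$sp) a$cleavage_after else 18L) + 1L),
               fmt_topology_string(a$tm_starts, a$tm_ends))
      else fmt_topology_string(a$tm_starts, a$tm_ends)
      pb_lines <- c(pb_lines, sprintf("%s  %d  %s  %s", id,
                                      length(a$tm_starts),
                                      if (pb_sp) "Y" else "0", pred))
      # --- SignalP
      sp_call <- a$sp
      if (stats::runif(1) < noise) sp_call <- !sp_call
      cpos <- (if (a$sp) a$cleavage_after else 18L) + 1L
      sp_lines <- c(sp_lines, sprintf(
        "%s 0.52 %d 0.51 %d 0.60 12 0.48 0.47 %s 0.45 SignalP-noTM",
        id, cpos, cpos, if (sp_call) "Y" else "N"))
      # --- alignments
      for (h in p$alignments) {
        if (noise > 0 && stats::runif(1) < noise) {
          if (stats::runif(1) < 0.5)
            h$e_value <- if (h$e_value <= 1e-3) 1e-2 else 1e-4
          else h$q_end <- max(h$q_start + 1L, floor(0.6 * h$q_len))
        }
        aln_rows[[length(aln_rows) + 1L]] <- sprintf(
          "%s\t%s\t47.5\t%d\t0\t0\t%d\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%s",
          id, h$subject_id, h$q_end - h$q_start + 1L, h$q_start, h$q_end,
          h$s_start, h$s_end, format(h$e_value, scientific = TRUE),
          format(h$bit_score), h$q_len, h$s_len, h$subject_desc)
      }
      # --- domains
      for (d in p$domains) {
        if (noise > 0 && stats::runif(1) < noise) {
          if (d$go != "-") d$go <- other_role_go(d$go)
          else if (d$interpro_id != "-") d$interpro_id <- "IPR999999"
          else d$signature_id <- "SSF99999"
        }
        dom_rows[[length(dom_rows) + 1L]] <- sprintf(
          "%s\t0\t%d\tPfam\t%s\t%s\t%d\t%d\t%s\tT\t01-01-2020\t%s\t%s\t%s",
          id, plen, d$signature_id, d$desc, d$start, d$end,
          format(d$e_value, scientific = TRUE), d$interpro_id,
          if (d$interpro_id == "-") "-" else d$desc, d$go)
      }
    }
    files <- list(
      fasta = fa,
      tmhmm = file.path(dir, paste0(strain, "_tmhmm.txt")),
      phobius = file.path(dir, paste0(strain, "_phobius.txt")),
      signalp = file.path(dir, paste0(strain, "_signalp.txt")),
      tcdb = file.path(dir, paste0(strain, "_tcdb.tsv")),
      domains = file.path(dir, paste0(strain, "_domains.tsv")))
    writeLines(tm_lines, files$tmhmm)
    writeLines(c("SEQENCE ID  TM  SP  PREDICTION", pb_lines), files$phobius)
    writeLines(c("# name Cmax pos Ymax pos Smax pos Smean D ? Dmaxcut net",
                 sp_lines), files$signalp)
    writeLines(as.character(unlist(aln_rows)), files$tcdb)
    writeLines(as.character(unlist(dom_rows)), files$domains)
    out[[strain]] <- files
  }
  truth_path <- file.path(dir, "truth.tsv")
  write_tsv(sim$truth, truth_path)
  out$truth <- truth_path
  invisible(out)
}
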