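# End-to-end orchestration: ORF extraction -> topology -> funnel -> GO roles
# -> TCDB transporters -> GPCR architecture -> report bundle.

#' Pipeline run configuration
#'
#' Either `synthetic` (a [generator_config()]) or `inputs` must be given.
#' `inputs` is a named list (one element per strain) of file paths:
#' `fasta` (required), and optionally `tmhmm`, `phobius`, `signalp`
#' (topology dialects), `tcdb` (alignment tabular) and `domains`
#' (InterProScan-style TSV). Strains without any topology file fall back to
#' the built-in hydropathy predictor.
#'
#' @param synthetic optional [generator_config()]; inputs are generated and
#'   written under `out_dir/inputs`, then read back through the same parsers
#'   real inputs use.
#' @param inputs optional named list of per-strain input paths.
#' @param out_dir output directory for intermediates and reports.
#' @param min_orf_codons minimum ORF length in codons (default 50).
#' @param min_cov reciprocal TCDB coverage threshold (default 0.70).
#' @param max_e inclusive e-value cutoff for alignments and domains
#'   (default 1e-3).
#' @param tm_gate inclusive GPCR raw-TM-count gate (default `c(7, 9)`).
#' @param merge_mode topology combination rule (default `"union"`).
#' @param category_map path to a TC category map TSV (default: packaged map).
#' @param gpcr_signatures path to a GPCR signature TSV (default: packaged).
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL,
                       out_dir = tempfile("membrane_run_"),
                       min_orf_codons = 50L, min_cov = 0.70, max_e = 1e-3,
                       tm_gate = c(7L, 9L), merge_mode = "union",
                       category_map = NULL, gpcr_signatures = NULL) {
  if (is.null(synthetic) && is.null(inputs))
    stop_input("either synthetic generator config or real inputs required")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "generator_config"))
  if (min_orf_codons < 1L) stop_input("min_orf_codons must be >= 1")
  if (min_cov < 0 || min_cov > 1) stop_input("min_cov must be in [0, 1]")
  if (max_e < 0) stop_input("max_e must be >= 0")
  if (length(tm_gate) != 2L || tm_gate[1] > tm_gate[2])
    stop_input("tm_gate must be a nonempty range")
  merge_mode <- match.arg(merge_mode, c("union", "intersection", "priority"))
  structure(list(synthetic = synthetic, inputs = inputs, out_dir = out_dir,
                 min_orf_codons = as.integer(min_orf_codons),
                 min_cov = min_cov, max_e = max_e,
                 tm_gate = as.integer(tm_gate), merge_mode = merge_mode,
                 category_map = category_map,
                 gpcr_signatures = gpcr_signatures),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the same keys as [run_config()]; a `synthetic` block (with
#' `n_transcripts`, `strain_names`, `orf_len_range`, `tm_count_range`,
#' `noise`, `seed`) is passed to [generator_config()], and an `inputs` block
#' maps strain names to per-strain file paths. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path YAML config file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  synthetic <- NULL
  if (!is.null(y$synthetic))
    synthetic <- do.call(generator_config, y$synthetic)
  inputs <- y$inputs
  if (!is.null(inputs))
    inputs <- lapply(inputs, function(files)
      lapply(files, function(f)
        if (file.exists(f)) f else file.path(base, f)))
  extra <- y[setdiff(names(y), c("synthetic", "inputs"))]
  do.call(run_config, c(list(synthetic = synthetic, inputs = inputs), extra))
}

# merged profile per protein from whichever dialect files a strain has
build_profiles <- function(files, rep_tab) {
  frags <- list()
  if (!is.null(files$tmhmm))
    frags$tmhmm <- read_topology_files(files$tmhmm, "tmhmm-short")
  if (!is.null(files$phobius))
    frags$phobius <- read_topology_files(files$phobius, "phobius-short")
  if (!is.null(files$signalp))
    frags$signalp <- read_topology_files(files$signalp, "signalp-short")
  if (!length(frags)) {
    profs <- lapply(seq_len(nrow(rep_tab)), function(i)
      predict_topology_fallback(rep_tab$aa_sequence[i],
                                rep_tab$transcript_id[i]))
    names(profs) <- rep_tab$transcript_id
    return(profs)
  }
  ids <- unique(unlist(lapply(frags, names)))
  profs <- lapply(ids, function(id) {
    pieces <- lapply(frags, `[[`, id)
    merge_predictions(pieces[!vapply(pieces, is.null, TRUE)])
  })
  stats::setNames(profs, ids)
}

run_strain <- function(strain, files, cfg, category_map, signatures) {
  dna <- Biostrings::readDNAStringSet(files$fasta)
  names(dna) <- sub("\\s.*$", "", names(dna))
  orfs <- extract_orfs_set(dna, cfg$min_orf_codons)
  reps <- representative_orfs(orfs)
  profiles <- build_profiles(files, reps)

  aln <- if (!is.null(files$tcdb)) read_alignment_table(files$tcdb)
         else empty_alignment_table()
  dom <- if (!is.null(files$domains)) read_domain_table(files$domains, cfg$max_e)
         else read_domain_table(tempfile_empty())

  annotated_ids <- unique(c(aln$query_id, dom$domains$protein_id,
                            dom$go$protein_id))
  reps$antisense <- flag_antisense(
    ifelse(reps$transcript_id %in% annotated_ids, reps$frame, NA_integer_))

  loc <- character(nrow(reps)); no_profile <- logical(nrow(reps))
  for (i in seq_len(nrow(reps))) {
    cl <- classify_localization(profiles[[reps$transcript_id[i]]],
                                reps$antisense[i])
    loc[i] <- cl
    no_profile[i] <- isTRUE(attr(cl, "no_profile"))
  }

  go_by_id <- split(dom$go$go_name, dom$go$protein_id)
  role <- vapply(reps$transcript_id,
                 function(id) assign_role(go_by_id[[id]] %||% character(0)),
                 "", USE.NAMES = FALSE)

  tc <- assign_transporters(aln, max_e = cfg$max_e, min_cov = cfg$min_cov,
                            map = category_map)
  mtc <- match(reps$transcript_id, tc$query_id)

  ann_text <- rbind(
    data.frame(protein_id = dom$domains$protein_id,
               text = dom$domains$description, stringsAsFactors = FALSE),
    data.frame(protein_id = dom$go$protein_id, text = dom$go$go_name,
               stringsAsFactors = FALSE),
    data.frame(protein_id = aln$query_id, text = aln$subject_desc,
               stringsAsFactors = FALSE))
  cand_ids <- find_gpcr_candidates(ann_text, profiles, cfg$tm_gate)
  gp <- if (length(cand_ids)) {
    do.call(rbind, lapply(cand_ids, function(id)
      classify_gpcr(id, dom$domains[dom$domains$protein_id == id, ,
                                    drop = FALSE],
                    profiles[[id]], signatures)))
  } else NULL
  mgp <- if (is.null(gp)) rep(NA_integer_, nrow(reps))
         else match(reps$transcript_id, gp$protein_id)

  tm_raw <- vapply(reps$transcript_id, function(id) {
    p <- profiles[[id]]; if (is.null(p)) 0L else raw_tm_count(p)
  }, 1L, USE.NAMES = FALSE)
  tm_nc <- vapply(reps$transcript_id, function(id) {
    p <- profiles[[id]]; if (is.null(p)) 0L else noncleaved_tm_count(p)
  }, 1L, USE.NAMES = FALSE)
  sp <- vapply(reps$transcript_id, function(id) {
    p <- profiles[[id]]; if (is.null(p)) FALSE else p$sp_present
  }, TRUE, USE.NAMES = FALSE)

  records <- data.frame(
    transcript_id = reps$transcript_id, strain = strain,
    orf_id = reps$orf_id, frame = reps$frame, partial = reps$partial,
    antisense = reps$antisense, localization = loc, no_profile = no_profile,
    role = role, sp_present = sp, tm_count_raw = tm_raw,
    tm_count_noncleaved = tm_nc,
    tc_id = ifelse(is.na(mtc), NA_character_, tc$tc_id[mtc]),
    tc_category = ifelse(is.na(mtc), NA_character_, tc$category[mtc]),
    tc_substrate = ifelse(is.na(mtc), NA_character_, tc$substrate[mtc]),
    tc_sugar_family = ifelse(is.na(mtc), NA_character_, tc$sugar_family[mtc]),
    gpcr_class = if (is.null(gp)) NA_character_ else
      ifelse(is.na(mgp), NA_character_, gp$gpcr_class[mgp]),
    gpcr_flags = if (is.null(gp)) NA_character_ else
      ifelse(is.na(mgp), NA_character_, gp$flags[mgp]),
    gpcr_n_term_end = if (is.null(gp)) NA_integer_ else
      ifelse(is.na(mgp), NA_integer_, gp$n_term_end[mgp]),
    stringsAsFactors = FALSE)
  list(records = records, orfs = orfs, profiles = profiles,
       n_tc_unparsable = attr(tc, "n_unparsable") %||% 0L)
}

tempfile_empty <- function() {
  f <- tempfile(fileext = ".tsv"); file.create(f); f
}

#' Run the full membrane-proteome mining pipeline
#'
#' Executes ORF extraction, topology profiling, funnel classification,
#' GO-role binning, TCDB transporter classification and GPCR discovery for
#' every strain in the configuration, persists every intermediate table, and
#' writes the report bundle plus a manifest of thresholds and input
#' checksums. Synthetic configurations first generate and write their
#' inputs, then read them back through the same parsers real data uses, so
#' a run is reproducible from config + seed alone.
#'
#' @param cfg a [run_config()].
#' @return list with `records` (one row per transcript), `reports` (see
#'   [write_reports()]), `truth` (synthetic runs only) and `out_dir`,
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  inputs <- cfg$inputs
  if (!is.null(cfg$synthetic)) {
    sim <- generate_transcriptome(cfg$synthetic)
    inputs <- emit_mock_annotations(sim, file.path(cfg$out_dir, "inputs"))
    truth <- sim$truth
    inputs$truth <- NULL
  }
  category_map <- load_category_map(cfg$category_map %||%
    system.file("extdata", "tcdb_category_map.tsv", package = "membraneMiner"))
  signatures <- load_gpcr_signatures(cfg$gpcr_signatures %||%
    system.file("extdata", "gpcr_signature_map.tsv", package = "membraneMiner"))

  per_strain <- lapply(names(inputs), function(strain) {
    res <- tryCatch(
      run_strain(strain, inputs[[strain]], cfg, category_map, signatures),
      error = function(e) stop(sprintf("stage failure in strain '%s': %s",
                                       strain, conditionMessage(e)),
                               call. = FALSE))
    res
  })
  records <- do.call(rbind, lapply(per_strain, `[[`, "records"))
  rownames(records) <- NULL
  orfs <- do.call(rbind, lapply(per_strain, `[[`, "orfs"))

  membrane <- records[records$localization %in% MEMBRANE_CLASSES, ,
                      drop = FALSE]
  tc_rows <- records[!is.na(records$tc_category), , drop = FALSE]
  tc_rows <- data.frame(strain = tc_rows$strain, category = tc_rows$tc_category,
                        substrate = tc_rows$tc_substrate,
                        sugar_family = tc_rows$tc_sugar_family,
                        stringsAsFactors = FALSE)
  gp_rows <- records[!is.na(records$gpcr_class), , drop = FALSE]
  gp_rows <- data.frame(strain = gp_rows$strain,
                        gpcr_class = gp_rows$gpcr_class,
                        flags = gp_rows$gpcr_flags,
                        n_term_end = gp_rows$gpcr_n_term_end,
                        stringsAsFactors = FALSE)
  reports <- list(
    funnel = funnel_counts(records),
    roles = if (nrow(membrane)) role_distribution(membrane) else
      suppressWarnings(role_distribution(membrane)),
    transporters = tabulate_transporters(tc_rows),
    gpcr = gpcr_report(gp_rows))

  paths <- write_reports(reports, records, orfs, cfg, inputs)
  invisible(list(records = records, reports = reports, truth = truth,
                 out_dir = cfg$out_dir, paths = paths))
}

#' Write the report bundle
#'
#' Persists the per-transcript record table, the ORF table and every summary
#' table as TSV, a combined JSON report, and a manifest recording thresholds
#' and input-file checksums.
#'
#' @param reports list of summary tables from [run_pipeline()].
#' @param records per-transcript classification table.
#' @param orfs full ORF table.
#' @param cfg the [run_config()] used.
#' @param inputs per-strain input file list (checksummed in the manifest).
#' @return named list of written paths, invisibly.
#' @export
write_reports <- function(reports, records, orfs, cfg, inputs) {
  rd <- file.path(cfg$out_dir, "reports")
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  p$records <- write_tsv(records, file.path(rd, "records.tsv"))
  p$orfs <- write_tsv(orfs, file.path(rd, "orfs.tsv"))
  p$funnel <- write_tsv(reports$funnel, file.path(rd, "funnel.tsv"))
  p$roles <- write_tsv(reports$roles, file.path(rd, "roles.tsv"))
  p$tc_categories <- write_tsv(reports$transporters$categories,
                               file.path(rd, "transporter_categories.tsv"))
  p$tc_substrates <- write_tsv(reports$transporters$substrates,
                               file.path(rd, "transporter_substrates.tsv"))
  p$sugar_families <- write_tsv(reports$transporters$sugar_families,
                                file.path(rd, "sugar_families.tsv"))
  p$tc_totals <- write_tsv(reports$transporters$strain_totals,
                           file.path(rd, "transporter_totals.tsv"))
  p$gpcr_classes <- write_tsv(reports$gpcr$classes,
                              file.path(rd, "gpcr_classes.tsv"))
  p$gpcr_architecture <- write_tsv(reports$gpcr$architecture,
                                   file.path(rd, "gpcr_architecture.tsv"))
  p$report_json <- file.path(rd, "report.json")
  jsonlite::write_json(reports, p$report_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  input_files <- unlist(inputs, use.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("membraneMiner")),
    thresholds = list(min_orf_codons = cfg$min_orf_codons,
                      min_cov = cfg$min_cov, max_e = cfg$max_e,
                      tm_gate = cfg$tm_gate, merge_mode = cfg$merge_mode),
    inputs = as.list(stats::setNames(unname(tools::md5sum(input_files)),
                                     basename(input_files))))
  p$manifest <- file.path(rd, "manifest.json")
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(p)
}

#' Score label recovery of a pipeline run against planted truth
#'
#' Per-transcript comparison of the run's labels with a synthetic truth
#' table (`NA` matching `NA`): localization class over all transcripts,
#' functional role over truth membrane transcripts, TCDB category /
#' substrate / sugar family over all, GPCR class and architecture flags over
#' all. `overall` is the fraction of transcripts whose full label tuple
#' matches.
#'
#' @param records `records` table from [run_pipeline()].
#' @param truth truth table from [generate_transcriptome()].
#' @return list with `per_field` (named accuracies) and `overall`.
#' @export
score_recovery <- function(records, truth) {
  m <- match(truth$transcript_id, records$transcript_id)
  stopifnot(!anyNA(m))
  r <- records[m, , drop = FALSE]
  eqna <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  mem <- truth$localization %in% MEMBRANE_CLASSES
  fields <- c(
    localization = mean(eqna(r$localization, truth$localization)),
    role = if (any(mem)) mean(eqna(r$role[mem], truth$go_role[mem])) else NA,
    tc_id = mean(eqna(r$tc_id, truth$tc_id)),
    gpcr_class = mean(eqna(r$gpcr_class, truth$gpcr_class)),
    gpcr_flags = mean(eqna(ifelse(is.na(r$gpcr_class), NA, r$gpcr_flags),
                           ifelse(is.na(truth$gpcr_class), NA,
                                  truth$gpcr_flags))))
  tuple <- eqna(r$localization, truth$localization) &
    (!mem | eqna(r$role, truth$go_role)) &
    eqna(r$tc_id, truth$tc_id) &
    eqna(r$gpcr_class, truth$gpcr_class)
  list(per_field = fields, overall = mean(tuple))
}
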