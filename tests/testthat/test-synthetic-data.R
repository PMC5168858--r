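test_that("generator configs are validated", {
  expect_error(generator_config(n_transcripts = 0), "n_transcripts")
  bad_mix <- default_class_mix(); bad_mix[1] <- bad_mix[1] + 0.1
  expect_error(generator_config(class_mix = bad_mix), "sum to 1")
  expect_error(generator_config(orf_len_range = c(400, 120)), "range")
  expect_error(generator_config(noise = 1.5), "noise")
})

test_that("the same seed gives byte-identical sequences, truth and files", {
  cfg <- generator_config(n_transcripts = 40, seed = 11,
                          strain_names = "S1")
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_mock_annotations(a, d1, noise = 0.2)
  emit_mock_annotations(b, d2, noise = 0.2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("a degenerate all-soluble mix plants only soluble transcripts", {
  mix <- default_class_mix() * 0
  mix["soluble"] <- 1
  cfg <- generator_config(n_transcripts = 50, class_mix = mix, seed = 3,
                          strain_names = "S1")
  sim <- generate_transcriptome(cfg)
  expect_equal(nrow(sim$truth), 50L)
  expect_true(all(sim$truth$class == "soluble"))
  expect_true(all(sim$truth$localization == "SOLUBLE"))
})

test_that("planted membrane fraction lands in the binomial 99% CI", {
  mix <- default_class_mix() * 0
  mix[c("soluble", "bitopic", "polytopic")] <- c(0.7, 0.15, 0.15)
  cfg <- generator_config(n_transcripts = 2000, class_mix = mix, seed = 5,
                          strain_names = "S1")
  sim <- generate_transcriptome(cfg)
  n_mem <- sum(sim$truth$localization %in%
                 c("BITOPIC_MEMBRANE", "POLYTOPIC_MEMBRANE"))
  ci <- qbinom(c(0.005, 0.995), 2000, 0.30)
  expect_gte(n_mem, ci[1])
  expect_lte(n_mem, ci[2])
})

test_that("noiseless annotations are consistent with the planted truth", {
  mix <- default_class_mix() * 0
  mix[c("bitopic", "gpcr_classC_sbp", "secreted")] <- c(0.4, 0.3, 0.3)
  cfg <- generator_config(n_transcripts = 40, class_mix = mix, seed = 9,
                          strain_names = "S1")
  sim <- generate_transcriptome(cfg)
  d <- withr::local_tempdir()
  emit_mock_annotations(sim, d, noise = 0)
  tm <- read_topology_files(file.path(d, "S1_tmhmm.txt"), "tmhmm-short")
  pb <- read_topology_files(file.path(d, "S1_phobius.txt"), "phobius-short")
  dom <- read_domain_table(file.path(d, "S1_domains.tsv"))
  bit <- sim$truth$transcript_id[sim$truth$class == "bitopic"]
  for (id in bit) {
    expect_equal(length(tm[[id]]$tm_starts), 1L)  # exactly one helix
    expect_false(pb[[id]]$sp_present)             # and no signal peptide
  }
  cls <- sim$truth$transcript_id[sim$truth$class == "gpcr_classC_sbp"]
  for (id in cls) {
    iprs <- dom$domains$interpro_id[dom$domains$protein_id == id]
    sigs <- dom$domains$signature_id[dom$domains$protein_id == id]
    expect_true("IPR017978" %in% iprs)   # class C (glutamate) signature
    expect_true("SSF53850" %in% sigs)    # SBP type II N-terminal domain
  }
  sec <- sim$truth$transcript_id[sim$truth$class == "secreted"]
  for (id in sec) expect_true(pb[[id]]$sp_present)
})

test_that("at full noise every corrupted record differs from truth", {
  mix <- default_class_mix() * 0
  mix[c("bitopic", "polytopic", "secreted")] <- c(0.4, 0.3, 0.3)
  cfg <- generator_config(n_transcripts = 60, class_mix = mix, seed = 13,
                          strain_names = "S1")
  sim <- generate_transcriptome(cfg)
  d <- withr::local_tempdir()
  emit_mock_annotations(sim, d, noise = 1)
  tm <- read_topology_files(file.path(d, "S1_tmhmm.txt"), "tmhmm-short")
  pb <- read_topology_files(file.path(d, "S1_phobius.txt"), "phobius-short")
  # direct recount: corrupted TMHMM records must disagree with the planted
  # raw helix count (SP rendered as an extra helix), corrupted Phobius
  # records must flip the SP call
  agree_tm <- vapply(sim$truth$transcript_id, function(id)
    length(tm[[id]]$tm_starts) == sim$truth$tm_count_raw[
      sim$truth$transcript_id == id], TRUE)
  agree_pb <- vapply(sim$truth$transcript_id, function(id)
    pb[[id]]$sp_present == sim$truth$sp_present[
      sim$truth$transcript_id == id], TRUE)
  expect_equal(mean(agree_tm), 0)
  expect_equal(mean(agree_pb), 0)
})

test_that("planted ORFs dominate: the representative ORF is always planted", {
  cfg <- generator_config(n_transcripts = 120, seed = 17,
                          strain_names = "S1")
  sim <- generate_transcriptome(cfg)
  reps <- representative_orfs(extract_orfs_set(sim$transcripts))
  m <- match(sim$truth$transcript_id, reps$transcript_id)
  expect_false(anyNA(m))
  expect_equal(reps$frame[m], sim$truth$frame)
  expect_equal(reps$nt_start[m], sim$truth$nt_start)
  expect_equal(reps$nt_end[m], sim$truth$nt_end)
  expect_false(any(reps$partial[m]))
  # translated length matches the planted protein length
  expect_equal(nchar(reps$aa_sequence[m]), sim$truth$protein_length)
})

test_that("the fallback predictor detects planted TM stretches", {
  mix <- default_class_mix() * 0
  mix[c("bitopic", "polytopic")] <- c(0.5, 0.5)
  cfg <- generator_config(n_transcripts = 150, class_mix = mix, seed = 19,
                          strain_names = "S1")
  sim <- generate_transcriptome(cfg)
  reps <- representative_orfs(extract_orfs_set(sim$transcripts))
  m <- match(sim$truth$transcript_id, reps$transcript_id)
  found <- vapply(seq_len(nrow(sim$truth)), function(i) {
    p <- predict_topology_fallback(reps$aa_sequence[m[i]], "p")
    raw_tm_count(p) >= sim$truth$tm_count_noncleaved[i]
  }, TRUE)
  expect_gte(mean(found), 0.99)
})
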