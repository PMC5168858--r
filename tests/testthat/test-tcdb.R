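hit_row <- function(q = "q1", s = "s1", qs = 1, qe = 70, ss = 1, se = 70,
                    qlen = 100, slen = 100, ev = 1e-9, bits = 100) {
  data.frame(query_id = q, subject_id = s, pct_identity = 50,
             aln_length = qe - qs + 1, q_start = qs, q_end = qe,
             s_start = ss, s_end = se, e_value = ev, bit_score = bits,
             q_len = qlen, s_len = slen, subject_desc = "",
             s_minus_strand = FALSE, stringsAsFactors = FALSE)
}

test_that("reciprocal coverage is inclusive at 70% on both sides", {
  expect_true(passes_reciprocal_coverage(hit_row(qe = 70, se = 70)))
  expect_false(passes_reciprocal_coverage(hit_row(qe = 69, se = 70)))
  # full query coverage but 100/150 on the subject fails
  expect_false(passes_reciprocal_coverage(
    hit_row(qe = 100, se = 100, slen = 150)))
  expect_error(passes_reciprocal_coverage(hit_row(qlen = 0)), "length")
})

test_that("the smallest-E surviving hit wins, with deterministic ties", {
  hits <- rbind(hit_row(s = "s1", ev = 1e-5), hit_row(s = "s2", ev = 1e-10))
  expect_equal(best_tcdb_hit(hits)$subject_id, "s2")
  none <- rbind(hit_row(ev = 1e-2), hit_row(ev = 0.5))
  expect_null(best_tcdb_hit(none))
  ties <- rbind(hit_row(s = "sB", ev = 1e-8, bits = 100),
                hit_row(s = "sA", ev = 1e-8, bits = 100),
                hit_row(s = "sC", ev = 1e-8, bits = 200))
  expect_equal(best_tcdb_hit(ties)$subject_id, "sC")
  ties2 <- ties[ties$bit_score == 100, ]
  expect_equal(best_tcdb_hit(ties2)$subject_id, "sA")
})

test_that("best-hit selection matches a brute-force oracle and ignores order", {
  set.seed(81)
  for (i in 1:100) {
    hits <- random_hits(sample(3:12, 1), n_queries = 1)
    got <- best_tcdb_hit(hits)
    want <- oracle_best_hit(hits)
    if (is.null(want)) expect_null(got)
    else expect_equal(got$subject_id, want$subject_id)
    perm <- hits[sample(nrow(hits)), ]
    got_perm <- best_tcdb_hit(perm)
    expect_equal(is.null(got_perm), is.null(got))
    if (!is.null(got)) expect_equal(got_perm$subject_id, got$subject_id)
  }
})

test_that("lowering the coverage threshold never loses surviving hits", {
  set.seed(82)
  hits <- random_hits(200, n_queries = 40)
  covs <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  n_surv <- vapply(covs, function(cv)
    nrow(best_tcdb_hits(hits, min_cov = cv)), 1L)
  expect_true(all(diff(n_surv) >= 0))
})

test_that("TC identity tags parse to five contiguous tiers", {
  tc <- parse_tc_id("3.A.1.201.5")
  expect_equal(tc$class_tier, 3L)
  expect_equal(tc$subclass_tier, "A")
  expect_equal(tc$family_tier, 1L)
  expect_equal(tc$subfamily_tier, 201L)
  expect_equal(tc$system_tier, 5L)
  partial <- parse_tc_id("(SWEET) (TCDB 2.A.123)")
  expect_equal(partial$tag, "2.A.123")
  expect_true(is.na(partial$subfamily_tier))
  embedded <- parse_tc_id("gnl|TC-DB|P0AE06|3.A.1.201.5")
  expect_equal(embedded$tag, "3.A.1.201.5")
  expect_error(parse_tc_id("not-a-tag"), "TC identity")
})

test_that("categorisation applies longest-prefix rules from the shipped map", {
  map <- load_category_map()
  got <- categorize_tc(c("3.A.5.8.1", "2.A.1.2.16", "2.A.123.1.4",
                         "2.A.1.1.8", "3.A.1.1.2", "3.A.1.201.5",
                         "8.A.1.1.1"), map)
  expect_equal(got$category,
               c("PROTEIN_BIOGENESIS_SECRETION", rep("SOLUTE_TRANSPORT", 5),
                 "OTHER"))
  # DHA outranks the generic MFS sugar rule by longest prefix
  expect_equal(got$substrate[2], "DRUGS_LIPIDS")
  expect_equal(got$sugar_family[3], "SWEET")
  expect_equal(got$sugar_family[4], "MFS")
  expect_equal(got$sugar_family[5], "ABC_SBP")
  expect_equal(got$substrate[6], "DRUGS_LIPIDS")
  expect_equal(got$substrate[7], "UNASSIGNED")
})

test_that("invalid category maps are rejected", {
  f <- withr::local_tempfile()
  writeLines(c("tc_prefix\tcategory\tsubstrate\tsugar_family",
               "2.A.1\tSOLUTE_TRANSPORT\tSUGARS_METABOLITES\tMFS",
               "2.A.1\tOTHER\tUNASSIGNED\tNONE"), f)
  expect_error(load_category_map(f), "duplicate")
  g <- withr::local_tempfile()
  writeLines(c("tc_prefix\tcategory\tsubstrate\tsugar_family",
               "3.A.5\tPROTEIN_BIOGENESIS_SECRETION\tUNASSIGNED\tMFS"), g)
  expect_error(load_category_map(g), "sugar_family")
})

test_that("transporter assignment composes filters, parsing and binning", {
  hits <- rbind(
    hit_row(q = "t1", s = "gnl|TC-DB|P1|2.A.123.1.4", ev = 1e-30),
    hit_row(q = "t1", s = "gnl|TC-DB|P2|9.B.99.1.1", ev = 1e-4),
    hit_row(q = "t2", s = "gnl|TC-DB|P3|1.I.1.1.1", ev = 1e-12, se = 60),
    hit_row(q = "t3", s = "no-tag-here", ev = 1e-12))
  expect_warning(a <- assign_transporters(hits), "parsable")
  expect_equal(a$tc_id[a$query_id == "t1"], "2.A.123.1.4")
  expect_equal(a$sugar_family[a$query_id == "t1"], "SWEET")
  # t2's only hit fails subject coverage; t3's best hit has no TC tag
  expect_false("t2" %in% a$query_id)
  expect_false("t3" %in% a$query_id)
  expect_equal(attr(a, "n_unparsable"), 1L)
})

test_that("transporter tables tally per strain with cross-strain totals", {
  asg <- data.frame(
    strain = rep(c("A", "B", "C"), times = c(10, 5, 5)),
    category = "SOLUTE_TRANSPORT",
    substrate = "SUGARS_METABOLITES",
    sugar_family = rep(c("MFS", "SSS"), times = c(12, 8)),
    stringsAsFactors = FALSE)
  tb <- tabulate_transporters(asg)
  expect_equal(margin_total(tb$strain_totals), 20)
  cat_tot <- margin_total(tb$categories,
                          where = list(category = "SOLUTE_TRANSPORT"))
  expect_equal(cat_tot, 20)
  per_strain <- tb$categories[tb$categories$strain != "Total", ]
  expect_equal(sum(per_strain$count), nrow(asg))
})
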