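gprof <- function(id = "p", k = 7, first = 350, sp = FALSE) {
  starts <- seq(first, by = 40, length.out = k)
  topology_profile(id, sp, if (sp) 18L else NA, starts, starts + 20L, "test")
}

test_that("candidacy needs both a keyword and 7-9 raw TM segments", {
  ann <- data.frame(protein_id = c("a", "b", "c", "d"),
                    text = c("putative G-protein coupled receptor",
                             "putative GPCR fragment",
                             "sugar transporter",
                             "GPCR-like protein"),
                    stringsAsFactors = FALSE)
  profiles <- list(a = gprof("a", 7), b = gprof("b", 6), c = gprof("c", 8),
                   d = gprof("d", 10))
  got <- find_gpcr_candidates(ann, profiles)
  expect_equal(got, "a")  # b: 6 TMs; c: no keyword; d: 10 TMs
  # boundary counts 7 and 9 pass, 6 and 10 fail
  for (k in c(7, 9))
    expect_equal(find_gpcr_candidates(
      data.frame(protein_id = "x", text = "GPCR"),
      list(x = gprof("x", k))), "x")
  for (k in c(6, 10))
    expect_length(find_gpcr_candidates(
      data.frame(protein_id = "x", text = "GPCR"),
      list(x = gprof("x", k))), 0)
})

test_that("the N-terminal region ends before the 7 most C-terminal helices", {
  reg <- delimit_n_terminal_region(gprof(k = 7, first = 350))
  expect_equal(reg$bundle_start, 350L)
  expect_equal(reg$region_end, 349L)
  # with 9 helices the bundle anchors at the C-terminus: helices 1-2 are
  # upstream, so a domain between helix 2 and helix 3 is still N-terminal
  p9 <- gprof(k = 9, first = 100)
  reg9 <- delimit_n_terminal_region(p9)
  expect_equal(reg9$bundle_start, p9$tm_starts[3])
  expect_error(delimit_n_terminal_region(gprof(k = 5)), "gate")
})

dom_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(signature_id = r[[1]], interpro_id = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               stringsAsFactors = FALSE)))
}

test_that("receptor class and architecture flags come from signature ids", {
  p <- gprof(k = 7, first = 400)
  d <- dom_df(list("PF00003", "IPR017978", 400, 600),
              list("SSF53850", NA, 20, 280))
  got <- classify_gpcr("p", d, p)
  expect_equal(got$gpcr_class, "CLASS_C")
  expect_equal(got$flags, "SBP_TYPE_II")
  expect_false(got$class_conflict)
  rho <- classify_gpcr("p", dom_df(list("PF00001", "IPR017452", 400, 600)), p)
  expect_equal(rho$gpcr_class, "RHODOPSIN_DICTY_CAR")
  none <- classify_gpcr("p", dom_df(list("PF09999", NA, 10, 50)), p)
  expect_equal(none$gpcr_class, "UNCLASSIFIED")
})

test_that("domains spanning the bundle start are not N-terminal", {
  p <- gprof(k = 7, first = 350)
  d <- dom_df(list("PF12708", "IPR011050", 10, 300),    # wholly inside
              list("PF13229", "IPR006626", 340, 420))   # spans the bundle
  got <- classify_gpcr("p", d, p)
  expect_equal(got$flags, "PECTIN_LYASE")
})

test_that("conflicting class signatures resolve to CLASS_C, flagged", {
  p <- gprof(k = 7, first = 400)
  d <- dom_df(list("PF00003", "IPR017978", 400, 600),
              list("PF00001", "IPR017452", 410, 590))
  got <- classify_gpcr("p", d, p)
  expect_equal(got$gpcr_class, "CLASS_C")
  expect_true(got$class_conflict)
})

test_that("class assignment is invariant under domain-hit order", {
  set.seed(91)
  p <- gprof(k = 8, first = 300)
  d <- dom_df(list("SSF53850", NA, 20, 200),
              list("PF00003", "IPR017978", 340, 600),
              list("PF12708", "IPR011050", 30, 150))
  base <- classify_gpcr("p", d, p)
  for (i in 1:10) {
    perm <- d[sample(nrow(d)), ]
    got <- classify_gpcr("p", perm, p)
    expect_equal(got$gpcr_class, base$gpcr_class)
    expect_equal(got$flags, base$flags)
  }
})

test_that("the GPCR report tallies classes with margin totals and fractions", {
  cand <- data.frame(
    strain = c(rep("S1", 4), rep("S2", 2)),
    gpcr_class = c("CLASS_C", "CLASS_C", "CLASS_C", "RHODOPSIN_DICTY_CAR",
                   "CLASS_C", "CLASS_C"),
    flags = c("SBP_TYPE_II", "", "PECTIN_LYASE,SBP_TYPE_II", "",
              "SBP_TYPE_II", ""),
    n_term_end = c(300L, 450L, 280L, 120L, 500L, 310L),
    stringsAsFactors = FALSE)
  rep <- gpcr_report(cand)
  s1_total <- margin_total(rep$classes, margin_col = "gpcr_class",
                           where = list(strain = "S1"))
  expect_equal(s1_total, 4)
  classc_total <- margin_total(rep$classes,
                               where = list(gpcr_class = "CLASS_C"))
  expect_equal(classc_total, 5)
  sbp <- rep$architecture[rep$architecture$flag == "SBP_TYPE_II", ]
  expect_equal(sbp$count, 3L)
  expect_equal(sbp$fraction, 0.5)
  expect_equal(rep$n_term_length$mean[rep$n_term_length$strain == "S2"], 405)
})
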