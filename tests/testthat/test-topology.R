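make_profile <- function(id = "p", sp = FALSE, cleav = NA, starts = integer(0),
                         ends = integer(0), src = "x") {
  topology_profile(id, sp, cleav, starts, ends, src)
}

test_that("TMHMM short lines map helices to ordered segments", {
  f <- withr::local_tempfile()
  writeLines(paste0("p1\tlen=500\tExpAA=160.1\tFirst60=0.1\tPredHel=7\t",
                    "Topology=o10-32i44-66o80-102i120-142o160-182i200-222o240-262i"),
             f)
  pr <- read_topology_files(f, "tmhmm-short")
  expect_named(pr, "p1")
  expect_equal(length(pr$p1$tm_starts), 7L)
  expect_equal(pr$p1$tm_starts[1], 10L)
  expect_equal(pr$p1$tm_ends[7], 262L)
  expect_false(pr$p1$sp_present)
})

test_that("SignalP short records carry the cleavage site", {
  f <- withr::local_tempfile()
  writeLines(c("# name Cmax pos Ymax pos Smax pos Smean D ? Dmaxcut net",
               "p1 0.5 23 0.5 23 0.6 12 0.5 0.5 Y 0.45 SignalP-noTM",
               "p2 0.1 12 0.1 12 0.2 5 0.1 0.1 N 0.45 SignalP-noTM"), f)
  pr <- read_topology_files(f, "signalp-short")
  expect_true(pr$p1$sp_present)
  expect_equal(pr$p1$cleavage_after, 22L)
  expect_false(pr$p2$sp_present)
})

test_that("Phobius short records carry both SP and TM segments", {
  f <- withr::local_tempfile()
  writeLines(c("SEQENCE ID  TM  SP  PREDICTION",
               "p1  2  Y  n4-15c18/19o50-70i90-110o",
               "p2  0  0  o"), f)
  pr <- read_topology_files(f, "phobius-short")
  expect_true(pr$p1$sp_present)
  expect_equal(pr$p1$cleavage_after, 18L)
  expect_equal(pr$p1$tm_starts, c(50L, 90L))
  expect_equal(length(pr$p2$tm_starts), 0L)
})

test_that("malformed predictor lines report file and line number", {
  f <- withr::local_tempfile()
  writeLines(c("p1\tlen=100", "whatever"), f)
  expect_error(read_topology_files(f, "tmhmm-short"), "line 1")
})

test_that("hydropathy fallback finds an extreme leucine stretch", {
  aa <- paste0(strrep("D", 40), strrep("L", 21), strrep("D", 40))
  pr <- predict_topology_fallback(aa, "p")
  expect_equal(length(pr$tm_starts), 1L)
  # segment covers the Leu run up to window slack
  expect_lte(abs(pr$tm_starts - 41), 18)
  expect_lte(abs(pr$tm_ends - 61), 18)
  expect_true(pr$tm_starts <= 61 && pr$tm_ends >= 41)
})

test_that("hydropathy fallback is silent on an all-aspartate protein", {
  pr <- predict_topology_fallback(strrep("D", 100), "p")
  expect_equal(length(pr$tm_starts), 0L)
  expect_false(pr$sp_present)
})

test_that("short sequences give an empty, flagged profile", {
  pr <- predict_topology_fallback("MKL", "p")
  expect_equal(length(pr$tm_starts), 0L)
  expect_true("too_short" %in% pr$flags)
})

test_that("fallback segments equal an independent sliding-window oracle", {
  set.seed(51)
  for (i in 1:500) {
    n <- sample(25:120, 1)
    aa <- random_protein(n)
    # salt some sequences with hydrophobic runs so segments actually occur
    if (i %% 3 == 0) {
      pos <- sample(seq_len(max(1, n - 21)), 1)
      substr(aa, pos, pos + 20) <- strrep("L", 21)
    }
    pr <- predict_topology_fallback(aa, "p")
    want <- oracle_kd_segments(aa)
    expect_equal(pr$tm_starts, want$starts, info = paste("case", i))
    expect_equal(pr$tm_ends, want$ends, info = paste("case", i))
  }
})

test_that("union merging is idempotent, commutative and associative", {
  set.seed(52)
  rand_prof <- function() {
    k <- sample(0:4, 1)
    s <- sort(sample(1:300, k))
    sp <- runif(1) < 0.4
    make_profile("p", sp = sp,
                 cleav = if (sp) sample(10:30, 1) else NA,
                 starts = s, ends = s + sample(15:30, k, replace = TRUE),
                 src = sample(letters, 1))
  }
  norm <- function(p) p[c("sp_present", "cleavage_after", "tm_starts", "tm_ends")]
  for (i in 1:50) {
    a <- rand_prof(); b <- rand_prof(); cc <- rand_prof()
    expect_equal(norm(merge_predictions(list(a, a))), norm(merge_predictions(list(a))))
    expect_equal(norm(merge_predictions(list(a, b))),
                 norm(merge_predictions(list(b, a))))
    expect_equal(norm(merge_predictions(list(merge_predictions(list(a, b)), cc))),
                 norm(merge_predictions(list(a, merge_predictions(list(b, cc))))))
  }
})

test_that("two agreeing sources merge to the same segments; SP unions", {
  a <- make_profile("p", starts = c(10, 50), ends = c(30, 70), src = "tmhmm")
  b <- make_profile("p", starts = c(10, 50), ends = c(30, 70), src = "phobius")
  m <- merge_predictions(list(a, b))
  expect_equal(m$tm_starts, c(10L, 50L))
  expect_equal(m$tm_ends, c(30L, 70L))
  sp_only <- make_profile("p", sp = TRUE, cleav = 22)
  none <- make_profile("p")
  m2 <- merge_predictions(list(sp_only, none))
  expect_true(m2$sp_present)
  expect_equal(m2$cleavage_after, 22L)
  expect_error(merge_predictions(list(a, make_profile("other"))), "different")
})

test_that("overlapping segments merge like a residue-coverage union", {
  a <- make_profile("p", starts = 10, ends = 30)
  b <- make_profile("p", starts = 25, ends = 45)
  m <- merge_predictions(list(a, b))
  expect_equal(m$tm_starts, 10L)
  expect_equal(m$tm_ends, 45L)
  set.seed(53)
  for (i in 1:100) {
    k <- sample(1:6, 1)
    s <- sample(1:200, k)
    e <- s + sample(5:40, k, replace = TRUE)
    prof <- lapply(seq_len(k), function(j)
      make_profile("p", starts = s[j], ends = e[j]))
    m <- merge_predictions(prof)
    want <- oracle_interval_union(s, e)
    expect_equal(m$tm_starts, want$starts)
    expect_equal(m$tm_ends, want$ends)
  }
})

test_that("non-cleaved TM counting discounts the signal-peptide helix", {
  p <- make_profile("p", sp = TRUE, cleav = 22, starts = c(5, 60),
                    ends = c(25, 80))
  expect_equal(noncleaved_tm_count(p), 1L)
  p2 <- make_profile("p", starts = c(5, 60, 100), ends = c(25, 80, 120))
  expect_equal(noncleaved_tm_count(p2), 3L)
  set.seed(54)
  for (i in 1:100) {
    k <- sample(0:5, 1)
    s <- sort(sample(1:300, k))
    sp <- runif(1) < 0.5
    cl <- if (sp) sample(5:50, 1) else NA
    p <- make_profile("p", sp = sp, cleav = cl, starts = s,
                      ends = s + 20L)
    want <- if (!sp) k else sum(s > cl)
    expect_equal(noncleaved_tm_count(p), want)
    expect_lte(noncleaved_tm_count(p), raw_tm_count(p))
    if (!sp) expect_equal(noncleaved_tm_count(p), raw_tm_count(p))
  }
})
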