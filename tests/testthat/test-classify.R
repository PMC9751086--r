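# Classifier unit tests build reads by hand against the shared synthetic
# locus so every expected category is known by construction.

make_read <- function(sh, qname, edits = NULL, del_at = NULL, extra = NULL,
                      offset = -5L) {
  # one read starting `offset` nt before the donor window, 150 nt long
  w <- list(start = sh$donor$span_start, end = sh$donor$span_end)
  s <- w$start + offset
  len <- 150L + if (!is.null(del_at)) 2L else 0L
  chunk <- substr(as.character(sh$locus$genome[["chrS"]]), s, s + len - 1L)
  cigar <- "150M"
  apply_at <- function(chunk, pos, base) {
    substr(chunk, pos - s + 1L, pos - s + 1L) <- base
    chunk
  }
  for (i in seq_len(nrow(edits %||% tibble::tibble()))) {
    chunk <- apply_at(chunk, edits$pos[i], edits$alt[i])
  }
  for (i in seq_len(nrow(extra %||% tibble::tibble()))) {
    chunk <- apply_at(chunk, extra$pos[i], extra$alt[i])
  }
  if (!is.null(del_at)) {
    left <- del_at - s + 1L
    chunk <- paste0(substr(chunk, 1, left), substr(chunk, left + 3L, len))
    cigar <- sprintf("%dM2D%dM", left, 150L - left)
  }
  sam_record(qname, s, chunk, cigar = cigar)
}

test_that("classify_read applies the four-category rules with precedence", {
  sh <- get_shared_locus()
  edits <- rbind(sh$donor$intended[, c("pos", "alt")],
                 sh$donor$shields[, c("pos", "alt")])
  cut <- sh$guides$cut_site[sh$guides$guide_id == "gRNA2"]
  recs <- rbind(
    make_read(sh, "ref_read"),
    make_read(sh, "ki_read", edits = edits),
    make_read(sh, "ki_plus_del", edits = edits, del_at = cut),
    make_read(sh, "lone_ki", edits = sh$donor$intended[, c("pos", "alt")]),
    make_read(sh, "stray", extra = tibble::tibble(
      pos = sh$donor$span_start + 10L,
      alt = chartr("ACGT", "TGCA", substr(as.character(sh$locus$genome[["chrS"]]),
                                          sh$donor$span_start + 10L,
                                          sh$donor$span_start + 10L))))
  )
  sam <- write_test_sam(recs, sh$locus$genome,
                        withr::local_tempfile(fileext = ".sam"))
  obs <- read_observations(sam, sh$locus$genome,
                           c(sh$donor$span_start, sh$donor$span_end))
  obs <- obs[match(recs$qname, obs$read_id), ]
  got <- classify_reads(obs, sh$donor)
  expect_equal(as.character(got$category),
               c("no_mutation",   # identical to reference
                 "intended_KI",   # intended edit plus all shields
                 "indel",         # indel wins over the intended edit
                 "nonspecific",   # intended edit without its shields
                 "nonspecific"))  # non-donor substitution
  # the shields requirement is configurable
  relaxed <- classify_reads(obs, sh$donor, require_shields = FALSE)
  expect_equal(as.character(relaxed$category[4]), "intended_KI")
})

test_that("reads not spanning the window are rejected by the classifier", {
  sh <- get_shared_locus()
  short <- sam_record("short", sh$donor$span_start + 10L, strrep("A", 50))
  sam <- write_test_sam(short, sh$locus$genome,
                        withr::local_tempfile(fileext = ".sam"))
  # decompose against a window the read does span ...
  obs <- read_observations(sam, sh$locus$genome,
                           c(sh$donor$span_start + 10L,
                             sh$donor$span_start + 59L))
  expect_equal(nrow(obs), 1L)
  # ... then ask for classification over the full donor window
  expect_error(classify_reads(obs, sh$donor), "span the window")
})

test_that("summarize_locus filters on flags, mapping quality and span", {
  sh <- get_shared_locus()
  base <- make_read(sh, "ok")
  dup <- make_read(sh, "dup"); dup$flag <- 1024L
  secondary <- make_read(sh, "sec"); secondary$flag <- 256L
  lowq <- make_read(sh, "lowq"); lowq$mapq <- 5L
  nonspan <- sam_record("nonspan", sh$donor$span_start + 20L, strrep("A", 50))
  sam <- write_test_sam(rbind(base, dup, secondary, lowq, nonspan),
                        sh$locus$genome,
                        withr::local_tempfile(fileext = ".sam"))
  tally <- summarize_locus(sam, sh$donor, sh$locus)
  expect_equal(tally$total, 1L)
  expect_equal(sum(tally$excluded$n), 4L)
})

test_that("error-free simulated mixtures are recovered exactly", {
  sh <- get_shared_locus()
  cfg <- small_config(seed = 21, n_reads = 200L, error_rate = 0)
  rd <- simulate_founder_reads(cfg, sh$locus, sh$donor)
  tally <- summarize_locus(rd$sam, sh$donor, sh$locus)
  truth <- table(factor(rd$truth$category,
                        levels = c("intended_KI", "indel", "no_mutation",
                                   "nonspecific")))
  expect_equal(tally$counts$n, as.integer(truth))
  expect_equal(sum(tally$counts$fraction), 1, tolerance = 1e-9)
})

test_that("an all-reference read set is 100% no_mutation", {
  sh <- get_shared_locus()
  cfg <- small_config(seed = 22, n_reads = 50L, error_rate = 0,
                      proportions = c(intended_KI = 0, indel = 0,
                                      no_mutation = 1, nonspecific = 0))
  rd <- simulate_founder_reads(cfg, sh$locus, sh$donor)
  tally <- summarize_locus(rd$sam, sh$donor, sh$locus)
  expect_equal(tally$counts$fraction[tally$counts$category == "no_mutation"], 1)
})

test_that("classification is invariant under read order", {
  sh <- get_shared_locus()
  cfg <- small_config(seed = 23, n_reads = 120L)
  rd <- simulate_founder_reads(cfg, sh$locus, sh$donor)
  obs <- read_observations(rd$sam, sh$locus$genome,
                           c(sh$donor$span_start, sh$donor$span_end))
  t1 <- table(classify_reads(obs, sh$donor)$category)
  perm <- withr::with_seed(1, sample(nrow(obs)))
  t2 <- table(classify_reads(obs[perm, ], sh$donor)$category)
  expect_equal(as.integer(t1), as.integer(t2))
})

test_that("zero spanning reads yield an explicit empty tally", {
  sh <- get_shared_locus()
  sam <- write_test_sam(sam_record("far", 100L, strrep("A", 50)),
                        sh$locus$genome,
                        withr::local_tempfile(fileext = ".sam"))
  tally <- summarize_locus(sam, sh$donor, sh$locus)
  expect_equal(tally$total, 0L)
  expect_true(all(is.na(tally$counts$fraction)))
})

test_that("cohort percentages reproduce the half-up one-decimal convention", {
  founders <- tibble::tibble(any_mutation = c(rep(TRUE, 35), rep(FALSE, 4)),
                             intended_ki = c(rep(TRUE, 15), rep(FALSE, 24)))
  cs <- cohort_summary(founders)
  expect_equal(cs$percent[cs$metric == "any_mutation"], 89.7)
  expect_equal(cs$percent[cs$metric == "intended_ki"], 38.5)
  none <- cohort_summary(tibble::tibble(any_mutation = rep(FALSE, 10),
                                        intended_ki = rep(FALSE, 10)))
  expect_equal(none$percent, c(0, 0))
  expect_error(cohort_summary(tibble::tibble(any_mutation = logical(),
                                             intended_ki = logical())),
               "empty")
})
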