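snvs <- function(pos, ref, alt, contig = "chrS") {
  tibble::tibble(contig = contig, pos = as.integer(pos), ref = ref, alt = alt)
}

test_that("background subtraction is exact tuple set arithmetic", {
  ctl <- snvs(c(100, 200, 300, 400), c("A", "C", "G", "T"),
              c("G", "T", "A", "C"))
  known <- snvs(900, "G", "A")
  founder <- rbind(
    ctl,                                        # 4 shared with control
    snvs(c(50, 60), c("A", "C"), c("T", "G"),
         contig = "chrUn_x"),                   # 2 on an unplaced contig
    known,                                      # 1 in the known list
    snvs(c(500, 600, 700), c("A", "A", "C"), c("C", "G", "T")))  # 3 de novo
  dn <- subtract_background(founder, ctl, known, contig_allowlist = "chrS")
  expect_equal(nrow(dn), 3L)
  expect_setequal(dn$pos, c(500L, 600L, 700L))
  ct <- glance(dn)
  expect_equal(ct$input, 10L)
  expect_equal(ct$removed_unplaced + ct$removed_as_control +
                 ct$removed_as_known + ct$retained, ct$input)
  # founder identical to control leaves nothing
  empty <- subtract_background(ctl, ctl, contig_allowlist = "chrS")
  expect_equal(nrow(empty), 0L)
})

test_that("tuple identity requires the full (contig,pos,ref,alt) match", {
  ctl <- snvs(100, "A", "G")
  founder <- snvs(100, "C", "G")   # same pos and alt, different ref
  expect_warning(dn <- subtract_background(founder, ctl,
                                           contig_allowlist = "chrS"),
                 "differ in ref")
  expect_equal(nrow(dn), 1L)
})

test_that("allowlisted contigs unknown to the control raise a naming error", {
  ctl <- snvs(100, "A", "G")
  founder <- rbind(snvs(100, "A", "G"), snvs(50, "C", "T", contig = "chrZ"))
  expect_error(subtract_background(founder, ctl,
                                   contig_allowlist = c("chrS", "chrZ")),
               "chrZ")
})

test_that("predicted_site_check counts the inclusive 500-nt boundary", {
  sites <- tibble::tibble(contig = "chrS", start = 1000L, end = 1010L,
                          name = "s1")  # 1-based 1001..1010
  at <- function(p) predicted_site_check(sites, snvs(p, "C", "A"),
                                         window_nt = 500L)$n_snvs
  expect_equal(at(501L), 1L)    # exactly 500 left of the first base
  expect_equal(at(500L), 0L)    # 501 away
  expect_equal(at(1510L), 1L)   # exactly 500 right of the last base
  expect_equal(at(1511L), 0L)
  expect_equal(at(1005L), 1L)   # inside: distance 0
  expect_equal(predicted_site_check(sites, snvs(integer(), character(),
                                                character()))$n_snvs, 0L)
})

test_that("only the site containing a planted SNV is flagged", {
  sites <- tibble::tibble(contig = "chrS",
                          start = seq(10000L, 70000L, by = 10000L),
                          end = seq(10000L, 70000L, by = 10000L) + 23L,
                          name = sprintf("site_%d", 1:7))
  dn <- snvs(sites$start[3] + 5L, "G", "T")
  chk <- predicted_site_check(sites, dn)
  expect_equal(chk$n_snvs, c(0L, 0L, 1L, 0L, 0L, 0L, 0L))
})

test_that("malformed BED lines are reported with their line number", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrS\t100\t200\tok", "chrS\t300"), bed)
  expect_error(predicted_site_check(bed, snvs(1, "C", "A")), "line 2")
})

test_that("scan_signatures matches planted clusters and nothing else", {
  sh <- get_shared_locus()
  pat <- derive_signature_pattern(sh$donor)
  expect_equal(nrow(scan_signatures(snvs(integer(), character(), character()),
                                    pat)), 0L)
  # plus-strand cluster with a single companion: C>A at p, N>A at p-3
  plus <- rbind(snvs(5000, "C", "A"), snvs(4997, "G", "A"))
  h <- scan_signatures(plus, pat)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$n_companions, 1L)
  expect_equal(h$companions[[1]]$offset, 3L)
  # minus-strand image of the N>T@-15 rule: G>T at p, companion at p+15
  # whose plus-strand alternate is the complement (A); the companion's ref
  # is chosen so it does not read as a central itself
  minus <- rbind(snvs(8000, "G", "T"), snvs(8015, "G", "A"))
  h2 <- scan_signatures(minus, pat)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$companions[[1]]$pos, 8015L)
  # lone centrals scattered without companions never match
  lone <- snvs(seq(1000, 9000, by = 1000), "C", "A")
  expect_equal(nrow(scan_signatures(lone, pat)), 0L)
})

test_that("every hit is a subset of the de novo set and obeys its offsets", {
  sh <- get_shared_locus()
  pat <- derive_signature_pattern(sh$donor)
  withr::with_seed(77, {
    n <- 300L
    pos <- sample(100000L, n)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                  character(1), USE.NAMES = FALSE)
  })
  dn <- snvs(pos, ref, alt)
  hits <- scan_signatures(dn, pat)
  key <- paste(dn$pos, dn$ref, dn$alt)
  for (i in seq_len(nrow(hits))) {
    expect_true(paste(hits$pos[i], hits$ref[i], hits$alt[i]) %in% key)
    m <- hits$companions[[i]]
    expect_true(all(paste(m$pos, m$ref, m$alt) %in% key))
    dirn <- if (hits$strand[i] == "+") -1L else 1L
    expect_equal(m$pos, hits$pos[i] + dirn * m$offset)
    want <- pat$companions$alt[match(m$offset, pat$companions$offset)]
    if (hits$strand[i] == "-") want <- chartr("ACGT", "TGCA", want)
    expect_equal(m$alt, want)
  }
})

test_that("hit counts are invariant under reverse-complement mirroring", {
  sh <- get_shared_locus()
  pat <- derive_signature_pattern(sh$donor)
  L <- 100000L
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- 250L
      pos <- sample(L, n)
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                    character(1), USE.NAMES = FALSE)
    })
    dn <- snvs(pos, ref, alt)
    mirrored <- snvs(L - pos + 1L, comp1(ref), comp1(alt))
    expect_equal(nrow(scan_signatures(mirrored, pat)),
                 nrow(scan_signatures(dn, pat)), info = paste("seed", seed))
  }
})

test_that("false-positive rate on uniform backgrounds matches the binomial closed form", {
  sh <- get_shared_locus()
  pat <- derive_signature_pattern(sh$donor)
  L <- 100000L; n <- 300L; reps <- 100L
  total <- 0L
  expected_central <- 0
  withr::with_seed(4242, {
    for (r in seq_len(reps)) {
      pos <- sample(L, n)
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                    character(1), USE.NAMES = FALSE)
      dn <- snvs(pos, ref, alt)
      total <- total + nrow(scan_signatures(dn, pat))
      expected_central <- expected_central +
        sum(ref == "C" & alt == "A") + sum(ref == "G" & alt == "T")
    }
  })
  # closed form: each central sees 4 candidate offsets, each occupied with
  # probability ~ n/L and carrying the required alternate with probability
  # 1/4 (uniform ref x uniform non-ref alt)
  q <- (n / L) * (1 / 4)
  p_hit <- 1 - (1 - q)^nrow(pat$companions)
  expect_gt(expected_central, 0)
  e_total <- expected_central * p_hit
  mc_se <- sqrt(e_total)
  expect_lt(abs(total - e_total), max(4 * mc_se, 4))
})
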