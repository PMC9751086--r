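test_that("synonymous_options agrees with exhaustive translation of all 64 codons", {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  translate1 <- function(codon) {
    as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                       no.init.codon = TRUE))
  }
  for (codon in codons) {
    for (p in 0:2) {
      orig <- substr(codon, p + 1, p + 1)
      expected <- character()
      for (b in setdiff(bases, orig)) {
        alt <- codon
        substr(alt, p + 1, p + 1) <- b
        if (translate1(alt) == translate1(codon)) expected <- c(expected, b)
      }
      expect_equal(synonymous_options(codon, p), sort(expected),
                   info = paste(codon, p))
    }
  }
  expect_equal(synonymous_options("ATG", 2), character(0))
  expect_equal(synonymous_options("GAC", 2), "T")
  expect_error(synonymous_options("GAN", 2), "outside A/C/G/T")
})

test_that("build_ssodn installs one silent PAM edit on the toy locus", {
  locus <- toy_locus()
  guide <- toy_guide(locus)
  expect_equal(nrow(guide), 1L)
  expect_equal(guide$pam, "AGG")
  donor <- build_ssodn(locus, guide)
  expect_equal(nrow(donor$shields), 1L)
  expect_equal(donor$shields$tag, "PAM")
  expect_equal(donor$shields$label, "c.24G>A")
  # re-translation oracle: shield alone leaves the protein unchanged
  edited <- apply_variants(locus$genome, donor$shields)
  tr <- function(g) as.character(Biostrings::translate(
    Biostrings::subseq(g[["chrT"]], 81, 110)))
  expect_equal(tr(edited), tr(locus$genome))
  # arm arithmetic: 2 x arm + edited-core span
  core <- max(c(donor$intended$pos, donor$shields$pos)) -
    min(c(donor$intended$pos, donor$shields$pos)) + 1L
  expect_equal(nchar(donor$ssodn), 2L * 50L + core)
  expect_true(validate_donor(donor, locus, guide)$pass)
})

test_that("build_ssodn then validate_donor round-trips on random loci", {
  for (seed in c(3, 14, 27)) {
    locus <- make_reference(small_config(seed = seed))
    guides <- gaa1935_guides(locus)
    donor <- build_ssodn(locus, guides)
    v <- validate_donor(donor, locus, guides)
    expect_true(v$pass, info = paste("seed", seed))
    # exactly one residue changes, and it is the intended one
    expect_true(tidy(v)$pass[tidy(v)$check ==
                               "protein changes at exactly the intended residue"])
  }
})

test_that("the published donor design validates in full", {
  sh <- get_shared_locus()
  v <- validate_donor(sh$donor, sh$locus, sh$guides)
  expect_true(v$pass)
  items <- tidy(v)
  expect_true(all(items$pass[grepl("synonymous", items$check)]))
  expect_true(all(items$pass[grepl("disrupted", items$check)]))
  expect_equal(glance(v)$n_failed, 0L)
})

test_that("validator flags an unedited oligo and a non-synonymous shield", {
  sh <- get_shared_locus()
  locus <- sh$locus
  # unedited reference window passed off as the donor
  plain <- substr(as.character(locus$genome[["chrS"]]),
                  sh$donor$span_start, sh$donor$span_end)
  undedited <- donor_spec(locus, shields = sh$donor$shields, ssodn = plain)
  v1 <- validate_donor(undedited, locus)
  expect_false(v1$pass)
  expect_false(tidy(v1)$pass[tidy(v1)$check == "intended edit present"])
  # a first-position change in GAC is not synonymous (c.1933G>T)
  bad <- donor_spec(locus, shields = tibble::tibble(
    label = "c.1933G>T", tag = "seed", guide_id = "gRNA2"))
  v2 <- validate_donor(bad, locus)
  expect_false(v2$pass)
  expect_false(tidy(v2)$pass[tidy(v2)$check == "shield c.1933G>T synonymous"])
})

test_that("build_ssodn fails structurally when no silent disruption exists", {
  # Met/Trp-only coding context: every PAM and seed base sits in an ATG or
  # TGG codon, neither of which admits any synonymous change.
  cds <- strrep("ATGTGG", 8)
  contig <- paste0(strrep("T", 80), cds, strrep("T", 80))
  genome <- Biostrings::DNAStringSet(c(chrM = contig))
  cmap <- coding_map(data.frame(contig = "chrM", start = 80, end = 80 + 48,
                                c_start = 1), "+")
  locus <- reference_locus(genome, cmap, "c.26T>C")  # ATG->ACG Met->Thr
  g <- find_guides(genome, "chrM")
  g <- g[g$strand == "+" & g$pam_start == 102L, ]   # PAM = TGG at c.22-24
  expect_equal(nrow(g), 1L)
  expect_error(build_ssodn(locus, g), class = "crisprki_no_shield")
})

test_that("donor specifications round-trip through FASTA plus edits table", {
  sh <- get_shared_locus()
  prefix <- file.path(withr::local_tempdir(), "donor")
  write_donor(sh$donor, prefix)
  back <- read_donor(prefix, sh$locus)
  expect_equal(back$ssodn, sh$donor$ssodn)
  expect_equal(back$arm_length, sh$donor$arm_length)
  expect_equal(as.data.frame(back$shields), as.data.frame(sh$donor$shields))
  expect_equal(back$intended$pos, sh$donor$intended$pos)
})
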