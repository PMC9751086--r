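test_that("c_to_genomic handles boundary and affine cases on a plus-strand CDS", {
  cm <- coding_map(data.frame(contig = "chr1", start = 100, end = 160,
                              c_start = 1), "+")
  # first c. position maps to the segment's gene-strand start
  expect_equal(c_to_genomic(cm, 1)$pos, 101L)
  # single plus-strand CDS starting at genomic 1-based 101: c.15 -> 115
  expect_equal(c_to_genomic(cm, 15)$pos, 115L)
  expect_error(c_to_genomic(cm, 61), "outside the mapped span c\\.1\\.\\.c\\.60")
  expect_error(c_to_genomic(cm, 0), "outside the mapped span")
})

test_that("c_to_genomic and genomic_to_c round-trip over random coding maps", {
  for (seed in 1:20) {
    cm <- random_cmap(seed)
    span <- min(cm$segments$c_start):max(cm$segments$c_start +
                                           (cm$segments$end - cm$segments$start) - 1)
    loc <- c_to_genomic(cm, span)
    back <- genomic_to_c(cm, loc$contig, loc$pos)
    expect_equal(back$c_pos, span)
    # every mapped genomic position is hit exactly once
    expect_false(anyDuplicated(loc$pos) > 0)
  }
})

test_that("two-exon minus-strand gene round-trips exhaustively", {
  cm <- random_cmap(99, force_strand = "-")
  expect_equal(cm$gene_strand, "-")
  span <- min(cm$segments$c_start):max(cm$segments$c_start +
                                         (cm$segments$end - cm$segments$start) - 1)
  loc <- c_to_genomic(cm, span)
  expect_equal(genomic_to_c(cm, loc$contig, loc$pos)$c_pos, span)
  # increasing c. runs along decreasing genomic coordinate within a segment
  for (i in seq_len(nrow(cm$segments))) {
    seg <- cm$segments[i, ]
    cc <- seg$c_start:(seg$c_start + (seg$end - seg$start) - 1L)
    pp <- c_to_genomic(cm, cc)$pos
    if (length(pp) > 1L) expect_true(all(diff(pp) == -1L))
  }
})

test_that("codon_of reads codons on the gene strand and concatenates to the CDS", {
  locus <- toy_locus()
  expect_equal(codon_of(locus$cmap, 1, locus$genome)$offset, 0L)
  expect_equal(codon_of(locus$cmap, 8, locus$genome)$codon, "GAC")
  expect_equal(codon_of(locus$cmap, 8, locus$genome)$aa, "D")
  codons <- vapply(seq(1, 28, by = 3),
                   function(c1) codon_of(locus$cmap, c1, locus$genome)$codon,
                   character(1))
  expect_equal(paste(codons, collapse = ""), toy_cds())
  expect_error(codon_of(locus$cmap, 31, locus$genome), "incompletely mapped")
})

test_that("variants apply and revert byte-for-byte", {
  withr::with_seed(5, {
    g <- Biostrings::DNAStringSet(c(chrV = rdna(200)))
    pos <- sample(200, 8)
    ref <- vapply(pos, function(p) substr(as.character(g[[1]]), p, p),
                  character(1))
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
  })
  v <- variant_tbl("chrV", pos, ref, alt, genome = g)
  g2 <- apply_variants(g, v)
  expect_false(identical(as.character(g2[[1]]), as.character(g[[1]])))
  g3 <- apply_variants(g2, variant_tbl("chrV", pos, alt, ref))
  expect_identical(as.character(g3[[1]]), as.character(g[[1]]))
  # stated ref must match the genome
  expect_error(variant_tbl("chrV", pos[1], setdiff(c("A","C","G","T"), ref[1])[1],
                           "A", genome = g), "mismatch|differ")
})

test_that("hgvs c. parsing accepts the supported subset only", {
  p <- parse_hgvs_c("c.1935C>A")
  expect_equal(p$c_pos, 1935L)
  expect_equal(p$ref, "C"); expect_equal(p$alt, "A")
  expect_error(parse_hgvs_c("c.1935+5C>A"), "cannot parse")
  expect_error(parse_hgvs_c("c.100del"), "cannot parse")
})

test_that("coding map and genome files round-trip", {
  locus <- toy_locus()
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genome(locus$genome, fa)
  write_coding_map(locus$cmap, tsv)
  g2 <- read_genome(fa)
  cm2 <- read_coding_map(tsv)
  expect_identical(as.character(g2[[1]]), as.character(locus$genome[[1]]))
  expect_equal(cm2$gene_strand, locus$cmap$gene_strand)
  expect_equal(as.data.frame(cm2$segments), as.data.frame(locus$cmap$segments))
})

test_that("reference_locus rejects a target outside the CDS", {
  locus <- toy_locus()
  b <- substr(as.character(locus$genome[[1]]), 5, 5)
  off_target <- variant_tbl("chrT", 5L, b,
                            setdiff(c("A", "C", "G", "T"), b)[1])
  expect_error(reference_locus(locus$genome, locus$cmap, off_target),
               "CDS segment")
})
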