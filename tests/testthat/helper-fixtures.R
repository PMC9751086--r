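# Fixtures are built in code: a hand-crafted single-guide toy locus, random
# coding maps for property tests, and a raw SAM writer independent of the
# package's own simulator output path.

`%||%` <- function(a, b) if (is.null(a)) b else a

rdna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 10-codon CDS: ATG GCT GAC CTG AAA GTT CCT AGG GCT CAT. The in-frame AGG at
# c.22-24 is an NGG PAM whose wobble G (c.24, Arg AGG->AGA) has a synonymous
# alternative; c.8A>T (GAC->GTC, Asp->Val) is the intended edit.
toy_cds <- function() "ATGGCTGACCTGAAAGTTCCTAGGGCTCAT"

toy_locus <- function(pad = 80L, seed = 42L) {
  contig <- withr::with_seed(seed, paste0(rdna(pad), toy_cds(), rdna(pad)))
  genome <- Biostrings::DNAStringSet(c(chrT = contig))
  cmap <- coding_map(
    data.frame(contig = "chrT", start = pad, end = pad + 30L, c_start = 1L),
    "+")
  reference_locus(genome, cmap, "c.8A>T")
}

# The plus-strand guide whose PAM is the in-frame AGG codon.
toy_guide <- function(locus, pad = 80L) {
  g <- find_guides(locus$genome, "chrT")
  g[g$strand == "+" & g$pam_start == pad + 22L, ]
}

# Random multi-segment coding map with a contiguous c. span, either strand.
random_cmap <- function(seed, contig = "chrR", force_strand = NULL) {
  withr::with_seed(seed, {
    n_seg <- sample(1:3, 1)
    widths <- sample(3:20, n_seg, replace = TRUE)
    gaps <- sample(5:20, n_seg, replace = TRUE)
    starts <- cumsum(gaps + c(0L, head(widths, -1L)))
    strand <- force_strand %||% sample(c("+", "-"), 1)
    ord <- if (strand == "+") seq_len(n_seg) else rev(seq_len(n_seg))
    w_ord <- widths[ord]
    c1 <- sample(1:50, 1)
    c_starts <- integer(n_seg)
    c_starts[ord] <- c1 + c(0L, cumsum(w_ord)[-n_seg])
    coding_map(data.frame(contig = contig, start = starts,
                          end = starts + widths, c_start = c_starts), strand)
  })
}

# Small default simulation config so unit tests stay fast; dots override.
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, contig_length = 6000L, locus_offset = 2500L,
               n_background = 10L, n_private = 3L, n_known = 4L,
               n_sites = 3L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Hand-rolled SAM writer (independent of the package's internal writer).
write_test_sam <- function(records, genome, path) {
  lens <- Biostrings::width(genome)
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(genome), lens),
             sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     records$qname, records$flag, records$rname,
                     records$pos, records$mapq, records$cigar,
                     records$seq, records$qual))
  writeLines(lines, path)
  path
}

sam_record <- function(qname, pos, seq, cigar = sprintf("%dM", nchar(seq)),
                       rname = "chrS", flag = 0L, mapq = 60L,
                       qual = strrep("F", nchar(seq))) {
  tibble::tibble(qname = qname, flag = flag, rname = rname, pos = pos,
                 mapq = mapq, cigar = cigar, seq = seq, qual = qual)
}

# Shared synthetic locus/donor used across classifier tests (built once).
shared <- new.env()
get_shared_locus <- function() {
  if (is.null(shared$locus)) {
    shared$locus <- make_reference(small_config(seed = 7))
    shared$donor <- gaa1935_donor(shared$locus)
    shared$guides <- gaa1935_guides(shared$locus)
  }
  shared
}
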