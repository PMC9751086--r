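# Small shared helpers. Sequences are plain upper-case ACGT character strings
# at this level; Biostrings containers appear only at the file-format surface.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' @param x A character vector of DNA sequences (ACGTN).
#' @return A character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Complement without reversal; works base-wise on whole strings.
comp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# Round half away from zero, the convention behind the printed founder
# percentages (35/39 -> 89.7, 15/39 -> 38.5).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside A/C/G/T: %s",
                  what, paste(unique(x[bad]), collapse = ", ")))
  }
  invisible(x)
}

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Fetch a 1-based inclusive slice of a contig from a DNAStringSet genome.
ref_slice <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) {
    abort(sprintf("contig '%s' not present in the genome", contig))
  }
  len <- Biostrings::width(genome[contig])
  if (start < 1L || end > len || start > end) {
    abort(sprintf("slice [%d, %d] out of bounds for contig '%s' (length %d)",
                  start, end, contig, len))
  }
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

ref_base_at <- function(genome, contig, pos) {
  ref_slice(genome, contig, pos, pos)
}

contig_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# Replace characters of a string at 1-based positions.
str_assign <- function(s, pos, values) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch[pos] <- values
  paste(ch, collapse = "")
}
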