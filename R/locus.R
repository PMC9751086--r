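# Coordinate model shared by all stages: a genome (DNAStringSet), a coding map
# translating HGVS-style c. positions to genomic coordinates, and single-
# nucleotide variants as one-row tibbles.
#
# Internal interval bookkeeping is 0-based half-open (BED convention); every
# user-facing variant position and every position returned by c_to_genomic()
# is 1-based, matching VCF and HGVS.

#' Build a coding map from CDS segments
#'
#' A coding map places a gene's coding sequence on the genome so that
#' HGVS-style `c.` positions (1 = first base of the start codon) can be
#' translated to genomic coordinates and back. Segments are given in genomic
#' 0-based half-open coordinates and ordered along the gene: for a
#' minus-strand gene, increasing `c.` runs along decreasing genomic
#' coordinate within each segment.
#'
#' @param segments Data frame with columns `contig`, `start` (0-based),
#'   `end` (exclusive) and `c_start` (first `c.` position covered by the
#'   segment, counted along the gene strand).
#' @param gene_strand `"+"` or `"-"`; strand the gene is read on.
#' @return A `coding_map` object.
#' @examples
#' cm <- coding_map(data.frame(contig = "chr1", start = 100, end = 130,
#'                             c_start = 1), "+")
#' c_to_genomic(cm, 15)
#' @export
coding_map <- function(segments, gene_strand = c("+", "-")) {
  gene_strand <- match.arg(gene_strand)
  seg <- as_tibble(segments)
  needed <- c("contig", "start", "end", "c_start")
  if (!all(needed %in% names(seg))) {
    abort(paste("coding map segments need columns:", paste(needed, collapse = ", ")))
  }
  seg <- mutate(seg,
                start = as.integer(.data$start),
                end = as.integer(.data$end),
                c_start = as.integer(.data$c_start))
  if (any(seg$start < 0L) || any(seg$end <= seg$start)) {
    abort("segments must satisfy 0 <= start < end")
  }
  seg <- arrange(seg, .data$c_start)
  seg$c_end <- seg$c_start + (seg$end - seg$start) - 1L
  if (nrow(seg) > 1L) {
    if (any(seg$c_start[-1L] <= seg$c_end[-nrow(seg)])) {
      abort("segment c. ranges overlap; c_start values must be strictly increasing")
    }
    for (ctg in unique(seg$contig)) {
      s <- seg[seg$contig == ctg, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
        abort(sprintf("genomic segments overlap on contig '%s'", ctg))
      }
    }
  }
  structure(list(segments = seg, gene_strand = gene_strand),
            class = "coding_map")
}

#' @export
print.coding_map <- function(x, ...) {
  cat(sprintf("<coding_map> %d segment(s), gene strand %s, c.%d..c.%d\n",
              nrow(x$segments), x$gene_strand,
              min(x$segments$c_start), max(x$segments$c_end)))
  print(x$segments)
  invisible(x)
}

c_span <- function(cmap) {
  c(min(cmap$segments$c_start), max(cmap$segments$c_end))
}

#' Translate coding (c.) positions to genomic coordinates
#'
#' @param cmap A [coding_map()].
#' @param c_pos Integer vector of `c.` positions.
#' @return A tibble with columns `c_pos`, `contig`, `pos` (1-based).
#' @export
c_to_genomic <- function(cmap, c_pos) {
  stopifnot(inherits(cmap, "coding_map"))
  c_pos <- as.integer(c_pos)
  span <- c_span(cmap)
  bad <- c_pos < span[1] | c_pos > span[2]
  if (any(bad)) {
    abort(sprintf("c. position(s) %s outside the mapped span c.%d..c.%d",
                  paste(c_pos[bad], collapse = ", "), span[1], span[2]))
  }
  seg <- cmap$segments
  idx <- vapply(c_pos, function(p) {
    which(p >= seg$c_start & p <= seg$c_end)[1]
  }, integer(1))
  if (anyNA(idx)) {
    abort(sprintf("c. position(s) %s fall between mapped segments",
                  paste(c_pos[is.na(idx)], collapse = ", ")))
  }
  off <- c_pos - seg$c_start[idx]
  pos <- if (cmap$gene_strand == "+") {
    seg$start[idx] + off + 1L          # 0-based start -> 1-based base
  } else {
    seg$end[idx] - off                 # end exclusive -> 1-based last base
  }
  tibble(c_pos = c_pos, contig = seg$contig[idx], pos = as.integer(pos))
}

#' Translate genomic coordinates to coding (c.) positions
#'
#' Inverse of [c_to_genomic()] on all mapped positions.
#'
#' @param cmap A [coding_map()].
#' @param contig,pos Parallel vectors of contig names and 1-based positions.
#' @return A tibble with columns `contig`, `pos`, `c_pos` (`NA` when the
#'   position is not covered by any CDS segment).
#' @export
genomic_to_c <- function(cmap, contig, pos) {
  stopifnot(inherits(cmap, "coding_map"))
  pos <- as.integer(pos)
  seg <- cmap$segments
  c_pos <- purrr::map2_int(contig, pos, function(ctg, p) {
    i <- which(seg$contig == ctg & p > seg$start & p <= seg$end)[1]
    if (is.na(i)) return(NA_integer_)
    if (cmap$gene_strand == "+") {
      seg$c_start[i] + (p - seg$start[i] - 1L)
    } else {
      seg$c_start[i] + (seg$end[i] - p)
    }
  })
  tibble(contig = contig, pos = pos, c_pos = c_pos)
}

#' Codon context of a coding position
#'
#' Returns the codon (read on the gene strand) containing a `c.` position
#' and the 0-based offset of that position within the codon.
#'
#' @param cmap A [coding_map()].
#' @param c_pos A single `c.` position.
#' @param genome A named `DNAStringSet`.
#' @return A list with elements `codon` (3-nt string), `offset` (0..2) and
#'   `aa` (single-letter amino acid).
#' @export
codon_of <- function(cmap, c_pos, genome) {
  c_pos <- as.integer(c_pos)
  stopifnot(length(c_pos) == 1L)
  offset <- (c_pos - 1L) %% 3L
  codon_c <- (c_pos - offset) + 0:2
  span <- c_span(cmap)
  if (any(codon_c < span[1]) || any(codon_c > span[2])) {
    abort(sprintf("codon spanning c.%d..c.%d is incompletely mapped (span c.%d..c.%d)",
                  codon_c[1], codon_c[3], span[1], span[2]))
  }
  loc <- c_to_genomic(cmap, codon_c)
  bases <- purrr::map2_chr(loc$contig, loc$pos, function(ctg, p) {
    ref_base_at(genome, ctg, p)
  })
  if (cmap$gene_strand == "-") bases <- comp(bases)
  codon <- paste(bases, collapse = "")
  list(codon = codon, offset = offset,
       aa = unname(Biostrings::GENETIC_CODE[codon]))
}

# Spliced CDS sequence over the mapped span, read on the gene strand.
cds_sequence <- function(cmap, genome) {
  seg <- cmap$segments
  parts <- purrr::pmap_chr(seg, function(contig, start, end, ...) {
    s <- ref_slice(genome, contig, start + 1L, end)
    if (cmap$gene_strand == "-") revcomp(s) else s
  })
  paste(parts, collapse = "")
}

# Translate a gene-strand nucleotide string starting at the first complete
# codon implied by its first c. position.
translate_from <- function(seq, first_c) {
  lead <- (3L - ((first_c - 1L) %% 3L)) %% 3L  # bases before first full codon
  body <- substr(seq, lead + 1L, nchar(seq))
  body <- substr(body, 1L, 3L * (nchar(body) %/% 3L))
  if (nchar(body) < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(body)))
}

#' Parse the supported subset of HGVS c. notation
#'
#' Only substitutions of the form `c.<pos><ref>><alt>` are supported
#' (e.g. `"c.1935C>A"`).
#'
#' @param x Character vector of HGVS-like strings.
#' @return A tibble with columns `label`, `c_pos`, `ref`, `alt`.
#' @export
parse_hgvs_c <- function(x) {
  m <- regmatches(x, regexec("^c\\.(\\d+)([ACGT])>([ACGT])$", x))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    abort(sprintf("cannot parse HGVS c. substitution(s): %s",
                  paste(x[bad], collapse = ", ")))
  }
  tibble(label = x,
         c_pos = as.integer(vapply(m, `[`, "", 2L)),
         ref = vapply(m, `[`, "", 3L),
         alt = vapply(m, `[`, "", 4L))
}

#' Construct single-nucleotide variants
#'
#' @param contig,pos,ref,alt Parallel vectors describing substitutions;
#'   `pos` is 1-based.
#' @param label Optional HGVS-like `c.` labels.
#' @param genome Optional genome; when supplied, `ref` is checked against it.
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`, `label`.
#' @export
variant_tbl <- function(contig, pos, ref, alt, label = NA_character_,
                        genome = NULL) {
  v <- tibble(contig = as.character(contig), pos = as.integer(pos),
              ref = toupper(ref), alt = toupper(alt),
              label = as.character(label))
  assert_dna(v$ref, "ref allele"); assert_dna(v$alt, "alt allele")
  if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L)) {
    abort("variant_tbl() represents single-nucleotide substitutions only")
  }
  if (any(v$ref == v$alt)) abort("ref and alt alleles must differ")
  if (!is.null(genome)) {
    obs <- purrr::map2_chr(v$contig, v$pos, ~ ref_base_at(genome, .x, .y))
    bad <- obs != v$ref
    if (any(bad)) {
      abort(sprintf("ref allele mismatch at %s:%d (stated %s, genome has %s)",
                    v$contig[bad][1], v$pos[bad][1], v$ref[bad][1], obs[bad][1]))
    }
  }
  v
}

# Resolve c.-notation substitutions against a coding map into variant rows.
# On minus-strand genes the stated ref/alt are gene-strand bases and are
# complemented onto the genomic plus strand.
variants_from_c <- function(labels, cmap, genome = NULL) {
  p <- parse_hgvs_c(labels)
  loc <- c_to_genomic(cmap, p$c_pos)
  ref <- p$ref; alt <- p$alt
  if (cmap$gene_strand == "-") { ref <- comp(ref); alt <- comp(alt) }
  variant_tbl(loc$contig, loc$pos, ref, alt, label = p$label, genome = genome)
}

#' Apply substitutions to a genome
#'
#' @param genome A named `DNAStringSet`.
#' @param variants A [variant_tbl()].
#' @return A new `DNAStringSet` with the substitutions applied. Applying a
#'   variant set and then the swapped (alt>ref) set restores the input.
#' @export
apply_variants <- function(genome, variants) {
  out <- genome
  for (ctg in unique(variants$contig)) {
    v <- variants[variants$contig == ctg, , drop = FALSE]
    s <- as.character(out[[ctg]])
    have <- substring(s, v$pos, v$pos)
    if (any(have != v$ref)) {
      i <- which(have != v$ref)[1]
      abort(sprintf("cannot apply %s:%d %s>%s: genome has %s",
                    ctg, v$pos[i], v$ref[i], v$alt[i], have[i]))
    }
    out[[ctg]] <- Biostrings::DNAString(str_assign(s, v$pos, v$alt))
  }
  out
}

#' Bundle a genome, coding map and target edit into a reference locus
#'
#' The container consumed by donor design and read classification. Checks
#' that the target edit falls inside the coding sequence, that its stated
#' reference allele matches the genome, and that the mapped CDS translates
#' without internal stop codons.
#'
#' @param genome A named `DNAStringSet`.
#' @param cmap A [coding_map()].
#' @param target The intended knock-in edit: either a one-row [variant_tbl()]
#'   or an HGVS-like string such as `"c.1935C>A"` (gene-strand alleles).
#' @return A `reference_locus` object with elements `genome`, `cmap`,
#'   `target`.
#' @export
reference_locus <- function(genome, cmap, target) {
  stopifnot(inherits(cmap, "coding_map"))
  if (is.character(target)) {
    target <- variants_from_c(target, cmap, genome)
  }
  if (nrow(target) != 1L) abort("exactly one target edit is expected")
  variant_tbl(target$contig, target$pos, target$ref, target$alt,
              target$label, genome = genome)
  cp <- genomic_to_c(cmap, target$contig, target$pos)$c_pos
  if (is.na(cp)) abort("target edit does not fall inside a CDS segment")
  if (is.na(target$label)) {
    gs_ref <- if (cmap$gene_strand == "-") comp(target$ref) else target$ref
    gs_alt <- if (cmap$gene_strand == "-") comp(target$alt) else target$alt
    target$label <- sprintf("c.%d%s>%s", cp, gs_ref, gs_alt)
  }
  prot <- translate_from(cds_sequence(cmap, genome), c_span(cmap)[1])
  if (grepl("\\*.", prot)) {
    abort("mapped CDS translates with an internal stop codon")
  }
  structure(list(genome = genome, cmap = cmap, target = target),
            class = "reference_locus")
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf("<reference_locus> %d contig(s); target %s at %s:%d (%s>%s)\n",
              length(x$genome), x$target$label, x$target$contig,
              x$target$pos, x$target$ref, x$target$alt))
  invisible(x)
}

## ---- file formats -----------------------------------------------------

#' Read / write reference contigs as FASTA
#'
#' Thin wrappers over Biostrings' FASTA support, kept so pipeline stages
#' share one entry point.
#'
#' @param path File path.
#' @param genome A named `DNAStringSet`.
#' @return `read_genome()` returns a `DNAStringSet`; `write_genome()`
#'   returns `path` invisibly.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @rdname read_genome
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read / write a coding map as a BED-like table
#'
#' The on-disk format is tab-separated with 0-based half-open segments and a
#' single header comment naming the gene strand:
#' `# coding_map gene_strand=+` then columns
#' `contig  start  end  c_start`.
#'
#' @param path File path.
#' @param cmap A [coding_map()].
#' @return `read_coding_map()` returns a `coding_map`; `write_coding_map()`
#'   returns `path` invisibly.
#' @export
read_coding_map <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("gene_strand=([+-])", first))[[1]]
  if (length(m) != 2L) {
    abort("coding map file must start with '# coding_map gene_strand=[+-]'")
  }
  seg <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                           col.names = c("contig", "start", "end", "c_start"),
                           colClasses = c("character", "integer", "integer",
                                          "integer"))
  coding_map(seg, m[2])
}

#' @rdname read_coding_map
#' @export
write_coding_map <- function(cmap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coding_map gene_strand=%s", cmap$gene_strand), con)
  utils::write.table(cmap$segments[, c("contig", "start", "end", "c_start")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
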