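# SpCas9 guide enumeration and dual overlapping guide geometry.
#
# A guide row stores the protospacer in guide orientation (5'->3' as it would
# be synthesized), its plus-strand genomic footprint, the NGG PAM, the blunt
# cut site 3 bp 5' of the PAM as a 0-based inter-base coordinate, and the
# 5-nt PAM-proximal seed interval.

guide_columns <- function() {
  tibble(guide_id = character(), protospacer = character(),
         strand = character(), contig = character(),
         proto_start = integer(), proto_end = integer(),
         pam = character(), pam_start = integer(), pam_end = integer(),
         cut_site = integer(), seed_start = integer(), seed_end = integer())
}

#' Enumerate SpCas9 guide candidates in a region
#'
#' Scans both strands of a region for every 20-nt protospacer followed by an
#' NGG PAM lying wholly inside the region. Rows are ordered by plus-strand
#' protospacer start, then strand (`+` before `-`). Efficacy or off-target
#' scoring is deliberately not computed; attach external scores by joining
#' on `protospacer` if you have them.
#'
#' @param genome A named `DNAStringSet`.
#' @param contig Contig to scan; defaults to the first contig.
#' @param start,end 1-based inclusive bounds of the region; default to the
#'   whole contig. A region shorter than 23 nt yields an empty tibble with a
#'   message, not an error.
#' @return A tibble of guides (possibly empty); see Details for columns.
#' @details Columns: `guide_id`, `protospacer` (guide orientation), `strand`,
#'   `contig`, `proto_start`/`proto_end` (plus-strand footprint, 1-based
#'   inclusive), `pam`, `pam_start`/`pam_end` (plus-strand footprint),
#'   `cut_site` (0-based inter-base: the cut falls between positions
#'   `cut_site` and `cut_site + 1`), `seed_start`/`seed_end` (plus-strand
#'   footprint of the 5 PAM-proximal protospacer bases).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "AAACGTAGCTAGCTAGGCTAGCTAGGAAA"))
#' find_guides(g, "chr")
#' @export
find_guides <- function(genome, contig = names(genome)[1],
                        start = 1L, end = NULL) {
  end <- end %||% unname(contig_lengths(genome)[contig])
  start <- as.integer(start); end <- as.integer(end)
  if (end - start + 1L < 23L) {
    inform(sprintf("region %s:%d-%d is shorter than 23 nt; no guides possible",
                   contig, start, end))
    return(guide_columns())
  }
  s <- ref_slice(genome, contig, start, end)

  # Plus strand: protospacer(20) + NGG. A PAM whose GG begins at local
  # offset j (1-based) puts the PAM at j-1..j+1 and needs 20 nt before it.
  gg <- gregexpr("(?=GG)", s, perl = TRUE)[[1]]
  gg <- gg[gg > 0]
  plus <- tibble()
  j <- gg[gg - 1L >= 21L & gg + 1L <= nchar(s)]
  if (length(j) > 0) {
    pam_start <- start + (j - 1L) - 1L      # genomic 1-based PAM N position
    plus <- tibble(
      strand = "+", contig = contig,
      proto_start = pam_start - 20L, proto_end = pam_start - 1L,
      pam_start = pam_start, pam_end = pam_start + 2L
    )
    plus$protospacer <- substr(rep(s, nrow(plus)),
                               plus$proto_start - start + 1L,
                               plus$proto_end - start + 1L)
    plus$pam <- substr(rep(s, nrow(plus)),
                       plus$pam_start - start + 1L,
                       plus$pam_end - start + 1L)
    plus$cut_site <- plus$pam_start - 4L
    plus$seed_start <- plus$proto_end - 4L
    plus$seed_end <- plus$proto_end
  }

  # Minus strand: CCN + protospacer on the plus strand reads as
  # protospacer(20) + NGG on the minus strand.
  cc <- gregexpr("(?=CC)", s, perl = TRUE)[[1]]
  cc <- cc[cc > 0]
  minus <- tibble()
  j <- cc[cc + 2L + 20L <= nchar(s)]
  if (length(j) > 0) {
    pam_start <- start + (j - 1L)           # genomic position of first C
    minus <- tibble(
      strand = "-", contig = contig,
      proto_start = pam_start + 3L, proto_end = pam_start + 22L,
      pam_start = pam_start, pam_end = pam_start + 2L
    )
    fwd_proto <- substr(rep(s, nrow(minus)),
                        minus$proto_start - start + 1L,
                        minus$proto_end - start + 1L)
    fwd_pam <- substr(rep(s, nrow(minus)),
                      minus$pam_start - start + 1L,
                      minus$pam_end - start + 1L)
    minus$protospacer <- revcomp(fwd_proto)
    minus$pam <- revcomp(fwd_pam)
    minus$cut_site <- minus$pam_end + 3L
    minus$seed_start <- minus$proto_start
    minus$seed_end <- minus$proto_start + 4L
  }

  out <- bind_rows(plus, minus)
  if (nrow(out) == 0L) return(guide_columns())
  out <- arrange(out, .data$proto_start, .data$strand)
  out$guide_id <- sprintf("g%03d_%s%d", seq_len(nrow(out)), out$strand,
                          out$proto_start)
  out[, names(guide_columns())]
}

#' Re-extract and check stored guide sequences against a genome
#'
#' @param guides A guide tibble from [find_guides()].
#' @param genome A named `DNAStringSet`.
#' @return Logical vector: does each row's stored protospacer and NGG PAM
#'   match what the genome holds at its coordinates?
#' @export
revalidate_guides <- function(guides, genome) {
  purrr::pmap_lgl(guides, function(protospacer, strand, contig, proto_start,
                                   proto_end, pam, pam_start, pam_end, ...) {
    p <- ref_slice(genome, contig, proto_start, proto_end)
    m <- ref_slice(genome, contig, pam_start, pam_end)
    if (strand == "-") { p <- revcomp(p); m <- revcomp(m) }
    identical(p, protospacer) && identical(m, pam) && grepl("^[ACGT]GG$", m)
  })
}

#' Locate specific protospacers among a region's guide candidates
#'
#' @param genome A named `DNAStringSet`.
#' @param protospacers Character vector of 20-nt protospacer sequences
#'   (guide orientation).
#' @param contig,start,end Region to scan, as in [find_guides()].
#' @return The matching guide rows, in the order of `protospacers`.
#' @export
locate_guides <- function(genome, protospacers, contig = names(genome)[1],
                          start = 1L, end = NULL) {
  all <- find_guides(genome, contig, start, end)
  hit <- all[match(protospacers, all$protospacer), , drop = FALSE]
  if (anyNA(hit$protospacer)) {
    abort(sprintf("protospacer(s) not found with an NGG PAM in the region: %s",
                  paste(protospacers[is.na(hit$protospacer)], collapse = ", ")))
  }
  hit
}

#' Geometry report for a dual overlapping guide pair
#'
#' Describes how two guides sit relative to each other and to the target
#' edit: whether their protospacer footprints overlap, whether they are on
#' opposite strands, each cut site's signed distance to the target base, and
#' whether the cut sites flank the target.
#'
#' @param g1,g2 One-row guide tibbles.
#' @param target A one-row [variant_tbl()] (the intended edit).
#' @return A one-row tibble with columns `overlap`, `opposite_strands`,
#'   `cut_distance_1`, `cut_distance_2`, `flanking`. Distances count bases
#'   from the cut to the target: `+d` means the target lies `d` bases to the
#'   right of the cut, `0` or negative means at/left of it.
#' @export
dual_overlap_report <- function(g1, g2, target) {
  if (g1$contig != g2$contig) {
    abort(sprintf("guides lie on different contigs ('%s' vs '%s')",
                  g1$contig, g2$contig))
  }
  if (!is.null(target) && target$contig != g1$contig) {
    abort("target edit is not on the guides' contig")
  }
  overlap <- g1$proto_start <= g2$proto_end && g2$proto_start <= g1$proto_end
  d1 <- target$pos - g1$cut_site
  d2 <- target$pos - g2$cut_site
  # Flanking: cuts on opposite sides of the target base, or a cut
  # immediately at its boundary (distance 0 or 1).
  side <- function(d) sign(d - 0.5)
  flanking <- side(d1) != side(d2) || d1 %in% c(0L, 1L) || d2 %in% c(0L, 1L)
  tibble(overlap = overlap,
         opposite_strands = g1$strand != g2$strand,
         cut_distance_1 = as.integer(d1),
         cut_distance_2 = as.integer(d2),
         flanking = flanking)
}

#' Read / write guide tables as TSV
#'
#' @param path File path.
#' @param guides A guide tibble.
#' @return `read_guides()` returns a guide tibble; `write_guides()` returns
#'   `path` invisibly.
#' @export
read_guides <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    guide_id = "c", protospacer = "c", strand = "c",
                    contig = "c", pam = "c", .default = "i"))
}

#' @rdname read_guides
#' @export
write_guides <- function(guides, path) {
  readr::write_tsv(guides, path)
  invisible(path)
}
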