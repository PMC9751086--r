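# ssODN donor construction and validation: homology arms, the intended edit,
# and codon-synonymous "shield" mutations in each guide's PAM or seed region
# so the repaired allele resists re-cutting. The companion-offset pattern the
# ectopic HDR scanner uses is derived from the same donor specification.

#' Synonymous alternatives at one codon position
#'
#' @param codon A 3-nt string over A/C/G/T.
#' @param position_in_codon 0, 1 or 2 (offset within the codon).
#' @return Character vector (possibly empty, sorted) of alternate bases `b`
#'   such that replacing the base at `position_in_codon` with `b` leaves the
#'   encoded amino acid unchanged. Computed against the standard nuclear
#'   codon table.
#' @examples
#' synonymous_options("GAC", 2)  # "T": GAT also codes Asp
#' synonymous_options("ATG", 2)  # none: Met has a single codon
#' @export
synonymous_options <- function(codon, position_in_codon) {
  codon <- toupper(codon)
  assert_dna(codon, "codon")
  if (nchar(codon) != 3L) abort("codon must be exactly 3 nt")
  stopifnot(position_in_codon %in% 0:2)
  orig <- substr(codon, position_in_codon + 1L, position_in_codon + 1L)
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  keep <- character()
  for (b in setdiff(DNA_BASES, orig)) {
    alt_codon <- str_assign(codon, position_in_codon + 1L, b)
    if (identical(unname(Biostrings::GENETIC_CODE[alt_codon]), aa)) {
      keep <- c(keep, b)
    }
  }
  sort(keep)
}

# Plus-strand genomic positions whose alteration breaks the GG of an NGG PAM.
pam_gg_positions <- function(guide) {
  if (guide$strand == "+") c(guide$pam_start + 1L, guide$pam_start + 2L)
  else c(guide$pam_start, guide$pam_start + 1L)
}

# Does this edit set disrupt the guide (PAM no longer NGG, or >=1 seed
# mismatch)? `edits` is a variant tibble on the plus strand.
guide_disrupted <- function(guide, edits) {
  e <- edits[edits$contig == guide$contig, , drop = FALSE]
  any(e$pos %in% pam_gg_positions(guide)) ||
    any(e$pos >= guide$seed_start & e$pos <= guide$seed_end)
}

shield_tag <- function(guide, pos) {
  if (pos >= guide$pam_start && pos <= guide$pam_end) "PAM" else "seed"
}

#' Assemble a donor specification
#'
#' Builds (or wraps) a single-stranded oligo donor: homology arms of
#' `arm_length` nt flanking the edited core, the intended edit, and shield
#' edits. Use [build_ssodn()] to choose shields automatically;
#' use this constructor directly to describe an externally designed donor
#' (for example one taken from a publication) so it can be run through
#' [validate_donor()] and [derive_signature_pattern()].
#'
#' @param locus A [reference_locus()].
#' @param shields Shield edits: a tibble with columns `label` (HGVS-like
#'   `c.` strings, gene-strand alleles), `tag` (`"PAM"` or `"seed"`) and
#'   `guide_id`; or with explicit `contig`/`pos`/`ref`/`alt` columns.
#' @param intended The intended edit; defaults to `locus$target`.
#' @param arm_length Homology arm length in nt (default 50).
#' @param orientation `"+"` or `"-"`: strand on which the oligo is written.
#' @param ssodn Optional explicit oligo sequence (in `orientation`). When
#'   omitted the oligo is constructed from the reference plus the edits;
#'   supply it to describe an oligo exactly as synthesized, including any
#'   mistakes you want [validate_donor()] to catch.
#' @return A `donor_spec` object.
#' @export
donor_spec <- function(locus, shields, intended = NULL, arm_length = 50L,
                       orientation = c("+", "-"), ssodn = NULL) {
  stopifnot(inherits(locus, "reference_locus"))
  orientation <- match.arg(orientation)
  intended <- intended %||% locus$target
  cmap <- locus$cmap

  shields <- as_tibble(shields)
  if (nrow(shields) == 0L) {
    shields <- tibble(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      label = character(), tag = character(),
                      guide_id = character())
  } else if (!"pos" %in% names(shields)) {
    v <- variants_from_c(shields$label, cmap, locus$genome)
    shields <- bind_rows(tibble(v, tag = shields$tag,
                                guide_id = shields$guide_id))
  } else {
    shields$label <- shields$label %||% NA_character_
  }
  if (nrow(shields) > 0 && !all(shields$tag %in% c("PAM", "seed"))) {
    abort("shield tags must be 'PAM' or 'seed'")
  }
  edits <- bind_rows(
    mutate(intended, tag = "intended", guide_id = NA_character_),
    shields
  )
  if (length(unique(edits$contig)) != 1L) {
    abort("all donor edits must lie on one contig")
  }
  if (anyDuplicated(edits$pos)) abort("donor edits collide at one position")
  contig <- edits$contig[1]
  span_start <- min(edits$pos) - as.integer(arm_length)
  span_end <- max(edits$pos) + as.integer(arm_length)
  clen <- unname(contig_lengths(locus$genome)[contig])
  if (span_start < 1L || span_end > clen) {
    abort("homology arms extend beyond the contig")
  }
  ref_window <- ref_slice(locus$genome, contig, span_start, span_end)
  built <- str_assign(ref_window, edits$pos - span_start + 1L, edits$alt)
  if (is.null(ssodn)) {
    ssodn <- if (orientation == "-") revcomp(built) else built
  } else {
    ssodn <- toupper(ssodn)
    if (nchar(ssodn) != nchar(built)) {
      abort(sprintf("supplied ssODN length %d does not match the %d-nt span",
                    nchar(ssodn), nchar(built)))
    }
  }
  structure(list(
    intended = intended, shields = shields, arm_length = as.integer(arm_length),
    orientation = orientation, contig = contig,
    span_start = span_start, span_end = span_end,
    ssodn = ssodn, gene_strand = cmap$gene_strand
  ), class = "donor_spec")
}

#' @export
print.donor_spec <- function(x, ...) {
  cat(sprintf("<donor_spec> %d-nt ssODN (%s) on %s:%d-%d\n",
              nchar(x$ssodn), x$orientation, x$contig, x$span_start, x$span_end))
  cat(sprintf("  intended: %s (%s:%d %s>%s), arms %d nt, %d shield edit(s)\n",
              x$intended$label, x$intended$contig, x$intended$pos,
              x$intended$ref, x$intended$alt, x$arm_length, nrow(x$shields)))
  invisible(x)
}

# All donor edits as one plus-strand variant tibble.
donor_edits <- function(donor) {
  bind_rows(mutate(donor$intended, tag = "intended", guide_id = NA_character_),
            donor$shields)
}

#' Design shield edits and assemble the donor automatically
#'
#' For each targeted guide, chooses a synonymous single-base edit that
#' disrupts the guide: preferentially one that breaks the NGG PAM, otherwise
#' one inside the 5-nt PAM-proximal seed. The choice is deterministic:
#' PAM-disrupting before seed, then left-most genomic position, then
#' alphabetically first gene-strand base.
#'
#' @param locus A [reference_locus()] whose `target` is the intended edit.
#' @param guides Guide tibble (rows from [find_guides()]).
#' @param arm_length Homology arm length in nt (default 50).
#' @param orientation Oligo orientation, `"+"` (default) or `"-"`.
#' @return A validated `donor_spec`.
#' @export
build_ssodn <- function(locus, guides, arm_length = 50L,
                        orientation = c("+", "-")) {
  orientation <- match.arg(orientation)
  cmap <- locus$cmap
  target <- locus$target
  far <- abs(target$pos - guides$cut_site) > arm_length
  if (any(far)) {
    abort(sprintf("cut site of guide %s is more than %d nt from the target edit",
                  guides$guide_id[far][1], arm_length))
  }

  pick_shield <- function(guide, positions, tag) {
    for (p in sort(positions)) {
      cp <- genomic_to_c(cmap, guide$contig, p)$c_pos
      if (is.na(cp)) next
      ctx <- codon_of(cmap, cp, locus$genome)
      opts <- synonymous_options(ctx$codon, ctx$offset)
      if (length(opts) == 0L) next
      alt_gene <- opts[1]
      ref_gene <- substr(ctx$codon, ctx$offset + 1L, ctx$offset + 1L)
      flip <- cmap$gene_strand == "-"
      return(variant_tbl(guide$contig, p,
                         if (flip) comp(ref_gene) else ref_gene,
                         if (flip) comp(alt_gene) else alt_gene,
                         label = sprintf("c.%d%s>%s", cp, ref_gene, alt_gene)) |>
               mutate(tag = tag, guide_id = guide$guide_id))
    }
    NULL
  }

  shields <- purrr::map(seq_len(nrow(guides)), function(i) {
    g <- guides[i, ]
    s <- pick_shield(g, pam_gg_positions(g), "PAM")
    if (is.null(s)) s <- pick_shield(g, g$seed_start:g$seed_end, "seed")
    if (is.null(s)) {
      abort(sprintf(paste0("no synonymous edit can disrupt the PAM or seed of ",
                           "guide %s"), g$guide_id),
            class = "crisprki_no_shield", guide = g$guide_id)
    }
    s
  })
  shields <- distinct(bind_rows(shields))
  shields <- shields[shields$pos != target$pos, , drop = FALSE]
  donor_spec(locus, shields, intended = target, arm_length = arm_length,
             orientation = orientation)
}

# Residue indices (relative to the mapped span's first full codon) where the
# protein translated after applying `edits` differs from the reference.
protein_changes <- function(locus, edits) {
  cmap <- locus$cmap
  first_c <- c_span(cmap)[1]
  ref_p <- translate_from(cds_sequence(cmap, locus$genome), first_c)
  alt_p <- translate_from(cds_sequence(cmap, apply_variants(locus$genome, edits)),
                          first_c)
  which(strsplit(ref_p, "")[[1]] != strsplit(alt_p, "")[[1]])
}

#' Validate a donor specification
#'
#' Checks every donor invariant and returns an itemized report rather than
#' erroring: arm lengths, exact reference match outside edited positions,
#' presence of the intended edit, synonymy of each shield, a
#' single-residue protein change, and (when `guides` is supplied) that each
#' guide is disrupted by at least one shield in its PAM or seed.
#'
#' @param donor A `donor_spec`.
#' @param locus The [reference_locus()] the donor targets.
#' @param guides Optional guide tibble for the disruption checks.
#' @return A `donor_validation` object; `tidy()` gives the per-item table,
#'   `glance()` the overall verdict.
#' @export
validate_donor <- function(donor, locus, guides = NULL) {
  cmap <- locus$cmap
  edits <- donor_edits(donor)
  oligo_plus <- if (donor$orientation == "-") revcomp(donor$ssodn) else donor$ssodn
  items <- list()
  add <- function(check, pass, detail = "") {
    items[[length(items) + 1L]] <<- tibble(check = check, pass = pass,
                                           detail = detail)
  }

  local_pos <- edits$pos - donor$span_start + 1L
  add("edit positions inside ssODN span",
      all(local_pos >= 1L & local_pos <= nchar(oligo_plus)))

  add("homology arm length",
      min(edits$pos) - donor$span_start == donor$arm_length &&
        donor$span_end - max(edits$pos) == donor$arm_length,
      sprintf("arms span %d/%d nt (expected %d)",
              min(edits$pos) - donor$span_start,
              donor$span_end - max(edits$pos), donor$arm_length))

  ref_window <- ref_slice(locus$genome, donor$contig, donor$span_start,
                          donor$span_end)
  mism <- which(strsplit(oligo_plus, "")[[1]] != strsplit(ref_window, "")[[1]])
  extra <- setdiff(mism, local_pos)
  add("arms and spacer match reference outside edited positions",
      length(extra) == 0L,
      if (length(extra)) sprintf("unexpected difference at %s",
                                 paste(donor$span_start + extra - 1L,
                                       collapse = ", ")) else "")

  ip <- donor$intended$pos - donor$span_start + 1L
  add("intended edit present",
      substr(oligo_plus, ip, ip) == donor$intended$alt,
      sprintf("ssODN has %s at %s:%d (intended %s)",
              substr(oligo_plus, ip, ip), donor$contig, donor$intended$pos,
              donor$intended$alt))

  for (i in seq_len(nrow(donor$shields))) {
    sh <- donor$shields[i, ]
    sp <- sh$pos - donor$span_start + 1L
    present <- substr(oligo_plus, sp, sp) == sh$alt
    syn <- length(protein_changes(locus, sh)) == 0L
    lbl <- sh$label %||% sprintf("%s:%d%s>%s", sh$contig, sh$pos, sh$ref, sh$alt)
    if (is.na(lbl)) lbl <- sprintf("%s:%d%s>%s", sh$contig, sh$pos, sh$ref, sh$alt)
    add(sprintf("shield %s present in ssODN", lbl), present)
    add(sprintf("shield %s synonymous", lbl), syn,
        if (!syn) "changes the encoded protein" else "")
  }

  changed <- protein_changes(locus, edits)
  intended_only <- protein_changes(locus, donor$intended)
  add("protein changes at exactly the intended residue",
      length(changed) == 1L && identical(changed, intended_only),
      sprintf("%d residue(s) change", length(changed)))

  if (!is.null(guides)) {
    for (i in seq_len(nrow(guides))) {
      g <- guides[i, ]
      has <- any(donor$shields$guide_id %in% g$guide_id) ||
        guide_disrupted(g, donor$shields)
      add(sprintf("guide %s disrupted by a PAM or seed shield", g$guide_id),
          guide_disrupted(g, edits))
    }
  }

  report <- bind_rows(items)
  structure(list(items = report, pass = all(report$pass), donor = donor),
            class = "donor_validation")
}

#' @export
print.donor_validation <- function(x, ...) {
  cat(sprintf("<donor_validation> %s (%d/%d checks pass)\n",
              if (x$pass) "PASS" else "FAIL",
              sum(x$items$pass), nrow(x$items)))
  for (i in seq_len(nrow(x$items))) {
    cat(sprintf("  [%s] %s%s\n", if (x$items$pass[i]) "ok" else "FAIL",
                x$items$check[i],
                if (!x$items$pass[i] && nzchar(x$items$detail[i]))
                  paste0(" — ", x$items$detail[i]) else ""))
  }
  invisible(x)
}

#' @export
tidy.donor_validation <- function(x, ...) x$items

#' @export
glance.donor_validation <- function(x, ...) {
  tibble(pass = x$pass, n_checks = nrow(x$items),
         n_failed = sum(!x$items$pass))
}

#' Derive the ectopic HDR signature pattern from a donor
#'
#' An oligo donor integrated somewhere other than the target locus leaves a
#' recognizable scar: the intended transversion together with the shield
#' edits at their fixed spacings. This function turns a donor specification
#' into that search pattern — the central `ref>alt` substitution plus one
#' companion rule per shield, expressed as (offset upstream along the gene
#' strand, required alternate base). Shields downstream of the intended edit
#' are excluded from the pattern (with a warning) and reported separately.
#'
#' @param donor A `donor_spec` whose edits carry `c.` labels.
#' @return A `signature_pattern`: list with `central` (`ref`, `alt`),
#'   `companions` (tibble `offset`, `alt`, `source`, ascending offsets) and
#'   `excluded` (downstream shields, if any).
#' @export
derive_signature_pattern <- function(donor) {
  stopifnot(inherits(donor, "donor_spec"))
  if (nrow(donor$shields) == 0L) {
    abort("no companions derivable: the donor has no shield edits")
  }
  ic <- parse_hgvs_c(donor$intended$label)
  sc <- parse_hgvs_c(donor$shields$label)
  comp_tbl <- tibble(offset = ic$c_pos - sc$c_pos, alt = sc$alt,
                     source = sc$label)
  down <- comp_tbl[comp_tbl$offset <= 0L, , drop = FALSE]
  up <- arrange(comp_tbl[comp_tbl$offset > 0L, , drop = FALSE], .data$offset)
  if (nrow(down) > 0L) {
    warn(sprintf("shield(s) downstream of the intended edit excluded from the pattern: %s",
                 paste(down$source, collapse = ", ")))
  }
  if (nrow(up) == 0L) {
    abort("no companions derivable: all shields lie downstream of the intended edit")
  }
  signature_pattern(ic$ref, ic$alt, up, excluded = down)
}

#' Construct a signature pattern directly
#'
#' @param central_ref,central_alt Reference and alternate base of the
#'   central substitution (gene/plus strand of the pattern).
#' @param companions Tibble with columns `offset` (nt upstream of the
#'   central position, positive) and `alt` (required alternate base);
#'   an optional `source` column records provenance.
#' @param excluded Optional tibble of rejected (downstream) companions.
#' @return A `signature_pattern` object. Matching is strand-symmetric: the
#'   scanner also applies the reverse-complement image of the pattern.
#' @export
signature_pattern <- function(central_ref, central_alt, companions,
                              excluded = NULL) {
  companions <- as_tibble(companions)
  if (!"source" %in% names(companions)) companions$source <- NA_character_
  if (nrow(companions) == 0L) abort("a signature pattern needs >=1 companion")
  if (any(companions$offset <= 0L) || anyDuplicated(companions$offset)) {
    abort("companion offsets must be positive and unique")
  }
  structure(list(central = list(ref = central_ref, alt = central_alt),
                 companions = arrange(companions, .data$offset),
                 excluded = excluded %||% companions[0, ],
                 strand_symmetric = TRUE),
            class = "signature_pattern")
}

#' @export
print.signature_pattern <- function(x, ...) {
  cat(sprintf("<signature_pattern> central %s>%s; companions: %s (strand-symmetric)\n",
              x$central$ref, x$central$alt,
              paste(sprintf("N>%s@-%d", x$companions$alt, x$companions$offset),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.signature_pattern <- function(x, ...) x$companions

#' Serialize a donor specification to disk
#'
#' Writes `<prefix>.fa` (the oligo as FASTA, in its stored orientation) and
#' `<prefix>_edits.tsv` (the edits table with a comment header carrying arm
#' length, orientation and genomic span). [read_donor()] restores the
#' `donor_spec` given the locus.
#'
#' @param donor A `donor_spec`.
#' @param prefix Output path prefix.
#' @param locus A [reference_locus()] (needed on read to re-anchor the donor).
#' @param path Path prefix used when writing.
#' @return `write_donor()` returns the two paths invisibly; `read_donor()`
#'   returns a `donor_spec`.
#' @export
write_donor <- function(donor, prefix) {
  fa <- paste0(prefix, ".fa")
  tsv <- paste0(prefix, "_edits.tsv")
  oligo <- Biostrings::DNAStringSet(stats::setNames(donor$ssodn, "ssODN"))
  Biostrings::writeXStringSet(oligo, fa, width = 70L)
  con <- file(tsv, "w")
  writeLines(sprintf("# donor_spec arm_length=%d orientation=%s contig=%s span=%d-%d",
                     donor$arm_length, donor$orientation, donor$contig,
                     donor$span_start, donor$span_end), con)
  utils::write.table(donor_edits(donor)[, c("pos", "ref", "alt", "label",
                                            "tag", "guide_id")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(fa, tsv))
}

#' @rdname write_donor
#' @export
read_donor <- function(prefix, locus) {
  tsv <- paste0(prefix, "_edits.tsv")
  fa <- paste0(prefix, ".fa")
  hdr <- readLines(tsv, n = 1L)
  arm <- as.integer(sub(".*arm_length=(\\d+).*", "\\1", hdr))
  ori <- sub(".*orientation=([+-]).*", "\\1", hdr)
  ed <- utils::read.table(tsv, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c("integer", "character", "character",
                                         "character", "character", "character"),
                          na.strings = "NA")
  ed$contig <- sub(".*contig=(\\S+).*", "\\1", hdr)
  intended <- ed[ed$tag == "intended", , drop = FALSE]
  shields <- ed[ed$tag != "intended", , drop = FALSE]
  ssodn <- as.character(Biostrings::readDNAStringSet(fa)[[1]])
  donor_spec(locus,
             shields = as_tibble(shields[, c("contig", "pos", "ref", "alt",
                                             "label", "tag", "guide_id")]),
             intended = variant_tbl(intended$contig, intended$pos,
                                    intended$ref, intended$alt,
                                    intended$label),
             arm_length = arm, orientation = ori, ssodn = ssodn)
}
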