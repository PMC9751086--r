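# Off-target analyses over whole-genome variant calls: de novo SNV
# subtraction against a wild-type control and a known-SNP catalog, a window
# check around predicted off-target sites, and the genome-wide scan for
# ectopic HDR signatures on both strands.

#' Read single-nucleotide variants from a VCF
#'
#' Site-level parsing: genotype and FILTER fields are ignored unless
#' `pass_only = TRUE`. Multi-allelic records are expanded; only records with
#' 1-nt REF and ALT are kept.
#'
#' @param path Path to an (optionally bgzipped) VCF.
#' @param pass_only Keep only records whose FILTER is `PASS` or `.`.
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`; attribute
#'   `"header_contigs"` carries the contig names declared in the header.
#' @export
read_snvs <- function(path, pass_only = FALSE) {
  vcf <- VariantAnnotation::readVcf(path)
  gr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  idx <- rep(seq_along(gr), n_alt)
  tbl <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr))[idx],
    pos = GenomicRanges::start(gr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = as.character(unlist(alt)),
    filter = as.character(VariantAnnotation::filt(vcf))[idx]
  )
  if (pass_only) tbl <- tbl[tbl$filter %in% c("PASS", "."), , drop = FALSE]
  tbl <- tbl[nchar(tbl$ref) == 1L & nchar(tbl$alt) == 1L &
               tbl$alt %in% DNA_BASES, , drop = FALSE]
  out <- select(tbl, "contig", "pos", "ref", "alt")
  attr(out, "header_contigs") <-
    as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(vcf)))
  out
}

as_snv_tbl <- function(x, pass_only = FALSE) {
  if (is.character(x)) read_snvs(x, pass_only = pass_only) else as_tibble(x)
}

snv_key <- function(x) paste(x$contig, x$pos, x$ref, x$alt, sep = ":")

#' Subtract background variation to get the de novo SNV set
#'
#' An SNV from the founder's calls is retained only if no identical
#' (contig, pos, ref, alt) record exists in the wild-type control calls or
#' the known-SNP catalog, and its contig is in the allowlist (emulating the
#' removal of variants on un-located chromosomes). Filters are applied in
#' the order unplaced-contig, control, known-SNP, and each input record is
#' counted once, so the provenance counters sum to the input count. A record
#' sharing position and alternate allele with a control/known record but
#' differing in reference allele is retained, with a warning.
#'
#' @param founder,control Founder and wild-type control calls: VCF paths or
#'   tibbles with `contig`, `pos`, `ref`, `alt`.
#' @param known Optional known-SNP catalog (same forms).
#' @param contig_allowlist Contigs to keep; default: the contigs declared in
#'   the control's header (or seen in its records), i.e. anything else is
#'   treated as un-located.
#' @param pass_only Apply FILTER=PASS when reading VCFs.
#' @return A `de_novo_set`: the retained SNV tibble, with provenance
#'   counters available via `glance()`.
#' @export
subtract_background <- function(founder, control, known = NULL,
                                contig_allowlist = NULL, pass_only = FALSE) {
  f <- as_snv_tbl(founder, pass_only)
  ctl <- as_snv_tbl(control, pass_only)
  kn <- if (is.null(known)) ctl[0, ] else as_snv_tbl(known, pass_only)

  c_hdr <- attr(ctl, "header_contigs") %||% unique(ctl$contig)
  allow <- contig_allowlist %||% c_hdr
  # Allowlisted founder contigs the control has never heard of point at a
  # naming mismatch between the two call sets, not at un-located sequence.
  bad <- setdiff(intersect(unique(f$contig), allow), c_hdr)
  if (length(bad) > 0L) {
    abort(sprintf("contig '%s' in founder calls is unknown to the control",
                  bad[1]))
  }

  n_input <- nrow(f)
  unplaced <- !(f$contig %in% allow)
  n_unplaced <- sum(unplaced)
  f <- f[!unplaced, , drop = FALSE]

  in_control <- snv_key(f) %in% snv_key(ctl)
  n_control <- sum(in_control)
  f <- f[!in_control, , drop = FALSE]

  in_known <- snv_key(f) %in% snv_key(kn)
  n_known <- sum(in_known)
  f <- f[!in_known, , drop = FALSE]

  near_key <- function(x) paste(x$contig, x$pos, x$alt, sep = ":")
  shadow <- near_key(f) %in% c(near_key(ctl), near_key(kn))
  if (any(shadow)) {
    warn(sprintf(paste0("%d retained SNV(s) share position and alt with a ",
                        "control/known record but differ in ref"),
                 sum(shadow)))
  }

  counters <- tibble(input = n_input, removed_unplaced = n_unplaced,
                     removed_as_control = n_control,
                     removed_as_known = n_known, retained = nrow(f))
  stopifnot(with(counters, removed_unplaced + removed_as_control +
                   removed_as_known + retained == input))
  structure(arrange(f, .data$contig, .data$pos),
            counters = counters,
            class = c("de_novo_set", class(f)))
}

#' @export
glance.de_novo_set <- function(x, ...) attr(x, "counters")

#' @export
print.de_novo_set <- function(x, ...) {
  ct <- attr(x, "counters")
  cat(sprintf(
    "<de_novo_set> %d retained of %d input (%d control, %d known, %d unplaced removed)\n",
    ct$retained, ct$input, ct$removed_as_control, ct$removed_as_known,
    ct$removed_unplaced))
  NextMethod()
}

read_bed_sites <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  rows <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L || is.na(suppressWarnings(as.integer(p[2]))) ||
        is.na(suppressWarnings(as.integer(p[3]))) ||
        as.integer(p[2]) >= as.integer(p[3])) {
      abort(sprintf("malformed BED line %d in %s", rows[i], path))
    }
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble(contig = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,    # back to 0-based
         end = GenomicRanges::end(gr),
         name = if (!is.null(gr$name)) as.character(gr$name)
                else sprintf("site_%d", seq_along(gr)))
}

#' Count de novo SNVs near predicted off-target sites
#'
#' For each predicted site interval, counts retained de novo SNVs whose
#' position lies within `window_nt` of the interval: distance 0 inside the
#' interval, and the boundary is inclusive (an SNV exactly `window_nt` away
#' is counted; one base further is not).
#'
#' @param sites Predicted off-target sites: BED path (0-based half-open) or
#'   a tibble with `contig`, `start` (0-based), `end`, optional `name`.
#' @param denovo A [subtract_background()] result or SNV tibble.
#' @param window_nt Window in nt (default 500).
#' @return A tibble with one row per site: `name`, `contig`, `start`, `end`,
#'   `n_snvs` and a list-column `snvs` of the matching records.
#' @export
predicted_site_check <- function(sites, denovo, window_nt = 500L) {
  if (is.character(sites)) sites <- read_bed_sites(sites)
  sites <- as_tibble(sites)
  if (!"name" %in% names(sites)) {
    sites$name <- sprintf("site_%d", seq_len(nrow(sites)))
  }
  dn <- as_tibble(denovo)
  res <- purrr::pmap(sites, function(contig, start, end, name, ...) {
    s1 <- start + 1L                       # first base, 1-based
    d <- dn[dn$contig == contig, , drop = FALSE]
    dist <- ifelse(d$pos < s1, s1 - d$pos, ifelse(d$pos > end, d$pos - end, 0L))
    hit <- d[dist <= window_nt, , drop = FALSE]
    tibble(name = name, contig = contig, start = start, end = end,
           n_snvs = nrow(hit), snvs = list(hit))
  })
  bind_rows(res)
}

#' Scan de novo SNVs for ectopic HDR signatures on both strands
#'
#' A hit is a de novo SNV matching the pattern's central substitution with
#' at least one de novo companion SNV at one of the pattern's offsets
#' upstream whose alternate allele equals the required base ("any one of the
#' criteria" suffices; all matching companions are recorded). "Upstream" is
#' read in the direction of the central substitution's strand, so the scan
#' is repeated for the reverse complement: on the minus pass the central
#' ref/alt and companion alleles are complemented and the offsets run
#' downstream in genome coordinates.
#'
#' @param denovo A [subtract_background()] result or SNV tibble.
#' @param pattern A [signature_pattern()], typically from
#'   [derive_signature_pattern()].
#' @return A tibble of hits sorted by position: `contig`, `pos`, `ref`,
#'   `alt`, `strand`, `n_companions`, and a list-column `companions`
#'   (`offset`, `pos`, `ref`, `alt` per matched companion).
#' @export
scan_signatures <- function(denovo, pattern) {
  stopifnot(inherits(pattern, "signature_pattern"))
  dn <- as_tibble(denovo)
  empty <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), strand = character(),
                  n_companions = integer(), companions = list())
  if (nrow(dn) == 0L) return(empty)
  comps <- pattern$companions

  scan_pass <- function(central_ref, central_alt, dir, strand) {
    centers <- dn[dn$ref == central_ref & dn$alt == central_alt, ,
                  drop = FALSE]
    if (nrow(centers) == 0L) return(empty)
    out <- purrr::pmap(centers, function(contig, pos, ref, alt, ...) {
      want_alt <- if (strand == "+") comps$alt else comp(comps$alt)
      cand <- tibble(offset = comps$offset,
                     pos = pos + dir * comps$offset, alt = want_alt)
      near <- distinct(dn[dn$contig == contig, , drop = FALSE],
                       .data$pos, .data$alt, .keep_all = TRUE)
      m <- left_join(cand, near, by = c("pos", "alt"))
      m <- m[!is.na(m$ref), c("offset", "pos", "ref", "alt"), drop = FALSE]
      if (nrow(m) == 0L) return(NULL)
      tibble(contig = contig, pos = pos, ref = ref, alt = alt,
             strand = strand, n_companions = nrow(m), companions = list(m))
    })
    bind_rows(out)
  }

  hits <- bind_rows(
    scan_pass(pattern$central$ref, pattern$central$alt, -1L, "+"),
    scan_pass(comp(pattern$central$ref), comp(pattern$central$alt), +1L, "-")
  )
  if (nrow(hits) == 0L) return(empty)
  arrange(hits, .data$contig, .data$pos, .data$strand)
}

#' Write signature hits as TSV
#'
#' Companion lists are flattened to `offset:alt` tokens.
#'
#' @param hits Result of [scan_signatures()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  flat <- mutate(hits, companions = map_chr(.data$companions, function(m) {
    paste(sprintf("-%d:%s>%s", m$offset, m$ref, m$alt), collapse = ",")
  }))
  readr::write_tsv(flat, path)
  invisible(path)
}
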