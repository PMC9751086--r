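# Seeded generators for every input the pipeline consumes: a toy genome
# embedding the reconstructed Gaa c.1935 locus core, mosaic founder read
# sets with ground-truth labels, and founder/control VCF pairs with
# background SNVs, a known-SNP catalog, predicted-site BEDs and optionally
# planted ectopic HDR signatures. Everything is bit-reproducible given
# (seed, config); truth tables suffice to compute exact expected outputs
# downstream.

# The three published protospacers targeting the Gaa c.1935 locus.
GAA1935_GUIDES <- c(
  gRNA1 = "CGCAGATGTCCGCCCCGACC",
  gRNA2 = "GCAGATGTCCGCCCCGACCA",
  gRNA3 = "GGGCGTGCCCCTGGTCGGGG"
)

# Reconstruct the 32-nt plus-strand locus core by overlap-assembling the
# printed guides: gRNA-3 reads on the plus strand, gRNA-1/2 are antisense.
assemble_core <- function() {
  merge_overlap <- function(a, b) {
    if (grepl(b, a, fixed = TRUE)) return(a)
    for (k in rev(seq_len(min(nchar(a), nchar(b)) - 1L))) {
      if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k)) {
        return(paste0(a, substr(b, k + 1L, nchar(b))))
      }
    }
    abort("fragments do not overlap")
  }
  core <- merge_overlap(GAA1935_GUIDES[["gRNA3"]],
                        revcomp(GAA1935_GUIDES[["gRNA2"]]))
  merge_overlap(core, revcomp(GAA1935_GUIDES[["gRNA1"]]))
}

# c. position of the core's first base: the core runs c.1911..c.1942 so the
# intended edit c.1935 sits on the third base of the Asp-645 codon (GAC).
CORE_C_START <- 1911L

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with the defaults
#' that emulate the founder experiment being modelled: a mosaic founder
#' whose reads are mostly faithful knock-in with minority indel and stray
#' outcomes, short-read error around 0.1%, and a clean off-target
#' background.
#'
#' @param seed Integer seed; every generator draws only from this.
#' @param contig,contig_length Name and length of the main synthetic contig.
#' @param locus_offset 0-based offset of the coding segment on the contig.
#' @param proportions Named mixture over read haplotypes
#'   (`intended_KI`, `indel`, `no_mutation`, `nonspecific`); must sum to 1.
#' @param n_reads Number of simulated reads; if `NULL` and `coverage` is
#'   given, drawn as Poisson(`coverage`).
#' @param coverage Optional target spanning-read depth.
#' @param read_length Read length in nt; must cover the donor footprint.
#' @param error_rate Independent per-base substitution error probability.
#' @param indel_size Signed indel size for the indel haplotype (default -2:
#'   a 2-nt deletion at the gRNA-2 cut site).
#' @param n_background Shared (founder and control) background SNVs.
#' @param n_private Founder-private SNVs (the expected de novo set).
#' @param n_known Known-SNP catalog size; half of them also appear in the
#'   founder's calls and are subtracted.
#' @param n_unplaced Founder SNVs placed on an un-located contig.
#' @param n_planted Ectopic HDR signature clusters planted in the founder.
#' @param planted_strand Strand of planted clusters, `"+"` or `"-"`.
#' @param n_sites,site_width Predicted off-target sites written to BED.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, contig = "chrS", contig_length = 50000L,
                       locus_offset = 25000L,
                       proportions = c(intended_KI = 0.55, indel = 0.25,
                                       no_mutation = 0.15, nonspecific = 0.05),
                       n_reads = 500L, coverage = NULL, read_length = 150L,
                       error_rate = 0.001, indel_size = -2L,
                       n_background = 40L, n_private = 5L, n_known = 8L,
                       n_unplaced = 2L, n_planted = 0L,
                       planted_strand = c("+", "-"),
                       n_sites = 7L, site_width = 23L) {
  planted_strand <- match.arg(planted_strand)
  if (abs(sum(proportions) - 1) > 1e-9) abort("mixture proportions must sum to 1")
  if (!setequal(names(proportions), OUTCOME_CATEGORIES)) {
    abort(sprintf("proportions must be named over: %s",
                  paste(OUTCOME_CATEGORIES, collapse = ", ")))
  }
  if (error_rate < 0 || error_rate > 1) abort("error_rate must be in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate the synthetic reference genome and coding map
#'
#' Builds a random contig embedding a 20-codon coding segment whose middle
#' carries the 32-nt locus core reconstructed from the printed guide
#' sequences, framed so that the codon at the target position is GAC (Asp).
#' A second, short "un-located" contig is included so background
#' subtraction's unplaced-variant handling can be exercised. Byte-identical
#' output for identical (seed, config).
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, writes `ref.fa` and
#'   `coding_map.tsv` there.
#' @return A [reference_locus()] whose target is the c.1935 C>A edit.
#' @export
make_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  core <- assemble_core()
  cds_start_c <- CORE_C_START - 2L          # back to a codon boundary (c.1909)
  withr::with_seed(config$seed, {
    main <- rand_dna(config$contig_length)
    repeat {
      cds <- paste0(rand_dna(2L), core, rand_dna(26L))
      if (!grepl("\\*", translate_from(cds, cds_start_c))) break
    }
    unplaced <- rand_dna(2000L)
  })
  off <- config$locus_offset
  if (off < 1000L || off + nchar(cds) + 1000L > config$contig_length) {
    abort("locus_offset places the coding segment too close to a contig end")
  }
  main <- paste0(substr(main, 1L, off), cds,
                 substr(main, off + nchar(cds) + 1L, config$contig_length))
  genome <- Biostrings::DNAStringSet(c(main, unplaced))
  names(genome) <- c(config$contig, "chrUn_synthetic")
  cmap <- coding_map(tibble(contig = config$contig, start = off,
                            end = off + nchar(cds), c_start = cds_start_c),
                     "+")
  locus <- reference_locus(genome, cmap, "c.1935C>A")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(genome, file.path(dir, "ref.fa"))
    write_coding_map(cmap, file.path(dir, "coding_map.tsv"))
  }
  locus
}

#' Published guide pair and donor design on the synthetic locus
#'
#' `gaa1935_guides()` locates the two overlapping guides used in vivo
#' (gRNA-2, antisense; gRNA-3, sense) on the synthetic reference;
#' `gaa1935_donor()` assembles the published donor: the intended c.1935C>A
#' edit with silent shield mutations at the PAM sites (c.1920C>T,
#' c.1932G>A) and seed regions (c.1923G>C, c.1929G>A) of the two guides.
#'
#' @param locus A [reference_locus()] from [make_reference()].
#' @return A guide tibble / a `donor_spec`.
#' @export
gaa1935_guides <- function(locus) {
  g <- locate_guides(locus$genome,
                     unname(GAA1935_GUIDES[c("gRNA2", "gRNA3")]),
                     contig = locus$target$contig)
  g$guide_id <- c("gRNA2", "gRNA3")
  g
}

#' @rdname gaa1935_guides
#' @export
gaa1935_donor <- function(locus) {
  donor_spec(locus, shields = tibble(
    label = c("c.1920C>T", "c.1923G>C", "c.1929G>A", "c.1932G>A"),
    tag = c("PAM", "seed", "seed", "PAM"),
    guide_id = c("gRNA2", "gRNA2", "gRNA3", "gRNA3")))
}

write_sam <- function(records, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  lens <- contig_lengths(genome)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  records <- records[order(records$rname, records$pos), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     records$qname, records$flag, records$rname, records$pos,
                     records$mapq, records$cigar, records$seq, records$qual),
             con)
  invisible(path)
}

#' Simulate a mosaic founder's on-target reads
#'
#' Draws reads from the configured haplotype mixture — the full donor
#' haplotype, an indel haplotype (deletion/insertion at the gRNA-2 cut
#' site), unedited reference, and a stray-substitution haplotype carrying
#' one random non-donor substitution in the window — applies independent
#' per-base errors, and writes perfectly aligned SAM records with a
#' ground-truth label per read. Error bases are written with low base
#' qualities (Phred 3–14) and true bases with Phred 37, so quality masking
#' at the default threshold removes exactly the injected errors; real
#' sequencers are noisier than this (see the package vignette).
#'
#' @param config A [sim_config()].
#' @param locus A [reference_locus()] from [make_reference()].
#' @param donor A `donor_spec` on that locus (default the published donor).
#' @param dir Output directory (created if needed).
#' @return A list with `sam` and `truth` paths and the `truth` tibble
#'   (`read_id`, `category`, `start`).
#' @export
simulate_founder_reads <- function(config, locus, donor = gaa1935_donor(locus),
                                   dir = tempfile("reads")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  window <- donor_window(donor)
  wlen <- window$end - window$start + 1L
  if (config$read_length < wlen) {
    abort(sprintf("read_length %d is shorter than the %d-nt donor window",
                  config$read_length, wlen))
  }
  guides <- gaa1935_guides(locus)
  cut <- guides$cut_site[guides$guide_id == "gRNA2"]
  edits <- donor_edits(donor)
  ref_chr <- as.character(locus$genome[[donor$contig]])
  rl <- config$read_length
  isz <- as.integer(config$indel_size)

  withr::with_seed(config$seed, {
    n <- config$n_reads %||% stats::rpois(1L, config$coverage)
    haps <- sample(names(config$proportions), n, replace = TRUE,
                   prob = config$proportions)
    v_pos <- integer(n); v_cigar <- character(n)
    v_seq <- character(n); v_qual <- character(n)
    for (i in seq_len(n)) {
      hap <- haps[i]
      del <- if (hap == "indel" && isz < 0L) -isz else 0L
      span <- rl + del
      s <- sample(seq(window$end - span + 1L, window$start), 1L)
      chunk <- substr(ref_chr, s, s + span - 1L)
      cigar <- sprintf("%dM", rl)
      if (hap == "intended_KI") {
        loc <- edits$pos - s + 1L
        chunk <- str_assign(chunk, loc, edits$alt)
      } else if (hap == "indel") {
        left <- cut - s + 1L
        if (isz < 0L) {
          chunk <- paste0(substr(chunk, 1L, left),
                          substr(chunk, left - isz + 1L, span))
          cigar <- sprintf("%dM%dD%dM", left, -isz, rl - left)
        } else {
          ins <- rand_dna(isz)
          chunk <- substr(paste0(substr(chunk, 1L, left), ins,
                                 substr(chunk, left + 1L, span)), 1L, rl)
          right <- rl - left - isz
          cigar <- if (right > 0L) sprintf("%dM%dI%dM", left, isz, right)
                   else sprintf("%dM%dI", left, isz)
        }
      } else if (hap == "nonspecific") {
        repeat {
          p <- sample(window$start:window$end, 1L)
          if (!p %in% edits$pos) break
        }
        b <- sample(setdiff(DNA_BASES, substr(ref_chr, p, p)), 1L)
        chunk <- str_assign(chunk, p - s + 1L, b)
      }
      qual <- rep(37L, rl)
      err <- which(stats::runif(rl) < config$error_rate)
      if (length(err) > 0L) {
        ch <- strsplit(chunk, "")[[1]]
        ch[err] <- vapply(ch[err],
                          function(b) sample(setdiff(DNA_BASES, b), 1L),
                          character(1))
        chunk <- paste(ch, collapse = "")
        qual[err] <- sample(3:14, length(err), replace = TRUE)
      }
      v_pos[i] <- s; v_cigar[i] <- cigar; v_seq[i] <- chunk
      v_qual[i] <- rawToChar(as.raw(qual + 33L))
    }
  })
  rec <- tibble(qname = sprintf("read%05d", seq_len(n)), flag = 0L,
                rname = donor$contig, pos = v_pos, mapq = 60L,
                cigar = v_cigar, seq = v_seq, qual = v_qual, category = haps)
  sam <- file.path(dir, "founder.sam")
  write_sam(rec, locus$genome, sam)
  truth <- tibble(read_id = rec$qname, category = rec$category,
                  start = rec$pos)
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth, truth_path)
  list(sam = sam, truth_path = truth_path, truth = truth)
}

write_vcf_snvs <- function(tbl, path, lens, sample = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##contig=<ID=%s,length=%d>", names(lens), lens), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"), con)
  tbl <- tbl[order(match(tbl$contig, names(lens)), tbl$pos), , drop = FALSE]
  if (nrow(tbl) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       tbl$contig, tbl$pos, tbl$ref, tbl$alt), con)
  }
  invisible(path)
}

#' Simulate a founder/control VCF pair with catalog, sites and signatures
#'
#' Writes four files emulating the off-target analysis inputs: founder
#' calls (shared background SNVs, founder-private SNVs, half of the
#' known-SNP catalog, a few variants on an un-located contig, and any
#' planted ectopic HDR signature clusters), wild-type control calls (the
#' shared background only), the known-SNP catalog, and a BED of predicted
#' off-target sites placed well away from every simulated variant so the
#' window check reproduces a clean negative result.
#'
#' @param config A [sim_config()]; `n_planted`/`planted_strand` control the
#'   signature clusters, which always carry all four companions.
#' @param locus A [reference_locus()] from [make_reference()].
#' @param pattern A [signature_pattern()]; default derived from the
#'   published donor.
#' @param dir Output directory.
#' @return A list with paths (`founder`, `control`, `known`, `sites`), the
#'   contig `allowlist`, and a `truth` list of tibbles (`background`,
#'   `private`, `known`, `planted`, `sites`).
#' @export
simulate_vcf_pair <- function(config, locus,
                              pattern = derive_signature_pattern(gaa1935_donor(locus)),
                              dir = tempfile("vcfs")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctg <- config$contig
  L <- config$contig_length
  ref_chr <- as.character(locus$genome[[ctg]])
  avoid_lo <- config$locus_offset - 200L
  avoid_hi <- config$locus_offset + 300L
  max_off <- max(pattern$companions$offset)

  withr::with_seed(config$seed + 1L, {
    pool <- setdiff(500:(L - 500L), avoid_lo:avoid_hi)
    n_pt <- config$n_background + config$n_private + config$n_known
    pos <- sample(pool, n_pt)
    mk <- function(p) {
      p <- as.integer(p)
      if (length(p) == 0L) {
        return(tibble(contig = character(), pos = integer(),
                      ref = character(), alt = character()))
      }
      ref <- substring(ref_chr, p, p)
      alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                    character(1), USE.NAMES = FALSE)
      tibble(contig = ctg, pos = as.integer(p), ref = ref, alt = alt)
    }
    background <- mk(pos[seq_len(config$n_background)])
    private <- mk(pos[config$n_background + seq_len(config$n_private)])
    known <- mk(pos[config$n_background + config$n_private +
                      seq_len(config$n_known)])
    used <- sort(pos)

    planted <- list()
    if (config$n_planted > 0L) {
      want_ref <- if (config$planted_strand == "+") pattern$central$ref
                  else comp(pattern$central$ref)
      dirn <- if (config$planted_strand == "+") -1L else +1L
      cand <- sample(pool)
      taken <- integer()
      for (p in cand) {
        if (length(planted) == config$n_planted) break
        if (substring(ref_chr, p, p) != want_ref) next
        cpos <- p + dirn * pattern$companions$offset
        cref <- substring(ref_chr, cpos, cpos)
        calt <- if (config$planted_strand == "+") pattern$companions$alt
                else comp(pattern$companions$alt)
        # No companion may itself read as a central substitution on either
        # strand, or the cluster would count twice; keeps plant -> recover
        # an exact round trip.
        mirror <- (cref == pattern$central$ref & calt == pattern$central$alt) |
          (cref == comp(pattern$central$ref) & calt == comp(pattern$central$alt))
        zone <- (p - max_off - 20L):(p + max_off + 20L)
        if (any(cref == calt) || any(mirror) || any(zone %in% used) ||
            any(zone %in% taken) || any(cpos %in% avoid_lo:avoid_hi)) next
        central_alt <- if (config$planted_strand == "+") pattern$central$alt
                       else comp(pattern$central$alt)
        planted[[length(planted) + 1L]] <- tibble(
          contig = ctg, pos = c(p, as.integer(cpos)),
          ref = c(want_ref, cref), alt = c(central_alt, calt),
          role = c("central", rep("companion", length(cpos))),
          cluster = length(planted) + 1L)
        taken <- c(taken, zone)
      }
      if (length(planted) < config$n_planted) {
        abort("could not place all planted signatures away from the locus core")
      }
    }
    planted <- bind_rows(planted)
    if (nrow(planted) == 0L) {
      planted <- tibble(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        role = character(), cluster = integer())
    }

    # Only variants that survive subtraction (founder-private and planted)
    # constrain site placement; shared background and known SNPs are removed
    # upstream of the window check.
    hot <- c(private$pos, planted$pos)
    site_pool <- setdiff(pool, unlist(lapply(hot, function(p)
      (p - 600L):(p + 600L))))
    site_start <- sort(sample(site_pool, config$n_sites))
    sites <- tibble(contig = ctg, start = site_start - 1L,
                    end = site_start - 1L + config$site_width,
                    name = sprintf("offtarget_%d", seq_len(config$n_sites)))

    unplaced <- tibble()
    if (config$n_unplaced > 0L) {
      up <- sample(100:1900, config$n_unplaced)
      uref <- substring(as.character(locus$genome[["chrUn_synthetic"]]), up, up)
      unplaced <- tibble(contig = "chrUn_synthetic", pos = as.integer(up),
                         ref = uref,
                         alt = vapply(uref, function(b)
                           sample(setdiff(DNA_BASES, b), 1L),
                           character(1), USE.NAMES = FALSE))
    }
    known_in_founder <- known[seq_len(config$n_known %/% 2L), , drop = FALSE]
  })

  lens <- contig_lengths(locus$genome)
  founder_tbl <- bind_rows(background, private, known_in_founder,
                           planted[, c("contig", "pos", "ref", "alt")],
                           unplaced)
  paths <- list(
    founder = write_vcf_snvs(founder_tbl, file.path(dir, "founder.vcf"), lens),
    control = write_vcf_snvs(background, file.path(dir, "control.vcf"), lens),
    known = write_vcf_snvs(known, file.path(dir, "known_snps.vcf"), lens),
    sites = file.path(dir, "predicted_sites.bed")
  )
  writeLines(sprintf("%s\t%d\t%d\t%s", sites$contig, sites$start, sites$end,
                     sites$name), paths$sites)
  c(paths, list(allowlist = ctg,
                truth = list(background = background, private = private,
                             known = known, planted = planted,
                             sites = sites)))
}
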