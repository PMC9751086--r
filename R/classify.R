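# On-target read classification: decompose aligned reads over the donor
# window into substitutions and indels, then assign each read to one of the
# four mosaic-founder outcome categories:
#   intended_KI  - the designed edit plus all covered shield edits, nothing else
#   indel        - any insertion/deletion touching the window
#   no_mutation  - reference across the window
#   nonspecific  - any other substitution pattern
# Precedence is indel > intended_KI > nonspecific > no_mutation: a read that
# physically carries an indel is not a faithful HDR product even if it also
# carries the intended base.

OUTCOME_CATEGORIES <- c("intended_KI", "indel", "no_mutation", "nonspecific")

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(lens = lens, ops = ops)
}

# Decompose one alignment against the reference contig string. `pos` is the
# 1-based leftmost reference position. Indels are recorded at the last
# reference base before the event (`len` > 0 insertion, < 0 deletion).
# Events come back as plain named lists of parallel vectors: this runs once
# per read over >10^4 reads, so no per-read tibble allocation.
decompose_alignment <- function(pos, cigar, seq, qual, ref_chr) {
  cg <- parse_cigar(cigar)
  rp <- pos; qp <- 1L
  subs_pos <- integer(); subs_ref <- character(); subs_alt <- character()
  subs_q <- integer()
  ind_pos <- integer(); ind_len <- integer(); ind_seq <- character()
  clip_lead <- if (length(cg$ops) && cg$ops[1] == "S") cg$lens[1] else 0L
  for (k in seq_along(cg$ops)) {
    len <- cg$lens[k]
    switch(cg$ops[k],
      "M" = , "=" = , "X" = {
        r <- substr(ref_chr, rp, rp + len - 1L)
        q <- substr(seq, qp, qp + len - 1L)
        if (r != q) {
          rr <- charToRaw(r); qq <- charToRaw(q)
          mm <- which(rr != qq)
          subs_pos <- c(subs_pos, rp + mm - 1L)
          subs_ref <- c(subs_ref, rawToChar(rr[mm], multiple = TRUE))
          subs_alt <- c(subs_alt, rawToChar(qq[mm], multiple = TRUE))
          subs_q <- c(subs_q,
                      as.integer(charToRaw(substr(qual, qp, qp + len - 1L))[mm]) - 33L)
        }
        rp <- rp + len; qp <- qp + len
      },
      "I" = {
        ind_pos <- c(ind_pos, rp - 1L)
        ind_len <- c(ind_len, len)
        ind_seq <- c(ind_seq, substr(seq, qp, qp + len - 1L))
        qp <- qp + len
      },
      "D" = , "N" = {
        ind_pos <- c(ind_pos, rp - 1L)
        ind_len <- c(ind_len, -len)
        ind_seq <- c(ind_seq, substr(ref_chr, rp, rp + len - 1L))
        rp <- rp + len
      },
      "S" = { qp <- qp + len },
      "H" = , "P" = NULL
    )
  }
  list(subs = list(pos = subs_pos, ref = subs_ref, alt = subs_alt,
                   qual = subs_q),
       indels = list(pos = ind_pos, len = ind_len, seq = ind_seq),
       ref_end = rp - 1L, clip_lead = clip_lead)
}

#' Load and decompose aligned reads over a window
#'
#' Reads a SAM or BAM file, keeps primary, mapped, non-duplicate alignments
#' with mapping quality at least `min_mapq` that fully span `window`, and
#' decomposes each against the reference into substitution and indel events.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly with
#'   [Rsamtools::asBam()].
#' @param genome A named `DNAStringSet`.
#' @param window Length-2 integer vector `c(start, end)` (1-based inclusive)
#'   or a one-row tibble/list with `start`/`end`; the on-target interval
#'   reads must span.
#' @param contig Contig of the window; defaults to the first genome contig.
#' @param min_mapq Minimum mapping quality (default 20).
#' @return A tibble with one row per retained read: `read_id`, `pos`, `end`,
#'   `mapq`, list-columns `subs` (`pos`/`ref`/`alt`/`qual` vectors) and
#'   `indels` (`pos`/`len`/`seq`), `clip_lead`, plus the raw `seq`/`qual`
#'   strings. The attribute `"excluded"` tabulates dropped reads by reason.
#' @export
read_observations <- function(path, genome, window,
                              contig = names(genome)[1], min_mapq = 20) {
  window <- as_window(window)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(Rsamtools::asBam(path, dest,
                                              overwrite = TRUE,
                                              indexDestination = FALSE))
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  rec <- Rsamtools::scanBam(path,
                            param = Rsamtools::ScanBamParam(what = what))[[1]]
  n <- length(rec$qname)
  if (n == 0L) {
    return(structure(tibble(read_id = character(), pos = integer(),
                            end = integer(), mapq = integer(),
                            subs = list(), indels = list(),
                            clip_lead = integer(), seq = character(),
                            qual = character()),
                     excluded = tibble(reason = character(), n = integer())))
  }
  flag <- rec$flag
  seq <- as.character(rec$seq)
  qual <- as.character(rec$qual)
  keep_flag <- bitwAnd(flag, 0x4) == 0L & bitwAnd(flag, 0x100) == 0L &
    bitwAnd(flag, 0x800) == 0L & bitwAnd(flag, 0x400) == 0L
  keep_ctg <- as.character(rec$rname) == contig
  keep_mapq <- !is.na(rec$mapq) & rec$mapq >= min_mapq
  ref_chr <- as.character(genome[[contig]])

  pre <- which(keep_flag & keep_ctg & keep_mapq)
  np <- length(pre)
  spans <- logical(np)
  subs <- vector("list", np); indels <- vector("list", np)
  ends <- integer(np); clips <- integer(np)
  for (i in seq_len(np)) {
    j <- pre[i]
    d <- decompose_alignment(rec$pos[j], rec$cigar[j], seq[j], qual[j], ref_chr)
    spans[i] <- rec$pos[j] <= window$start && d$ref_end >= window$end
    if (!spans[i]) next
    subs[[i]] <- d$subs; indels[[i]] <- d$indels
    ends[i] <- d$ref_end; clips[i] <- d$clip_lead
  }
  k <- which(spans)
  out <- tibble(read_id = rec$qname[pre[k]], pos = rec$pos[pre[k]],
                end = ends[k], mapq = as.integer(rec$mapq[pre[k]]),
                subs = subs[k], indels = indels[k], clip_lead = clips[k],
                seq = seq[pre[k]], qual = qual[pre[k]])
  excluded <- tibble(
    reason = c("flag (secondary/supplementary/duplicate/unmapped)",
               "other contig", "mapping quality", "not spanning window"),
    n = c(sum(!keep_flag), sum(keep_flag & !keep_ctg),
          sum(keep_flag & keep_ctg & !keep_mapq), sum(!spans)))
  attr(out, "excluded") <- excluded
  out
}

as_window <- function(window) {
  if (is.numeric(window) && length(window) == 2L) {
    return(list(start = as.integer(window[1]), end = as.integer(window[2])))
  }
  list(start = as.integer(window$start), end = as.integer(window$end))
}

donor_window <- function(donor) {
  list(start = donor$span_start, end = donor$span_end)
}

# Phred base qualities of one read at reference positions (valid only for
# reads without indels before those positions; callers restrict accordingly).
quals_at <- function(qual, read_pos, clip_lead, ref_pos) {
  idx <- ref_pos - read_pos + 1L + clip_lead
  as.integer(charToRaw(qual))[idx] - 33L
}

#' Classify decomposed reads into the four outcome categories
#'
#' @param obs Tibble from [read_observations()]; every row must span the
#'   window (rows that do not raise an error — filter upstream).
#' @param donor A `donor_spec`.
#' @param window Window as in [read_observations()]; defaults to the donor
#'   footprint.
#' @param require_shields When `TRUE` (default), a read only counts as
#'   `intended_KI` if every shield position it covers (and has not been
#'   quality-masked at) carries the shield's alternate base; a lone intended
#'   edit without its shields is `nonspecific`. Set to `FALSE` to count any
#'   read whose substitutions are a subset of the donor's edits including
#'   the intended one.
#' @param min_base_quality Optional Phred threshold: substitutions below it
#'   are ignored and donor-edit positions below it are treated as uncovered.
#'   Default `NULL` (no masking).
#' @return `obs` with a `category` factor column added.
#' @export
classify_reads <- function(obs, donor, window = NULL, require_shields = TRUE,
                           min_base_quality = NULL) {
  window <- as_window(window %||% donor_window(donor))
  if (nrow(obs) > 0 && any(obs$pos > window$start | obs$end < window$end)) {
    abort("all observations must fully span the window; filter upstream")
  }
  ip <- donor$intended$pos
  ialt <- donor$intended$alt
  sh <- donor$shields
  donor_pos <- c(ip, sh$pos)
  donor_key <- paste(donor_pos, c(ialt, sh$alt))
  intended_key <- paste(ip, ialt)
  shield_key <- paste(sh$pos, sh$alt)

  n <- nrow(obs)
  subs_l <- obs$subs; ind_l <- obs$indels
  read_pos <- obs$pos; clip <- obs$clip_lead; qual_s <- obs$qual
  categories <- character(n)
  for (i in seq_len(n)) {
    ind <- ind_l[[i]]
    ind_in <- length(ind$pos) > 0 && any(
      (ind$len > 0 & ind$pos >= window$start - 1L & ind$pos <= window$end) |
      (ind$len < 0 & ind$pos + 1L <= window$end &
         ind$pos - ind$len >= window$start))
    if (ind_in) { categories[i] <- "indel"; next }
    s <- subs_l[[i]]
    keep <- s$pos >= window$start & s$pos <= window$end
    masked <- integer()
    if (!is.null(min_base_quality)) {
      keep <- keep & s$qual >= min_base_quality
      mq <- quals_at(qual_s[i], read_pos[i], clip[i], donor_pos)
      masked <- donor_pos[mq < min_base_quality]
    }
    sub_key <- paste(s$pos[keep], s$alt[keep])
    intended_ok <- !(ip %in% masked) && intended_key %in% sub_key
    shields_ok <- all(shield_key[!(sh$pos %in% masked)] %in% sub_key)
    only_donor <- all(sub_key %in% donor_key)
    ki <- intended_ok && only_donor && (!require_shields || shields_ok)
    categories[i] <- if (ki) "intended_KI"
      else if (length(sub_key) == 0L) "no_mutation"
      else "nonspecific"
  }
  obs$category <- factor(categories, levels = OUTCOME_CATEGORIES)
  obs
}

#' Classify a single read observation
#'
#' Scalar convenience over [classify_reads()].
#'
#' @inheritParams classify_reads
#' @param obs A one-row tibble from [read_observations()].
#' @return The category as a length-1 character string.
#' @export
classify_read <- function(obs, donor, window = NULL, require_shields = TRUE,
                          min_base_quality = NULL) {
  stopifnot(nrow(obs) == 1L)
  as.character(classify_reads(obs, donor, window, require_shields,
                              min_base_quality)$category)
}

#' Tally editing outcomes over all reads spanning the on-target window
#'
#' Runs [read_observations()] and [classify_reads()] and tallies the four
#' categories, mirroring a stacked-bar mosaicism summary of a founder's
#' whole-genome reads.
#'
#' @param reads Path to a SAM/BAM file, or a tibble already produced by
#'   [read_observations()].
#' @param donor A `donor_spec`.
#' @param locus A [reference_locus()] (used for the reference sequence when
#'   `reads` is a path).
#' @param window Window, default the donor footprint.
#' @param min_mapq Minimum mapping quality (default 20).
#' @inheritParams classify_reads
#' @return An `outcome_tally`: counts and fractions per category plus the
#'   excluded-read accounting. With zero spanning reads the tally has
#'   `total = 0` and `NA` fractions.
#' @export
summarize_locus <- function(reads, donor, locus = NULL, window = NULL,
                            min_mapq = 20, require_shields = TRUE,
                            min_base_quality = NULL) {
  window <- as_window(window %||% donor_window(donor))
  if (is.character(reads)) {
    if (is.null(locus)) abort("a reference_locus is needed to read alignments")
    reads <- read_observations(reads, locus$genome, window,
                               contig = donor$contig, min_mapq = min_mapq)
  }
  excluded <- attr(reads, "excluded") %||%
    tibble(reason = character(), n = integer())
  cls <- classify_reads(reads, donor, window, require_shields,
                        min_base_quality)
  counts <- table(cls$category)
  total <- sum(counts)
  tally <- tibble(category = OUTCOME_CATEGORIES,
                  n = as.integer(counts[OUTCOME_CATEGORIES]),
                  fraction = if (total > 0)
                    as.integer(counts[OUTCOME_CATEGORIES]) / total
                  else NA_real_)
  structure(list(counts = tally, total = total,
                 window = window, excluded = excluded),
            class = "outcome_tally")
}

#' @export
print.outcome_tally <- function(x, ...) {
  cat(sprintf("<outcome_tally> %d spanning read(s) over %d-%d\n",
              x$total, x$window$start, x$window$end))
  if (x$total == 0L) {
    cat("  no spanning reads: fractions undefined\n")
  }
  print(x$counts)
  invisible(x)
}

#' @export
tidy.outcome_tally <- function(x, ...) x$counts

#' @export
glance.outcome_tally <- function(x, ...) {
  tibble(total = x$total,
         excluded = sum(attr(x, "excluded")$n %||% x$excluded$n),
         dominant = if (x$total > 0)
           x$counts$category[which.max(x$counts$n)] else NA_character_)
}

#' Stacked-bar plot of an outcome tally
#'
#' @param object An `outcome_tally`.
#' @param label Bar label (e.g. the founder's name).
#' @param ... Ignored.
#' @return A ggplot: one stacked bar of read fractions over the four
#'   categories.
#' @export
autoplot.outcome_tally <- function(object, label = "founder", ...) {
  d <- mutate(object$counts, who = label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$who, y = .data$fraction,
                                  fill = .data$category)) +
    ggplot2::geom_col(position = "stack", width = 0.6) +
    ggplot2::scale_fill_manual(values = c(
      intended_KI = "#c0392b", indel = "#2b6cb0",
      no_mutation = "#1a1a1a", nonspecific = "#9e9e9e")) +
    ggplot2::labs(x = NULL, y = "fraction of spanning reads",
                  fill = "outcome") +
    ggplot2::theme_minimal()
}

#' Cohort-level founder percentages
#'
#' Summarizes per-founder genotype flags into the percentage of founders
#' positive for any on-target mutation and for the intended knock-in,
#' rounding half-up to one decimal (so 35 of 39 prints as 89.7 and 15 of 39
#' as 38.5).
#'
#' @param founders Tibble with one row per founder and logical columns
#'   `any_mutation` and `intended_ki`.
#' @return A tibble with columns `metric`, `n_positive`, `n_total`,
#'   `percent`.
#' @export
cohort_summary <- function(founders) {
  founders <- as_tibble(founders)
  if (nrow(founders) == 0L) abort("empty founder cohort")
  if (!all(c("any_mutation", "intended_ki") %in% names(founders))) {
    abort("founders need logical columns 'any_mutation' and 'intended_ki'")
  }
  n <- nrow(founders)
  tibble(metric = c("any_mutation", "intended_ki"),
         n_positive = c(sum(founders$any_mutation), sum(founders$intended_ki)),
         n_total = n) |>
    mutate(percent = round_half_up(100 * .data$n_positive / .data$n_total, 1))
}

#' Read / write outcome tallies as TSV
#'
#' @param tally An `outcome_tally`.
#' @param path File path.
#' @return `write_tally()` returns `path` invisibly; `read_tally()` returns
#'   the counts tibble.
#' @export
write_tally <- function(tally, path) {
  readr::write_tsv(tally$counts, path)
  invisible(path)
}

#' @rdname write_tally
#' @export
read_tally <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
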