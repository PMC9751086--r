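# End-to-end orchestration: named stages over a single configuration list,
# with a JSON run manifest recording config hashes, seeds and artifacts so
# multi-step filtering is auditable. The stage order mirrors the project
# flow: design -> donor validation -> founder on-target analysis ->
# off-target analysis.

PIPELINE_STAGES <- c("simulate", "design", "validate-donor", "classify",
                     "scan", "check-sites", "report")

#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param seed Integer seed forwarded to the simulator.
#' @param ... Further settings: file paths (`reference`, `coding_map`,
#'   `guides`, `donor_prefix`, `alignments`, `founder_vcf`, `control_vcf`,
#'   `known_vcf`, `sites_bed`), thresholds (`min_mapq`, `window_nt`,
#'   `arm_length`, `require_shields`, `min_base_quality`), the `target`
#'   edit in c. notation, and a `sim` list of [sim_config()] overrides.
#' @param path Path to a JSON file holding the same fields.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, ...) {
  cfg <- c(list(out_dir = out_dir, seed = as.integer(seed)), list(...))
  defaults <- list(min_mapq = 20, window_nt = 500L, arm_length = 50L,
                   require_shields = TRUE, min_base_quality = NULL,
                   target = "c.1935C>A", sim = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$out_dir)) abort("pipeline config must name out_dir")
  do.call(pipeline_config, cfg)
}

need <- function(cfg, field) {
  v <- cfg[[field]]
  if (is.null(v)) abort(sprintf("missing-config field=%s", field))
  if (is.character(v) && !is.null(attr(v, "is_path", TRUE))) return(v)
  v
}

need_file <- function(cfg, field) {
  p <- need(cfg, field)
  if (!file.exists(p)) abort(sprintf("missing-input field=%s path=%s", field, p))
  p
}

append_manifest <- function(cfg, stage, outputs) {
  mf <- file.path(cfg$out_dir, "manifest.json")
  old <- if (file.exists(mf)) jsonlite::read_json(mf) else list()
  strip <- cfg; strip$out_dir <- NULL
  old[[length(old) + 1L]] <- list(
    stage = stage, seed = cfg$seed,
    config_hash = rlang::hash(strip),
    package_version = as.character(utils::packageVersion("crisprki")),
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(old, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

load_locus <- function(cfg) {
  genome <- read_genome(need_file(cfg, "reference"))
  cmap <- read_coding_map(need_file(cfg, "coding_map"))
  reference_locus(genome, cmap, need(cfg, "target"))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate every downstream input), `design`
#' (automatic shield choice and donor assembly), `validate-donor`,
#' `classify` (on-target read tally), `scan` (background subtraction plus
#' ectopic HDR signature scan), `check-sites` (predicted off-target window
#' check) and `report` (stacked-fraction table from a tally). Artifacts are
#' written atomically into `out_dir` (temp file then rename) and recorded
#' in `out_dir/manifest.json`. Re-running a stage with identical inputs and
#' config reproduces its outputs byte for byte; only the manifest carries
#' timestamps.
#'
#' @param stage One of the stage names above.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (0 on success) and `outputs`
#'   (named paths). Missing inputs abort with a one-line
#'   `field=... path=...` reason.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$out_dir, "")
  art <- switch(stage,
    "simulate" = {
      sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
      locus <- make_reference(sc, dir = config$out_dir)
      guides <- gaa1935_guides(locus)
      write_guides(guides, file.path(config$out_dir, "guides.tsv"))
      donor <- gaa1935_donor(locus)
      write_donor(donor, file.path(config$out_dir, "donor"))
      rd <- simulate_founder_reads(sc, locus, donor, dir = config$out_dir)
      vc <- simulate_vcf_pair(sc, locus, dir = config$out_dir)
      c(reference = file.path(config$out_dir, "ref.fa"),
        coding_map = file.path(config$out_dir, "coding_map.tsv"),
        guides = file.path(config$out_dir, "guides.tsv"),
        donor = file.path(config$out_dir, "donor.fa"),
        alignments = rd$sam, truth = rd$truth_path,
        founder_vcf = vc$founder, control_vcf = vc$control,
        known_vcf = vc$known, sites_bed = vc$sites)
    },
    "design" = {
      locus <- load_locus(config)
      guides <- if (!is.null(config$guides)) read_guides(need_file(config, "guides"))
                else gaa1935_guides(locus)
      donor <- build_ssodn(locus, guides, arm_length = config$arm_length)
      paths <- write_donor(donor, file.path(config$out_dir, "donor"))
      c(donor = paths[1], donor_edits = paths[2])
    },
    "validate-donor" = {
      locus <- load_locus(config)
      prefix <- need(config, "donor_prefix")
      if (!file.exists(paste0(prefix, ".fa"))) {
        abort(sprintf("missing-input field=donor_prefix path=%s.fa", prefix))
      }
      donor <- read_donor(prefix, locus)
      guides <- if (!is.null(config$guides)) read_guides(need_file(config, "guides"))
                else NULL
      rep <- validate_donor(donor, locus, guides)
      p <- file.path(config$out_dir, "donor_validation.tsv")
      readr::write_tsv(tidy(rep), p)
      if (!rep$pass) warn("donor validation FAILED; see donor_validation.tsv")
      c(validation = p)
    },
    "classify" = {
      locus <- load_locus(config)
      donor <- read_donor(need(config, "donor_prefix"), locus)
      tally <- summarize_locus(need_file(config, "alignments"), donor, locus,
                               min_mapq = config$min_mapq,
                               require_shields = config$require_shields,
                               min_base_quality = config$min_base_quality)
      p <- file.path(config$out_dir, "tally.tsv")
      write_tally(tally, p)
      c(tally = p)
    },
    "scan" = {
      locus <- load_locus(config)
      donor <- read_donor(need(config, "donor_prefix"), locus)
      pattern <- derive_signature_pattern(donor)
      dn <- subtract_background(need_file(config, "founder_vcf"),
                                need_file(config, "control_vcf"),
                                known = if (!is.null(config$known_vcf))
                                  need_file(config, "known_vcf") else NULL,
                                contig_allowlist = config$contig_allowlist)
      hits <- scan_signatures(dn, pattern)
      p1 <- file.path(config$out_dir, "signature_hits.tsv")
      write_hits(hits, p1)
      p2 <- file.path(config$out_dir, "subtraction_counts.tsv")
      readr::write_tsv(glance(dn), p2)
      inform(sprintf("scan: %d input, %d de novo, %d signature hit(s)",
                     glance(dn)$input, glance(dn)$retained, nrow(hits)))
      c(hits = p1, accounting = p2)
    },
    "check-sites" = {
      dn <- subtract_background(need_file(config, "founder_vcf"),
                                need_file(config, "control_vcf"),
                                known = if (!is.null(config$known_vcf))
                                  need_file(config, "known_vcf") else NULL,
                                contig_allowlist = config$contig_allowlist)
      chk <- predicted_site_check(need_file(config, "sites_bed"), dn,
                                  window_nt = config$window_nt)
      p <- file.path(config$out_dir, "site_check.tsv")
      readr::write_tsv(select(chk, -"snvs"), p)
      c(site_check = p)
    },
    "report" = {
      tly <- read_tally(need_file(config, "tally"))
      rep <- mutate(tly, percent = round_half_up(100 * .data$fraction, 1))
      p <- file.path(config$out_dir, "report.tsv")
      readr::write_tsv(rep, p)
      c(report = p)
    })
  append_manifest(config, stage, art)
  invisible(list(status = 0L, outputs = art))
}

#' Read a pipeline run manifest
#'
#' @param out_dir The pipeline output directory.
#' @return A tibble with one row per completed stage.
#' @export
read_manifest <- function(out_dir) {
  mf <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  bind_rows(lapply(mf, function(r) {
    tibble(stage = r$stage, seed = r$seed, config_hash = r$config_hash,
           time = r$time, n_outputs = length(r$outputs))
  }))
}
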