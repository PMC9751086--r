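---
title: "Donor design, founder mosaicism and ectopic HDR scanning with crisprki"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor design, founder mosaicism and ectopic HDR scanning with crisprki}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprki)
```

# The problem

Installing a single pathogenic point mutation in the mouse germline with
CRISPR-Cas9 and a single-stranded oligo donor (ssODN) raises three analysis
tasks this package covers end to end: designing the donor so the repaired
allele resists re-cutting; quantifying mosaicism in founder animals from
aligned reads over the target window; and searching founder genomes for
evidence that the donor integrated somewhere it should not have. The worked
locus is *Gaa* c.1935C>A (p.Asp645Glu), edited with two overlapping guides —
one sense, one antisense — whose cut sites sit 8 and 11 nt from the target
base.

# Coordinate model

All positional bookkeeping runs through a `coding_map`, which places ordered
CDS segments (0-based half-open, the BED convention) on the genome together
with the first coding (`c.`) position each covers. User-facing variant
positions are 1-based, matching VCF and HGVS. `c_to_genomic()` and
`genomic_to_c()` are exact inverses over the mapped span on either gene
strand; `codon_of()` reads the codon containing a coding position on the
gene strand. Only the `c.<pos><ref>><alt>` substitution subset of HGVS is
parsed — transcript databases and intronic notation are out of scope.

# Donor design

A donor specification is: homology arms of `arm_length` nt (default 50, the
conventional choice for ssODN knock-ins) flanking the edited core; the
intended edit; and shield edits, each tagged `PAM` or `seed` and attributed
to a guide. The invariants `validate_donor()` enforces:

* arms match the reference exactly outside edited positions, and are exactly
  `arm_length` nt;
* every shield is synonymous (the translated CDS is unchanged);
* the protein changes at exactly the intended residue;
* each targeted guide is disrupted: its NGG PAM no longer matches NGG, or at
  least one shield falls in its seed (the 5 PAM-proximal protospacer
  nucleotides — the standard SpCas9 seed definition). Either disruption mode
  suffices.

`build_ssodn()` chooses shields automatically. Where several synonymous
options exist the policy is deterministic so builds are reproducible:
PAM-breaking edits are preferred to seed edits (a destroyed PAM blocks
recognition outright), then the left-most genomic position, then the
alphabetically first gene-strand base. The published donor for this locus
installs two shields per guide (PAM *and* seed); the automatic policy stops
at one per guide, which already satisfies every invariant — both donors
validate.

## The signature pattern

`derive_signature_pattern()` turns a donor into the search pattern for
ectopic integration: the central `ref>alt` substitution plus one companion
rule per shield, expressed as (offset upstream along the gene strand,
required alternate base). For the worked donor the offsets are the
c.-label spacings 1935 − {1932, 1929, 1923, 1920} = {3, 6, 12, 15} with
required alternates {A, A, C, T}. Shields downstream of the intended edit
(possible in principle, absent from the published design) are excluded from
the pattern with a warning and reported separately: the stated matching
criteria are upstream-only, and we chose not to invent a downstream rule
the source analysis never exercised.

# Founder read classification

Reads fully spanning the window (default: the donor footprint) are
decomposed against the reference into substitutions and indels, then
assigned one of four categories with precedence
**indel > intended_KI > nonspecific > no_mutation**:

* `indel` — any insertion or deletion touching the window. Precedence is
  deliberate: a read physically carrying an indel is not a faithful HDR
  product even if it also carries the intended base.
* `intended_KI` — the intended edit present, every shield position the read
  covers (and is not quality-masked at) carrying the shield allele, and no
  other substitution in the window.
* `no_mutation` — reference across the window.
* `nonspecific` — any other substitution pattern.

A read carrying the intended edit but missing its shields is `nonspecific`
by default: such a read is not a copy of the donor. This is configurable
(`require_shields = FALSE`) because the distinction is not observable in
Sanger-style summaries. Fractions are read-level, not consensus-allele
level. The full-span requirement avoids censoring bias in the category
fractions; partial reads are excluded and accounted for rather than
classified.

Filters: primary, mapped, non-duplicate alignments with mapping quality ≥ 20
by default (coverage-grade WGS needs no more); optional base-quality masking
(`min_base_quality`, default off) ignores substitutions below the threshold
and treats donor-edit positions below it as uncovered.

Cohort summaries round percentages half-up to one decimal, the convention
under which 35/39 prints as 89.7 and 15/39 as 38.5.

# Off-target analyses

`subtract_background()` reduces founder calls to a de novo SNV set by exact
(contig, pos, ref, alt) tuple matching against the wild-type control and a
known-SNP catalog — no fuzzy position matching — after dropping variants on
contigs outside the allowlist (un-located scaffolds). Provenance counters
(input, removed per filter, retained) always sum to the input count, and a
record matching a control/known record in position and alternate but not
reference is retained with a warning. Genotype and FILTER fields are ignored
by default (site-level analysis); `pass_only = TRUE` restricts to PASS.

`predicted_site_check()` counts retained de novo SNVs within `window_nt`
(default 500) of each predicted off-target interval; distance is 0 inside
the interval and the boundary is inclusive — an SNV exactly 500 nt out
counts, 501 does not.

`scan_signatures()` reports a hit for any de novo SNV matching the central
substitution that has **at least one** de novo companion at a pattern offset
with the required alternate ("any one criterion" suffices; all matching
companions are recorded). "Upstream" is read in the direction of the central
substitution's strand: the plus-strand pass subtracts offsets in genome
coordinates; the reverse-complement pass matches the complemented central
(G>T for C>A) with complemented companion alternates at the same offsets
*downstream*. This is the only reading under which repeating the search on
the reverse complement can add matches. Extra de novo variants near a hit
at non-pattern offsets neither strengthen nor void it — they are simply not
part of the criteria.

# The simulator: what the stated world is

`sim_config()` fixes the generative model all tests and examples share:

| parameter | default | why |
|---|---|---|
| mixture over {KI, indel, none, stray} | 0.55 / 0.25 / 0.15 / 0.05 | a strongly edited mosaic founder: majority faithful HDR, minority indel, like the best founders this workflow is built to find |
| read length / depth | 150 nt, 500 reads (or Poisson around `coverage`) | short-read WGS at >50× over the window |
| per-base error | 0.001 | typical short-read substitution error |
| indel haplotype | 2-nt deletion at the antisense guide's cut site | a representative NHEJ outcome; configurable |
| background SNVs / founder-private SNVs | 40 / 5 | a clean inbred background where subtraction leaves a handful of true de novo variants |
| predicted sites | 7 intervals, 23 nt | one per predicted off-target region of the guide pair |

The reference generator embeds the 32-nt locus core — reconstructed by
overlap-assembling the published protospacers — into a 20-codon coding
segment padded with random, stop-free codons, inside an otherwise random
contig. The padding is arbitrary by construction; nothing downstream depends
on it. Everything is bit-reproducible given (seed, config), and every
generator emits a truth table sufficient to compute exact expected outputs
downstream.

Deliberate simplifications, and what a green test therefore does *not*
establish:

* **Reads are emitted pre-aligned.** Alignment is upstream of this package;
  classification, not mapping, is under test. Mapping artifacts (soft-clips
  at indels, mismapped paralogs) are not emulated.
* **Base qualities are perfectly informative**: injected errors carry Phred
  3–14, true bases Phred 37. With `min_base_quality = 20` the classifier
  recovers the realized mixture essentially exactly; without masking,
  roughly 12% of reads (1 − 0.999^132 over the 132-nt window) acquire an
  error substitution and drain into `nonspecific`. Real sequencers miscall
  at high quality too, so on real data masking reduces, but does not
  eliminate, that leakage.
* **Stray substitutions avoid donor-edit positions**, so truth labels are
  unambiguous.
* **Planted signature clusters** always carry all four companions, never
  collide with the locus core, and are placed so that no companion itself
  reads as a central substitution on either strand — otherwise a single
  cluster legitimately matches twice (the scanner's strand symmetry is a
  feature, not a bug, but it would make plant-and-recover counts ambiguous).
* Predicted sites are placed > 600 nt from any variant that survives
  subtraction, so the clean negative window check is guaranteed by
  construction, mirroring the negative result the analysis is designed to
  demonstrate.

# Numerical and policy choices

* Internal intervals 0-based half-open; VCF/HGVS surfaces 1-based.
* Standard nuclear codon table only; ambiguity codes are rejected.
* The cut site is the canonical blunt position 3 bp 5′ of the PAM; no
  staggered-cut model.
* NGG PAMs only; NAG-tolerated sites are not enumerated.
* Guide efficacy and off-target *scoring* are not re-implemented; predicted
  off-target regions are accepted as BED input, and external scores can be
  joined onto the guide table.
* Rounding: half-up at one decimal for printed percentages.
* Degenerate inputs: a region shorter than 23 nt yields an empty guide table
  with a message (not an error); zero spanning reads yield a tally with
  total 0 and `NA` fractions, reported explicitly; an empty de novo set
  scans to zero hits.
* Tie-breaks in shield choice are documented above and deterministic.

# Known limitations

No haplotype phasing across read pairs; no structural-variant evidence
(ectopic integration that produces a rearrangement rather than an SNV
cluster is invisible here, as it is to any SNV-level scan); no Sanger trace
decomposition; no transcript-database coordinate support. The cohort
summary takes genotype flags as input — deciding a founder's flags from its
tally (e.g. a minimum KI read fraction) is left to the caller, since the
source workflow made that call by Sanger sequencing, not from the WGS
tallies.
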