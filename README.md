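# crisprki

Design and founder analysis of single-base CRISPR-Cas9 knock-in alleles made
with single-stranded oligodeoxynucleotide (ssODN) donors.

When a point mutation is installed in the mouse germline by homology-directed
repair (HDR), three computational problems sit around the wet lab:

1. **Donor design.** The ssODN must carry the intended edit flanked by
   homology arms, plus *silent shield mutations* — synonymous substitutions
   placed in each guide's NGG protospacer-adjacent motif (PAM) or 5-nt
   PAM-proximal seed — so the repaired allele is no longer cut. With a dual
   overlapping guide pair (one sense, one antisense) every shield must be
   codon-checked against the reading frame.
2. **Founder mosaicism.** Zygote editing yields mosaic founders. Reads
   spanning the target window are classified into four outcome categories —
   intended knock-in (the edit *and* its shields, nothing else), indel,
   no mutation, nonspecific mutation — with precedence
   indel > knock-in > nonspecific > none, and tallied into per-founder
   fractions.
3. **Off-target evidence.** Founder variant calls are reduced to a *de novo*
   SNV set by exact-tuple subtraction of wild-type control calls and a
   known-SNP catalog (variants on un-located contigs dropped); predicted
   off-target sites are checked for de novo SNVs within an inclusive 500-nt
   window; and the genome is scanned for **ectopic HDR signatures** — a
   central C>A transversion accompanied by a de novo N>A 3 or 6 nt upstream,
   N>C 12 nt upstream, or N>T 15 nt upstream, with the search repeated on
   the reverse-complement strand. The companion offsets are not hard-coded:
   they are derived from the donor specification (the shield-to-edit
   spacings), so the scanner adapts to any donor.

The package is organised tidyverse-style: user-facing functions take and
return tibbles, fitted/report objects have `tidy()`, `glance()` and
`autoplot()` methods, and a seeded simulator generates every input (FASTA,
SAM, VCF, BED) so the full pipeline runs without external data. The worked
locus throughout is the *Gaa* c.1935C>A (p.Asp645Glu) knock-in: the 32-nt
target core is reconstructed by overlap-assembling the published guide
protospacers and framed so that codon 645 reads GAC (Asp).

## Worked example

```r
library(crisprki)

locus  <- make_reference(sim_config(seed = 1))   # synthetic genome + coding map
guides <- gaa1935_guides(locus)                  # the dual overlapping pair
donor  <- gaa1935_donor(locus)                   # published donor design
validate_donor(donor, locus, guides)$pass        # TRUE

derive_signature_pattern(donor)
#> <signature_pattern> central C>A; companions: N>A@-3, N>A@-6, N>C@-12, N>T@-15 (strand-symmetric)

rd    <- simulate_founder_reads(sim_config(seed = 1, n_reads = 2000), locus, donor)
tally <- summarize_locus(rd$sam, donor, locus, min_base_quality = 20)
tally
#> <outcome_tally> 2000 spanning read(s) over 24962-25077
#>   category        n fraction
#> 1 intended_KI  1129   0.564
#> 2 indel         462   0.231
#> 3 no_mutation   302   0.151
#> 4 nonspecific   107   0.0535
```

The tally fractions are the per-read mosaicism estimate for one founder: here
56% of spanning reads carry the faithful knock-in haplotype (the c.1935C>A
edit plus all four shields), 23% carry an indel at a cut site, and so on.
`autoplot(tally)` draws the stacked-bar view. Cohort-level genotype flags
summarise with the half-up one-decimal convention:

```r
cohort_summary(tibble::tibble(any_mutation = c(rep(TRUE, 35), rep(FALSE, 4)),
                              intended_ki  = c(rep(TRUE, 15), rep(FALSE, 24))))
#>   metric       n_positive n_total percent
#> 1 any_mutation         35      39    89.7
#> 2 intended_ki          15      39    38.5
```

For the off-target side, `subtract_background()` takes founder/control VCFs
plus a known-SNP catalog, `predicted_site_check()` audits BED intervals, and
`scan_signatures()` runs the donor-derived ectopic HDR scan on both strands.
`run_stage()` (or the `inst/cli/crisprki` script) chains the stages
`simulate → design → validate-donor → classify → scan → check-sites → report`
with a JSON run manifest.

## Acceptance script

`scripts/acceptance.R` rebuilds the synthetic locus from the published guide
sequences, assembles and validates the published donor specification, derives
the ectopic HDR signature pattern from it, and reports the resulting
summary quantity as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
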