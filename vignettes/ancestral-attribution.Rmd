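---
title: "Attributing composite-breed variant sites to their ancestor breeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing composite-breed variant sites to their ancestor breeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossorigin)
```

## The procedure and its assumptions

`crossorigin` attributes variant sites observed in a composite (crossbred)
cohort to one of its two founder breeds. The reasoning is purely genotypic
and cohort-level: it does not phase haplotypes, model recombination, or test
read-level allelic imbalance. It assumes

- the two ancestor cohorts are samples of the actual founder populations,
  diverged enough that many sites are (near-)fixed for *different* homozygous
  genotypes between them;
- the offspring cohort is a genomic mosaic of the two ancestries, so at a
  site where the ancestors disagree cleanly, the offspring's prevailing
  homozygous genotype identifies the contributing ancestor;
- genotypes at a site are comparable across cohorts, i.e. called against the
  same reference and the same REF/ALT pair (sites are aligned on
  chromosome, position and alleles; sites absent from any cohort are
  dropped and counted).

The pipeline runs: variant filtering → ancestor major-genotype calling →
informative-site detection → offspring screening → origin assignment →
gene-window aggregation → summaries (`run_ancestry_pipeline()` orchestrates;
every stage is exported on its own).

## Thresholds and what they mean

| parameter | default | role |
|---|---|---|
| `ancestor_major_prop` | 0.75 | a genotype is an ancestor cohort's major genotype iff `count/n > 0.75`, missing genotypes included in `n` |
| `offspring_major_prop` | 0.60 | same rule for the offspring cohort |
| `offspring_max_missing` | 0.50 | offspring sites with more than half the genotypes missing are screened out before calling |
| `window_bp` | 1000 | a site is credited to every gene whose body intersects the 1,000-bp window centered on the site |

The proportion comparisons are strict (`>`), which fixes the minimum
qualifying counts: 14 of 18 at the 75% rule and 4 of 6 at the 60% rule.
Stating the rule as "appeared in more than 14 of 18" is consistent with the
strict proportion reading (13/18 ≈ 0.72 fails, 14/18 ≈ 0.78 passes); reading
"more than 14" as "at least 15" would contradict the 75% rule itself, so the
proportion rule is what the code implements. The denominator deliberately
includes missing genotypes: a genotype must dominate the *cohort*, not just
the called subset. Offspring missingness gets its own dedicated 50% screen
first, because transcriptome-derived genotypes are missing wherever a region
is not expressed, which is informative about coverage rather than genotype.

Ties for the most frequent genotype produce no call (`NONE`). This is a
determinism/conservatism choice: an arbitrary winner would let sample order
decide an attribution.

Informative sites require *homozygous* majors in both ancestors that differ
from each other. A heterozygous major cannot anchor an origin: both alleles
are present in that ancestor, so observing either in the offspring proves
nothing. Offspring sites whose homozygous major matches neither ancestor
(possible under drift, error, or a third ancestry) are reported as
`UNASSIGNED` rather than silently dropped, so the assigned + unassigned
counts always partition the screened informative set.

## Variant filtering

Hard filters reimplement the standard GATK-style expressions literally, with
strict inequalities exactly as written (SNPs:
`QUAL < 30 || QD < 2 || FS > 60 || MQ < 40 || SOR > 4`; indels:
`QUAL < 30 || QD < 2 || FS > 200 || SOR > 10 || MQ < 40`). A site missing an
annotation named in its expression is removed and counted in a warning —
engines differ between versions on missing annotations, and
literal-and-conservative is reproducible.

The cluster rule removes every SNP belonging to a run of ≥ 3 SNPs whose
positional span (`max − min + 1`, 1-based inclusive) is at most 10 bp;
indels neither trigger nor suffer removal. The span arithmetic is stated
here because "3 SNPs in a 10-bp window" admits off-by-one readings; the
tests pin it with window-scan oracles (positions 100/105/109 span exactly
10 and are all removed).

Cohort filters follow VCFtools semantics: biallelic sites, mean per-sample
depth ≥ 5, minor-allele frequency ≥ 0.05 over non-missing alleles, and a
called-genotype fraction ≥ 0.5 (`--max-missing 0.5` names the *minimum
called* fraction). MAF and depth boundaries are inclusive, the VCFtools
convention. By default the pipeline applies these criteria to the pooled
samples of all three cohorts after site alignment
(`cohort_filter_mode = "merged"`), mirroring a jointly called multi-breed
call set. This is not cosmetic: within one ancestor cohort an informative
site is monomorphic (MAF 0), so per-cohort MAF filtering would remove
exactly the sites the method needs; pooled across breeds, the same sites are
strongly polymorphic. A `per_cohort` mode is available for pre-filtered
single-cohort workflows.

## The gene-window rule

"1,000 bp centered around the site" is implemented as the closed window
`[pos − 500, pos + 500]` intersected with gene *bodies* — equivalently, a
site within 500 bp of a gene is credited to it, and a site is credited to
every overlapping gene. Annotated UTRs or flank features are not consulted;
gene-body intersection plus the window is the whole rule. SNPs and indels
are aggregated into separate per-gene summaries (with a combined total row),
since the two classes are reported separately. A gene's category is `BOTH`
as soon as each ancestor contributes at least one site; the counts
themselves are kept so stricter definitions can be derived downstream.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the study conditions the pipeline targets:
cohorts of 3 (ancestor A), 18 (ancestor B) and 6 (offspring); biallelic SNPs
and indels (10% indels, half insertions); a fraction (default 0.5) of
informative sites where the cohorts are fixed for opposite homozygotes with
per-individual fixation 0.95 (the drifted remainder is mostly heterozygous);
offspring loci independently assigned an origin with probability 0.25 for
ancestor A (the smaller, maternal-type cohort); offspring missingness 0.05
inside gene bodies and 0.7 outside, emulating transcriptome-derived
genotypes; SNP substitutions drawn with a 0.71 transition probability so
simulated Ts/Tv lands near real resequencing values; QUAL/QD/FS/MQ/SOR/DP
drawn from distributions that straddle every hard-filter threshold so both
branches of each clause are exercised. Identical seeds give byte-identical
output files.

It deliberately does **not** simulate recombination-aware haplotype blocks
(the procedure is site-wise, so block structure cannot change its verdicts),
linkage between sites, read-level data, genotype-likelihood noise, or
multi-allelic sites (a single ALT per site; the cohort filter would discard
multi-allelic records anyway). Passing tests therefore demonstrate that the
*procedure* is implemented correctly and recovers known truth under
site-independent admixture — they do not validate robustness to correlated
errors, reference bias, or ancestry misspecification in real data.

Under the default conditions the attribution error at an assigned site
requires at least 4 of 6 offspring draws to hit the opposite homozygote,
each with probability 0.2 × (1 − 0.95) = 0.01 per draw — a per-site error
probability below 10⁻⁶ — so the ≥ 95% accuracy bound used in the recovery
tests is loose by construction, and with fixation 1 and no missingness the
recovery is exact.

## Numerical and degenerate-input choices

- Coordinates are 1-based inclusive throughout (VCF/GFF3 convention);
  genotypes are treated as unphased (`|` equals `/`).
- Genotype codes collapse diploid biallelic calls to
  `HOM_REF`/`HET`/`HOM_ALT`/`MISSING`; allele indices > 1 become `MISSING`
  at read time.
- An all-missing site is removed by the cohort filter, not an error; an
  empty genotype vector is an error.
- Ts/Tv with zero transversions is reported as `NA` ("undefined"), not an
  exception; ratios and percentages are kept at full precision and rounded
  to 2 decimals only when printed.
- The k-mer genome-size utility is the closed form `G = K_num / K_depth`
  only; heterozygosity or repeat-content estimation from k-mer spectra is
  out of scope.

## Problem sizes in the test suite

The suite validates each filter and the caller against independent
brute-force oracles on 1,000-site simulations, exhaustively enumerates all
genotype compositions for cohorts up to n = 6, checks exact truth recovery
on 2,000 noise-free sites and the accuracy bound on 2,000 drifted sites, and
re-checks the conservation invariants on 20 randomly drawn simulator
configurations of 150 sites each. These sizes give every rule multiple
boundary cases while keeping the whole suite near half a minute.

## Known limitations

Attribution is gene-count based, not expression-magnitude based: a gene
"derives from" an ancestor by its assigned-site tally, which is a genotypic
statement about expressed variants, not a quantitative allele-specific
expression test. Sites are treated independently; correlated genotyping
error across a region can therefore produce clustered wrong assignments
that site-wise accuracy bounds do not capture. Cohorts of 3 are close to
the method's floor: with `n = 3`, the 75% rule requires unanimity, so
ancestor-A informativeness decays quickly with drift or missingness — a
real design constraint inherited from small founder panels, visible in the
simulator whenever `fixation < 1`.
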