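---
title: "Methods: NAT2 star-allele typing, EM phasing and phenotype inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NAT2 star-allele typing, EM phasing and phenotype inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nat2typer)
```

## Scope and model

`nat2typer` types the 873 bp intronless coding exon of human *NAT2* from
per-sample Sanger consensus sequences and infers the trimodal acetylator
phenotype. The genetic model is the standard star-allele nomenclature: a
haplotype is the exact set of coding SNPs carried on one chromosome
relative to the `NAT2*4` reference allele; named alleles fall into allelic
groups (*4, *5, *6, *7, *11, *12, *13, *14) defined by one signature SNP
each; and the phenotype follows the co-dominant defective-allele rule —
slow, intermediate and rapid acetylators carry two, one and zero
slow-function alleles. When either allele's function is unrecorded the
phenotype is reported as not determinable (`ND`) rather than guessed.

## Reference, catalogue and allele table

The bundled reference FASTA is a **synthetic stand-in** for the `NAT2*4`
coding sequence (the GenBank record is not redistributed here). It is
constructed to satisfy everything the pipeline relies on: 873 bases, ATG
start, terminal stop and no internal stops, the documented reference base
at each of the 13 catalogued SNP positions, and codon contexts that
reproduce the documented amino-acid consequences of the seven globally
common SNPs (e.g. c.341T>C = p.Ile114Thr, c.590G>A = p.Arg197Gln). All
pipeline logic depends only on those constraints, never on the remaining
(arbitrary) codons. Amino-acid annotations of the six rarer catalogued
SNPs derive from the synthetic codons and are internally consistent rather
than authoritative.

The default allele table ships 21 entries: the ten alleles observed above
1% in at least one Brazilian state (`*4`, `*5A`, `*5B`, `*5C`, `*6A`,
`*7B`, `*12A`, `*12B`, `*13A`, `*14B`), nine rarer newly named alleles
(`*5AA`, `*5BA`, `*5BB`, `*5CA`, `*12Q`, `*12R`, `*12S`, `*13H`, `*28`),
and the conventional companions `*11A` and `*12C`. Functions are `rapid`
or `slow` where established; new alleles carrying the c.341T>C slow
signature are classed slow, and the remaining new alleles are conservatively
`unknown` (their carriers type as `ND`). Users extend or replace the table
via TSV (`nat2_allele_table(path)`).

### Signature priority

Several alleles stack multiple signature SNPs, so group assignment tests
signatures in a fixed priority order: the four slow signatures first
(c.191G>A → \*14, c.341T>C → \*5, c.590G>A → \*6, c.857G>A → \*7), then
c.803A>G → \*12 **before** c.481C>T → \*11, then c.282C>T → \*13. Putting
803 ahead of 481 is forced by the published allele definitions themselves:
`*12C` (481+803) and `*12S` (33+481+803) both carry c.481C>T yet belong to
the \*12 group. With this order, the computed group of every shipped
allele equals its stored group (a unit test asserts this). `NAT2*28`
carries only c.622T>C — none of the seven canonical signatures — so the
default map carries a table-driven extension c.622T>C → \*28; a non-empty
haplotype matching no signature at all falls back to the reference group
\*4 (it is signature-equivalent to the reference).

## Variant calling

Fragment pairs (`_F`/`_R`) are merged over their best compatible overlap
(≥ 30 bases, ≥ 90% compatible positions): identical calls are kept, a
plain base against a containing ambiguity code resolves to the code, and
contradictory bases resolve to `N`. The consensus is aligned to the
reference with ends-free pairwise alignment (match +1, mismatch −1, gap
open −5, gap extend −1), with IUPAC codes scoring as matches against any
compatible base, so amplicon flanks and partial coverage cost nothing.
Two quality gates reject unusable input: aligned coverage below 50% of
the shorter of sample and exon, or aligned identity below 80%.

At each catalogued site, a plain base yields a homozygous call, a two-base
IUPAC code equal to {ref, alt} a heterozygous call, and anything else
(`N`, three/four-base codes, a third base, or a site falling in an
alignment gap) is treated as missing — diploid data cannot support more
than two alleles at a site, and indels are outside the typing model.
Substitutions at uncatalogued positions are reported as novel-variant
records but never enter phasing or typing; confirming a novel variant is a
wet-lab re-sequencing decision, not something the caller should do
silently.

## EM phasing

Haplotype frequencies are estimated by the classical Excoffier–Slatkin
gene-counting EM at a single multi-SNP locus. With genotype g having k
heterozygous sites there are 2^(k−1) compatible unordered haplotype pairs
(enumerated exactly; a cap of 12 heterozygous sites guards against
pathological input — the worst real samples here have ≤ 8). The E-step
weighs pair (h₁, h₂) proportionally to 2^[h₁≠h₂] f(h₁) f(h₂); the M-step
divides expected chromosome counts by 2N. Initialisation is uniform over
the observed-compatible haplotypes, which makes the fit deterministic
given the data; optional random restarts exist but are off by default.
Convergence is declared when the log-likelihood gain drops below 1e-8
(default; `tol`), with a 500-iteration ceiling; the trace is stored and is
non-decreasing by construction (asserted in tests). Frequencies below
1e-12 are pruned afterwards.

Samples with up to 2 missing catalogued calls are phased by summing over
every fill-in of the missing genotypes; beyond that the pair space grows
without information to support it, and the sample is excluded (but
counted). The maximum-posterior pair is reported per sample with its
posterior; a sample is *phased* when that posterior reaches
`min_posterior = 0.90`. This threshold is this package's own operational
rule — statistical phasing offers no natural sharp criterion — and it is
exposed as a parameter. Ties are broken by lexicographic haplotype order
for reproducibility. The model deliberately omits recombination priors
(PHASE-style coalescent modelling): within a single 873 bp exon,
recombination is not an informative signal at cohort sizes in the
hundreds, and the EM's determinism makes results exactly reproducible.

Dual-route validation: on cohorts of ≤ 4 SNPs the restricted-support EM
is checked against a dense EM over the complete 2^k haplotype space
written independently in the test suite, and parameter recovery from
simulated cohorts (n = 2000) must achieve RMSE < 0.01 against the
generating frequencies.

## Population statistics

Frequencies are computed by chromosome counting (two per phased sample)
per stratum; pooling across strata sums counts, which is exactly the
sample-size-weighted frequency mean. Hardy-Weinberg equilibrium is tested
per SNP with the exact conditional test: given the allele counts, the
p-value sums the probabilities of all heterozygote counts no more probable
than the one observed (monomorphic sites return 1 by convention). A
multi-allelic chi-square over diplotype classes with rare-allele pooling
is provided as an optional extension, but per-SNP biallelic testing is the
default. Stratum comparisons use the Pearson chi-square without continuity
correction (one-vs-rest 2×2, or the full 2×k distribution); expected cells
below 1 trigger an advisory warning. Reported percentages are rounded to
one decimal with round-half-even; tests against printed percentages use a
±0.1 tolerance, since one-decimal rounding of published tables is not
always exactly recoverable.

## Synthetic cohorts: what they emulate, and what not

`sample_cohort()` draws, for every sample, two haplotypes i.i.d. from its
stratum's frequency vector — Hardy-Weinberg equilibrium by construction —
and emits a truth manifest plus the error-free genotype table.
`render_sequences()` superimposes the two chromosome sequences into one
IUPAC consensus, after applying independent per-base substitution noise at
`error_rate` (0–0.05) to each chromosome. The shipped presets are the
five regional frequency vectors of the ten common alleles; the ~6% of mass
each region carries in rarer alleles is assigned to a catch-all `other`
pseudo-allele of unknown function, materialised as a private haplotype
({c.345C>T}) that matches no named allele and therefore types as `novel`/
`ND` — mirroring how unassignable rare haplotypes behave in real cohorts.

The generator emulates sampling noise, heterozygote ambiguity and uniform
base-call error. It does **not** emulate chromatogram-level artefacts
(peak height, dye blobs), indels, allele dropout, population substructure
within a stratum, or relatedness. Pipeline accuracy on these cohorts
therefore demonstrates correctness of the statistical machinery under the
stated model, not robustness to every Sanger failure mode.

Default validation sizes were chosen to exercise cohort-scale behaviour
while keeping the suite quick: end-to-end runs at n = 120–300, parameter
recovery at n = 2000, a five-region phasing cohort of n = 956, and 1000
replicates for the Hardy-Weinberg nominal-rate check at n = 500.

## Known limitations

* Exactness of phasing is statistical, not guaranteed: a rare double
  heterozygote can receive a confident but wrong maximum-posterior pair
  (the EM supports whatever haplotype set explains the cohort best). The
  end-to-end tests quantify this; at error rate 0 and realistic regional
  frequencies, phenotype accuracy among phased samples is 100% in the
  validation runs and phase accuracy ≥ 99%.
* The allele table is a curated subset; haplotypes outside it type as
  `novel` and, unless they carry a slow signature, contribute `ND`
  phenotypes. This is conservative by design.
* Only substitutions are typed. Indels are tolerated by the aligner but
  any catalogued site inside a gap becomes missing.
* The synthetic reference preserves everything the methods depend on, but
  analyses that would read untyped codons (e.g. translating the whole
  exon) are outside its warranty.
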