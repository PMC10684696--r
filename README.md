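# nat2typer

Sequence-based star-allele typing of the human *NAT2* gene and inference of
the trimodal acetylator phenotype.

## The problem

Arylamine N-acetyltransferase 2 (NAT2) is a phase-II drug-metabolizing
enzyme; N-acetylation is the main detoxification route for isoniazid,
hydralazine, dapsone, several sulphonamides and other clinically important
drugs. The *NAT2* gene has a single 873 bp intronless coding exon whose
common SNPs combine into named haplotypes ("star alleles", e.g. `NAT2*5B`)
with rapid or slow enzymatic function. An individual's diplotype predicts
their acetylator phenotype by a simple co-dominant rule: carriers of two,
one or no defective (slow) alleles are **slow**, **intermediate** or
**rapid** acetylators, respectively. Because Sanger sequencing of a diploid
sample reports heterozygous positions as IUPAC ambiguity codes, the two
underlying haplotypes must be reconstructed statistically before alleles
can be named.

`nat2typer` implements that whole chain for population surveys:

1. **Variant calling** — `call_genotypes()` aligns each sample's consensus
   sequence of the coding exon to the `NAT2*4` reference (ends-free affine
   alignment: match +1, mismatch −1, gap open −5, extend −1; IUPAC codes
   match any compatible base) and decodes per-site diploid genotypes.
   Optional `_F`/`_R` fragment pairs are merged first.
2. **Phasing** — `hap_em()` fits haplotype frequencies by the
   Excoffier–Slatkin EM algorithm. For a genotype with *k* heterozygous
   sites there are 2^(k−1) compatible haplotype pairs; the E-step weighs
   each pair (h₁, h₂) by 2^[h₁≠h₂]·f(h₁)·f(h₂), the M-step re-estimates
   frequencies from expected chromosome counts. `predict()` then assigns
   each sample its maximum-posterior pair; samples below a 0.90 posterior
   are flagged unphased.
3. **Typing** — `assign_allele()` matches haplotypes to the shipped allele
   table (exact SNP-set match), `allelic_group()` assigns the *4/*5/*6/*7/
   *11/*12/*13/*14 group from signature SNPs, and `infer_phenotype()`
   applies the defective-allele rule.
4. **Population statistics** — stratified allele/genotype/phenotype
   frequency tables by chromosome counting, sample-size-weighted pooling,
   an exact Hardy-Weinberg test conditional on allele counts, and Pearson
   chi-square comparisons between strata.
5. **Synthetic cohorts** — `sample_cohort()` draws truth-annotated
   diplotypes under Hardy-Weinberg equilibrium from regional haplotype
   frequency presets and `render_sequences()` emits them as IUPAC consensus
   FASTA (with optional base-call noise), so the entire pipeline is
   testable end to end without any external data.

The bundled reference FASTA is a *synthetic* stand-in for the `NAT2*4`
coding sequence: correct length, reading frame, and reference base plus
codon context at every catalogued SNP position (see the methods vignette).

## Worked example

```r
library(nat2typer)

spec   <- region_cohort_spec("Southeast", n = 120, seed = 42)
cohort <- sample_cohort(spec)
seqs   <- render_sequences(cohort$truth, seed = 42)   # IUPAC consensus FASTA
strata <- setNames(cohort$truth$stratum, cohort$truth$sample_id)

res <- nat2_pipeline(seqs, strata = strata)
res$fit
#> Haplotype-frequency EM fit (120 samples, 11 haplotypes)
#> log-likelihood: -385.6831 after 71 iterations (converged)

head(res$typed[res$typed$phased,
               c("sample_id", "allele1", "allele2", "phenotype")], 5)
#>        sample_id  allele1 allele2    phenotype
#> 1 Southeast_0001 NAT2*12A  NAT2*4        rapid
#> 2 Southeast_0002 NAT2*12A  NAT2*4        rapid
#> 3 Southeast_0003  NAT2*5B NAT2*6A         slow
#> 4 Southeast_0004  NAT2*6A   novel           ND
#> 5 Southeast_0005 NAT2*13A NAT2*6A intermediate

res$frequencies$phenotype$Southeast
#> Frequency table [phenotype] stratum 'Southeast' (n = 120)
#>          item count  pct
#>  intermediate    45 37.5
#>          slow    40 33.3
#>         rapid    18 15.0
#>            ND    15 12.5
#>      unphased     2  1.7
```

Sample `Southeast_0003` carries two defective alleles (`*5B`, `*6A`) and is
a slow acetylator; `Southeast_0004` carries one haplotype not matching any
named allele, so its phenotype is not determinable (`ND`). The same cohort
pushed through `end_to_end_recovery(spec)` reports 100% phenotype accuracy
among phased samples and an allele-frequency RMSE of 0.004 against the
generator truth.

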