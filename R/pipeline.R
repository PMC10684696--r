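#' Run the full typing pipeline on a FASTA of consensus sequences
#'
#' Convenience wrapper chaining [call_genotypes()], [hap_em()],
#' [predict.hap_em()], [type_samples()] and [count_frequencies()].
#'
#' @param x FASTA path or `DNAStringSet` of per-sample consensus sequences
#'   (IUPAC heterozygote codes; optional `_F`/`_R` fragment pairs).
#' @param strata optional named vector sample id -> stratum.
#' @param reference,catalog,table pipeline inputs (defaults: bundled).
#' @param min_posterior phasing threshold (default 0.90).
#' @return list with `genotypes`, `fit`, `diplotypes`, `typed`, and
#'   `frequencies` (per-stratum allele/genotype/phenotype tables).
#' @examples
#' spec <- region_cohort_spec("Southeast", n = 40, seed = 7)
#' seqs <- render_sequences(sample_cohort(spec)$truth, seed = 7)
#' res <- nat2_pipeline(seqs)
#' res$typed[1:3, c("sample_id", "allele1", "allele2", "phenotype")]
#' @export
nat2_pipeline <- function(x, strata = NULL, reference = nat2_reference(),
                          catalog = nat2_catalog(reference = reference),
                          table = nat2_allele_table(reference = reference),
                          min_posterior = 0.9) {
  genotypes <- call_genotypes(x, reference, catalog, strata = strata)
  fit <- hap_em(genotypes)
  diplotypes <- predict(fit, min_posterior = min_posterior)
  typed <- type_samples(diplotypes, catalog, table)
  freqs <- list(
    allele = count_frequencies(typed, "allele"),
    genotype = count_frequencies(typed, "genotype"),
    phenotype = count_frequencies(typed, "phenotype")
  )
  list(genotypes = genotypes, fit = fit, diplotypes = diplotypes,
       typed = typed, frequencies = freqs)
}
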