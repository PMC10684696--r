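# Synthetic cohorts: truth-annotated diplotypes drawn under Hardy-Weinberg
# equilibrium from stratified haplotype frequencies, optionally rendered as
# IUPAC consensus FASTA with configurable base-error noise.

# The regional frequency presets list only the named alleles above 1 percent;
# the remainder mass is carried by a catch-all pseudo-allele "other"
# (function unknown), materialised as the singleton haplotype {c.345C>T},
# which collides with no shipped allele definition.
.OTHER_ALLELE <- "other"
.OTHER_TOKENS <- "c.345C>T"

#' Regional haplotype-frequency presets
#'
#' Builds, from the bundled regional allele-frequency table, one named
#' frequency vector per geographical region (North, Northeast, Midwest,
#' Southeast, South).  Frequencies are proportions summing to 1; the mass
#' not covered by the ten named alleles is assigned to the `"other"`
#' pseudo-allele (about 6 percent per region).
#'
#' @return named list of named numeric vectors.
#' @examples
#' round(region_presets()$South, 3)
#' @export
region_presets <- function() {
  tab <- allele_frequencies_regions()
  tab <- tab[tab$region != "Total", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tab))) {
    pct <- unlist(tab[i, -(1:2)])
    f <- pct / 100
    f <- c(f, setNames(1 - sum(f), .OTHER_ALLELE))
    out[[tab$region[i]]] <- f
  }
  out
}

#' Specify a synthetic cohort
#'
#' @param strata list of strata, each a list with `label`, `n` (samples) and
#'   `freqs` (named haplotype-frequency vector over allele names; must sum
#'   to 1 within 1e-9).
#' @param seed integer RNG seed; the whole cohort (and any rendering noise)
#'   is reproducible from it.
#' @param error_rate per-base substitution probability applied when
#'   rendering sequences, in `[0, 0.05]`.
#' @param iupac_render if `TRUE` (default) sequences are rendered as one
#'   consensus per sample with heterozygous positions as IUPAC codes; if
#'   `FALSE` the two chromosome sequences are emitted separately.
#' @return object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(list(list(label = "South", n = 50,
#'                               freqs = region_presets()$South)), seed = 7)
#' @export
cohort_spec <- function(strata, seed = 1, error_rate = 0,
                        iupac_render = TRUE) {
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  for (s in strata) {
    if (!all(c("label", "n", "freqs") %in% names(s)))
      stop("each stratum needs label, n and freqs")
    if (s$n < 1) stop("stratum '", s$label, "': n_samples must be >= 1")
    if (is.null(names(s$freqs)) || abs(sum(s$freqs) - 1) > 1e-9)
      stop("stratum '", s$label, "': frequencies must be named and sum to 1")
    if (any(s$freqs < 0)) stop("negative frequency in stratum '", s$label, "'")
  }
  structure(list(strata = strata, seed = as.integer(seed),
                 error_rate = error_rate, iupac_render = iupac_render),
            class = "cohort_spec")
}

#' Convenience spec over the regional presets
#'
#' @param regions region names (subset of `names(region_presets())`).
#' @param n samples per region (recycled).
#' @inheritParams cohort_spec
#' @return a [cohort_spec()].
#' @export
region_cohort_spec <- function(regions, n, seed = 1, error_rate = 0,
                               iupac_render = TRUE) {
  presets <- region_presets()
  if (!all(regions %in% names(presets)))
    stop("unknown region(s): ",
         paste(setdiff(regions, names(presets)), collapse = ", "))
  n <- rep_len(n, length(regions))
  strata <- mapply(function(r, k) list(label = r, n = k, freqs = presets[[r]]),
                   regions, n, SIMPLIFY = FALSE)
  cohort_spec(strata, seed = seed, error_rate = error_rate,
              iupac_render = iupac_render)
}

# tokens carried by a (possibly pseudo-) allele name
allele_name_tokens <- function(name, table) {
  if (name == .OTHER_ALLELE) return(.OTHER_TOKENS)
  allele_tokens(table, name)
}

allele_name_func <- function(name, table) {
  if (name == .OTHER_ALLELE) return("unknown")
  table$func[match(name, table$name)]
}

#' Draw a truth-annotated synthetic cohort
#'
#' Each sample draws two haplotypes i.i.d. from its stratum's frequency
#' vector (Hardy-Weinberg equilibrium by construction).  The output carries
#' both the truth manifest (allele names, haplotype strings, truth
#' phenotype) and the error-free unphased genotype table.  Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param table a [nat2_allele_table()] resolving allele names.
#' @param catalog a [nat2_catalog()] defining the site order.
#' @return list with `truth` (data frame: `sample_id`, `stratum`, `hap1`,
#'   `hap2` allele names with `hap1 <= hap2`, `h1`, `h2` haplotype strings,
#'   `phenotype`) and `genotypes` (a [nat2_genotypes()] object).
#' @export
sample_cohort <- function(spec, table = nat2_allele_table(),
                          catalog = nat2_catalog()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  truth <- list()
  for (s in spec$strata) {
    alleles <- names(s$freqs)
    for (a in setdiff(alleles, .OTHER_ALLELE))
      allele_tokens(table, a)   # errors early on unknown names
    draw1 <- sample(alleles, s$n, replace = TRUE, prob = s$freqs)
    draw2 <- sample(alleles, s$n, replace = TRUE, prob = s$freqs)
    truth[[s$label]] <- data.frame(
      sample_id = sprintf("%s_%04d", s$label, seq_len(s$n)),
      stratum = s$label,
      hap1 = pmin(draw1, draw2), hap2 = pmax(draw1, draw2),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  hapstr <- function(name) tokens_to_hap(allele_name_tokens(name, table), catalog)
  uniq <- unique(c(truth$hap1, truth$hap2))
  hs <- vapply(uniq, hapstr, "")
  truth$h1 <- pmin(hs[truth$hap1], hs[truth$hap2])
  truth$h2 <- pmax(hs[truth$hap1], hs[truth$hap2])
  fn <- vapply(uniq, allele_name_func, "", table = table)
  truth$phenotype <- mapply(function(a, b)
    infer_phenotype(fn[a], fn[b])$phenotype, truth$hap1, truth$hap2,
    USE.NAMES = FALSE)

  hm <- do.call(rbind, lapply(strsplit(hs, ""), as.integer))
  rownames(hm) <- uniq
  geno <- hm[truth$hap1, , drop = FALSE] + hm[truth$hap2, , drop = FALSE]
  storage.mode(geno) <- "integer"
  gt <- nat2_genotypes(geno, catalog,
                       data.frame(sample_id = truth$sample_id,
                                  stratum = truth$stratum,
                                  stringsAsFactors = FALSE))
  list(truth = truth, genotypes = gt, spec = spec)
}

#' Render a truth manifest as consensus sequences
#'
#' For each sample the two haplotype sequences are built from the reference,
#' per-base substitution noise is applied independently to each chromosome at
#' `error_rate`, and the chromosomes are superimposed: discordant positions
#' become the corresponding two-base IUPAC ambiguity code.  With
#' `iupac_render = FALSE` the two noisy chromosome sequences are returned as
#' separate `<id>_h1` / `<id>_h2` records instead.
#'
#' @param truth truth manifest from [sample_cohort()].
#' @param reference a [nat2_reference()] object.
#' @param table a [nat2_allele_table()].
#' @param catalog a [nat2_catalog()].
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed for the noise (use the cohort seed for byte-identical
#'   reruns).
#' @param iupac_render see [cohort_spec()].
#' @return a `Biostrings::DNAStringSet`, one record per sample (or two when
#'   `iupac_render = FALSE`).
#' @export
render_sequences <- function(truth, reference = nat2_reference(),
                             table = nat2_allele_table(),
                             catalog = nat2_catalog(),
                             error_rate = 0, seed = 1,
                             iupac_render = TRUE) {
  set.seed(seed)
  refchars <- strsplit(reference$sequence, "")[[1]]
  L <- length(refchars)
  hapseq <- function(name) {
    tokens <- allele_name_tokens(name, table)
    ch <- refchars
    if (length(tokens)) {
      p <- parse_snp_token(tokens)
      ch[p$c_position] <- p$alt
    }
    ch
  }
  uniq <- unique(c(truth$hap1, truth$hap2))
  hseqs <- lapply(setNames(uniq, uniq), hapseq)
  bases <- c("A", "C", "G", "T")
  noisy <- function(ch) {
    if (error_rate > 0) {
      hit <- which(runif(L) < error_rate)
      for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    ch
  }
  out <- character(0)
  for (i in seq_len(nrow(truth))) {
    c1 <- noisy(hseqs[[truth$hap1[i]]])
    c2 <- noisy(hseqs[[truth$hap2[i]]])
    if (iupac_render) {
      cons <- c1
      d <- which(c1 != c2)
      for (j in d) cons[j] <- iupac_code(c1[j], c2[j])
      out[truth$sample_id[i]] <- paste(cons, collapse = "")
    } else {
      out[paste0(truth$sample_id[i], "_h1")] <- paste(c1, collapse = "")
      out[paste0(truth$sample_id[i], "_h2")] <- paste(c2, collapse = "")
    }
  }
  Biostrings::DNAStringSet(out)
}

#' Write a DNAStringSet to FASTA
#' @param x a `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' End-to-end recovery harness
#'
#' Draws a cohort from `spec`, renders consensus sequences at the spec's
#' error rate, and pushes them back through the whole pipeline (variant
#' calling, EM phasing, star-allele typing).  Reports how well the truth is
#' recovered.
#'
#' @param spec a [cohort_spec()].
#' @param reference,table,catalog pipeline inputs (defaults: bundled).
#' @param min_posterior phasing threshold, see [predict.hap_em()].
#' @return object of class `nat2_recovery`: list with `n`, `n_phased`,
#'   `unphased_fraction`, `phase_accuracy` (fraction of phased samples whose
#'   MAP pair equals the truth pair), `phenotype_accuracy` (among phased),
#'   `allele_freq_rmse` (called vs truth allele frequencies, `novel` mapped
#'   to `other`), `confusion` (truth x called phenotype table), `typed`,
#'   `truth`.
#' @export
end_to_end_recovery <- function(spec, reference = nat2_reference(),
                                table = nat2_allele_table(),
                                catalog = nat2_catalog(),
                                min_posterior = 0.9) {
  cohort <- sample_cohort(spec, table, catalog)
  seqs <- render_sequences(cohort$truth, reference, table, catalog,
                           error_rate = spec$error_rate, seed = spec$seed,
                           iupac_render = TRUE)
  strata <- setNames(cohort$truth$stratum, cohort$truth$sample_id)
  geno <- suppressWarnings(
    call_genotypes(seqs, reference, catalog, strata = strata))
  fit <- hap_em(geno)
  dip <- predict(fit, min_posterior = min_posterior)
  typed <- type_samples(dip, catalog, table)

  truth <- cohort$truth
  ph <- isTRUE_vec(dip$phased)
  pred_pair <- paste(dip$hap1, dip$hap2)
  true_pair <- paste(truth$h1, truth$h2)
  phase_acc <- if (any(ph)) mean(pred_pair[ph] == true_pair[ph]) else NA_real_
  pheno_acc <- if (any(ph))
    mean(typed$phenotype[ph] == truth$phenotype[ph]) else NA_real_
  confusion <- table(truth = truth$phenotype[ph],
                     called = typed$phenotype[ph])

  norm_name <- function(x) ifelse(x == "novel", .OTHER_ALLELE, x)
  called <- norm_name(c(typed$allele1[ph], typed$allele2[ph]))
  truth_alleles <- c(truth$hap1, truth$hap2)
  items <- sort(unique(c(called, truth_alleles)))
  f_called <- table(factor(called, levels = items)) / length(called)
  f_truth <- table(factor(truth_alleles, levels = items)) / length(truth_alleles)
  rmse <- sqrt(mean((as.numeric(f_called) - as.numeric(f_truth))^2))

  structure(list(
    n = nrow(truth), n_phased = sum(ph),
    unphased_fraction = 1 - sum(ph) / nrow(truth),
    phase_accuracy = phase_acc, phenotype_accuracy = pheno_acc,
    allele_freq_rmse = rmse, confusion = confusion,
    typed = typed, truth = truth, fit = fit
  ), class = "nat2_recovery")
}

#' @export
print.nat2_recovery <- function(x, ...) {
  cat("End-to-end recovery on ", x$n, " synthetic samples\n", sep = "")
  cat(sprintf("  phased: %d (%.1f%% unphased)\n", x$n_phased,
              100 * x$unphased_fraction))
  cat(sprintf("  phase accuracy (among phased):     %.3f\n", x$phase_accuracy))
  cat(sprintf("  phenotype accuracy (among phased): %.3f\n",
              x$phenotype_accuracy))
  cat(sprintf("  allele-frequency RMSE:             %.4f\n",
              x$allele_freq_rmse))
  cat("  phenotype confusion (truth x called):\n")
  print(x$confusion)
  invisible(x)
}
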