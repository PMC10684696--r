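# Population statistics: stratified frequency tables, weighted pooling,
# Hardy-Weinberg exact tests and pairwise chi-square comparisons.

# ---- frequency tables ------------------------------------------------------

#' Construct a frequency table
#'
#' A frequency table holds item counts for one stratum at one unit level.
#' For `snp`, `allele` and `group` units `n_total` counts chromosomes; for
#' `genotype` and `phenotype` units it counts samples.
#'
#' @param counts named nonnegative numeric vector of item counts.
#' @param unit one of `snp`, `allele`, `group`, `genotype`, `phenotype`.
#' @param stratum stratum label.
#' @param n_total total count; defaults to `sum(counts)`.
#' @return object of class `nat2_freq`.
#' @export
freq_table <- function(counts, unit, stratum = "all",
                       n_total = sum(counts)) {
  unit <- match.arg(unit, c("snp", "allele", "group", "genotype", "phenotype"))
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (n_total <= 0) stop("n_total must be positive")
  if (abs(sum(counts) - n_total) > 1e-6 * max(1, n_total) + 0.5)
    warning("counts do not sum to n_total (printed-table rounding?)")
  structure(list(stratum = stratum, unit = unit,
                 counts = counts, n_total = n_total),
            class = "nat2_freq")
}

#' @export
print.nat2_freq <- function(x, ...) {
  cat("Frequency table [", x$unit, "] stratum '", x$stratum,
      "' (n = ", format(x$n_total), ")\n", sep = "")
  df <- data.frame(item = names(x$counts), count = unname(x$counts),
                   pct = round(100 * x$counts / x$n_total, 1))
  print(df[order(-df$count), ], row.names = FALSE)
  invisible(x)
}

#' Frequencies (proportions) of a frequency table
#' @param x a `nat2_freq` table.
#' @return named numeric vector of `counts / n_total`.
#' @export
frequencies <- function(x) x$counts / x$n_total

#' Build a frequency table from printed percentages
#'
#' Converts a published percentage row with its chromosome/sample count into
#' a `nat2_freq` table (counts are `pct/100 * n` and need not be integral).
#'
#' @param pct named numeric vector of percentages.
#' @param n total chromosomes/samples behind the percentages.
#' @inheritParams freq_table
#' @return a `nat2_freq` table.
#' @export
freq_from_percent <- function(pct, n, unit, stratum = "all") {
  counts <- pct / 100 * n
  suppressWarnings(freq_table(counts, unit, stratum, n_total = n))
}

#' Count stratified frequencies from typed samples
#'
#' Computes per-stratum frequency tables at a given unit level from the
#' output of [type_samples()].  Allele and group tables count two
#' chromosomes per phased sample; genotype tables use canonical sorted-pair
#' labels; phenotype tables count per sample (including `ND`).  Unphased
#' samples are excluded from allele/group/genotype tables.
#'
#' @param typed data frame from [type_samples()].
#' @param unit `allele`, `group`, `genotype` or `phenotype`.
#' @param by column to stratify on (default `"stratum"`); use `NULL` for a
#'   single pooled table.
#' @return named list of `nat2_freq` tables, one per stratum; empty strata
#'   are omitted with a warning.
#' @export
count_frequencies <- function(typed, unit = c("allele", "group", "genotype",
                                              "phenotype"),
                              by = "stratum") {
  unit <- match.arg(unit)
  strata <- if (is.null(by)) rep("all", nrow(typed)) else typed[[by]]
  out <- list()
  for (s in unique(strata)) {
    rows <- typed[strata == s, , drop = FALSE]
    if (unit != "phenotype") rows <- rows[isTRUE_vec(rows$phased), , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("stratum '", s, "' has no usable samples; omitted")
      next
    }
    counts <- switch(unit,
      allele = table(c(rows$allele1, rows$allele2)),
      group = table(c(rows$group1, rows$group2)),
      genotype = table(paste(pmin(rows$allele1, rows$allele2),
                             pmax(rows$allele1, rows$allele2), sep = "/")),
      phenotype = table(rows$phenotype)
    )
    counts <- setNames(as.numeric(counts), names(counts))
    out[[s]] <- freq_table(counts, unit, stratum = s)
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Pool frequency tables by weighted aggregation
#'
#' Pooled counts are the sums of per-stratum counts; the pooled frequency of
#' an item is its pooled count over the pooled total, i.e. the
#' sample-size-weighted mean of the stratum frequencies.
#'
#' @param tables list of `nat2_freq` tables sharing the same unit.
#' @param stratum label for the pooled table (default `"pooled"`).
#' @return a `nat2_freq` table.
#' @export
aggregate_weighted <- function(tables, stratum = "pooled") {
  if (inherits(tables, "nat2_freq")) tables <- list(tables)
  units <- vapply(tables, function(t) t$unit, "")
  if (length(unique(units)) != 1L)
    stop("cannot aggregate tables of mixed units: ",
         paste(unique(units), collapse = ", "))
  items <- unique(unlist(lapply(tables, function(t) names(t$counts))))
  counts <- setNames(numeric(length(items)), items)
  n_total <- 0
  for (t in tables) {
    counts[names(t$counts)] <- counts[names(t$counts)] + t$counts
    n_total <- n_total + t$n_total
  }
  suppressWarnings(freq_table(counts, units[1L], stratum, n_total = n_total))
}

# ---- Hardy-Weinberg --------------------------------------------------------

#' Exact test for Hardy-Weinberg equilibrium at a biallelic site
#'
#' Exact two-sided test conditional on the allele counts: the p-value is the
#' sum of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.  Monomorphic
#' sites return `p = 1` by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (homozygous reference,
#'   heterozygous, homozygous alternate).
#' @return the exact p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)   # ~1
#' hwe_exact_test(50, 0, 50)    # << 1e-6
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped sample is required")
  nA <- 2 * n_AA + n_Aa
  n1 <- min(nA, 2 * n - nA)   # minor-allele copy count
  if (n1 == 0) return(1.0)
  n2 <- 2 * n - n1
  hs <- seq(n1 %% 2, n1, by = 2)
  logp <- vapply(hs, function(h) {
    a <- (n1 - h) / 2
    c2 <- (n2 - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(a) - lfactorial(h) -
      lfactorial(c2) + lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs_h <- n_Aa
  p_obs <- p[match(obs_h, hs)]
  if (is.na(p_obs)) stop("observed heterozygote count inconsistent with counts")
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg exact tests across all catalogued sites
#'
#' @param genotypes a [nat2_genotypes()] object.
#' @return data frame with `c_position`, genotype counts and the exact
#'   p-value per site (missing calls excluded sitewise).
#' @export
hwe_scan <- function(genotypes) {
  g <- genotypes$geno
  out <- data.frame(c_position = genotypes$sites$c_position,
                    n_AA = 0L, n_Aa = 0L, n_aa = 0L, p = NA_real_)
  for (j in seq_len(ncol(g))) {
    x <- g[, j]
    out$n_AA[j] <- sum(x == 0L, na.rm = TRUE)
    out$n_Aa[j] <- sum(x == 1L, na.rm = TRUE)
    out$n_aa[j] <- sum(x == 2L, na.rm = TRUE)
    out$p[j] <- hwe_exact_test(out$n_AA[j], out$n_Aa[j], out$n_aa[j])
  }
  out
}

#' Multi-allelic Hardy-Weinberg chi-square (pooled rare alleles)
#'
#' Optional extension beyond the default per-SNP biallelic testing: compares
#' observed diplotype counts with Hardy-Weinberg expectations computed from
#' allele frequencies, pooling alleles rarer than `pool_below` into a single
#' class.  Uses the Pearson statistic with `k(k+1)/2 - k` degrees of freedom
#' for `k` allele classes.
#'
#' @param typed output of [type_samples()] (phased samples are used).
#' @param pool_below pool alleles with frequency below this value
#'   (default 0.05).
#' @return list with `chi2`, `df`, `p`, `k`.
#' @export
hwe_genotype_chisq <- function(typed, pool_below = 0.05) {
  rows <- typed[isTRUE_vec(typed$phased), , drop = FALSE]
  if (nrow(rows) == 0L) stop("no phased samples")
  alleles <- c(rows$allele1, rows$allele2)
  f <- table(alleles) / length(alleles)
  lab <- function(a) ifelse(f[a] < pool_below, "rare", a)
  a1 <- lab(rows$allele1); a2 <- lab(rows$allele2)
  cls <- sort(unique(c(a1, a2)))
  k <- length(cls)
  fr <- table(factor(c(a1, a2), levels = cls)) / (2 * nrow(rows))
  # expected counts over all unordered pairs
  pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
  pairs <- pairs[pairs$i <= pairs$j, ]
  labels <- paste(pmin(cls[pairs$i], cls[pairs$j]),
                  pmax(cls[pairs$i], cls[pairs$j]), sep = "/")
  expd <- ifelse(pairs$i == pairs$j, fr[pairs$i]^2,
                 2 * fr[pairs$i] * fr[pairs$j]) * nrow(rows)
  obs <- table(factor(paste(pmin(a1, a2), pmax(a1, a2), sep = "/"),
                      levels = labels))
  chi2 <- sum((as.numeric(obs) - expd)^2 / ifelse(expd > 0, expd, NA),
              na.rm = TRUE)
  df <- k * (k + 1) / 2 - k
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), k = k)
}

# ---- chi-square comparison -------------------------------------------------

#' Pairwise chi-square comparison of two strata
#'
#' Pearson chi-square without continuity correction on the 2 x k
#' contingency table built from two frequency tables: with `item` given, the
#' comparison is item-versus-rest (k = 2); otherwise the full item
#' distribution is compared (k = number of distinct items).  Expected counts
#' below 1 trigger a warning recommending an exact alternative.
#'
#' @param a,b `nat2_freq` tables sharing a unit.
#' @param item optional item label for a one-vs-rest comparison.
#' @return object of class `nat2_chi2`: list with `strata`, `item`, `chi2`,
#'   `df`, `p`, `observed`, `expected`.
#' @export
chi2_compare <- function(a, b, item = NULL) {
  if (a$unit != b$unit)
    stop("cannot compare tables of different units: ", a$unit, " vs ", b$unit)
  if (!is.null(item)) {
    m <- rbind(
      c(sum(a$counts[names(a$counts) == item]),
        a$n_total - sum(a$counts[names(a$counts) == item])),
      c(sum(b$counts[names(b$counts) == item]),
        b$n_total - sum(b$counts[names(b$counts) == item]))
    )
    colnames(m) <- c(item, "rest")
  } else {
    items <- sort(unique(c(names(a$counts), names(b$counts))))
    m <- rbind(
      vapply(items, function(i) sum(a$counts[names(a$counts) == i]), 0),
      vapply(items, function(i) sum(b$counts[names(b$counts) == i]), 0)
    )
    m <- m[, colSums(m) > 0, drop = FALSE]
  }
  rownames(m) <- c(a$stratum, b$stratum)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in the contingency table")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  if (any(ct$expected < 1))
    warning("expected cell count below 1; consider an exact test")
  structure(list(strata = c(a$stratum, b$stratum), item = item,
                 chi2 = unname(ct$statistic), df = as.integer(ct$parameter),
                 p = ct$p.value, observed = m, expected = ct$expected),
            class = "nat2_chi2")
}

#' @export
print.nat2_chi2 <- function(x, ...) {
  cat("Chi-square comparison: ", x$strata[1], " vs ", x$strata[2],
      if (!is.null(x$item)) paste0(" [", x$item, " vs rest]"), "\n", sep = "")
  cat(sprintf("X-squared = %.4f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

# ---- printed-table utilities ----------------------------------------------

#' Load the bundled Brazil-wide genotype frequency table
#'
#' The 21 diplotypes with population frequency of at least 1 percent, with
#' their printed subject counts and percentages and, for cross-checking
#' only, the phenotype section each was printed under.
#'
#' @param path optional TSV path; `NULL` uses the bundled table.
#' @return data frame with `genotype`, `n_subjects`, `freq_pct`,
#'   `printed_class`.
#' @export
genotype_frequencies_brazil <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "genotype_frequencies_brazil.tsv",
                        package = "nat2typer", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Load the bundled regional allele frequency table
#'
#' Printed percentage frequencies of the ten common alleles in the five
#' geographical regions (plus the national total row), with per-region
#' chromosome counts.
#'
#' @param path optional TSV path; `NULL` uses the bundled table.
#' @return data frame; first two columns `region` and `n_alleles`, then one
#'   column per allele.
#' @export
allele_frequencies_regions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "allele_frequencies_regions.tsv",
                        package = "nat2typer", mustWork = TRUE)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Classify a genotype frequency table into phenotype classes
#'
#' Each row's genotype label is parsed into a star-allele pair, classified
#' with the zero/one/two-defective-allele rule using the allele table's
#' functions, and the printed frequencies are summed per phenotype class.
#' Rows naming an allele absent from the table are routed to `ND`.
#'
#' @param rows data frame with columns `genotype` and `freq_pct` (e.g.
#'   [genotype_frequencies_brazil()]).
#' @param table a [nat2_allele_table()].
#' @return list with `sums` (named numeric: summed `freq_pct` per class) and
#'   `rows` (input with a `phenotype` column appended).
#' @examples
#' pp <- phenotype_partition(genotype_frequencies_brazil())
#' pp$sums
#' @export
phenotype_partition <- function(rows, table = nat2_allele_table()) {
  pheno <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    al <- parse_genotype_label(rows$genotype[i])
    if (!all(al %in% table$name)) {
      pheno[i] <- "ND"
      next
    }
    f1 <- table$func[match(al[1], table$name)]
    f2 <- table$func[match(al[2], table$name)]
    pheno[i] <- infer_phenotype(f1, f2)$phenotype
  }
  rows$phenotype <- pheno
  sums <- vapply(c("rapid", "intermediate", "slow", "ND"), function(cl)
    sum(rows$freq_pct[pheno == cl]), 0)
  list(sums = sums, rows = rows)
}
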