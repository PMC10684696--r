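make_typed <- function(pairs, stratum = "all") {
  f <- function(n) ALLELES$func[match(n, ALLELES$name)]
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    a <- pairs[[i]]
    ph <- infer_phenotype(f(a[1]), f(a[2]))
    data.frame(sample_id = paste0("s", i), stratum = stratum,
               allele1 = min(a), allele2 = max(a),
               group1 = ALLELES$group[match(min(a), ALLELES$name)],
               group2 = ALLELES$group[match(max(a), ALLELES$name)],
               func1 = f(min(a)), func2 = f(max(a)),
               phenotype = ph$phenotype,
               defective_count = ph$defective_count,
               phased = TRUE, stringsAsFactors = FALSE)
  }))
}

test_that("frequency counting follows chromosome-counting conventions", {
  typed <- make_typed(rep(list(c("NAT2*4", "NAT2*4")), 10))
  ft <- count_frequencies(typed, "allele")$all
  expect_identical(unname(ft$counts["NAT2*4"]), 20)
  expect_identical(ft$n_total, 20)

  typed2 <- make_typed(list(c("NAT2*5B", "NAT2*6A")))
  gt <- count_frequencies(typed2, "genotype")$all
  expect_identical(names(gt$counts), "NAT2*5B/NAT2*6A")
  at <- count_frequencies(typed2, "allele")$all
  expect_identical(unname(at$counts[c("NAT2*5B", "NAT2*6A")]), c(1, 1))

  # round-trip: counted frequencies equal the generator's empirical truth
  spec <- region_cohort_spec("Northeast", n = 150, seed = 21)
  cohort <- sample_cohort(spec, ALLELES, CATALOG)
  res <- phase_genotypes(cohort$genotypes)
  typed3 <- type_samples(res$diplotypes, CATALOG, ALLELES)
  ph <- typed3$phased
  called <- count_frequencies(typed3, "allele")$Northeast
  truth_names <- c(cohort$truth$hap1[ph], cohort$truth$hap2[ph])
  truth_names[truth_names == "other"] <- "novel"
  truth_counts <- table(truth_names)
  for (nm in names(truth_counts))
    expect_identical(unname(called$counts[nm]),
                     as.numeric(truth_counts[[nm]]), label = nm)
})

test_that("weighted aggregation pools counts, not percentages", {
  # two equal-n strata at frequencies 0 and 1 pool to 0.5
  a <- freq_table(c(x = 0, y = 10), "allele", "A")
  b <- freq_table(c(x = 10, y = 0), "allele", "B")
  pooled <- aggregate_weighted(list(a, b))
  expect_equal(unname(frequencies(pooled)["x"]), 0.5)

  # identity on a single table
  one <- aggregate_weighted(list(a))
  expect_identical(one$counts, a$counts)
  expect_identical(one$n_total, a$n_total)

  # pooling equals direct counting on the concatenated cohort
  t1 <- make_typed(list(c("NAT2*4", "NAT2*5B"), c("NAT2*4", "NAT2*4")), "P")
  t2 <- make_typed(list(c("NAT2*5B", "NAT2*5B")), "Q")
  both <- rbind(t1, t2)
  pooled2 <- aggregate_weighted(count_frequencies(both, "allele"))
  direct <- count_frequencies(both, "allele", by = NULL)$all
  expect_identical(pooled2$counts[sort(names(pooled2$counts))],
                   direct$counts[sort(names(direct$counts))])

  expect_error(
    aggregate_weighted(list(a, freq_table(c(x = 1), "phenotype", "C"))),
    "mixed units")
})

test_that("regional allele rows pool to the national frequencies", {
  tab <- allele_frequencies_regions()
  regional <- tab[tab$region != "Total", ]
  tables <- lapply(seq_len(nrow(regional)), function(i)
    freq_from_percent(unlist(regional[i, -(1:2)]), regional$n_alleles[i],
                      "allele", regional$region[i]))
  pooled <- aggregate_weighted(tables)
  pct <- 100 * frequencies(pooled)
  expect_equal(unname(pct["NAT2*4"]), 20.4, tolerance = 0.1 / 20.4)
  expect_equal(unname(pct["NAT2*5B"]), 29.3, tolerance = 0.1 / 29.3)
  expect_equal(unname(pct["NAT2*6A"]), 17.1, tolerance = 0.1 / 17.1)
})

test_that("HWE exact test matches analytic expectations", {
  expect_gt(hwe_exact_test(25, 50, 25), 0.99)   # perfect equilibrium
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)    # total heterozygote deficit
  expect_identical(hwe_exact_test(40, 0, 0), 1.0)  # monomorphic convention
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")
})

test_that("HWE exact test agrees with the random-pairing oracle", {
  # the worked small example
  expect_equal(hwe_exact_test(3, 5, 2), oracle_hwe_p(3, 5, 2),
               tolerance = 1e-12)
  # random genotype-count triples with n <= 50
  set.seed(11)
  for (r in 1:25) {
    n <- sample(5:50, 1)
    g <- sample(0:2, n, TRUE, prob = c(0.4, 0.4, 0.2))
    counts <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 oracle_hwe_p(counts[1], counts[2], counts[3]),
                 tolerance = 1e-9,
                 label = paste(counts, collapse = "/"))
  }
})

test_that("hwe_scan covers all catalogued sites of a synthetic cohort", {
  spec <- region_cohort_spec("Southeast", n = 400, seed = 31)
  gt <- sample_cohort(spec, ALLELES, CATALOG)$genotypes
  scan <- hwe_scan(gt)
  expect_identical(scan$c_position, CATALOG$c_position)
  expect_true(all(scan$n_AA + scan$n_Aa + scan$n_aa == 400L))
  # cohort is HWE by construction: no site wildly out of equilibrium
  expect_gt(min(scan$p), 1e-4)
})

test_that("chi-square comparison equals the hand-computed Pearson statistic", {
  # identical distributions: chi2 = 0, p = 1
  a <- freq_table(c(x = 30, y = 70), "allele", "A")
  same <- chi2_compare(a, freq_table(c(x = 30, y = 70), "allele", "B"))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # carrier-style 2x2 built from printed regional counts
  rs <- freq_table(c("*5B" = 107, other = 371), "allele", "RS")
  pr <- freq_table(c("*5B" = 11, other = 7), "allele", "PR")
  got <- chi2_compare(rs, pr, item = "*5B")
  oracle <- hand_pearson(rbind(c(107, 371), c(11, 7)))
  expect_equal(got$chi2, oracle$chi2, tolerance = 1e-12)
  expect_identical(got$df, 1L)
  expect_equal(got$p, oracle$p, tolerance = 1e-12)

  # symmetry in the two strata and invariance under item relabeling
  rev <- chi2_compare(pr, rs, item = "*5B")
  expect_equal(rev$chi2, got$chi2)
  relab <- chi2_compare(
    freq_table(c(q = 107, z = 371), "allele", "RS"),
    freq_table(c(q = 11, z = 7), "allele", "PR"), item = "q")
  expect_equal(relab$chi2, got$chi2)

  # guards
  expect_error(chi2_compare(a, freq_table(c(x = 1), "phenotype", "B")),
               "different units")
  expect_warning(
    chi2_compare(freq_table(c(x = 1, y = 400), "allele", "A"),
                 freq_table(c(x = 0, y = 200), "allele", "B"), item = "x"),
    "expected cell")
})

test_that("regional phenotype distributions separate at cohort scale", {
  # South vs Southeast at n = 500 per arm: the full 2x3 phenotype
  # comparison should be significant in essentially every replicate
  sig <- logical(20)
  for (r in 1:20) {
    spec <- region_cohort_spec(c("South", "Southeast"), n = 500,
                               seed = 1000 + r)
    truth <- sample_cohort(spec, ALLELES, CATALOG)$truth
    keep <- truth$phenotype != "ND"
    tabs <- lapply(c("South", "Southeast"), function(s) {
      counts <- table(truth$phenotype[keep & truth$stratum == s])
      freq_table(setNames(as.numeric(counts), names(counts)),
                 "phenotype", s)
    })
    cmp <- chi2_compare(tabs[[1]], tabs[[2]])
    expect_identical(cmp$df, 2L)
    sig[r] <- cmp$p < 0.05
  }
  expect_gte(mean(sig), 0.95)
})

test_that("multi-allelic HWE chi-square runs on typed cohorts", {
  spec <- region_cohort_spec("North", n = 300, seed = 41)
  cohort <- sample_cohort(spec, ALLELES, CATALOG)
  typed <- type_samples(phase_genotypes(cohort$genotypes)$diplotypes,
                        CATALOG, ALLELES)
  res <- hwe_genotype_chisq(typed, pool_below = 0.05)
  expect_gt(res$df, 0)
  expect_gte(res$p, 0.001)  # HWE holds by construction
})
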