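test_that("pair enumeration yields 2^(k-1) unordered pairs", {
  # fully homozygous: a single pair of identical haplotypes
  p0 <- enumerate_pairs(c(0L, 2L, 0L))
  expect_identical(nrow(p0), 1L)
  expect_identical(unname(p0[1, "h1"]), unname(p0[1, "h2"]))

  expect_identical(nrow(enumerate_pairs(c(1L, 0L))), 1L)
  expect_identical(nrow(enumerate_pairs(c(1L, 1L, 0L))), 2L)

  # k = 5: cross-check the count against brute-force enumeration of all
  # ordered haplotype pairs summing to the genotype
  g <- rep(1L, 5)
  pairs <- enumerate_pairs(g)
  expect_identical(nrow(pairs), 16L)
  hm <- as.matrix(expand.grid(rep(list(0:1), 5)))
  brute <- character(0)
  for (a in seq_len(32)) for (b in seq_len(32))
    if (all(hm[a, ] + hm[b, ] == g)) {
      ha <- paste(hm[a, ], collapse = ""); hb <- paste(hm[b, ], collapse = "")
      brute <- c(brute, paste(min(ha, hb), max(ha, hb)))
    }
  expect_identical(sort(paste(pairs[, 1], pairs[, 2])), sort(unique(brute)))
  expect_identical(nrow(pairs), length(unique(brute)))

  expect_error(enumerate_pairs(rep(1L, 13)), "combinatorial")
})

test_that("EM fixed points match direct counting on degenerate cohorts", {
  # all samples homozygous for one haplotype
  fit1 <- hap_em(matrix(2L, nrow = 10, ncol = 3))
  expect_equal(unname(coef(fit1)), 1)
  expect_identical(names(coef(fit1)), "111")

  # two homozygous classes, no double heterozygotes: 50/50
  g <- rbind(matrix(0L, 50, 2), matrix(2L, 50, 2))
  fit2 <- hap_em(g)
  expect_equal(sort(unname(coef(fit2))), c(0.5, 0.5))
  expect_setequal(names(coef(fit2)), c("00", "11"))

  # cohorts with at most one het site reduce to chromosome counting
  g3 <- matrix(c(0L, 1L, 1L, 2L, 0L, 2L, 1L), ncol = 1)
  fit3 <- hap_em(g3)
  n_alt <- sum(g3)
  expect_equal(unname(coef(fit3)[c("0", "1")]),
               c(1 - n_alt / 14, n_alt / 14))
})

test_that("EM log-likelihood is non-decreasing on random cohorts", {
  for (sd in 1:5) {
    set.seed(sd)
    tf <- runif(8); tf <- tf / sum(tf)
    names(tf) <- apply(as.matrix(expand.grid(rep(list(0:1), 3))), 1,
                       paste, collapse = "")
    g <- draw_geno(tf, 40, seed = sd)
    fit <- hap_em(g)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_true(fit$converged)
  }
})

test_that("EM matches the dense brute-force oracle on small cohorts", {
  for (sd in 1:3) {
    set.seed(sd)
    tf <- runif(8); tf <- tf / sum(tf)
    names(tf) <- apply(as.matrix(expand.grid(rep(list(0:1), 3))), 1,
                       paste, collapse = "")
    g <- draw_geno(tf, 25, seed = sd + 100)
    fit <- hap_em(g, tol = 1e-12, max_iter = 5000)
    oracle <- brute_em(g)
    est <- coef(fit)
    expect_equal(unname(oracle[names(est)]), unname(est), tolerance = 1e-6)
    # mass outside the implementation's support is negligible
    expect_lt(sum(oracle[setdiff(names(oracle), names(est))]), 1e-8)
  }
})

test_that("MAP posteriors follow the closed form and the tie convention", {
  # fit on data engineered to the target frequencies
  # {AB: .45, ab: .45, Ab: .05, aB: .05} via exact homozygote counts
  g <- rbind(
    matrix(rep(c(0L, 0L), 45), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 2L), 45), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 0L), 5), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 2L), 5), ncol = 2, byrow = TRUE)
  )
  fit <- hap_em(g)
  expect_equal(unname(coef(fit)[c("00", "11", "10", "01")]),
               c(.45, .45, .05, .05), tolerance = 1e-9)

  dh <- predict(fit, newdata = matrix(c(1L, 1L), 1))
  expect_identical(c(dh$hap1, dh$hap2), c("00", "11"))
  expect_equal(dh$posterior, 2 * .45 * .45 / (2 * .45 * .45 + 2 * .05 * .05),
               tolerance = 1e-9)
  expect_true(dh$phased)

  # symmetric frequencies: posterior exactly 1/2, unphased at the 0.90 rule
  g_sym <- rbind(
    matrix(rep(c(0L, 0L), 25), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 2L), 25), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 0L), 25), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 2L), 25), ncol = 2, byrow = TRUE)
  )
  fit_sym <- hap_em(g_sym)
  dh2 <- predict(fit_sym, newdata = matrix(c(1L, 1L), 1))
  expect_equal(dh2$posterior, 0.5, tolerance = 1e-9)
  expect_false(dh2$phased)
  # tie broken to the lexicographically smallest pair
  expect_identical(c(dh2$hap1, dh2$hap2), c("00", "11"))

  # at most one het site: posterior exactly 1
  dh3 <- predict(fit, newdata = rbind(c(0L, 0L), c(1L, 0L)))
  expect_equal(dh3$posterior, c(1, 1))
  expect_true(all(dh3$phased))

  # genotype incompatible with every positive-frequency haplotype
  fit_c <- hap_em(matrix(0L, 10, 2))
  dh4 <- predict(fit_c, newdata = matrix(c(2L, 2L), 1))
  expect_equal(dh4$posterior, 0)
  expect_false(dh4$phased)
})

test_that("parameter recovery: frequencies from a regional preset, n = 2000", {
  preset <- region_presets()$South
  hmap <- preset_hap_map(preset)
  truth <- setNames(as.numeric(preset), unname(hmap[names(preset)]))
  g <- draw_geno(truth, 2000, seed = 7)
  fit <- hap_em(g)
  est <- coef(fit)
  items <- union(names(est), names(truth))
  e <- ifelse(is.na(est[items]), 0, est[items])
  t_ <- ifelse(is.na(truth[items]), 0, truth[items])
  rmse <- sqrt(mean((e - t_)^2))
  expect_lt(rmse, 0.01)
  # every individual frequency within +/- 0.02 of truth
  expect_true(all(abs(e - t_) < 0.02))
})

test_that("missingness handling: few missing sites phased, many excluded", {
  preset <- region_presets()$Southeast
  hmap <- preset_hap_map(preset)
  g <- draw_geno(setNames(as.numeric(preset), unname(hmap[names(preset)])),
                 100, seed = 9)
  g[1, 1:2] <- NA   # phaseable by fill-in enumeration
  g[2, 1:4] <- NA   # beyond the cap: excluded
  fit <- hap_em(g)
  expect_identical(fit$excluded, "s2")
  expect_identical(fit$n, 99L)
  dip <- predict(fit)
  expect_false(dip$phased[2])
  expect_true(is.na(dip$hap1[2]))
})

test_that("unphased fraction on a national-scale synthetic cohort is small", {
  spec <- region_cohort_spec(
    c("North", "Northeast", "Midwest", "Southeast", "South"),
    n = c(189, 78, 106, 335, 248), seed = 5)
  res <- phase_genotypes(sample_cohort(spec, ALLELES, CATALOG)$genotypes)
  expect_lt(mean(!res$diplotypes$phased), 0.05)
})

test_that("hap_em methods behave like a standard model object", {
  g <- draw_geno(c("00" = .6, "11" = .4), 30, seed = 1)
  fit <- hap_em(g)
  expect_s3_class(fit, "hap_em")
  expect_output(print(fit), "Haplotype-frequency EM fit")
  expect_output(print(summary(fit)), "haplotype frequencies")
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$loglik_trace[fit$n_iter])
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]), dim(g))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
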