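# Haplotype phasing: Excoffier-Slatkin EM over unphased multi-site diploid
# genotypes, with maximum-posterior diplotype assignment.
#
# Haplotypes are represented as strings of '0'/'1' over the catalogued sites
# (column order of the genotype matrix); '1' marks the alternate allele.

# ---- pair enumeration ------------------------------------------------------

#' Enumerate the haplotype pairs compatible with an unphased genotype
#'
#' For a genotype with `k` heterozygous sites there are `2^(k-1)` unordered
#' compatible pairs (`1` pair for `k` of 0 or 1).
#'
#' @param g integer vector of alt dosages (0/1/2) over the sites; no missing
#'   values.
#' @param max_het maximum number of heterozygous sites accepted before a
#'   combinatorial-explosion error is raised (default 12).
#' @return character matrix with columns `h1`, `h2`; one row per unordered
#'   pair, `h1 <= h2` lexicographically.
#' @examples
#' enumerate_pairs(c(1L, 1L, 0L))  # 2 pairs
#' @export
enumerate_pairs <- function(g, max_het = 12) {
  if (anyNA(g)) stop("enumerate_pairs() requires complete genotypes")
  het <- which(g == 1L)
  k <- length(het)
  if (k > max_het)
    stop("combinatorial explosion: ", k, " heterozygous sites exceeds the ",
         "cap of ", max_het)
  base <- ifelse(g == 2L, "1", "0")
  if (k == 0L) {
    h <- paste(base, collapse = "")
    return(matrix(c(h, h), 1L, 2L, dimnames = list(NULL, c("h1", "h2"))))
  }
  n_pairs <- 2L^(k - 1L)
  out <- matrix("", n_pairs, 2L, dimnames = list(NULL, c("h1", "h2")))
  for (m in seq_len(n_pairs) - 1L) {
    a <- base; b <- base
    a[het[1L]] <- "0"; b[het[1L]] <- "1"   # fix first het site: kills mirror pairs
    if (k > 1L) {
      bits <- as.integer(intToBits(m))[seq_len(k - 1L)]
      a[het[-1L]] <- as.character(bits)
      b[het[-1L]] <- as.character(1L - bits)
    }
    ha <- paste(a, collapse = ""); hb <- paste(b, collapse = "")
    if (ha <= hb) out[m + 1L, ] <- c(ha, hb) else out[m + 1L, ] <- c(hb, ha)
  }
  out
}

# pairs for a genotype that may have missing sites: enumerate every fill-in
# (0/1/2 per missing site) and pool the resulting pairs
enumerate_pairs_missing <- function(g, max_het = 12, max_missing = 2) {
  miss <- which(is.na(g))
  if (length(miss) == 0L) return(enumerate_pairs(g, max_het))
  if (length(miss) > max_missing)
    stop("too many missing sites (", length(miss), " > ", max_missing, ")")
  fills <- expand.grid(rep(list(0:2), length(miss)))
  out <- vector("list", nrow(fills))
  for (i in seq_len(nrow(fills))) {
    gi <- g
    gi[miss] <- as.integer(unlist(fills[i, ]))
    out[[i]] <- enumerate_pairs(gi, max_het)
  }
  do.call(rbind, out)
}

# ---- EM fit ----------------------------------------------------------------

#' Estimate haplotype frequencies by EM
#'
#' Excoffier-Slatkin gene-counting EM for haplotype frequencies at a single
#' multi-SNP locus.  In the E-step the posterior of each compatible pair
#' `(h1, h2)` of a sample is proportional to `2^[h1 != h2] f(h1) f(h2)`; the
#' M-step sets each frequency to its expected chromosome count over `2N`.
#' Iteration stops when the log-likelihood gain drops below `tol` or after
#' `max_iter` iterations.  The log-likelihood is non-decreasing across
#' iterations.
#'
#' Samples with more than `max_missing` missing catalogued calls are excluded
#' (and listed in the fit); samples with at most `max_missing` missing sites
#' are handled by summing over every fill-in.  Deterministic given the data:
#' initialisation is uniform over the observed-compatible haplotypes, and
#' `seed` is only used when `n_restarts > 0` requests additional random
#' restarts.
#'
#' @param x a [nat2_genotypes()] object, or an integer matrix of alt dosages
#'   (samples x sites; 0/1/2/NA).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @param max_het cap on heterozygous sites per sample (default 12).
#' @param max_missing cap on missing sites per sample before exclusion
#'   (default 2).
#' @param n_restarts number of additional random restarts (default 0).
#' @param seed RNG seed for restarts; ignored when `n_restarts = 0`.
#' @return an object of class `hap_em` with components `freqs` (named,
#'   decreasing), `loglik_trace`, `n_iter`, `converged`, `excluded`
#'   (sample ids), `sites`, `geno`, `samples`, `n` (samples used).
#' @seealso [predict.hap_em()] for MAP diplotype assignment.
#' @examples
#' g <- rbind(c(0L, 0L), c(2L, 2L), c(1L, 1L))
#' fit <- hap_em(g)
#' coef(fit)
#' @export
hap_em <- function(x, tol = 1e-8, max_iter = 500, max_het = 12,
                   max_missing = 2, n_restarts = 0, seed = NULL) {
  cl <- match.call()
  if (inherits(x, "nat2_genotypes")) {
    geno <- x$geno; sites <- x$sites; samples <- x$samples
  } else {
    geno <- as.matrix(x); sites <- NULL
    samples <- data.frame(
      sample_id = if (is.null(rownames(geno)))
        paste0("s", seq_len(nrow(geno))) else rownames(geno),
      stratum = "all", stringsAsFactors = FALSE)
  }
  if (nrow(geno) < 1L) stop("at least one genotype is required")

  n_missing <- rowSums(is.na(geno))
  use <- n_missing <= max_missing
  excluded <- samples$sample_id[!use]
  pair_list <- lapply(which(use), function(i)
    enumerate_pairs_missing(geno[i, ], max_het, max_missing))
  N <- length(pair_list)
  if (N == 0L) stop("no phaseable samples")

  all_pairs <- do.call(rbind, pair_list)
  haps <- sort(unique(as.vector(all_pairs)))
  H <- length(haps)
  i1 <- match(all_pairs[, 1L], haps)
  i2 <- match(all_pairs[, 2L], haps)
  sidx <- rep(seq_len(N), vapply(pair_list, nrow, 1L))
  mult <- ifelse(i1 == i2, 1, 2)

  run_em <- function(f) {
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      num <- mult * f[i1] * f[i2]
      denom <- as.vector(rowsum(num, sidx))
      if (any(!is.finite(denom)) || any(denom <= 0))
        stop("non-finite likelihood in EM")
      ll <- sum(log(denom))
      trace <- c(trace, ll)
      w <- num / denom[sidx]
      counts <- as.vector(rowsum(c(w, w), c(i1, i2)))
      # rowsum() orders groups ascending; some hap indices may be absent
      grp <- sort(unique(c(i1, i2)))
      cnt <- numeric(H); cnt[grp] <- counts
      f_new <- cnt / (2 * N)
      if (it > 1L && trace[it] - trace[it - 1L] < tol) {
        converged <- TRUE
        f <- f_new
        break
      }
      f <- f_new
    }
    list(f = f, trace = trace, converged = converged)
  }

  best <- run_em(rep(1 / H, H))
  if (n_restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(n_restarts)) {
      f0 <- runif(H); f0 <- f0 / sum(f0)
      cand <- run_em(f0)
      if (max(cand$trace) > max(best$trace)) best <- cand
    }
  }

  f <- best$f
  names(f) <- haps
  f <- f[f >= 1e-12]
  f <- f / sum(f)
  f <- sort(f, decreasing = TRUE)

  structure(list(
    freqs = f, loglik_trace = best$trace, n_iter = length(best$trace),
    converged = best$converged, excluded = excluded,
    sites = sites, geno = geno, samples = samples, n = N,
    max_het = max_het, max_missing = max_missing, call = cl
  ), class = "hap_em")
}

#' @export
print.hap_em <- function(x, ...) {
  cat("Haplotype-frequency EM fit (", x$n, " samples, ",
      length(x$freqs), " haplotypes)\n", sep = "")
  cat("log-likelihood: ", format(x$loglik_trace[x$n_iter]), " after ",
      x$n_iter, " iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n", sep = "")
  if (length(x$excluded))
    cat("excluded (missingness): ", length(x$excluded), " sample(s)\n", sep = "")
  top <- utils::head(x$freqs, 5L)
  cat("top haplotypes:\n")
  print(round(top, 4))
  invisible(x)
}

#' @export
summary.hap_em <- function(object, ...) {
  structure(list(
    fit = object,
    freq_table = data.frame(haplotype = names(object$freqs),
                            frequency = unname(object$freqs),
                            stringsAsFactors = FALSE)
  ), class = "summary.hap_em")
}

#' @export
print.summary.hap_em <- function(x, ...) {
  print(x$fit)
  cat("\nall haplotype frequencies:\n")
  print(x$freq_table, digits = 4)
  invisible(x)
}

#' @export
coef.hap_em <- function(object, ...) object$freqs

#' @export
logLik.hap_em <- function(object, ...) {
  structure(object$loglik_trace[object$n_iter],
            df = length(object$freqs) - 1L, nobs = object$n,
            class = "logLik")
}

#' @export
plot.hap_em <- function(x, n_top = 10, ...) {
  op <- par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(par(op))
  top <- utils::head(x$freqs, n_top)
  barplot(top, las = 2, ylab = "frequency",
          main = "haplotype frequencies", ...)
  par(mar = c(4, 4, 2, 1))
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b", pch = 16,
       xlab = "EM iteration", ylab = "log-likelihood", main = "EM trace")
  invisible(x)
}

#' Simulate genotype cohorts from a fitted haplotype-frequency model
#'
#' Draws, for each replicate, `n` diplotypes under Hardy-Weinberg equilibrium
#' (two haplotypes i.i.d. from the fitted frequencies) and returns the
#' corresponding unphased dosage matrices.
#'
#' @param object a `hap_em` fit.
#' @param nsim number of replicate cohorts.
#' @param seed optional RNG seed.
#' @param n samples per cohort (default: the fitted cohort size).
#' @param ... unused.
#' @return list of `nsim` integer dosage matrices.
#' @export
simulate.hap_em <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- object$n
  haps <- names(object$freqs)
  hm <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    a <- sample(length(haps), n, replace = TRUE, prob = object$freqs)
    b <- sample(length(haps), n, replace = TRUE, prob = object$freqs)
    g <- hm[a, , drop = FALSE] + hm[b, , drop = FALSE]
    rownames(g) <- paste0("sim", r, "_", seq_len(n))
    colnames(g) <- colnames(object$geno)
    out[[r]] <- g
  }
  out
}

# ---- MAP diplotype assignment ----------------------------------------------

#' Assign maximum-posterior diplotypes
#'
#' For each sample, the posterior of every compatible haplotype pair is
#' computed under the fitted frequencies and the maximum-posterior pair is
#' returned.  A sample is flagged `phased` when its posterior reaches
#' `min_posterior`; unphased samples are retained in the output (so they can
#' be counted) but are conventionally excluded from downstream allele and
#' genotype summaries.  Ties are broken by canonical (lexicographic)
#' haplotype ordering; a genotype incompatible with every positive-frequency
#' pair gets posterior 0.
#'
#' @param object a [hap_em()] fit.
#' @param newdata optional [nat2_genotypes()] object or dosage matrix; by
#'   default the training genotypes are phased.
#' @param min_posterior posterior threshold for declaring a sample phased
#'   (default 0.90).
#' @param ... unused.
#' @return data frame with `sample_id`, `stratum`, `hap1`, `hap2` ('0'/'1'
#'   site strings), `posterior`, `phased`.
#' @export
predict.hap_em <- function(object, newdata = NULL, min_posterior = 0.9, ...) {
  if (is.null(newdata)) {
    geno <- object$geno; samples <- object$samples
  } else if (inherits(newdata, "nat2_genotypes")) {
    geno <- newdata$geno; samples <- newdata$samples
  } else {
    geno <- as.matrix(newdata)
    samples <- data.frame(
      sample_id = if (is.null(rownames(geno)))
        paste0("s", seq_len(nrow(geno))) else rownames(geno),
      stratum = "all", stringsAsFactors = FALSE)
  }
  f <- object$freqs
  n <- nrow(geno)
  hap1 <- hap2 <- rep(NA_character_, n)
  post <- rep(NA_real_, n)
  phased <- rep(FALSE, n)
  for (i in seq_len(n)) {
    g <- geno[i, ]
    if (sum(is.na(g)) > object$max_missing) next
    pairs <- enumerate_pairs_missing(g, object$max_het, object$max_missing)
    f1 <- f[pairs[, 1L]]; f2 <- f[pairs[, 2L]]
    f1[is.na(f1)] <- 0; f2[is.na(f2)] <- 0
    p <- ifelse(pairs[, 1L] == pairs[, 2L], 1, 2) * f1 * f2
    tot <- sum(p)
    if (tot <= 0) {
      ord <- order(pairs[, 1L], pairs[, 2L])
      hap1[i] <- pairs[ord[1L], 1L]; hap2[i] <- pairs[ord[1L], 2L]
      post[i] <- 0
      next
    }
    ord <- order(pairs[, 1L], pairs[, 2L])
    pairs <- pairs[ord, , drop = FALSE]; p <- p[ord]
    best <- which.max(p)
    hap1[i] <- pairs[best, 1L]; hap2[i] <- pairs[best, 2L]
    post[i] <- p[best] / tot
    phased[i] <- post[i] >= min_posterior
  }
  data.frame(sample_id = samples$sample_id,
             stratum = if (is.null(samples$stratum)) "all" else samples$stratum,
             hap1 = hap1, hap2 = hap2, posterior = post, phased = phased,
             stringsAsFactors = FALSE)
}

#' Fit and phase in one call
#'
#' Convenience wrapper: fits [hap_em()] on a cohort and assigns each sample
#' its maximum-posterior diplotype.
#'
#' @inheritParams hap_em
#' @param min_posterior see [predict.hap_em()].
#' @return list with `fit` (the `hap_em` object) and `diplotypes` (the
#'   prediction data frame).
#' @export
phase_genotypes <- function(x, min_posterior = 0.9, ...) {
  fit <- hap_em(x, ...)
  list(fit = fit, diplotypes = predict(fit, min_posterior = min_posterior))
}
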