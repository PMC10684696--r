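# Shared fixtures and independent oracles used across the suite.

REF <- nat2_reference()
CATALOG <- nat2_catalog(reference = REF)
ALLELES <- nat2_allele_table(reference = REF)

# ---- dense brute-force EM over the complete 2^m haplotype space ------------
# Independent of the package implementation: no restriction to
# observed-compatible haplotypes and no pair-enumeration shortcut (ordered
# pairs, explicit double loop).
brute_em <- function(geno, tol = 1e-12, max_iter = 5000) {
  m <- ncol(geno)
  hm <- as.matrix(expand.grid(rep(list(0:1), m)))
  H <- nrow(hm)
  hstr <- apply(hm, 1, paste, collapse = "")
  pairs <- lapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    ij <- NULL
    for (a in seq_len(H)) for (b in seq_len(H))
      if (all(hm[a, ] + hm[b, ] == g)) ij <- rbind(ij, c(a, b))
    ij
  })
  f <- rep(1 / H, H)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    counts <- numeric(H)
    ll <- 0
    for (s in seq_along(pairs)) {
      ij <- pairs[[s]]
      w <- f[ij[, 1]] * f[ij[, 2]]
      d <- sum(w)
      ll <- ll + log(d)
      w <- w / d
      for (r in seq_len(nrow(ij))) {
        counts[ij[r, 1]] <- counts[ij[r, 1]] + w[r]
        counts[ij[r, 2]] <- counts[ij[r, 2]] + w[r]
      }
    }
    f <- counts / (2 * nrow(geno))
    if (it > 1 && ll - ll_old < tol) break
    ll_old <- ll
  }
  setNames(f, hstr)
}

# ---- exact HWE oracle by sequential random pairing -------------------------
# Distribution of the heterozygote count when n1 minor and n2 major
# chromosomes are paired at random, built by recursion on pair draws rather
# than the closed-form conditional probability.
pairing_het_dist <- function(n1, n2) {
  memo <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    key <- paste(a, b)
    if (exists(key, memo, inherits = FALSE)) return(get(key, memo))
    t <- a + b
    if (t == 0) return(c("0" = 1))
    tot <- choose(t, 2)
    out <- numeric(0)
    add <- function(dist, p, dh) {
      for (h in names(dist)) {
        k <- as.character(as.integer(h) + dh)
        out[k] <<- (if (is.na(out[k])) 0 else out[k]) + p * dist[[h]]
      }
    }
    if (a >= 2) add(rec(a - 2, b), choose(a, 2) / tot, 0L)
    if (b >= 2) add(rec(a, b - 2), choose(b, 2) / tot, 0L)
    if (a >= 1 && b >= 1) add(rec(a - 1, b - 1), a * b / tot, 1L)
    assign(key, out, memo)
    out
  }
  rec(n1, n2)
}

oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  n1 <- min(nA, 2 * n - nA)
  if (n1 == 0) return(1.0)
  dist <- pairing_het_dist(n1, 2 * n - n1)
  p_obs <- dist[[as.character(n_Aa)]]
  min(1, sum(dist[dist <= p_obs * (1 + 1e-9)]))
}

# ---- hand-computed Pearson chi-square --------------------------------------
hand_pearson <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2 <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

# ---- small helpers ---------------------------------------------------------
ref_substr <- function(from, to) substr(REF$sequence, from, to)

with_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# genotype matrix of a cohort drawn from given haplotype-string frequencies
draw_geno <- function(freqs, n, seed) {
  set.seed(seed)
  hm <- do.call(rbind, lapply(strsplit(names(freqs), ""), as.integer))
  a <- sample(length(freqs), n, TRUE, freqs)
  b <- sample(length(freqs), n, TRUE, freqs)
  g <- hm[a, , drop = FALSE] + hm[b, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

# allele-name -> haplotype-string map for a frequency preset
preset_hap_map <- function(freqs) {
  vapply(names(freqs), function(a) {
    tokens <- if (a == "other") "c.345C>T" else {
      k <- ALLELES$key[match(a, ALLELES$name)]
      if (k == "") character(0) else strsplit(k, ",")[[1]]
    }
    tokens_to_hap(tokens, CATALOG)
  }, "")
}
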