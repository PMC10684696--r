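# Typing: haplotypes -> star alleles and allelic groups; diplotypes ->
# acetylator phenotypes.

#' Convert a binary haplotype string to SNP tokens
#'
#' @param hap haplotype as a '0'/'1' string over the catalogue sites.
#' @param sites the `nat2_catalog` rows corresponding to the string positions.
#' @return character vector of tokens such as `"c.341T>C"` (empty for the
#'   reference haplotype).
#' @export
hap_to_tokens <- function(hap, sites) {
  bits <- as.integer(strsplit(hap, "")[[1]])
  if (length(bits) != nrow(sites))
    stop("haplotype string length does not match the site catalogue")
  format_snp_token(sites[bits == 1L, , drop = FALSE])
}

#' Convert SNP tokens to a binary haplotype string
#' @param tokens character vector of SNP tokens (possibly empty).
#' @param sites the `nat2_catalog` data frame.
#' @return '0'/'1' string over the catalogue sites.
#' @export
tokens_to_hap <- function(tokens, sites) {
  bits <- rep("0", nrow(sites))
  if (length(tokens)) {
    pos <- parse_snp_token(tokens)$c_position
    j <- match(pos, sites$c_position)
    if (anyNA(j)) stop("token position not in catalogue: c.", pos[is.na(j)][1])
    bits[j] <- "1"
  }
  paste(bits, collapse = "")
}

#' Assign a haplotype to its allelic group by signature SNP
#'
#' Allelic groups are defined by the presence of one signature SNP relative
#' to the reference allele.  The signatures are checked in a fixed priority
#' order — the four slow signatures (c.191G>A for \*14, c.341T>C for \*5,
#' c.590G>A for \*6, c.857G>A for \*7) before the phenotype-neutral ones
#' (c.803A>G for \*12, c.481C>T for \*11, c.282C>T for \*13, and the
#' table-driven extension c.622T>C for \*28) — because common alleles stack
#' several signatures (e.g. NAT2\*5B carries c.481C>T and c.803A>G yet
#' belongs to \*5; \*12C carries c.481C>T yet belongs to \*12).  The empty
#' haplotype is the reference group \*4; a non-empty haplotype carrying no
#' mapped signature also falls back to \*4 (signature-equivalent to the
#' reference).
#'
#' @param tokens character vector of SNP tokens carried by the haplotype.
#' @param signatures named character vector token -> group, in priority
#'   order; defaults to the shipped signature map.
#' @return group symbol, e.g. `"*5"`.
#' @examples
#' allelic_group(c("c.191G>A", "c.282C>T"))  # "*14"
#' allelic_group(c("c.282C>T", "c.803A>G"))  # "*12"
#' @export
allelic_group <- function(tokens, signatures = .DEFAULT_SIGNATURES) {
  for (sig in names(signatures))
    if (sig %in% tokens) return(unname(signatures[sig]))
  "*4"
}

#' Match a haplotype to a star allele
#'
#' An exact SNP-set match against the allele table returns the named allele
#' with its function; otherwise the haplotype is reported as `"novel"`, its
#' group is still assigned by signature, and its function is `slow` when it
#' carries a slow-signature SNP (c.191G>A, c.341T>C, c.590G>A or c.857G>A)
#' and `unknown` otherwise.
#'
#' @param tokens character vector of SNP tokens (or a '0'/'1' haplotype
#'   string when `sites` is supplied).
#' @param table a [nat2_allele_table()].
#' @param sites optional catalogue for string input.
#' @return list with `name`, `group`, `func`, `exact_match`, `tokens`.
#' @examples
#' tab <- nat2_allele_table()
#' assign_allele(c("c.341T>C", "c.481C>T", "c.803A>G"), tab)$name  # NAT2*5B
#' @export
assign_allele <- function(tokens, table, sites = NULL) {
  if (length(tokens) == 1L && grepl("^[01]+$", tokens) && !is.null(sites))
    tokens <- hap_to_tokens(tokens, sites)
  key <- hap_key(tokens)
  signatures <- attr(table, "signatures")
  i <- match(key, table$key)
  if (!is.na(i))
    return(list(name = table$name[i], group = table$group[i],
                func = table$func[i], exact_match = TRUE, tokens = tokens))
  list(name = "novel",
       group = allelic_group(tokens, signatures),
       func = if (any(tokens %in% .SLOW_SIGNATURES)) "slow" else "unknown",
       exact_match = FALSE, tokens = tokens)
}

#' Infer the acetylator phenotype of a diplotype
#'
#' Trimodal rule: slow, intermediate and rapid acetylators carry two, one or
#' no defective (slow-function) alleles, respectively.  If either allele's
#' function is unknown the phenotype is not determinable (`"ND"`).
#' Symmetric in its two arguments.
#'
#' @param func1,func2 allele functions: `"rapid"`, `"slow"` or `"unknown"`.
#' @return list with `phenotype` (`rapid`/`intermediate`/`slow`/`ND`) and
#'   `defective_count` (0-2, or `NA` for ND).
#' @examples
#' infer_phenotype("slow", "slow")$phenotype    # "slow"
#' infer_phenotype("rapid", "slow")$phenotype   # "intermediate"
#' @export
infer_phenotype <- function(func1, func2) {
  ok <- c("rapid", "slow", "unknown")
  if (!(func1 %in% ok) || !(func2 %in% ok))
    stop("allele function must be rapid, slow or unknown")
  if (func1 == "unknown" || func2 == "unknown")
    return(list(phenotype = "ND", defective_count = NA_integer_))
  d <- sum(c(func1, func2) == "slow")
  list(phenotype = c("rapid", "intermediate", "slow")[d + 1L],
       defective_count = as.integer(d))
}

#' Type phased samples: star alleles, groups and phenotypes
#'
#' Applies [assign_allele()] to both haplotypes of every phased diplotype and
#' [infer_phenotype()] to the pair.  Unphased samples are retained with `NA`
#' alleles and phenotype `"unphased"` so they can be tallied.
#'
#' @param diplotypes output of [predict.hap_em()].
#' @param sites the `nat2_catalog` used for phasing.
#' @param table a [nat2_allele_table()].
#' @return data frame with `sample_id`, `stratum`, `allele1`, `allele2`,
#'   `group1`, `group2`, `func1`, `func2`, `phenotype`, `defective_count`,
#'   `phased`.
#' @export
type_samples <- function(diplotypes, sites, table = nat2_allele_table()) {
  n <- nrow(diplotypes)
  out <- data.frame(
    sample_id = diplotypes$sample_id, stratum = diplotypes$stratum,
    allele1 = NA_character_, allele2 = NA_character_,
    group1 = NA_character_, group2 = NA_character_,
    func1 = NA_character_, func2 = NA_character_,
    phenotype = "unphased", defective_count = NA_integer_,
    phased = diplotypes$phased, stringsAsFactors = FALSE
  )
  cache <- new.env(parent = emptyenv())
  lookup <- function(hap) {
    if (exists(hap, envir = cache, inherits = FALSE))
      return(get(hap, envir = cache))
    res <- assign_allele(hap_to_tokens(hap, sites), table)
    assign(hap, res, envir = cache)
    res
  }
  for (i in seq_len(n)) {
    if (!isTRUE(diplotypes$phased[i])) next
    a1 <- lookup(diplotypes$hap1[i])
    a2 <- lookup(diplotypes$hap2[i])
    ph <- infer_phenotype(a1$func, a2$func)
    # canonical order: alphabetical allele names for stable genotype labels
    if (a2$name < a1$name) { tmp <- a1; a1 <- a2; a2 <- tmp }
    out$allele1[i] <- a1$name; out$allele2[i] <- a2$name
    out$group1[i] <- a1$group; out$group2[i] <- a2$group
    out$func1[i] <- a1$func; out$func2[i] <- a2$func
    out$phenotype[i] <- ph$phenotype
    out$defective_count[i] <- ph$defective_count
  }
  out
}

#' Parse a genotype label such as `"*5B/*6A"`
#'
#' Accepts labels with or without the `NAT2` prefix on either side.
#'
#' @param label character, `"<allele>/<allele>"`.
#' @return character vector of two full allele names (`"NAT2*..."`).
#' @export
parse_genotype_label <- function(label) {
  parts <- trimws(strsplit(label, "/")[[1]])
  if (length(parts) != 2L) stop("genotype label must be 'allele/allele': ", label)
  vapply(parts, function(p) {
    if (startsWith(p, "*")) paste0("NAT2", p) else p
  }, "", USE.NAMES = FALSE)
}
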