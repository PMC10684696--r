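# Variant calling: merge sequencing fragments, align a sample's consensus
# sequence to the reference exon, and decode per-site diploid genotypes from
# IUPAC ambiguity codes.

# ---- genotype container ----------------------------------------------------

#' Construct a genotype-set container
#'
#' Internal canonical container shared by the caller and the synthetic
#' generator: an integer matrix of per-site diploid calls coded as alt-allele
#' dosage (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing), plus per-sample metadata.
#'
#' @param geno integer matrix, samples x catalogued sites; column names are
#'   c.-positions as characters.
#' @param sites the `nat2_catalog` rows the columns refer to (same order).
#' @param samples data frame with at least `sample_id`; optional `stratum`.
#' @return object of class `nat2_genotypes`.
#' @export
nat2_genotypes <- function(geno, sites, samples) {
  stopifnot(is.matrix(geno), nrow(geno) == nrow(samples),
            ncol(geno) == nrow(sites))
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  colnames(geno) <- as.character(sites$c_position)
  rownames(geno) <- samples$sample_id
  if (is.null(samples$stratum)) samples$stratum <- "all"
  samples$het_count <- as.integer(rowSums(geno == 1L, na.rm = TRUE))
  samples$n_missing <- as.integer(rowSums(is.na(geno)))
  structure(list(geno = geno, sites = sites, samples = samples),
            class = "nat2_genotypes")
}

#' @export
print.nat2_genotypes <- function(x, ...) {
  cat("NAT2 unphased genotypes: ", nrow(x$geno), " samples x ",
      ncol(x$geno), " sites\n", sep = "")
  cat("strata: ", paste(unique(x$samples$stratum), collapse = ", "), "\n",
      sep = "")
  cat("heterozygous sites per sample: median ",
      stats::median(x$samples$het_count), ", max ",
      max(x$samples$het_count), "\n", sep = "")
  invisible(x)
}

# ---- fragment merging ------------------------------------------------------

#' Merge forward and reverse sequencing fragments into one consensus
#'
#' The exon is sequenced as two overlapping fragments in opposite
#' orientations.  The reverse fragment is supplied in sequencing orientation
#' and is reverse-complemented here; the two reads are then joined over their
#' best overlap.  Within the overlap, identical calls are kept; a plain base
#' against a compatible ambiguity code resolves to the ambiguity code; two
#' incompatible calls resolve to `N`.
#'
#' @param forward,reverse character sequences (IUPAC letters); `reverse` in
#'   sequencing orientation (i.e. reverse-complement of the coding strand).
#' @param min_overlap minimum acceptable overlap length (default 30).
#' @return merged consensus sequence on the coding strand.
#' @export
merge_fragments <- function(forward, reverse, min_overlap = 30) {
  fwd <- toupper(forward)
  rev <- toupper(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(reverse)))))
  nf <- nchar(fwd); nr <- nchar(rev)
  if (min(nf, nr) < min_overlap)
    stop("fragments do not overlap by at least ", min_overlap,
         " compatible bases")
  fchars <- strsplit(fwd, "")[[1]]
  rchars <- strsplit(rev, "")[[1]]
  best <- NULL
  for (L in seq(min(nf, nr), min_overlap)) {
    a <- fchars[(nf - L + 1L):nf]
    b <- rchars[1:L]
    comp <- mapply(iupac_compatible, a, b)
    ncomp <- sum(comp)
    if (ncomp / L >= 0.9) {
      if (is.null(best) || ncomp > best$ncomp)
        best <- list(L = L, ncomp = ncomp)
    }
  }
  if (is.null(best))
    stop("fragments do not overlap by at least ", min_overlap,
         " compatible bases")
  L <- best$L
  ov <- character(L)
  for (i in seq_len(L))
    ov[i] <- iupac_consensus(fchars[nf - L + i], rchars[i])
  paste0(substr(fwd, 1, nf - L), paste(ov, collapse = ""),
         substr(rev, L + 1L, nr))
}

# ---- alignment -------------------------------------------------------------

#' Align a sample consensus sequence to the reference exon
#'
#' Pairwise alignment with affine gap penalties (match +1, mismatch -1, gap
#' open -5, gap extend -1; end gaps free, so amplicon flanks and partial
#' coverage are tolerated).  IUPAC ambiguity codes score as a match against
#' any compatible base.  Returns a strictly monotone map between sample
#' positions and c.-coordinates.
#'
#' @param sequence character, the sample consensus (IUPAC letters allowed).
#' @param reference a [nat2_reference()] object.
#' @param min_identity minimum fraction of compatible aligned columns
#'   (default 0.8); below it a quality error is raised.
#' @param min_coverage minimum fraction of `min(sample length, exon length)`
#'   that must be aligned (default 0.5); guards against spurious short
#'   overlaps of unrelated sequences.
#' @return list with `map` (data frame: `sample_pos`, `c_position`,
#'   `sample_base`, `ref_base`, `compatible`), `identity`, `coverage`, and
#'   `score`.
#' @export
align_to_reference <- function(sequence, reference, min_identity = 0.8,
                               min_coverage = 0.5) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sample sequence")
  submat <- iupac_substitution_matrix()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(sequence),
    subject = Biostrings::DNAString(reference$sequence),
    type = "overlap", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 1
  )
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  p_pos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  s_pos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  n <- length(pat)
  sample_pos <- integer(n); c_position <- integer(n)
  keep <- logical(n); compatible <- logical(n)
  for (i in seq_len(n)) {
    if (pat[i] != "-") p_pos <- p_pos + 1L
    if (sub[i] != "-") s_pos <- s_pos + 1L
    if (pat[i] != "-" && sub[i] != "-") {
      keep[i] <- TRUE
      sample_pos[i] <- p_pos
      c_position[i] <- s_pos
      compatible[i] <- iupac_compatible(pat[i], sub[i])
    }
  }
  map <- data.frame(
    sample_pos = sample_pos[keep], c_position = c_position[keep],
    sample_base = pat[keep], ref_base = sub[keep],
    compatible = compatible[keep], stringsAsFactors = FALSE
  )
  if (nrow(map) == 0L) stop("alignment quality error: no aligned positions")
  identity <- mean(map$compatible)
  coverage <- nrow(map) / min(nchar(sequence), reference$length)
  if (coverage < min_coverage)
    stop(sprintf(
      "alignment quality error: only %.0f%% of the sequence aligned",
      100 * coverage))
  if (identity < min_identity)
    stop(sprintf(
      "alignment quality error: identity %.1f%% below the %.0f%% floor",
      100 * identity, 100 * min_identity))
  list(map = map, identity = identity, coverage = coverage,
       score = Biostrings::score(aln))
}

# ---- genotype calling ------------------------------------------------------

# decode one aligned base at a catalogued site into an alt dosage
decode_site <- function(base, ref, alt) {
  set <- iupac_bases(base)
  if (length(set) == 1L) {
    if (set == ref) return(0L)
    if (set == alt) return(2L)
    return(NA_integer_)            # third base: missing (novel logged upstream)
  }
  if (length(set) == 2L && all(sort(c(ref, alt)) == set)) return(1L)
  NA_integer_                      # N, 3/4-base codes, incompatible het codes
}

#' Call an unphased genotype for one sample
#'
#' Aligns the sample consensus to the reference and decodes every catalogued
#' site it covers: a plain base is a homozygous call, a two-base IUPAC code
#' compatible with reference/alternate is a heterozygous call, and anything
#' else (gap, `N`, a third base, wider ambiguity) goes to `missing_sites`.
#' Substitutions at uncatalogued positions are reported in `novel` but take
#' no part in typing.
#'
#' @param sequence sample consensus sequence.
#' @param reference a [nat2_reference()] object.
#' @param catalog a [nat2_catalog()] data frame.
#' @param sample_id sample label.
#' @param min_identity alignment identity floor, see [align_to_reference()].
#' @return list with `sample_id`, `geno` (integer dosage vector over
#'   catalogue sites), `calls` (named `"X/Y"` strings), `het_count`,
#'   `missing_sites`, `novel` (data frame), `identity`.
#' @export
call_genotype <- function(sequence, reference, catalog, sample_id = "sample",
                          min_identity = 0.8) {
  aln <- align_to_reference(sequence, reference, min_identity = min_identity)
  map <- aln$map
  idx <- match(catalog$c_position, map$c_position)
  geno <- integer(nrow(catalog))
  for (j in seq_len(nrow(catalog))) {
    if (is.na(idx[j])) { geno[j] <- NA_integer_; next }
    geno[j] <- decode_site(map$sample_base[idx[j]],
                           catalog$ref[j], catalog$alt[j])
  }
  # novel substitutions: incompatible aligned plain bases / het codes at
  # uncatalogued positions, or third bases at catalogued ones
  mm <- map[!map$compatible, , drop = FALSE]
  novel <- mm[!(mm$c_position %in% catalog$c_position) |
                is.na(geno[match(mm$c_position, catalog$c_position)]),
              c("c_position", "ref_base", "sample_base")]
  rownames(novel) <- NULL
  calls <- character(nrow(catalog))
  for (j in seq_len(nrow(catalog))) {
    calls[j] <- switch(as.character(geno[j]),
      "0" = paste(catalog$ref[j], catalog$ref[j], sep = "/"),
      "1" = paste(catalog$ref[j], catalog$alt[j], sep = "/"),
      "2" = paste(catalog$alt[j], catalog$alt[j], sep = "/"),
      "./.")
  }
  names(calls) <- as.character(catalog$c_position)
  list(sample_id = sample_id, geno = geno, calls = calls,
       het_count = sum(geno == 1L, na.rm = TRUE),
       missing_sites = catalog$c_position[is.na(geno)],
       novel = novel, identity = aln$identity)
}

#' Call genotypes for a FASTA of sample consensus sequences
#'
#' Accepts either a path to a FASTA file or a `DNAStringSet`.  Records named
#' `<id>_F` / `<id>_R` are treated as forward/reverse fragments of sample
#' `<id>` and merged with [merge_fragments()]; all other records are taken as
#' one consensus per sample.
#'
#' @param x FASTA path or `Biostrings::DNAStringSet`.
#' @param reference a [nat2_reference()] object.
#' @param catalog a [nat2_catalog()] data frame.
#' @param strata optional named character vector, sample id -> stratum label.
#' @param min_overlap passed to [merge_fragments()].
#' @param min_identity passed to [align_to_reference()].
#' @return a [nat2_genotypes()] object; novel-variant records are attached as
#'   attribute `novel` and reported with a warning.
#' @export
call_genotypes <- function(x, reference = nat2_reference(),
                           catalog = nat2_catalog(reference = reference),
                           strata = NULL, min_overlap = 30,
                           min_identity = 0.8) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  seqs <- setNames(toupper(as.character(x)), names(x))
  ids <- names(seqs)
  frag <- grepl("_[FR]$", ids)
  consensus <- as.list(seqs[!frag])
  for (id in unique(sub("_[FR]$", "", ids[frag]))) {
    f <- seqs[paste0(id, "_F")]; r <- seqs[paste0(id, "_R")]
    if (is.na(f) || is.na(r))
      stop("sample ", id, ": both _F and _R fragments are required")
    consensus[[id]] <- merge_fragments(f, r, min_overlap = min_overlap)
  }
  n <- length(consensus)
  geno <- matrix(NA_integer_, n, nrow(catalog))
  novel <- list()
  for (i in seq_len(n)) {
    cg <- call_genotype(consensus[[i]], reference, catalog,
                        sample_id = names(consensus)[i],
                        min_identity = min_identity)
    geno[i, ] <- cg$geno
    if (nrow(cg$novel))
      novel[[length(novel) + 1L]] <- cbind(sample_id = cg$sample_id, cg$novel)
  }
  samples <- data.frame(sample_id = names(consensus),
                        stringsAsFactors = FALSE)
  if (!is.null(strata)) samples$stratum <- unname(strata[samples$sample_id])
  out <- nat2_genotypes(geno, catalog, samples)
  novel <- if (length(novel)) do.call(rbind, novel) else
    data.frame(sample_id = character(0), c_position = integer(0),
               ref_base = character(0), sample_base = character(0))
  attr(out, "novel") <- novel
  if (nrow(novel))
    warning(nrow(novel), " uncatalogued variant call(s) excluded from typing; ",
            "see attr(, 'novel')")
  out
}

# ---- TSV output ------------------------------------------------------------

#' Write calls as a VCF-like TSV
#'
#' One row per sample x catalogued site with genotype in `0/0`, `0/1`, `1/1`
#' or `./.` notation.
#'
#' @param genotypes a `nat2_genotypes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_like <- function(genotypes, path) {
  g <- genotypes$geno; s <- genotypes$sites
  gt <- c("0/0", "0/1", "1/1")[g + 1L]
  gt[is.na(gt)] <- "./."
  out <- data.frame(
    sample = rep(rownames(g), times = ncol(g)),
    c_position = rep(s$c_position, each = nrow(g)),
    rsid = rep(s$rsid, each = nrow(g)),
    ref = rep(s$ref, each = nrow(g)),
    alt = rep(s$alt, each = nrow(g)),
    genotype = as.vector(gt), stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-sample genotype dosage table consumed by phasing
#' @inheritParams write_vcf_like
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  out <- data.frame(sample_id = genotypes$samples$sample_id,
                    stratum = genotypes$samples$stratum,
                    genotypes$geno, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
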