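# Reference model: the 873 bp NAT2 coding exon, the SNP catalogue and the
# star-allele definition table.

#' Load the NAT2 coding-exon reference sequence
#'
#' Reads a single-record FASTA holding the coding strand of the NAT2 coding
#' exon (the NAT2*4 reference allele) and validates it: exactly 873 bases,
#' starting with `ATG`, plain `A/C/G/T` only.  With no argument, the bundled
#' reference is used.  The bundled file is a synthetic stand-in for the
#' GenBank NAT2*4 coding sequence: it has the correct length, reading frame
#' and reference base plus codon context at every catalogued SNP position,
#' but the remaining codons are arbitrary.
#'
#' @param path path to a FASTA file; `NULL` (default) uses the bundled
#'   synthetic reference.
#' @return an object of class `nat2_reference`: a list with elements
#'   `sequence` (character, length-1), `source_id`, and `length`.
#' @examples
#' ref <- nat2_reference()
#' ref$length           # 873
#' substr(ref$sequence, 1, 3)  # "ATG"
#' @export
nat2_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nat2_reference_synthetic.fa",
                        package = "nat2typer", mustWork = TRUE)
    source_id <- "AY331807 (synthetic stand-in)"
  } else {
    source_id <- basename(path)
  }
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("malformed FASTA '", path, "': no records")
  if (length(set) > 1L) stop("reference FASTA must hold a single record, got ",
                             length(set))
  seq <- toupper(as.character(set[[1]]))
  if (nchar(seq) != 873L)
    stop("reference validation failed: expected 873 bases, observed ",
         nchar(seq))
  if (!grepl("^[ACGT]+$", seq))
    stop("reference validation failed: sequence contains non-ACGT characters")
  if (substr(seq, 1, 3) != "ATG")
    stop("reference validation failed: sequence does not start with ATG")
  structure(list(sequence = seq, source_id = source_id, length = nchar(seq)),
            class = "nat2_reference")
}

#' @export
print.nat2_reference <- function(x, ...) {
  cat("NAT2 coding-exon reference (", x$length, " bp, source: ",
      x$source_id, ")\n", sep = "")
  cat(substr(x$sequence, 1, 60), "...\n", sep = "")
  invisible(x)
}

#' Load the SNP catalogue
#'
#' The catalogue lists the coding-exon substitutions used for typing, in
#' HGVS-style c.-coordinates (1-based from the A of the initiator ATG).
#' Every reference base is validated against the reference sequence.
#'
#' @param path TSV with columns `c_position`, `ref`, `alt`, `rsid`, `effect`
#'   (`synonymous`/`nonsynonymous`), `aa_change`; `NULL` uses the bundled
#'   catalogue of the 13 catalogued NAT2 coding SNPs (the seven globally most
#'   common ones plus six carried by rarer named alleles).
#' @param reference a [nat2_reference()] object used for validation.
#' @return data frame of class `nat2_catalog`, ordered by position.
#' @examples
#' cat13 <- nat2_catalog()
#' subset(cat13, rsid == "rs1801280")  # c.341T>C
#' @export
nat2_catalog <- function(path = NULL, reference = nat2_reference()) {
  if (is.null(path))
    path <- system.file("extdata", "nat2_snp_catalog.tsv",
                        package = "nat2typer", mustWork = TRUE)
  cat <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(c_position = "integer"))
  needed <- c("c_position", "ref", "alt", "rsid", "effect", "aa_change")
  if (!all(needed %in% names(cat)))
    stop("SNP catalogue must have columns: ", paste(needed, collapse = ", "))
  if (any(cat$c_position < 1L | cat$c_position > reference$length))
    stop("catalogue positions outside [1, ", reference$length, "]")
  obs <- substring(reference$sequence, cat$c_position, cat$c_position)
  bad <- which(obs != cat$ref)
  if (length(bad))
    stop("catalogue reference-base mismatch at c.", cat$c_position[bad[1]],
         ": catalogue says ", cat$ref[bad[1]], ", reference has ", obs[bad[1]])
  if (any(cat$ref == cat$alt)) stop("ref and alt bases must differ")
  if (anyDuplicated(cat$c_position)) stop("duplicated catalogue positions")
  cat <- cat[order(cat$c_position), , drop = FALSE]
  rownames(cat) <- NULL
  class(cat) <- c("nat2_catalog", "data.frame")
  cat
}

# ---- SNP token helpers -----------------------------------------------------

#' Parse HGVS-style SNP tokens
#'
#' Tokens look like `"c.341T>C"`.  Used throughout for haplotype definitions.
#'
#' @param tokens character vector of tokens.
#' @return data frame with columns `c_position`, `ref`, `alt`.
#' @export
parse_snp_token <- function(tokens) {
  m <- regmatches(tokens, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", tokens))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable SNP token: '", tokens[bad][1], "'")
  data.frame(
    c_position = as.integer(vapply(m, `[`, "", 2L)),
    ref = vapply(m, `[`, "", 3L),
    alt = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

#' Format catalogue rows as SNP tokens
#' @param snps data frame with `c_position`, `ref`, `alt`.
#' @return character vector like `"c.341T>C"`.
#' @export
format_snp_token <- function(snps) {
  if (nrow(snps) == 0L) return(character(0))
  paste0("c.", snps$c_position, snps$ref, ">", snps$alt)
}

# canonical comma-joined key of a token set, sorted by position ("" = reference)
hap_key <- function(tokens) {
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return("")
  pos <- parse_snp_token(tokens)$c_position
  if (anyDuplicated(pos)) stop("haplotype carries two alleles at one position")
  paste(tokens[order(pos)], collapse = ",")
}

# ---- allele table ----------------------------------------------------------

# Default signature map, in priority order.  The four slow signatures come
# first; among the neutral signatures c.803A>G precedes c.481C>T because
# alleles carrying both (e.g. *12C, *12S) belong to the *12 group.  c.622T>C
# is a table-driven extension for the *28 group, which carries none of the
# seven canonical signature SNPs.
.DEFAULT_SIGNATURES <- c(
  "c.191G>A" = "*14",
  "c.341T>C" = "*5",
  "c.590G>A" = "*6",
  "c.857G>A" = "*7",
  "c.803A>G" = "*12",
  "c.481C>T" = "*11",
  "c.282C>T" = "*13",
  "c.622T>C" = "*28"
)

# signature SNPs whose presence makes an (unnamed) haplotype defective
.SLOW_SIGNATURES <- c("c.191G>A", "c.341T>C", "c.590G>A", "c.857G>A")

#' Load a star-allele definition table
#'
#' Reads a TSV mapping star-allele names to exact SNP sets, acetylator
#' function and allelic group.  Every SNP token is validated against the
#' reference; duplicate haplotypes and duplicate names are rejected; the
#' table must contain the reference allele `NAT2*4` (empty haplotype,
#' function rapid).
#'
#' The bundled default covers the ten alleles common in Brazilian samples
#' (frequency > 1 percent in at least one state), the nine newly named rarer
#' alleles, and the conventional companions `NAT2*11A` and `NAT2*12C`.
#' Rarer alleles not reducible to a signature-consistent minimal definition
#' carry function `unknown`.
#'
#' @param path TSV with columns `name`, `snps` (comma-separated tokens, `.`
#'   or empty for the reference haplotype), `func`
#'   (`rapid`/`slow`/`unknown`), `group`; `NULL` uses the bundled table.
#' @param reference a [nat2_reference()] object.
#' @param signatures named character vector mapping signature SNP tokens to
#'   group symbols, in priority order.
#' @return data frame of class `nat2_allele_table` with an extra column
#'   `key` (canonical haplotype key) and attribute `signatures`.
#' @examples
#' tab <- nat2_allele_table()
#' subset(tab, name == "NAT2*5B")$snps   # "c.341T>C,c.481C>T,c.803A>G"
#' @export
nat2_allele_table <- function(path = NULL, reference = nat2_reference(),
                              signatures = .DEFAULT_SIGNATURES) {
  if (is.null(path))
    path <- system.file("extdata", "nat2_alleles.tsv",
                        package = "nat2typer", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  needed <- c("name", "snps", "func", "group")
  if (!all(needed %in% names(tab)))
    stop("allele table must have columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicate allele name: ", tab$name[duplicated(tab$name)][1])
  if (!all(tab$func %in% c("rapid", "slow", "unknown")))
    stop("allele function must be rapid, slow or unknown")
  keys <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    raw <- trimws(tab$snps[i])
    tokens <- if (raw %in% c("", ".", "(none)")) character(0) else
      trimws(strsplit(raw, ",")[[1]])
    if (length(tokens)) {
      parsed <- parse_snp_token(tokens)
      obs <- substring(reference$sequence, parsed$c_position, parsed$c_position)
      bad <- which(obs != parsed$ref)
      if (length(bad))
        stop("allele ", tab$name[i], ": SNP token ref base mismatch at c.",
             parsed$c_position[bad[1]], " (token says ", parsed$ref[bad[1]],
             ", reference has ", obs[bad[1]], ")")
    }
    keys[i] <- hap_key(tokens)
  }
  if (anyDuplicated(keys)) {
    d <- which(duplicated(keys))[1]
    stop("duplicate haplotype definition: ", tab$name[d], " repeats ",
         tab$name[match(keys[d], keys)])
  }
  ref_row <- which(keys == "")
  if (length(ref_row) != 1L || tab$func[ref_row] != "rapid")
    stop("allele table must contain the reference allele (empty haplotype, rapid)")
  tab$key <- keys
  rownames(tab) <- NULL
  structure(tab, class = c("nat2_allele_table", "data.frame"),
            signatures = signatures)
}

#' Serialize an allele table to TSV
#'
#' Inverse of [nat2_allele_table()]: reloading the written file yields an
#' identical table.
#'
#' @param table a `nat2_allele_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(table, path) {
  out <- as.data.frame(table)[, c("name", "snps", "func", "group")]
  out$snps[out$snps %in% c("", ".")] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# tokens of one table row (by allele name)
allele_tokens <- function(table, name) {
  i <- match(name, table$name)
  if (is.na(i)) stop("unknown allele name: ", name)
  k <- table$key[i]
  if (k == "") character(0) else strsplit(k, ",")[[1]]
}
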