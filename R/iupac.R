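# IUPAC nucleotide ambiguity machinery shared by the calling, merging and
# rendering code.  Heterozygous Sanger positions arrive as two-base codes
# (R = A/G, Y = C/T, S = G/C, W = A/T, K = G/T, M = A/C).

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Expand an IUPAC code to its base set
#'
#' @param code single character, one of `A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`.
#' @return character vector of the plain bases the code stands for.
#' @examples
#' iupac_bases("Y")  # "C" "T"
#' @export
iupac_bases <- function(code) {
  s <- .IUPAC_SETS[[toupper(code)]]
  if (is.null(s)) stop("not an IUPAC nucleotide code: '", code, "'")
  s
}

#' Encode an unordered pair of bases as an IUPAC code
#'
#' @param b1,b2 plain bases (`A`, `C`, `G` or `T`).
#' @return single character: the base itself if `b1 == b2`, otherwise the
#'   two-base ambiguity code.
#' @examples
#' iupac_code("C", "T")  # "Y"
#' @export
iupac_code <- function(b1, b2) {
  set <- sort(unique(toupper(c(b1, b2))))
  if (!all(set %in% c("A", "C", "G", "T")))
    stop("iupac_code() takes plain bases, got: ", paste(c(b1, b2), collapse = "/"))
  for (code in names(.IUPAC_SETS)) {
    if (length(.IUPAC_SETS[[code]]) == length(set) &&
        all(.IUPAC_SETS[[code]] == set)) return(code)
  }
  stop("unreachable")
}

# TRUE iff the base sets of two codes intersect (used as alignment "match").
iupac_compatible <- function(c1, c2) {
  length(intersect(iupac_bases(c1), iupac_bases(c2))) > 0L
}

# Consensus of two calls at one position: identical -> itself; one call's set
# contained in the other's -> the more ambiguous code; otherwise N.
iupac_consensus <- function(c1, c2) {
  s1 <- iupac_bases(c1); s2 <- iupac_bases(c2)
  if (length(s1) == length(s2) && all(s1 == s2)) return(toupper(c1))
  if (all(s1 %in% s2)) return(toupper(c2))
  if (all(s2 %in% s1)) return(toupper(c1))
  "N"
}

# Substitution matrix over the 15 IUPAC letters: +1 when compatible, -1
# otherwise.  Shared by align_to_reference().
iupac_substitution_matrix <- function(match = 1, mismatch = -1) {
  letters15 <- names(.IUPAC_SETS)
  m <- matrix(mismatch, length(letters15), length(letters15),
              dimnames = list(letters15, letters15))
  for (a in letters15) for (b in letters15)
    if (iupac_compatible(a, b)) m[a, b] <- match
  m
}
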