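AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein <- function(x, arg = "sequence") {
  if (length(x) != 1 || is.na(x) || nchar(x) == 0) {
    abort(sprintf("%s must be a single non-empty string", arg))
  }
  x <- toupper(x)
  letters_seen <- unique(strsplit(x, "")[[1]])
  bad <- setdiff(letters_seen, c(AA_ALPHABET20, "X"))
  if (length(bad) > 0) {
    abort(sprintf("%s contains invalid residue letter(s): %s",
                  arg, paste(bad, collapse = ", ")))
  }
  x
}

load_substitution_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Global pairwise protein alignment with identity and similarity
#'
#' Needleman-Wunsch global alignment with affine gap penalties, following
#' the EMBOSS needle defaults (BLOSUM62, gap open 10, gap extend 0.5; a gap
#' of length L costs open + extend * L). Identity is the percentage of
#' alignment columns with identical residues and similarity the percentage
#' with a positive substitution score, both over the full alignment length
#' including gap columns. A domain is called conserved when identity is at
#' least 40%.
#'
#' @param a,b Amino-acid sequences (single strings over the 20-letter
#'   alphabet plus X). Case-insensitive; gap characters are rejected.
#' @param matrix Substitution matrix name (a Biostrings dataset such as
#'   `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A one-row tibble of class `domain_comparison`: `score`,
#'   `identity_pct`, `similarity_pct`, `aligned_length`, `identical_sites`,
#'   `conserved`, `alignment_a`, `alignment_b`.
#' @examples
#' global_align("HEAGAWGHEE", "PAWHEAE")
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  a <- check_protein(a, "a")
  b <- check_protein(b, "b")
  mat <- load_substitution_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    a, b,
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  sa <- as.character(Biostrings::alignedPattern(aln))
  sb <- as.character(Biostrings::alignedSubject(aln))
  ra <- strsplit(sa, "")[[1]]
  rb <- strsplit(sb, "")[[1]]
  len <- length(ra)
  no_gap <- ra != "-" & rb != "-"
  identical_sites <- sum(no_gap & ra == rb)
  positive <- no_gap
  positive[no_gap] <- mat[cbind(ra[no_gap], rb[no_gap])] > 0
  identity_pct <- 100 * identical_sites / len
  res <- tibble(
    score = Biostrings::score(aln),
    identity_pct = identity_pct,
    similarity_pct = 100 * sum(positive) / len,
    aligned_length = len,
    identical_sites = identical_sites,
    conserved = domain_conserved(identity_pct),
    alignment_a = sa,
    alignment_b = sb
  )
  class(res) <- c("domain_comparison", class(res))
  res
}

#' Domain conservation call from percent identity
#'
#' A domain counts as conserved when its amino-acid identity to the
#' orthologous reference domain is at least 40% (inclusive).
#'
#' @param identity_pct Percent identity in \[0, 100\]. Vectorized.
#' @return Logical vector.
#' @export
domain_conserved <- function(identity_pct) {
  if (!all(is.finite(identity_pct)) ||
      any(identity_pct < 0) || any(identity_pct > 100)) {
    abort("identity_pct must lie in [0, 100]")
  }
  identity_pct >= 40
}

#' Conserved-site count inside an aligned window
#'
#' Counts the columns of a pairwise alignment window where both sequences
#' carry the same (non-gap) residue, the "similar at x/n sites" style of
#' statement used for short conserved motifs. Gap columns count toward the
#' window length but never toward identity.
#'
#' @param aligned_a,aligned_b Gapped aligned strings of equal length.
#' @param start,end 1-based inclusive column interval; defaults to the full
#'   alignment.
#' @return Tibble with `identical_sites` and `window_length`.
#' @export
window_conservation <- function(aligned_a, aligned_b, start = 1,
                                end = nchar(aligned_a)) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort("aligned strings must have equal length")
  }
  if (start < 1 || end > nchar(aligned_a) || start > end) {
    abort("window out of bounds")
  }
  ra <- strsplit(toupper(aligned_a), "")[[1]][start:end]
  rb <- strsplit(toupper(aligned_b), "")[[1]][start:end]
  tibble(
    identical_sites = sum(ra != "-" & rb != "-" & ra == rb),
    window_length = length(ra)
  )
}

#' Extract an annotated domain from a protein sequence
#'
#' Cuts a 1-based inclusive residue interval out of a sequence, the
#' coordinate convention used for domain annotations.
#'
#' @param residues Amino-acid string.
#' @param start,end 1-based inclusive residue coordinates.
#' @return The domain substring.
#' @export
extract_domain <- function(residues, start, end) {
  residues <- check_protein(residues, "residues")
  if (start < 1 || end > nchar(residues) || start > end) {
    abort("domain coordinates out of bounds")
  }
  substr(residues, start, end)
}
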