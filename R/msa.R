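#' Read an alignment or sequence set from FASTA
#'
#' @param path FASTA file (aligned or not).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Mask alignment columns by gap fraction
#'
#' Removes every column in which the fraction of sequences carrying a gap
#' is at or above `max_gap_fraction` ("gaps in 10% or more of the
#' sequences" at the default); a column is kept iff
#' gap_count / n_rows < max_gap_fraction. Row order and the order of the
#' surviving columns are preserved.
#'
#' @param aln named character vector (or AAStringSet) of aligned rows.
#' @param max_gap_fraction removal threshold, inclusive on the gap side.
#'   Default 0.10.
#' @return list with `alignment` (masked rows) and `kept` (the indices of
#'   the retained columns in the input).
#' @export
mask_alignment <- function(aln, max_gap_fraction = 0.10) {
  m <- .aln_matrix(aln)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty alignment")
  gapfrac <- colMeans(matrix(m %in% .gap_chars, nrow = nrow(m)))
  kept <- which(gapfrac < max_gap_fraction)
  masked <- apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  if (!length(kept))
    masked <- stats::setNames(rep("", nrow(m)), rownames(m))
  list(alignment = stats::setNames(as.character(masked), rownames(m)),
       kept = kept)
}

#' Global pairwise identity of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gaps, followed by an
#' identity computation under a configurable denominator convention:
#' `"alnlen"` (full alignment length including gapped columns, the
#' EMBOSS-needle convention and the default), `"shorter"` (length of the
#' shorter input), or `"cols"` (aligned residue-residue columns only).
#'
#' @param a,b protein sequences (character strings).
#' @param matrix substitution matrix name (default "BLOSUM62"); ignored
#'   when `match`/`mismatch` are given.
#' @param gap_open,gap_extend affine gap costs. Defaults 10 and 0.5.
#' @param denominator identity denominator convention.
#' @param match,mismatch optional simple scoring scheme; when both are
#'   given a uniform match/mismatch matrix replaces `matrix`.
#' @return list of class `identity_result`: percent_identity, n_identical,
#'   denominator, alignment_length.
#' @export
pairwise_identity <- function(a, b, matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5,
                              denominator = c("alnlen", "shorter", "cols"),
                              match = NULL, mismatch = NULL) {
  denominator <- match.arg(denominator)
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity: empty sequence")
  if (!is.null(match) && !is.null(mismatch)) {
    letters <- union(.AA20, unique(strsplit(toupper(paste0(a, b)), "")[[1]]))
    matrix <- outer(letters, letters,
                    function(x, y) ifelse(x == y, match, mismatch))
    dimnames(matrix) <- list(letters, letters)
    qa <- toupper(a); qb <- toupper(b)
  } else {
    qa <- .sanitize_protein(a); qb <- .sanitize_protein(b)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = qa, subject = qb, type = "global",
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  pa <- strsplit(pat, "")[[1]]
  pb <- strsplit(sub, "")[[1]]
  n_identical <- sum(pa == pb & !(pa %in% .gap_chars))
  alnlen <- length(pa)
  denom <- switch(denominator,
                  alnlen = alnlen,
                  shorter = min(nchar(a), nchar(b)),
                  cols = sum(!(pa %in% .gap_chars) & !(pb %in% .gap_chars)))
  structure(list(percent_identity = 100 * n_identical / denom,
                 n_identical = n_identical,
                 denominator = denom,
                 alignment_length = alnlen),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("%.1f%% identity (%d identical / %d, alignment length %d)\n",
              x$percent_identity, x$n_identical, x$denominator,
              x$alignment_length))
  invisible(x)
}
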