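#' Global identity of the two canonical human NRBP paralogs
#'
#' Convenience wrapper for the family's headline sequence comparison: a
#' global affine-gap alignment of canonical human NRBP1 (UniProt Q9UHY1)
#' against NRBP2 (Q9NSY0), reported as percent identity over the full
#' alignment length. The two canonical sequences are not bundled with the
#' package; download them from UniProt and pass the FASTA path (both
#' records in one file, NRBP1 first).
#'
#' @param fasta path to a FASTA file holding the two canonical sequences.
#' @param ... passed to [pairwise_identity()] (scoring matrix, gap costs,
#'   denominator convention).
#' @return an `identity_result` (see [pairwise_identity()]).
#' @export
nrbp1_nrbp2_identity <- function(fasta = system.file(
  "extdata", "uniprot_nrbp1_nrbp2.fasta", package = "nrbpfam"), ...) {
  if (is.null(fasta) || !nzchar(fasta) || !file.exists(fasta))
    stop("canonical NRBP1/NRBP2 sequences are not bundled with the ",
         "package; download UniProt Q9UHY1 and Q9NSY0 as one FASTA file ",
         "and pass its path")
  seqs <- read_fasta(fasta)
  if (length(seqs) != 2L)
    stop("expected exactly two sequences (NRBP1, NRBP2), found ",
         length(seqs))
  pairwise_identity(seqs[[1]], seqs[[2]], ...)
}
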