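#' Consensus residues of the protein kinase catalytic triad
#'
#' The ATP-binding beta3-strand lysine, the catalytic aspartate of the
#' HRDxxxN catalytic loop, and the metal-binding aspartate of the
#' activation-loop DFG motif. The classifier scores sequences against
#' exactly these residues, with no conservative substitutions allowed.
#'
#' @export
TRIAD_CONSENSUS <- c(beta3_K = "K", HRD_D = "D", DFG_D = "D")

.gap_chars <- c("-", ".")

.aln_matrix <- function(aln) {
  if (inherits(aln, "AAStringSet") || inherits(aln, "AAMultipleAlignment"))
    aln <- as.character(aln)
  if (!is.character(aln) || is.null(names(aln)))
    stop("alignment must be a named character vector or AAStringSet")
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows must have equal length")
  if (anyDuplicated(names(aln)))
    stop("alignment row labels must be unique")
  do.call(rbind, strsplit(toupper(aln), ""))
}

#' Build a position-specific scoring model of the kinase domain
#'
#' Turns a seed alignment into per-column log-odds scores over the 20
#' residues, with the three catalytic-triad columns annotated. Columns with
#' a gap fraction above 50% are dropped as insert columns and the triad
#' indices remapped accordingly. Log-odds in bits:
#' log2( (count + pseudocount) / (n + 20 * pseudocount) / background ).
#'
#' @param seed_alignment named character vector (or AAStringSet) of aligned
#'   rows of equal length.
#' @param triad_columns integer vector of the three triad column indices in
#'   the seed alignment (1-based), in the order beta3_K, HRD_D, DFG_D.
#' @param pseudocount Laplace smoothing count (>= 0). Default 1.
#' @param background per-residue background frequencies (default uniform
#'   1/20).
#' @param gap_open,gap_extend affine gap costs (bits) used when aligning
#'   sequences to the model.
#' @return list of class `kinase_profile` with elements `scores` (20 x C
#'   matrix), `triad_columns` (named, remapped to model columns),
#'   `consensus` (top-scoring residue per column), gap costs and background.
#' @export
build_profile <- function(seed_alignment, triad_columns, pseudocount = 1,
                          background = rep(1 / 20, 20),
                          gap_open = 10, gap_extend = 1) {
  stopifnot(length(triad_columns) == 3L, pseudocount >= 0,
            length(background) == 20L, all(background > 0))
  m <- .aln_matrix(seed_alignment)
  ncol_aln <- ncol(m)
  triad_columns <- as.integer(triad_columns)
  if (is.unsorted(triad_columns, strictly = TRUE) ||
      any(triad_columns < 1L) || any(triad_columns > ncol_aln))
    stop("triad columns must be strictly increasing and within the alignment")
  gapfrac <- colMeans(matrix(m %in% .gap_chars, nrow = nrow(m)))
  keep <- gapfrac <= 0.5
  if (any(!keep[triad_columns]))
    stop("a triad column has >50% gaps and would be dropped: ",
         "seed alignment unusable")
  remap <- cumsum(keep)
  m <- m[, keep, drop = FALSE]
  C <- ncol(m)
  scores <- matrix(0, nrow = 20, ncol = C, dimnames = list(.AA20, NULL))
  for (i in seq_len(C)) {
    col <- m[, i]
    col <- col[!(col %in% .gap_chars)]
    counts <- table(factor(col, levels = .AA20))
    n <- length(col)
    freq <- (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
    scores[, i] <- log2(freq / background)
  }
  cons <- .AA20[apply(scores, 2, which.max)]
  structure(list(scores = scores,
                 triad_columns = stats::setNames(remap[triad_columns],
                                                 names(TRIAD_CONSENSUS)),
                 consensus = cons,
                 gap_open = gap_open, gap_extend = gap_extend,
                 background = background),
            class = "kinase_profile")
}

#' @export
print.kinase_profile <- function(x, ...) {
  cat(sprintf("kinase profile: %d columns, triad at %s\n",
              ncol(x$scores),
              paste(sprintf("%s=%d", names(x$triad_columns),
                            x$triad_columns), collapse = " ")))
  invisible(x)
}

#' Align a protein sequence to a position-specific model
#'
#' Global affine-gap dynamic programming maximizing the summed
#' position-specific scores. Every model column is assigned exactly one
#' query residue index or a gap; assigned indices are strictly increasing.
#'
#' @param seq protein sequence (character string).
#' @param profile a [build_profile()] model.
#' @return list with `score` (bits) and `column_map`, an integer vector with
#'   one entry per model column: the 1-based query index, or NA for a gap.
#' @export
align_to_profile <- function(seq, profile) {
  stopifnot(inherits(profile, "kinase_profile"))
  if (!nzchar(seq)) stop("align_to_profile: empty sequence")
  residues <- strsplit(toupper(seq), "")[[1]]
  idx <- match(residues, .AA20, nomatch = 0L)
  res <- .align_profile_cpp(profile$scores, as.integer(idx),
                            profile$gap_open, profile$gap_extend)
  res$column_map <- as.integer(res$column_map)
  res
}

#' Read the catalytic-triad residues of an aligned sequence
#'
#' Looks up the residues mapped to the three annotated triad columns and
#' compares each against the kinase consensus (K for beta3, D for the HRD
#' catalytic loop, D for the DFG motif). A column mapped to a gap counts as
#' a mismatch: an absent catalytic residue cannot be functional.
#'
#' @param aln result of [align_to_profile()] for this profile.
#' @param seq the aligned protein sequence.
#' @param profile the model used for the alignment.
#' @param sequence_id identifier recorded in the call.
#' @return list of class `triad_call` with the observed residues, per-site
#'   match flags, the mismatch count, and an unset pseudokinase verdict
#'   (see [classify_pseudokinase()]).
#' @export
call_triad <- function(aln, seq, profile, sequence_id = "seq") {
  stopifnot(inherits(profile, "kinase_profile"))
  residues <- strsplit(toupper(seq), "")[[1]]
  obs <- vapply(profile$triad_columns, function(col) {
    qi <- aln$column_map[col]
    if (is.na(qi)) "-" else residues[qi]
  }, character(1))
  matches <- obs == TRIAD_CONSENSUS[names(obs)]
  structure(list(sequence_id = sequence_id,
                 residues = obs,
                 matches = matches,
                 n_mismatches = sum(!matches),
                 is_pseudokinase = NA),
            class = "triad_call")
}

#' Apply the 2-of-3 pseudokinase rule
#'
#' A protein is rated a pseudokinase when at least two of the three
#' catalytic-triad residues do not match the protein kinase consensus.
#'
#' @param call a [call_triad()] result.
#' @return The call with `is_pseudokinase` set.
#' @export
classify_pseudokinase <- function(call) {
  stopifnot(inherits(call, "triad_call"))
  call$is_pseudokinase <- call$n_mismatches >= 2L
  call
}

#' Classify a set of sequences against a kinase-domain model
#'
#' Convenience wrapper: aligns each sequence to the model, reads the triad,
#' and applies the 2-of-3 pseudokinase rule.
#'
#' @param seqs named character vector of protein sequences.
#' @param profile a [build_profile()] model.
#' @return data.frame with one row per sequence: id, the three observed
#'   triad residues, n_mismatches and is_pseudokinase.
#' @export
classify_sequences <- function(seqs, profile) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  rows <- lapply(names(seqs), function(id) {
    aln <- align_to_profile(seqs[[id]], profile)
    call <- classify_pseudokinase(call_triad(aln, seqs[[id]], profile, id))
    data.frame(id = id,
               residue_beta3 = call$residues[["beta3_K"]],
               residue_HRD = call$residues[["HRD_D"]],
               residue_DFG = call$residues[["DFG_D"]],
               n_mismatches = call$n_mismatches,
               is_pseudokinase = call$is_pseudokinase,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a triad-column annotation table
#'
#' Sidecar TSV with columns `role` (beta3_K, HRD_D, DFG_D) and `column`
#' (1-based index into the seed alignment).
#'
#' @param path TSV file path.
#' @return integer vector of the three columns, ordered beta3_K, HRD_D,
#'   DFG_D.
#' @export
read_triad_columns <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("role", "column") %in% names(tab)))
  missing <- setdiff(names(TRIAD_CONSENSUS), tab$role)
  if (length(missing))
    stop("triad annotation missing roles: ", paste(missing, collapse = ", "))
  stats::setNames(tab$column[match(names(TRIAD_CONSENSUS), tab$role)],
                  names(TRIAD_CONSENSUS))
}
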