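#' Scoring configuration for desk-scale local search
#'
#' Substitution matrix, affine gap costs and fixed Karlin-Altschul
#' parameters used to turn raw local-alignment scores into bit scores and
#' E-values. The defaults correspond to the common gapped protein search
#' setting (BLOSUM62, gap open 11 / extend 1, lambda = 0.267, K = 0.041);
#' the parameters are fixed constants, not estimated, because only ordering
#' and rough magnitude matter at desk scale.
#'
#' @param matrix name of a substitution matrix shipped with Biostrings
#'   (e.g. "BLOSUM62").
#' @param gap_open,gap_extend affine gap opening and extension costs
#'   (positive).
#' @param lambda,K Karlin-Altschul parameters.
#' @param e_ceiling hits with E-value above this are not reported.
#' @return list of class `search_scoring`.
#' @export
search_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, e_ceiling = 10) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 e_ceiling = e_ceiling),
            class = "search_scoring")
}

#' Convert a raw alignment score to a bit score
#'
#' S' = (lambda * S - ln K) / ln 2.
#'
#' @param score raw alignment score.
#' @param lambda,K Karlin-Altschul parameters.
#' @return bit score.
#' @export
bit_score <- function(score, lambda = 0.267, K = 0.041) {
  (lambda * score - log(K)) / log(2)
}

#' E-value of a bit score in an m x n search space
#'
#' E = m * n * 2^(-S'). For a fixed bit score, E increases monotonically
#' with either sequence length.
#'
#' @param bits bit score.
#' @param m,n query and subject lengths (residues).
#' @return expectation value.
#' @export
evalue_from_bits <- function(bits, m, n) {
  m * n * 2^(-bits)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Residues outside the 20-letter alphabet are replaced by X so they score
# as (near-)mismatches under the substitution matrix.
.sanitize_protein <- function(x) {
  gsub(sprintf("[^%s]", paste(.AA20, collapse = "")), "X", toupper(x))
}

#' Best local alignment of two protein sequences
#'
#' Smith-Waterman alignment with affine gaps under a standard substitution
#' matrix (via Biostrings), reported as one 12-column hit record with a bit
#' score and E-value from fixed Karlin-Altschul parameters. A desk-scale
#' stand-in for a full database search tool: no seeding heuristics, one
#' best-scoring alignment per pair.
#'
#' @param query,subject protein sequences (character strings, 20-letter
#'   alphabet; other letters are scored as mismatches).
#' @param scoring a [search_scoring()].
#' @param query_id,subject_id identifiers written into the hit record.
#' @return A one-row hit data.frame, or NULL when the E-value exceeds the
#'   configured report ceiling.
#' @export
local_search <- function(query, subject, scoring = search_scoring(),
                         query_id = "query", subject_id = "subject") {
  stopifnot(inherits(scoring, "search_scoring"))
  if (!nzchar(query) || !nzchar(subject))
    stop("local_search: empty sequence")
  q <- .sanitize_protein(query)
  s <- .sanitize_protein(subject)
  aln <- Biostrings::pairwiseAlignment(
    pattern = q, subject = s, type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  bits <- bit_score(Biostrings::score(aln), scoring$lambda, scoring$K)
  ev <- evalue_from_bits(bits, nchar(q), nchar(s))
  if (ev > scoring$e_ceiling) return(NULL)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  alen <- nchar(pat)
  nmat <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  gapopens <- .count_gap_opens(pat) + .count_gap_opens(sub)
  hit_record(qseqid = query_id, sseqid = subject_id,
             pident = round(100 * nmat / alen, 3),
             length = alen, mismatch = nmis, gapopen = gapopens,
             qstart = Biostrings::start(Biostrings::pattern(aln)),
             qend = Biostrings::end(Biostrings::pattern(aln)),
             sstart = Biostrings::start(Biostrings::subject(aln)),
             send = Biostrings::end(Biostrings::subject(aln)),
             evalue = ev, bitscore = round(bits, 1))
}

.count_gap_opens <- function(aligned) {
  length(gregexpr("-+", aligned)[[1]][gregexpr("-+", aligned)[[1]] > 0])
}
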