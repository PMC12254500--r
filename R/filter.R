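#' Configuration for the homolog acceptance filter chain
#'
#' Holds the thresholds of the four-stage ortholog filter: E-value cutoff,
#' reciprocal top-hit acceptance against a reference set, minimum reference
#' coverage, and folded-region representation with a residue tolerance.
#'
#' @param evalue_cutoff maximum E-value, inclusive. Default 1e-28, the
#'   threshold needed to keep unrelated protein kinase families out of the
#'   candidate set.
#' @param min_reference_coverage minimum fraction of the reference covered by
#'   the (pooled) aligned spans, inclusive. Default 0.80.
#' @param folded_region 1-based inclusive interval `c(start, end)` of the
#'   structured (folded) region on the reference, or NULL to skip the filter.
#' @param folded_tolerance total number of folded-region residues allowed to
#'   be uncovered. Default 40.
#' @param accepted_reference_ids identifiers accepted as reciprocal top hits
#'   (the reference paralogs).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(evalue_cutoff = 1e-28,
                          min_reference_coverage = 0.80,
                          folded_region = NULL,
                          folded_tolerance = 40,
                          accepted_reference_ids = character()) {
  stopifnot(evalue_cutoff >= 0,
            min_reference_coverage > 0, min_reference_coverage <= 1,
            folded_tolerance >= 0)
  if (!is.null(folded_region)) {
    stopifnot(length(folded_region) == 2L, folded_region[1] >= 1,
              folded_region[1] <= folded_region[2])
  }
  structure(list(evalue_cutoff = evalue_cutoff,
                 min_reference_coverage = min_reference_coverage,
                 folded_region = folded_region,
                 folded_tolerance = folded_tolerance,
                 accepted_reference_ids = as.character(accepted_reference_ids)),
            class = "filter_config")
}

#' Keep hits at or below an E-value cutoff
#'
#' The cutoff is inclusive (`evalue <= cutoff`), matching common search-tool
#' semantics. Row order is preserved.
#'
#' @param hits hit-table data.frame.
#' @param cutoff maximum E-value (>= 0).
#' @return The subset of `hits` passing the cutoff.
#' @export
apply_evalue_cutoff <- function(hits, cutoff) {
  stopifnot(cutoff >= 0)
  validate_hits(hits)
  hits[hits$evalue <= cutoff, , drop = FALSE]
}

#' Reciprocal top-hit acceptance
#'
#' A candidate is accepted if and only if the subject of its maximal
#' bit-score reverse hit is one of the accepted reference identifiers.
#' Ties at the top bit score accept if any tied subject is an accepted
#' reference. Candidates with no reverse hit are rejected.
#'
#' @param candidates character vector of candidate sequence ids.
#' @param reverse_hits hit table of the reverse search, with candidates as
#'   queries (`qseqid`).
#' @param accepted_reference_ids ids whose top-ranking status accepts a
#'   candidate.
#' @return Character vector of accepted candidates, in input order.
#' @export
reciprocal_filter <- function(candidates, reverse_hits,
                              accepted_reference_ids) {
  validate_hits(reverse_hits)
  accepted <- vapply(candidates, function(cand) {
    rh <- reverse_hits[reverse_hits$qseqid == cand, , drop = FALSE]
    if (!nrow(rh)) return(FALSE)
    top <- rh$sseqid[rh$bitscore == max(rh$bitscore)]
    any(top %in% accepted_reference_ids)
  }, logical(1))
  candidates[accepted]
}

# Pooled residue coverage on the subject (or query) for each hit's
# (qseqid, sseqid) pair: all spans of the pair are unioned.
.pair_covered_ranges <- function(hits, on = c("subject", "query")) {
  on <- match.arg(on)
  if (on == "subject") {
    starts <- hits$sstart; ends <- hits$send
  } else {
    starts <- hits$qstart; ends <- hits$qend
  }
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  ir <- split(IRanges::IRanges(start = starts, end = ends), key)
  lapply(ir, IRanges::reduce)
}

#' Reference-coverage filter
#'
#' A hit passes when the union of reference residues covered by the aligned
#' spans of its query-reference pair, divided by the reference length, is at
#' least `min_fraction` (inclusive). Multiple hits of the same pair pool
#' their spans, so a pair represented by several partial alignments is judged
#' on their union.
#'
#' @param hits hit-table data.frame.
#' @param reference_lengths named numeric vector, id -> length in residues of
#'   the sequence carrying the coverage coordinates (the subject by default).
#' @param min_fraction minimum covered fraction (0-1], inclusive.
#' @param on compute coverage on the `"subject"` (default: the reference is
#'   the forward-search subject) or on the `"query"`.
#' @return The subset of `hits` whose pair passes.
#' @export
coverage_filter <- function(hits, reference_lengths, min_fraction,
                            on = c("subject", "query")) {
  on <- match.arg(on)
  validate_hits(hits)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (!nrow(hits)) return(hits)
  ref_ids <- if (on == "subject") hits$sseqid else hits$qseqid
  missing <- setdiff(unique(ref_ids), names(reference_lengths))
  if (length(missing))
    stop("no reference length known for: ", paste(missing, collapse = ", "))
  cov <- .pair_covered_ranges(hits, on)
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  frac <- vapply(seq_len(nrow(hits)), function(i) {
    covered <- sum(IRanges::width(cov[[key[i]]]))
    covered / reference_lengths[[ref_ids[i]]]
  }, numeric(1))
  hits[frac >= min_fraction, , drop = FALSE]
}

#' Folded-region representation filter
#'
#' A hit passes when at most `tolerance` residues of the folded region of the
#' reference are left uncovered by the aligned span(s) of its pair (spans of
#' the same query-reference pair are pooled). The tolerance is a total
#' uncovered-residue budget over the whole folded region, not per terminus.
#'
#' @param hits hit-table data.frame (coverage coordinates on the subject).
#' @param folded_region 1-based inclusive `c(start, end)` on the reference.
#' @param tolerance maximum number of uncovered folded-region residues.
#' @param reference_lengths optional named lengths used to check that the
#'   folded region lies within each reference.
#' @return The subset of `hits` passing.
#' @export
folded_region_filter <- function(hits, folded_region, tolerance,
                                 reference_lengths = NULL) {
  validate_hits(hits)
  stopifnot(length(folded_region) == 2L, tolerance >= 0)
  if (folded_region[1] < 1 || folded_region[1] > folded_region[2])
    stop("invalid folded region")
  if (!is.null(reference_lengths) && nrow(hits)) {
    lens <- reference_lengths[unique(hits$sseqid)]
    if (any(!is.na(lens) & folded_region[2] > lens))
      stop("folded region extends beyond the reference sequence")
  }
  if (!nrow(hits)) return(hits)
  fold_width <- folded_region[2] - folded_region[1] + 1
  cov <- .pair_covered_ranges(hits, "subject")
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  uncovered <- vapply(seq_len(nrow(hits)), function(i) {
    inside <- IRanges::restrict(cov[[key[i]]],
                                start = folded_region[1],
                                end = folded_region[2])
    fold_width - sum(IRanges::width(inside))
  }, numeric(1))
  hits[uncovered <= tolerance, , drop = FALSE]
}

#' Run the full homolog acceptance chain
#'
#' Applies, in order: the E-value cutoff on the forward hits, the reciprocal
#' top-hit rule on the reverse hits, the reference-coverage filter and the
#' folded-region filter. A candidate is accepted when it passes the
#' reciprocal rule and retains at least one forward hit to an accepted
#' reference after every hit-level filter.
#'
#' @param forward forward-search hit table (candidates as queries, reference
#'   paralogs as subjects).
#' @param reverse reverse-search hit table (candidates as queries against the
#'   reference proteome).
#' @param config a [filter_config()].
#' @param reference_lengths named lengths of the reference sequences.
#' @return list with `accepted` (character vector) and `report`, a
#'   per-candidate data.frame of pass/fail flags per rule.
#' @export
filter_chain <- function(forward, reverse, config, reference_lengths) {
  stopifnot(inherits(config, "filter_config"))
  validate_hits(forward); validate_hits(reverse)
  if (length(config$accepted_reference_ids))
    forward <- forward[forward$sseqid %in% config$accepted_reference_ids, ,
                       drop = FALSE]
  candidates <- unique(forward$qseqid)

  h1 <- apply_evalue_cutoff(forward, config$evalue_cutoff)
  pass_evalue <- candidates %in% h1$qseqid

  recip <- reciprocal_filter(candidates, reverse,
                             config$accepted_reference_ids)
  pass_recip <- candidates %in% recip

  h2 <- coverage_filter(h1, reference_lengths,
                        config$min_reference_coverage)
  pass_cov <- candidates %in% h2$qseqid

  if (!is.null(config$folded_region)) {
    h3 <- folded_region_filter(h2, config$folded_region,
                               config$folded_tolerance, reference_lengths)
  } else h3 <- h2
  pass_fold <- candidates %in% h3$qseqid

  accepted_flag <- pass_evalue & pass_recip & pass_cov & pass_fold
  report <- data.frame(candidate = candidates,
                       pass_evalue = pass_evalue,
                       pass_reciprocal = pass_recip,
                       pass_coverage = pass_cov,
                       pass_folded = pass_fold,
                       accepted = accepted_flag,
                       stringsAsFactors = FALSE)
  list(accepted = candidates[accepted_flag], report = report)
}
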