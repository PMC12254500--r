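#' Simulate forward and reverse hit tables for a simulated family
#'
#' Runs the desk-scale [local_search()] of every simulated sequence against
#' each reference (the forward table) and likewise against the full
#' reference set standing in for a proteome (the reverse table), emitting
#' 12-column tabular records that round-trip through [parse_hit_table()].
#' Empty candidate sequences are skipped with a warning.
#'
#' @param sim a [simulate_family()] result, or a named character vector of
#'   candidate protein sequences.
#' @param references named character vector of reference protein sequences
#'   (must be non-empty). For a meaningful reverse search this set should
#'   include decoy proteins beyond the accepted references.
#' @param scoring a [search_scoring()].
#' @return list with `forward` and `reverse` hit-table data.frames
#'   (here identical search spaces: candidates as queries against the
#'   references; the semantics differ only in how the filter chain uses
#'   them).
#' @export
simulate_hit_tables <- function(sim, references,
                                scoring = search_scoring()) {
  candidates <- if (inherits(sim, "family_sim")) sim$sequences else sim
  stopifnot(is.character(candidates), !is.null(names(candidates)),
            is.character(references), length(references) > 0,
            !is.null(names(references)))
  empty <- !nzchar(candidates)
  if (any(empty)) {
    warning("skipping empty candidate sequence(s): ",
            paste(names(candidates)[empty], collapse = ", "))
    candidates <- candidates[!empty]
  }
  search_all <- function() {
    rows <- list()
    for (cand in names(candidates)) {
      for (ref in names(references)) {
        h <- local_search(candidates[[cand]], references[[ref]],
                          scoring, query_id = cand, subject_id = ref)
        if (!is.null(h)) rows[[length(rows) + 1L]] <- h
      }
    }
    if (!length(rows)) return(parse_hit_table(character(0)))
    do.call(rbind, rows)
  }
  fw <- search_all()
  list(forward = fw, reverse = fw)
}
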