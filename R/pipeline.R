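#' Pipeline configuration
#'
#' Paths and options for the end-to-end run: filter the forward/reverse
#' hit tables, classify the accepted sequences against a kinase-domain
#' model, and compute clade divergence statistics on an externally
#' inferred tree.
#'
#' @param forward_hits,reverse_hits paths to 12-column tabular hit files.
#' @param sequences path to a FASTA of candidate sequences.
#' @param reference_lengths named numeric vector of reference lengths, or a
#'   2-column TSV path (id, length).
#' @param filter a [filter_config()].
#' @param seed_alignment path to the aligned-FASTA kinase-domain seed.
#' @param triad_columns path to the triad-column sidecar TSV.
#' @param tree path to a Newick tree (optional; divergence skipped if NULL).
#' @param clades path to a leaf-to-clade TSV (required with `tree`).
#' @param clade_pairs character vector of "A:B" pairs to test.
#' @param outgroup optional outgroup leaf label for rerooting.
#' @param out_dir directory for stage outputs and the report.
#' @param seed integer seed recorded in the report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(forward_hits, reverse_hits, sequences,
                            reference_lengths, filter = filter_config(),
                            seed_alignment = NULL, triad_columns = NULL,
                            tree = NULL, clades = NULL,
                            clade_pairs = character(),
                            outgroup = NULL, out_dir = tempfile("nrbpfam_"),
                            seed = 1L) {
  structure(list(forward_hits = forward_hits, reverse_hits = reverse_hits,
                 sequences = sequences,
                 reference_lengths = reference_lengths, filter = filter,
                 seed_alignment = seed_alignment,
                 triad_columns = triad_columns,
                 tree = tree, clades = clades, clade_pairs = clade_pairs,
                 outgroup = outgroup, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the analysis pipeline end-to-end
#'
#' Stages: homolog filtering (E-value, reciprocal top hit, coverage,
#' folded region) -> pseudokinase classification of the accepted
#' sequences -> divergence statistics on the supplied tree. Each stage
#' writes its outputs into `out_dir` before the next begins, so a partial
#' failure leaves completed stage outputs intact. The machine-readable
#' report (JSON) carries per-stage counts and the fully resolved
#' configuration for provenance.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 thresholds = list(
                   evalue_cutoff = config$filter$evalue_cutoff,
                   min_reference_coverage = config$filter$min_reference_coverage,
                   folded_region = config$filter$folded_region,
                   folded_tolerance = config$filter$folded_tolerance))

  ref_len <- config$reference_lengths
  if (is.character(ref_len) && length(ref_len) == 1L) {
    tab <- utils::read.delim(ref_len, stringsAsFactors = FALSE)
    ref_len <- stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  }

  # --- stage: filter ----------------------------------------------------
  filt <- .stage("filter", {
    fw <- parse_hit_table(config$forward_hits)
    rv <- parse_hit_table(config$reverse_hits)
    res <- filter_chain(fw, rv, config$filter, ref_len)
    utils::write.table(res$report,
                       file.path(config$out_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$accepted, file.path(config$out_dir, "accepted_ids.txt"))
    res
  })
  report$filter <- list(candidates_in = nrow(filt$report),
                        accepted = length(filt$accepted))
  message(sprintf("filter: %d/%d candidates accepted",
                  length(filt$accepted), nrow(filt$report)))

  # --- stage: classify --------------------------------------------------
  if (!is.null(config$seed_alignment)) {
    cls <- .stage("classify", {
      seqs <- read_fasta(config$sequences)
      seqs <- seqs[intersect(filt$accepted, names(seqs))]
      if (!length(seqs)) {
        message("classify: 0 sequences after filtering")
        NULL
      } else {
        profile <- build_profile(read_fasta(config$seed_alignment),
                                 read_triad_columns(config$triad_columns))
        out <- classify_sequences(seqs, profile)
        utils::write.table(out,
                           file.path(config$out_dir, "triad_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out
      }
    })
    report$classify <- list(
      n_sequences = if (is.null(cls)) 0L else nrow(cls),
      pseudokinase_fraction = if (is.null(cls)) NA_real_
                              else mean(cls$is_pseudokinase))
  }

  # --- stage: divergence ------------------------------------------------
  if (!is.null(config$tree)) {
    if (!length(filt$accepted)) {
      warning("divergence stage skipped: no accepted candidates")
    } else {
      div <- .stage("divergence", {
        tree <- parse_newick(config$tree)
        if (!is.null(config$outgroup))
          tree <- root_at_outgroup(tree, config$outgroup)
        dist <- leaf_root_distances(tree)
        assign <- read_clade_assignment(config$clades)
        rep <- compare_clade_distances(dist, assign, config$clade_pairs)
        utils::write.table(
          data.frame(leaf = names(dist), distance = dist),
          file.path(config$out_dir, "leaf_root_distances.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(rep,
                           file.path(config$out_dir, "divergence_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        rep
      })
      report$divergence <- lapply(seq_len(nrow(div)), function(i)
        as.list(div[i, c("clade1", "clade2", "mean1", "mean2",
                         "t", "df", "p", "p_adj")]))
    }
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
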