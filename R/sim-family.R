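#' Configuration for the gene-family simulator
#'
#' Describes a three-clade metazoan gene family: one single-copy
#' "invertebrate" clade and two post-duplication paralog clades (P1, P2),
#' of which P2 evolves at a rate elevated by `rate_multiplier_fast_clade`.
#' With a multiplier of 1 the two paralog clades are exchangeable in
#' distribution.
#'
#' @param n_leaves_per_clade leaves per clade (positive integer).
#' @param seq_length protein length in residues (positive integer); all
#'   generated sequences have identical length.
#' @param base_rate expected substitutions per site per branch-time unit
#'   (>= 0).
#' @param rate_multiplier_fast_clade relative rate of the fast (P2) clade
#'   (>= 0).
#' @param triad_state_per_clade named character vector mapping each clade
#'   label (invertebrate, P1, P2) to "intact" or "degenerate". The default
#'   is degenerate everywhere: the family emulated is one in which every
#'   member is a pseudokinase.
#' @param seed integer seed; a single seed expands into independent
#'   sub-streams for the tree, the ancestral sequence and the evolution
#'   along branches.
#' @return list of class `family_sim_config`.
#' @export
family_sim_config <- function(n_leaves_per_clade,
                              seq_length = 300L,
                              base_rate = 0.05,
                              rate_multiplier_fast_clade = 1,
                              triad_state_per_clade = c(
                                invertebrate = "degenerate",
                                P1 = "degenerate",
                                P2 = "degenerate"),
                              seed = 1L) {
  if (!is.numeric(n_leaves_per_clade) || n_leaves_per_clade < 2 ||
      n_leaves_per_clade != round(n_leaves_per_clade))
    stop("n_leaves_per_clade must be an integer >= 2")
  if (!is.numeric(seq_length) || seq_length < 10 ||
      seq_length != round(seq_length))
    stop("seq_length must be a positive integer >= 10")
  stopifnot(base_rate >= 0, rate_multiplier_fast_clade >= 0)
  clades <- c("invertebrate", "P1", "P2")
  if (!all(clades %in% names(triad_state_per_clade)) ||
      !all(triad_state_per_clade[clades] %in% c("intact", "degenerate")))
    stop("triad_state_per_clade must map invertebrate/P1/P2 to ",
         "'intact' or 'degenerate'")
  structure(list(n_leaves_per_clade = as.integer(n_leaves_per_clade),
                 seq_length = as.integer(seq_length),
                 base_rate = base_rate,
                 rate_multiplier_fast_clade = rate_multiplier_fast_clade,
                 triad_state_per_clade = triad_state_per_clade[clades],
                 seed = as.integer(seed)),
            class = "family_sim_config")
}

# Balanced binary topology over the given labels. Internal edges have the
# deterministic length `internal_len`; pendant edges draw from
# `pendant_fun(k)`. Randomness confined to pendant edges keeps
# leaf-to-root distances i.i.d. within a clade, so downstream two-sample
# tests are calibrated.
.balanced_newick <- function(labels, internal_len, pendant_lens) {
  build <- function(idx, top) {
    if (length(idx) == 1L)
      return(sprintf("%s:%.8f", labels[idx], pendant_lens[idx]))
    half <- ceiling(length(idx) / 2)
    s <- sprintf("(%s,%s)",
                 build(idx[seq_len(half)], FALSE),
                 build(idx[-seq_len(half)], FALSE))
    if (top) s else sprintf("%s:%.8f", s, internal_len)
  }
  build(seq_along(labels), TRUE)
}

.derive_streams <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Simulate a three-clade gene family with known ground truth
#'
#' Generates an outgroup-rooted tree with the invertebrate clade sister to
#' the paralog pair (P1, P2), evolves protein sequences along it under an
#' i.i.d. per-site replacement process (substitution probability
#' 1 - exp(-branch length), uniform over the other 19 residues), scales
#' every branch inside the fast P2 clade by the configured rate
#' multiplier, and plants the configured catalytic-triad states: leaves of
#' "intact" clades carry K/D/D at the triad positions, leaves of
#' "degenerate" clades carry random non-consensus residues at all three.
#' Identical configuration and seed give byte-identical output.
#'
#' @param config a [family_sim_config()].
#' @return list of class `family_sim`: `sequences` (named character
#'   vector), `true_tree` (`ape::phylo`, branch lengths in substitutions
#'   per site), `true_labels` (leaf -> clade), `true_triad_states`
#'   (leaf -> intact/degenerate), `triad_positions` (the three residue
#'   positions, named beta3_K/HRD_D/DFG_D), and the config.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "family_sim_config"))
  n <- config$n_leaves_per_clade
  L <- config$seq_length
  rate <- config$base_rate
  rho <- config$rate_multiplier_fast_clade
  streams <- .derive_streams(config$seed, 3L)

  leaf <- function(clade) sprintf("%s_%d", clade, seq_len(n))
  labels <- list(invertebrate = leaf("invertebrate"),
                 P1 = leaf("P1"), P2 = leaf("P2"))

  # --- tree stream ------------------------------------------------------
  set.seed(streams[1])
  pend <- function(scale) stats::rexp(n, rate = 1 / (rate * scale + 1e-12))
  nwk_inv <- .balanced_newick(labels$invertebrate, rate, pend(1))
  nwk_p1 <- .balanced_newick(labels$P1, rate, pend(1))
  nwk_p2 <- .balanced_newick(labels$P2, rate * rho, pend(rho))
  # stems: invertebrate clade vs the duplication node under the root
  newick <- sprintf("(%s:%.8f,(%s:%.8f,%s:%.8f):%.8f);",
                    nwk_inv, rate, nwk_p1, rate, nwk_p2, rate * rho, rate)
  tree <- ape::read.tree(text = newick)

  # --- ancestral sequence stream ---------------------------------------
  triad_positions <- stats::setNames(
    as.integer(round(L * c(0.20, 0.50, 0.65))), names(TRIAD_CONSENSUS))
  set.seed(streams[2])
  anc <- sample(.AA20, L, replace = TRUE)
  anc[triad_positions] <- TRIAD_CONSENSUS

  # --- evolution stream -------------------------------------------------
  set.seed(streams[3])
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- anc
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    bl <- ord$edge.length[k]
    p_sub <- 1 - exp(-bl)
    s <- seqs[[parent]]
    hit <- which(stats::runif(L) < p_sub)
    if (length(hit)) {
      repl <- vapply(s[hit], function(res)
        sample(setdiff(.AA20, res), 1L), character(1))
      s[hit] <- repl
    }
    s[triad_positions] <- anc[triad_positions]  # triad held invariant
    seqs[[child]] <- s
  }

  # --- plant triad states ----------------------------------------------
  true_labels <- stats::setNames(
    rep(names(labels), times = lengths(labels)), unlist(labels))
  true_states <- stats::setNames(
    unname(config$triad_state_per_clade[true_labels]), names(true_labels))
  sequences <- character(ntip)
  names(sequences) <- tree$tip.label
  for (i in seq_len(ntip)) {
    s <- seqs[[i]]
    lab <- tree$tip.label[i]
    if (true_states[[lab]] == "degenerate") {
      s[triad_positions] <- vapply(TRIAD_CONSENSUS, function(res)
        sample(setdiff(.AA20, res), 1L), character(1))
    }
    sequences[i] <- paste(s, collapse = "")
  }

  structure(list(sequences = sequences,
                 true_tree = tree,
                 true_labels = true_labels[tree$tip.label],
                 true_triad_states = true_states[tree$tip.label],
                 triad_positions = triad_positions,
                 config = config),
            class = "family_sim")
}

#' @export
print.family_sim <- function(x, ...) {
  cat(sprintf("simulated family: %d leaves (%s), %d residues, rate x%.2g in P2\n",
              length(x$sequences),
              paste(names(table(x$true_labels)), collapse = "/"),
              x$config$seq_length,
              x$config$rate_multiplier_fast_clade))
  invisible(x)
}

#' Write the simulator outputs to standard text formats
#'
#' FASTA for the sequences, Newick for the true tree (branch lengths in
#' substitutions per site), and two TSVs for the leaf-to-clade and
#' leaf-to-triad-state maps.
#'
#' @param sim a [simulate_family()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_family_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "family_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "family.fasta"),
             tree = file.path(dir, "family.nwk"),
             clades = file.path(dir, "clades.tsv"),
             triads = file.path(dir, "triad_states.tsv"))
  write_fasta(sim$sequences, paths["fasta"])
  ape::write.tree(sim$true_tree, paths["tree"])
  utils::write.table(
    data.frame(leaf = names(sim$true_labels), clade = sim$true_labels),
    paths["clades"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(leaf = names(sim$true_triad_states),
               triad_state = sim$true_triad_states),
    paths["triads"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
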