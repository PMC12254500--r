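#' Parse a Newick tree
#'
#' Wraps the ape parser with a light well-formedness check that reports the
#' character offset of unbalanced parentheses. Internal-node labels are kept
#' and, when numeric, are interpreted as support values (the usual
#' convention of ultrafast-bootstrap annotated trees).
#'
#' @param text Newick string, or the path of a file containing one.
#' @return an `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop(sprintf("malformed Newick: unbalanced ')' at character %d",
                 which(depth < 0)[1]))
  if (depth[length(depth)] != 0)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input",
                 depth[length(depth)]))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  tree
}

#' Root a tree on an outgroup leaf
#'
#' Places the outgroup as sister to everything else, splitting the
#' outgroup's pendant branch length equally across the two edges incident
#' to the new root.
#'
#' @param tree an `ape::phylo`.
#' @param outgroup a leaf label present in the tree.
#' @return the rerooted `ape::phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(outgroup, tree$tip.label)
  if (is.na(tip)) stop("outgroup leaf not found in tree: ", outgroup)
  edge_len <- tree$edge.length[tree$edge[, 2] == tip]
  phytools::reroot(tree, tip, position = edge_len / 2)
}

#' Leaf-to-root path distances
#'
#' The distance of each leaf is the sum of branch lengths along the unique
#' path from the root to that leaf (substitutions per site when the tree's
#' branch lengths are).
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @return named numeric vector, leaf label -> distance.
#' @export
leaf_root_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- tree$edge[which(is.na(tree$edge.length))[1], 2]
    lab <- if (bad <= length(tree$tip.label)) tree$tip.label[bad]
           else paste0("internal node ", bad)
    stop("missing branch length above ", lab)
  }
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Test a leaf set for monophyly and return the clade's support
#'
#' TRUE when some node's descendant-leaf set equals the given set exactly;
#' the support value parsed from that node's label is returned alongside
#' (NA when the node is unlabelled or the label is not numeric).
#'
#' @param tree a rooted `ape::phylo`.
#' @param leaves character vector of leaf labels.
#' @return list with `monophyletic` (logical) and `support` (numeric or NA).
#' @export
is_monophyletic <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"), length(leaves) > 0)
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown))
    stop("unknown leaves: ", paste(unknown, collapse = ", "))
  ntip <- length(tree$tip.label)
  if (length(leaves) == 1L)
    return(list(monophyletic = TRUE, support = NA_real_))
  mrca <- ape::getMRCA(tree, leaves)
  clade_tips <- ape::extract.clade(tree, mrca)$tip.label
  mono <- setequal(clade_tips, leaves)
  support <- NA_real_
  if (mono && !is.null(tree$node.label)) {
    lab <- tree$node.label[mrca - ntip]
    if (!is.na(lab) && nzchar(lab))
      support <- suppressWarnings(as.numeric(lab))
  }
  list(monophyletic = mono, support = support)
}

.welch_flagged <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  s1 <- stats::var(x); s2 <- stats::var(y)
  if (s1 == 0 && s2 == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = n1 + n2 - 2, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = n1 + n2 - 2,
                p = .Machine$double.xmin, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Clade-wise divergence comparison
#'
#' For each requested clade pair, compares the leaf-to-root distance samples
#' with a two-sided Welch t-test (Welch-Satterthwaite degrees of freedom)
#' and adjusts the p-values across pairs with the Benjamini-Hochberg
#' step-up. Clades whose two samples are both constant are reported with
#' the conventional values t = 0, p = 1 (equal means) or p at the machine
#' floor (unequal means) and flagged as degenerate rather than raising, so
#' pipelines survive constant clades.
#'
#' @param distances named numeric vector of leaf-to-root distances.
#' @param assignment named character vector, leaf label -> clade label.
#' @param pairs list of length-2 character vectors (or "A:B" strings) of
#'   clade labels to test.
#' @return data.frame of class `divergence_report`: one row per pair with
#'   group means/sds/sizes, Welch t, df, two-sided p, BH-adjusted p and a
#'   degeneracy flag.
#' @export
compare_clade_distances <- function(distances, assignment, pairs) {
  stopifnot(!is.null(names(distances)), !is.null(names(assignment)))
  if (is.character(pairs)) pairs <- strsplit(pairs, ":", fixed = TRUE)
  missing <- setdiff(names(assignment), names(distances))
  clades <- split(names(assignment), unname(assignment))
  samples <- lapply(clades, function(lv) {
    unname(distances[intersect(lv, names(distances))])
  })
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    for (cl in pr) {
      if (is.null(samples[[cl]]))
        stop("clade not present in assignment: ", cl)
      if (length(samples[[cl]]) < 2L)
        stop("clade with fewer than 2 leaves: ", cl)
    }
    x <- samples[[pr[1]]]; y <- samples[[pr[2]]]
    w <- .welch_flagged(x, y)
    data.frame(clade1 = pr[1], clade2 = pr[2],
               n1 = length(x), n2 = length(y),
               mean1 = mean(x), mean2 = mean(y),
               sd1 = stats::sd(x), sd2 = stats::sd(y),
               t = w$t, df = w$df, p = w$p,
               degenerate = w$degenerate,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$p_adj <- stats::p.adjust(report$p, method = "BH")
  class(report) <- c("divergence_report", class(report))
  report
}

#' Paired comparison of per-sequence scores against two references
#'
#' Two-sided paired t-test on the within-pair differences (e.g. bit scores
#' of the same query against reference 1 vs reference 2), with df = n - 1.
#' Also reports the fraction of pairs favoring reference 1. Degenerate
#' inputs follow the zero-variance convention: all-zero differences give
#' t = 0, p = 1; constant non-zero differences give an infinite t with p
#' reported at the machine floor, flagged.
#'
#' @param scores1,scores2 numeric vectors of paired scores (same length,
#'   n >= 2).
#' @return list: mean_difference, t, df, p, fraction_favoring_ref1,
#'   degenerate flag.
#' @export
paired_score_test <- function(scores1, scores2) {
  stopifnot(length(scores1) == length(scores2), length(scores1) >= 2)
  d <- scores1 - scores2
  n <- length(d)
  frac <- mean(d > 0)
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(mean_difference = 0, t = 0, df = n - 1, p = 1,
                  fraction_favoring_ref1 = frac, degenerate = TRUE))
    return(list(mean_difference = mean(d), t = sign(mean(d)) * Inf,
                df = n - 1, p = .Machine$double.xmin,
                fraction_favoring_ref1 = frac, degenerate = TRUE))
  }
  ht <- stats::t.test(d)
  list(mean_difference = mean(d), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value,
       fraction_favoring_ref1 = frac, degenerate = FALSE)
}

#' Read a leaf-to-clade assignment table
#'
#' Two-column TSV: leaf id, clade label (header optional; detected from the
#' first line).
#'
#' @param path TSV file.
#' @return named character vector, leaf -> clade.
#' @export
read_clade_assignment <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("leaf|clade", tolower(first))
  tab <- utils::read.delim(path, header = header,
                           stringsAsFactors = FALSE)
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}
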