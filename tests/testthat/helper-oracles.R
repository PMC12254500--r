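# Independent oracles used to cross-check the package's implementations.
# These deliberately avoid the code paths they verify: textbook formulas,
# exhaustive enumeration and per-residue brute force only.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# --- Welch / BH / paired t, from the textbook formulas -------------------

oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  # step-up: running minimum from the largest rank down
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

oracle_paired_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# --- per-residue coverage brute force ------------------------------------

# fraction of 1..ref_len covered by the union of inclusive spans
oracle_coverage <- function(spans, ref_len) {
  covered <- logical(ref_len)
  for (sp in spans) covered[sp[1]:sp[2]] <- TRUE
  mean(covered)
}

oracle_uncovered_in_region <- function(spans, region) {
  residues <- region[1]:region[2]
  covered <- logical(length(residues))
  for (sp in spans) covered[residues >= sp[1] & residues <= sp[2]] <- TRUE
  sum(!covered)
}

# --- brute-force global profile alignment --------------------------------

# Enumerates every global alignment of a profile (scores: 20 x C) with a
# sequence, scoring matches by the column's residue score and gap runs by
# -(open + (len-1) * extend); switching between profile-gaps and
# sequence-insertions opens a new gap. Exponential: use only for C, n <= ~12.
oracle_profile_align <- function(scores, seq_idx, gap_open, gap_extend) {
  C <- ncol(scores); n <- length(seq_idx)
  colmin <- apply(scores, 2, min)
  res_score <- function(i, j) {
    r <- seq_idx[j]
    if (r >= 1 && r <= 20) scores[r, i] else colmin[i]
  }
  best <- -Inf
  recurse <- function(i, j, acc, prev) {
    # i columns and j residues consumed; prev in {"M","D","I",""}
    if (i == C && j == n) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i < C && j < n)
      recurse(i + 1, j + 1, acc + res_score(i + 1, j + 1), "M")
    if (i < C)
      recurse(i + 1, j, acc - if (prev == "D") gap_extend else gap_open, "D")
    if (j < n)
      recurse(i, j + 1, acc - if (prev == "I") gap_extend else gap_open, "I")
  }
  recurse(0, 0, 0, "")
  best
}

# --- misc ---------------------------------------------------------------

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# random alignment with the given gap probability
random_alignment <- function(n_rows, n_cols, gap_prob) {
  rows <- replicate(n_rows, {
    chars <- sample(AA20, n_cols, replace = TRUE)
    gaps <- runif(n_cols) < gap_prob
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  })
  stats::setNames(rows, sprintf("row%d", seq_len(n_rows)))
}

oracle_mask <- function(aln, max_gap_fraction) {
  m <- do.call(rbind, strsplit(unname(aln), ""))
  keep <- integer(0)
  for (j in seq_len(ncol(m))) {
    gf <- sum(m[, j] %in% c("-", ".")) / nrow(m)
    if (gf < max_gap_fraction) keep <- c(keep, j)
  }
  keep
}
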