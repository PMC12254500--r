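test_that("Newick parsing keeps topology, lengths and support labels", {
  tr <- parse_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$Nnode, 2L)
  tr2 <- parse_newick("((A:1,B:1)100:1,C:1);")
  expect_equal(is_monophyletic(tr2, c("A", "B"))$support, 100)
  expect_error(parse_newick("((A:1,B:2):0.5,C:3;"), "unclosed")
  expect_error(parse_newick("(A:1))B;"), "character 6")
})

test_that("rerooting splits the outgroup branch 50/50", {
  tr <- parse_newick("((A:1,B:2):0.5,C:3);")
  tr2 <- root_at_outgroup(tr, "C")
  d <- leaf_root_distances(tr2)
  expect_equal(d[["C"]], 1.5)
  expect_equal(d[["A"]], 1.5 + 0.5 + 1)   # hand path-sum
  expect_equal(d[["B"]], 1.5 + 0.5 + 2)
  expect_error(root_at_outgroup(tr, "Z"), "not found")
})

test_that("leaf-to-root distances are path sums of branch lengths", {
  expect_equal(leaf_root_distances(parse_newick("(A:1,B:2);")),
               c(A = 1, B = 2))
  expect_equal(leaf_root_distances(
    parse_newick("((A:0.1,B:0.2):0.3,C:0.4);")),
    c(A = 0.4, B = 0.5, C = 0.4))
  # zero-length branches contribute nothing
  expect_equal(leaf_root_distances(
    parse_newick("(((A:1):0,B:2):0,C:3);"))[["A"]], 1)
})

test_that("distances are invariant to child rotation and serialization", {
  d1 <- leaf_root_distances(parse_newick("((A:0.1,B:0.2):0.3,C:0.4);"))
  d2 <- leaf_root_distances(parse_newick("(C:0.4,(B:0.2,A:0.1):0.3);"))
  expect_equal(d1[sort(names(d1))], d2[sort(names(d2))])
})

test_that("monophyly detection matches exact descendant sets", {
  tr <- parse_newick("((A:1,B:1)95:1,C:1);")
  expect_true(is_monophyletic(tr, c("A", "B"))$monophyletic)
  expect_false(is_monophyletic(tr, c("A", "C"))$monophyletic)
  whole <- is_monophyletic(tr, c("A", "B", "C"))
  expect_true(whole$monophyletic)
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
})

test_that("Welch comparison reproduces the textbook example", {
  d <- stats::setNames(c(2, 4, 6, 1, 2, 3),
                       c("x1", "x2", "x3", "y1", "y2", "y3"))
  asg <- stats::setNames(rep(c("X", "Y"), each = 3), names(d))
  rep <- compare_clade_distances(d, asg, list(c("X", "Y")))
  expect_equal(rep$t, 1.549193, tolerance = 1e-6)
  expect_equal(rep$df, 2.941176, tolerance = 1e-6)
  o <- oracle_welch(c(2, 4, 6), c(1, 2, 3))
  expect_equal(rep$p, o$p, tolerance = 1e-12)
})

test_that("identical clades give t = 0, p = 1; degenerate clades are flagged", {
  d <- stats::setNames(c(1, 2, 3, 1, 2, 3), sprintf("l%d", 1:6))
  asg <- stats::setNames(rep(c("X", "Y"), each = 3), names(d))
  rep <- compare_clade_distances(d, asg, list(c("X", "Y")))
  expect_equal(rep$t, 0)
  expect_equal(rep$p, 1)
  dc <- stats::setNames(c(1, 1, 2, 2), sprintf("l%d", 1:4))
  asgc <- stats::setNames(rep(c("X", "Y"), each = 2), names(dc))
  repc <- compare_clade_distances(dc, asgc, list(c("X", "Y")))
  expect_true(repc$degenerate)
  expect_true(is.infinite(repc$t))
  expect_error(compare_clade_distances(dc[1:3], asgc[1:3],
                                       list(c("X", "Y"))), "fewer than 2")
})

test_that("Welch results match the textbook formulas on random samples", {
  set.seed(51)
  for (rep in 1:100) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    d <- stats::setNames(c(x, y),
                         sprintf("l%d", seq_len(length(x) + length(y))))
    asg <- stats::setNames(rep(c("X", "Y"), c(length(x), length(y))),
                           names(d))
    got <- compare_clade_distances(d, asg, list(c("X", "Y")))
    want <- oracle_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("BH adjustment is a step-up: monotone, bounded, identity at m=1", {
  d <- stats::setNames(rnorm(40), sprintf("l%d", 1:40))
  asg <- stats::setNames(rep(c("A", "B", "C", "D"), each = 10), names(d))
  rep <- compare_clade_distances(
    d, asg, list(c("A", "B"), c("A", "C"), c("A", "D")))
  expect_equal(rep$p_adj, oracle_bh(rep$p), tolerance = 1e-12)
  expect_true(all(rep$p_adj >= rep$p))
  expect_true(all(rep$p_adj <= 1))
  ord <- order(rep$p)
  expect_true(all(diff(rep$p_adj[ord]) >= 0))
  one <- compare_clade_distances(d, asg, list(c("A", "B")))
  expect_equal(one$p_adj, one$p)
  # worked step-up case: 0.01, 0.02, 0.03 over three pairs -> all 0.03
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
})

test_that("the paired score test matches its textbook formula", {
  res <- paired_score_test(c(2, 3, 4), c(0, 0, 0))
  o <- oracle_paired_t(c(2, 3, 4))
  expect_equal(res$t, o$t, tolerance = 1e-12)      # 3 * sqrt(3)
  expect_equal(res$df, 2)
  expect_equal(res$p, o$p, tolerance = 1e-12)
  expect_equal(res$fraction_favoring_ref1, 1)
  set.seed(53)
  for (rep in 1:100) {
    a <- rnorm(sample(3:40, 1)); b <- rnorm(length(a), 0.3)
    got <- paired_score_test(a, b)
    want <- oracle_paired_t(a - b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("degenerate paired differences follow the zero-variance convention", {
  all_one <- paired_score_test(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_true(all_one$degenerate)
  expect_true(is.infinite(all_one$t))
  expect_lte(all_one$p, .Machine$double.xmin)
  sym <- paired_score_test(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
})
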