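mk_hit <- function(q = "q", s = "REF1", ev = 1e-50, sstart = 1, send = 500,
                   bit = 300) {
  hit_record(q, s, 90, send - sstart + 1, 10, 0, 1, send - sstart + 1,
             sstart, send, ev, bit)
}

test_that("the E-value cutoff is inclusive and order-preserving", {
  hits <- rbind(mk_hit("a", ev = 1e-30), mk_hit("b", ev = 1e-20),
                mk_hit("c", ev = 1e-28))
  kept <- apply_evalue_cutoff(hits, 1e-28)
  expect_equal(kept$qseqid, c("a", "c"))
})

test_that("reciprocal filter accepts on top-ranking reference, ties accept", {
  rv <- rbind(
    mk_hit("good", "NRBP1_HUMAN", bit = 300),
    mk_hit("good", "KIN_OTHER", bit = 200),
    mk_hit("bad", "KIN_OTHER", bit = 300),
    mk_hit("bad", "NRBP1_HUMAN", bit = 250),
    mk_hit("tie", "NRBP1_HUMAN", bit = 280),
    mk_hit("tie", "KIN_OTHER", bit = 280))
  acc <- reciprocal_filter(c("good", "bad", "tie", "norev"), rv,
                           c("NRBP1_HUMAN", "NRBP2_HUMAN"))
  expect_setequal(acc, c("good", "tie"))
})

test_that("coverage filter is inclusive at the threshold and pools spans", {
  lens <- c(REF1 = 500)
  expect_equal(nrow(coverage_filter(mk_hit(sstart = 1, send = 400),
                                    lens, 0.80)), 1L)     # 0.80 exactly
  expect_equal(nrow(coverage_filter(mk_hit(sstart = 1, send = 399),
                                    lens, 0.80)), 0L)
  two <- rbind(mk_hit(sstart = 1, send = 250), mk_hit(sstart = 200,
                                                      send = 450))
  # union 1-450 = 450/500 = 0.90, against the per-residue oracle
  expect_equal(oracle_coverage(list(c(1, 250), c(200, 450)), 500), 0.90)
  expect_equal(nrow(coverage_filter(two, lens, 0.80)), 2L)
})

test_that("folded-region filter counts uncovered residues against tolerance", {
  lens <- c(REF1 = 500)
  full <- mk_hit(sstart = 44, send = 500)
  expect_equal(nrow(folded_region_filter(full, c(44, 500), 40, lens)), 1L)
  over <- mk_hit(sstart = 85, send = 500)   # 41 uncovered
  expect_equal(nrow(folded_region_filter(over, c(44, 500), 40, lens)), 0L)
  mid <- mk_hit(sstart = 60, send = 490)    # 16 + 10 = 26 uncovered
  expect_equal(oracle_uncovered_in_region(list(c(60, 490)), c(44, 500)), 26)
  expect_equal(nrow(folded_region_filter(mid, c(44, 500), 40, lens)), 1L)
  expect_error(folded_region_filter(full, c(44, 600), 40, lens), "beyond")
})

test_that("interval-union coverage equals per-residue brute force", {
  set.seed(11)
  for (rep in 1:200) {
    ref_len <- sample(50:1000, 1)
    k <- sample(1:4, 1)
    spans <- replicate(k, sort(sample(ref_len, 2, replace = TRUE)),
                       simplify = FALSE)
    hits <- do.call(rbind, lapply(spans, function(sp)
      mk_hit(sstart = sp[1], send = sp[2])))
    frac <- oracle_coverage(spans, ref_len)
    thr <- runif(1, 0.1, 1)
    got <- nrow(coverage_filter(hits, c(REF1 = ref_len), thr)) > 0
    expect_equal(got, frac >= thr)
    region <- sort(sample(ref_len, 2, replace = TRUE))
    tol <- sample(0:50, 1)
    unc <- oracle_uncovered_in_region(spans, region)
    gotf <- nrow(folded_region_filter(hits, region, tol,
                                      c(REF1 = ref_len))) > 0
    expect_equal(gotf, unc <= tol)
  }
})

test_that("relaxing any threshold never shrinks the accepted set", {
  fw <- parse_hit_table(system.file("extdata", "toy_forward_hits.tsv",
                                    package = "nrbpfam"))
  rv <- parse_hit_table(system.file("extdata", "toy_reverse_hits.tsv",
                                    package = "nrbpfam"))
  lens <- c(REF1 = 500, REF2 = 480)
  base <- filter_config(1e-28, 0.80, c(44, 500), 40, c("REF1", "REF2"))
  acc0 <- filter_chain(fw, rv, base, lens)$accepted
  relaxed <- list(
    filter_config(1e-20, 0.80, c(44, 500), 40, c("REF1", "REF2")),
    filter_config(1e-28, 0.70, c(44, 500), 40, c("REF1", "REF2")),
    filter_config(1e-28, 0.80, c(44, 500), 80, c("REF1", "REF2")))
  for (cfg in relaxed) {
    acc <- filter_chain(fw, rv, cfg, lens)$accepted
    expect_true(all(acc0 %in% acc))
  }
})

test_that("each filter is idempotent", {
  hits <- rbind(mk_hit("a", ev = 1e-30, sstart = 1, send = 450),
                mk_hit("b", ev = 1e-10, sstart = 100, send = 300))
  once <- apply_evalue_cutoff(hits, 1e-28)
  expect_equal(apply_evalue_cutoff(once, 1e-28), once)
  lens <- c(REF1 = 500)
  cov1 <- coverage_filter(hits, lens, 0.5)
  expect_equal(coverage_filter(cov1, lens, 0.5), cov1)
  f1 <- folded_region_filter(hits, c(44, 500), 60, lens)
  expect_equal(folded_region_filter(f1, c(44, 500), 60, lens), f1)
})

test_that("the packaged toy fixture keeps exactly its documented subset", {
  fw <- parse_hit_table(system.file("extdata", "toy_forward_hits.tsv",
                                    package = "nrbpfam"))
  rv <- parse_hit_table(system.file("extdata", "toy_reverse_hits.tsv",
                                    package = "nrbpfam"))
  cfg <- filter_config(evalue_cutoff = 1e-28,
                       min_reference_coverage = 0.80,
                       folded_region = c(44, 500), folded_tolerance = 40,
                       accepted_reference_ids = c("REF1", "REF2"))
  res <- filter_chain(fw, rv, cfg, c(REF1 = 500, REF2 = 480))
  # hand-derived: c02 fails the E-value cutoff, c04 a top decoy reverse
  # hit, c07 coverage (399/500), c08 the folded tolerance (41 uncovered),
  # c10 has no reverse hit
  expect_equal(res$accepted, c("c01", "c03", "c05", "c06", "c09"))
  expect_false(res$report$pass_evalue[res$report$candidate == "c02"])
  expect_false(res$report$pass_reciprocal[res$report$candidate == "c04"])
  expect_false(res$report$pass_coverage[res$report$candidate == "c07"])
  expect_false(res$report$pass_folded[res$report$candidate == "c08"])
})
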