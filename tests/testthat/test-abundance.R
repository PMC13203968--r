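test_that("quality trimming removes terminal low-quality runs only", {
  r <- qc_trim(strrep("A", 100), rep(30L, 100))
  expect_equal(nchar(r$sequence), 100)
  # 70 bp read with 15 leading Q10 bases trims to 55 -> rejected
  expect_null(qc_trim(strrep("A", 70), c(rep(10L, 15), rep(30L, 55))))
  expect_null(qc_trim(strrep("A", 80), rep(10L, 80)))
  # interior low-quality bases survive
  q <- c(rep(10L, 5), rep(30L, 30), rep(5L, 3), rep(30L, 60), rep(10L, 2))
  r2 <- qc_trim(strrep("A", 100), q)
  expect_equal(nchar(r2$sequence), 93)
  expect_error(qc_trim("ACGT", c(30L, 30L)), "lengths differ")
})

test_that("quality trimming is idempotent", {
  reads <- sim_reads(sim_spec(seed = 21), n = 50)
  for (rd in reads$reads) {
    t1 <- qc_trim(rd$sequence, rd$qualities)
    if (is.null(t1)) next
    t2 <- qc_trim(t1$sequence, t1$qualities)
    expect_identical(t1, t2)
  }
})

test_that("planted trim points are recovered exactly", {
  reads <- sim_reads(sim_spec(seed = 22), n = 100)
  for (i in seq_along(reads$reads)) {
    rd <- reads$reads[[i]]
    out <- qc_trim(rd$sequence, rd$qualities)
    if (reads$truth$retained[i]) {
      expect_equal(nchar(out$sequence), reads$truth$trimmed_length[i])
    } else {
      expect_null(out)
    }
  }
})

test_that("alignment filter boundaries are inclusive", {
  rec <- function(al, ed, rl) data.frame(read_length = rl,
                                         aligned_length = al,
                                         edit_distance = ed)
  expect_true(filter_alignments(rec(100, 5, 100)))   # identity exactly 0.95
  expect_false(filter_alignments(rec(100, 6, 100)))
  expect_true(filter_alignments(rec(80, 0, 100)))    # length exactly 80
  expect_false(filter_alignments(rec(79, 0, 79)))
  expect_true(filter_alignments(rec(80, 0, 100)))    # fraction exactly 0.80
  expect_false(filter_alignments(rec(80, 0, 101)))   # fraction 0.792
  expect_error(filter_alignments(rec(100, 120, 100)), "edit_distance")
})

test_that("tightening filter thresholds never adds alignments", {
  sim <- sim_alignment_records(sim_spec(seed = 31), n = 500)
  base <- filter_alignments(sim$records)
  for (args in list(list(min_identity = 0.97), list(min_aligned = 90),
                    list(min_fraction = 0.9))) {
    tight <- do.call(filter_alignments, c(list(sim$records), args))
    expect_true(all(tight <= base))
  }
  # planted sub-threshold records all fail; the rest all pass
  expect_equal(!base, sim$truth$expected_fail)
})

test_that("rpkm arithmetic and scaling laws hold", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 123, 1e7), 0)
  expect_equal(rpkm(7, 1500, 2e6), 7 / 3)
  set.seed(5)
  for (i in 1:20) {
    cnt <- rpois(1, 50); len <- runif(1, 100, 5000); tot <- runif(1, 1e5, 1e8)
    expect_equal(rpkm(2 * cnt, len, tot), 2 * rpkm(cnt, len, tot))
    expect_equal(rpkm(cnt, 2 * len, tot), rpkm(cnt, len, tot) / 2)
    expect_equal(rpkm(cnt, len, 2 * tot), rpkm(cnt, len, tot) / 2)
  }
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "total")
})

test_that("read recruitment is a plain proportion", {
  expect_equal(read_recruitment(0, 10), 0)
  expect_equal(read_recruitment(10, 10), 1)
  expect_equal(read_recruitment(585, 1000), 0.585)
  expect_error(read_recruitment(11, 10), "mapped_reads")
})

test_that("marker means and the relative-abundance equations agree", {
  counts <- data.frame(
    sample_id = "s1",
    feature_id = c("A_mk1", "A_mk2", "B_mk1", "B_coxMSL"),
    count = c(20, 40, 30, 15))
  features <- data.frame(
    feature_id = c("A_mk1", "A_mk2", "B_mk1", "B_coxMSL", "C_ops"),
    cluster_id = c("A", "A", "B", "B", "C"),
    feature_type = c("marker", "marker", "marker", "operon", "operon"),
    length_bp = c(1000, 2000, 1000, 1000, 1000))
  totals <- data.frame(sample_id = "s1", total_reads = 1e6)
  cr <- cluster_rpkm(counts, features, totals)
  # hand arithmetic: A markers RPKM 20 and 20 -> mean 20; B marker 30
  expect_equal(unname(cr$marker_rpkm["s1", ]), c(20, 30))
  expect_equal(unname(cr$coxmsl_rpkm["s1", "B"]), 15)
  # cluster C has an operon but no marker gene -> excluded entirely
  expect_equal(cr$excluded_clusters, "C")
  e1 <- relative_abundance(cr$marker_rpkm)
  expect_equal(unname(e1["s1", ]), c(0.4, 0.6))
  e2 <- cox_relative_abundance(cr$coxmsl_rpkm, cr$marker_rpkm)
  # denominator is the whole-community marker sum (50), not the pcox sum
  expect_equal(unname(e2["s1", "B"]), 15 / 50)
  # a marker with count zero still enters the mean
  expect_equal(unname(relative_abundance(matrix(c(1), 1, 1))[1, 1]), 1)
})

test_that("all-zero samples give an undefined sentinel", {
  m <- matrix(c(1, 2, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  e1 <- relative_abundance(m)
  expect_equal(unname(e1["s1", ]), c(1 / 3, 2 / 3))
  expect_true(all(is.na(e1["s2", ])))
  expect_error(relative_abundance(m - 2), "nonnegative")
})

test_that("dominance threshold is inclusive over group means", {
  ab <- matrix(c(0.002, 0, 0, 0,
                 0, 0, 0.0005, 0.0015), 2, 4,
               dimnames = list(c("s1", "s2"), c("c1", "c2", "c3", "c4")))
  # groups: s1 alone, s2 alone; c1 mean 0.002 in g1; c4 mean 0.0015 in g2
  expect_setequal(dominant_clusters(ab, c("g1", "g2")), c("c1", "c4"))
  # exactly at the boundary counts
  ab2 <- matrix(0.001, 1, 1, dimnames = list("s1", "c1"))
  expect_equal(dominant_clusters(ab2, "g1"), "c1")
  expect_length(dominant_clusters(ab2 * 0, "g1"), 0)
})
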