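make_genes <- function(roles, strands, genome = "G1", contig = "c1") {
  n <- length(roles)
  data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), genome_id = genome,
    contig_id = contig, start = 1L + (seq_len(n) - 1L) * 1100L,
    end = seq_len(n) * 1100L - 100L, strand = strands, rank = seq_len(n),
    cog_id = vapply(roles, function(r) switch(r, M = "COG1319",
                                              S = "COG2080",
                                              L = NA_character_, "COG9999"),
                    character(1)),
    protein_id = ifelse(roles == "L", "p_coxL", NA),
    stringsAsFactors = FALSE)
}

test_that("homology gate keeps the E-value boundary inclusive", {
  hits <- data.frame(query_id = c("a", "b", "c", "c"),
                     evalue = c(1e-5, 1, 1, 1e-9))
  expect_equal(gate_homology(hits), c("a", "c"))  # min E-value decides c
  expect_equal(gate_homology(hits[0, ]), character(0))
  expect_error(gate_homology(data.frame(query_id = "x", evalue = -1)),
               "negative")
})

test_that("homology gate agrees with a linear-scan oracle", {
  set.seed(42)
  for (rep in 1:20) {
    hits <- data.frame(
      query_id = sample(letters[1:8], 30, replace = TRUE),
      evalue = 10^runif(30, -10, 1))
    keep <- gate_homology(hits)
    for (q in unique(hits$query_id)) {
      best <- Inf
      for (i in seq_len(nrow(hits)))
        if (hits$query_id[i] == q) best <- min(best, hits$evalue[i])
      expect_equal(q %in% keep, best <= 1e-5)
    }
  }
})

test_that("monophyly gate resolves forced clade memberships", {
  pass <- gate_monophyly("((cand,form1),(f2a,(f2b,f2c)));", "cand",
                         "form1", c("f2a", "f2b", "f2c"))
  expect_true(pass[["cand"]])
  fail <- gate_monophyly("((cand,f2a),((form1,x),(f2b,f2c)));", "cand",
                         "form1", c("f2a", "f2b", "f2c"))
  expect_false(fail[["cand"]])
})

test_that("candidates missing from the tree fail with a warning", {
  expect_warning(
    res <- gate_monophyly("((cand,form1),(f2a,(f2b,f2c)));",
                          c("cand", "ghost"), "form1",
                          c("f2a", "f2b", "f2c")),
    "ghost")
  expect_true(res[["cand"]])
  expect_false(res[["ghost"]])
})

test_that("operon detection requires coxM before coxS before coxL", {
  # canonical adjacent M, S, L on + strand
  g <- make_genes(c("x", "M", "S", "L", "x"), rep("+", 5))
  op <- detect_coxmsl_operon(g, "g04")
  expect_equal(op$coxM_gene_id, "g02")
  expect_equal(op$coxS_gene_id, "g03")
  expect_equal(c(op$offset_m_s, op$offset_s_l), c(0L, 0L))
  # order violated: S before M upstream of L (the coxSLM signature)
  g2 <- make_genes(c("x", "S", "M", "L", "x"), rep("+", 5))
  expect_null(detect_coxmsl_operon(g2, "g04"))
  expect_error(detect_coxmsl_operon(g, "nope"), "unknown gene")
})

test_that("operon detection respects transcription direction on -", {
  # coordinate order L, S, M on the minus strand is transcription order
  # M -> S -> L
  g <- make_genes(c("L", "S", "M"), rep("-", 3))
  op <- detect_coxmsl_operon(g, "g01")
  expect_equal(op$coxM_gene_id, "g03")
  # same coordinates on + strand violate the order
  g2 <- make_genes(c("L", "S", "M"), rep("+", 3))
  expect_null(detect_coxmsl_operon(g2, "g01"))
})

test_that("the upstream window boundary is exactly five genes", {
  # sweep the S->L gap: M adjacent to S, S at distance d from L
  for (d in 1:6) {
    roles <- c("M", "S", rep("x", d - 1), "L")
    g <- make_genes(roles, rep("+", length(roles)))
    op <- detect_coxmsl_operon(g, g$gene_id[length(roles)])
    # hand enumeration: M sits d+1 genes upstream; window is 5
    if (d + 1 <= 5) {
      expect_equal(op$offset_s_l, d - 1L)
    } else {
      expect_null(op)
    }
  }
})

test_that("strand and adjacency toggles restrict operon calls", {
  g <- make_genes(c("M", "S", "L"), c("-", "-", "+"))
  expect_null(detect_coxmsl_operon(g, "g03"))
  expect_false(is.null(detect_coxmsl_operon(
    g, "g03", screen_config(require_same_strand = FALSE))))
  g2 <- make_genes(c("M", "S", "x", "L"), rep("+", 4))
  expect_false(is.null(detect_coxmsl_operon(g2, "g04")))
  expect_null(detect_coxmsl_operon(
    g2, "g04", screen_config(allow_intervening_genes = FALSE)))
})

test_that("nearest-to-coxL assignment wins among multiple candidates", {
  g <- make_genes(c("M", "S", "M", "S", "L"), rep("+", 5))
  op <- detect_coxmsl_operon(g, "g05")
  expect_equal(op$coxS_gene_id, "g04")
  expect_equal(op$coxM_gene_id, "g03")
})

test_that("screening funnel is monotone and recovers planted truth", {
  sg <- sim_genomes(sim_spec(seed = 101))
  mc <- extract_motif_window(sg$alignment, sg$form1_ref_id,
                             sg$window_start)
  scr <- screen_genomes(sg$genes, sg$hits, mc, sg$tree, sg$form1_ref_id,
                        sg$form2_ref_ids)
  expect_true(all(diff(scr$funnel$genes) <= 0))
  expect_true(all(diff(scr$funnel$genomes) <= 0))
  expect_identical(scr$pcox_genomes, sg$truth$pcox_genomes)
  # decoy genomes never appear among the calls
  expect_length(intersect(scr$pcox_genomes, sg$truth$decoys$genome_id), 0)
})

test_that("empty hit table yields an empty funnel", {
  sg <- sim_genomes(sim_spec(seed = 102))
  mc <- extract_motif_window(sg$alignment, sg$form1_ref_id,
                             sg$window_start)
  scr <- screen_genomes(sg$genes, sg$hits[0, ], mc, sg$tree,
                        sg$form1_ref_id, sg$form2_ref_ids)
  expect_equal(scr$funnel$genes, rep(0L, 4))
  expect_length(scr$pcox_genomes, 0)
})

test_that("hits keyed to unknown proteins are reported as orphans", {
  sg <- sim_genomes(sim_spec(seed = 103))
  mc <- extract_motif_window(sg$alignment, sg$form1_ref_id,
                             sg$window_start)
  bad <- rbind(sg$hits,
               data.frame(query_id = "phantom", subject_id = "form1_ref",
                          evalue = 1e-30, bitscore = 300))
  expect_error(screen_genomes(sg$genes, bad, mc, sg$tree,
                              sg$form1_ref_id, sg$form2_ref_ids),
               "phantom")
})
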