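toy_nodes <- function(values, types, clusters) {
  structure(list(
    info = data.frame(node_id = colnames(values), node_type = types,
                      cluster_id = clusters, stringsAsFactors = FALSE),
    values = values), class = "series_nodes")
}

test_that("Spearman all-pairs handles monotone, anti-monotone and ties", {
  x <- 1:10
  v <- cbind(a = x, b = x^3, c = rev(x))
  e <- spearman_all_pairs(v)
  expect_equal(e$rho[e$node_a == "a" & e$node_b == "b"], 1)
  expect_equal(e$rho[e$node_a == "a" & e$node_b == "c"], -1)
  set.seed(21)
  for (i in 1:30) {
    m <- cbind(p = sample(1:4, 8, TRUE), q = sample(1:5, 8, TRUE))
    got <- spearman_all_pairs(m)$rho
    expect_equal(got, oracle_spearman(m[, 1], m[, 2]), tolerance = 1e-12)
    # cross-check against base R
    expect_equal(got, cor(m[, 1], m[, 2], method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_all_pairs(v[1:3, ]), "four")
})

test_that("constant series are excluded as undefined", {
  v <- cbind(a = 1:8, b = rep(2, 8), c = 8:1)
  e <- spearman_all_pairs(v)
  expect_true(all(is.na(e$rho[e$node_a == "b" | e$node_b == "b"])))
  expect_false(any(is.na(e$rho[e$node_a == "a" & e$node_b == "c"])))
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(22)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 1))
    # monotone in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("edge retention applies the pcox-specific rule", {
  set.seed(23)
  n <- 40
  base <- rnorm(n)
  values <- cbind(
    A_CO = base + rnorm(n, 0, 0.05),      # pcox of cluster A
    A = base + rnorm(n, 0, 0.05),         # whole of cluster A
    B = base + rnorm(n, 0, 0.05),         # whole of cluster B
    C_CO = rnorm(n),                      # pcox of non-dominant cluster C
    temp = base + rnorm(n, 0, 0.05))      # environmental series
  nodes <- toy_nodes(values, c("PCOX", "WHOLE", "WHOLE", "PCOX", "ENV"),
                     c("A", "A", "B", "C", NA))
  edges <- spearman_all_pairs(nodes)
  net <- retain_edges(edges, nodes, dominant = "A")
  kept <- net$edges[net$edges$retained, ]
  pair <- function(df, a, b) df[(df$node_a == a & df$node_b == b) |
                                (df$node_a == b & df$node_b == a), ]
  # (pcox_A, whole_A): strong but excluded by the self-cluster rule
  expect_gt(abs(pair(net$edges, "A_CO", "A")$rho), 0.95)
  expect_false(pair(net$edges, "A_CO", "A")$retained)
  # (pcox_A, whole_B): retained
  expect_true(pair(net$edges, "A_CO", "B")$retained)
  # (pcox_A, env): retained
  expect_true(pair(net$edges, "A_CO", "temp")$retained)
  # (whole_A, whole_B): no pcox endpoint -> dropped despite high rho
  expect_false(pair(net$edges, "A", "B")$retained)
  # C_CO is pcox but not dominant -> none of its edges retained
  expect_false(any(kept$node_a == "C_CO" | kept$node_b == "C_CO"))
})

test_that("any_dominant scope also bars other dominant clusters' wholes", {
  set.seed(24)
  n <- 40
  base <- rnorm(n)
  values <- cbind(A_CO = base + rnorm(n, 0, 0.05),
                  B = base + rnorm(n, 0, 0.05),
                  D = base + rnorm(n, 0, 0.05))
  nodes <- toy_nodes(values, c("PCOX", "WHOLE", "WHOLE"), c("A", "B", "D"))
  edges <- spearman_all_pairs(nodes)
  self <- retain_edges(edges, nodes, dominant = c("A", "B"),
                       scope = "self_cluster")
  anyd <- retain_edges(edges, nodes, dominant = c("A", "B"),
                       scope = "any_dominant")
  pick <- function(net, b) net$edges$retained[
    net$edges$node_a == "A_CO" & net$edges$node_b == b]
  expect_true(pick(self, "B"))    # other cluster's whole is fine here
  expect_false(pick(anyd, "B"))   # but barred under any_dominant
  expect_true(pick(anyd, "D"))    # non-dominant whole remains linkable
})

test_that("retention is monotone in both thresholds", {
  sp <- sim_spec(seed = 25, n_samples = 50, n_groups = 1,
                 planted_pairs = data.frame(
                   node_a = c("SC001_CO", "SC002_CO"),
                   node_b = c("SC012", "salinity"), rho = 0.9))
  sc <- sim_community(sp)
  nodes <- series_nodes(sc$whole, sc$pcox,
                        sc$meta[c("temperature", "salinity")])
  edges <- spearman_all_pairs(nodes)
  dom <- colnames(sc$pcox)
  base <- retain_edges(edges, nodes, dom, rho_min = 0.5, q_max = 0.05)
  for (args in list(list(rho_min = 0.85), list(q_max = 0.001))) {
    tight <- do.call(retain_edges,
                     c(list(edges, nodes, dom),
                       args))
    expect_true(all(tight$edges$retained <= base$edges$retained))
  }
})

test_that("modules are the connected components of retained edges", {
  e <- data.frame(node_a = c("a", "c", "x"), node_b = c("b", "d", "y"),
                  retained = c(TRUE, TRUE, FALSE))
  mods <- find_modules(e)
  expect_equal(mods, list(c("a", "b"), c("c", "d")))
  path <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                     retained = TRUE)
  expect_length(find_modules(path), 1)
  expect_length(find_modules(e[0, ]), 0)
})

test_that("module extraction matches a depth-first traversal oracle", {
  set.seed(26)
  for (i in 1:40) {
    nn <- sample(5:15, 1)
    ne <- sample(3:12, 1)
    e <- data.frame(node_a = sprintf("n%02d", sample(nn, ne, TRUE)),
                    node_b = sprintf("n%02d", sample(nn, ne, TRUE)),
                    retained = TRUE)
    got <- find_modules(e)
    want <- oracle_components(e$node_a, e$node_b)
    norm <- function(l) sort(vapply(l, paste, "", collapse = "|"))
    expect_equal(norm(got), norm(want))
  }
})
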