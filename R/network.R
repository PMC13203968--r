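#' Assemble co-occurrence series nodes
#'
#' Builds the node table for the co-occurrence analysis from the pcox and
#' whole-community abundance matrices plus environmental covariates. pcox
#' nodes are named `<cluster>_CO` by convention.
#'
#' @param whole Samples x clusters matrix of whole-community relative
#'   abundances.
#' @param pcox Samples x clusters matrix of pcox relative abundances
#'   (columns a subset of `whole`'s).
#' @param env Optional data.frame of numeric environmental parameters over
#'   the same samples.
#'
#' @return List of class `"series_nodes"`: `info` (data.frame `node_id`,
#'   `node_type` in PCOX/WHOLE/ENV, `cluster_id`) and `values` (samples x
#'   nodes matrix).
#' @export
series_nodes <- function(whole, pcox, env = NULL) {
  if (nrow(whole) != nrow(pcox))
    stop("whole and pcox matrices cover different samples")
  info <- rbind(
    data.frame(node_id = paste0(colnames(pcox), "_CO"), node_type = "PCOX",
               cluster_id = colnames(pcox), stringsAsFactors = FALSE),
    data.frame(node_id = colnames(whole), node_type = "WHOLE",
               cluster_id = colnames(whole), stringsAsFactors = FALSE))
  values <- cbind(pcox, whole)
  if (!is.null(env)) {
    env <- as.data.frame(env)
    num <- env[vapply(env, is.numeric, logical(1))]
    if (nrow(num) != nrow(whole)) stop("env covers different samples")
    info <- rbind(info, data.frame(node_id = names(num), node_type = "ENV",
                                   cluster_id = NA_character_,
                                   stringsAsFactors = FALSE))
    values <- cbind(values, as.matrix(num))
  }
  colnames(values) <- info$node_id
  structure(list(info = info, values = values), class = "series_nodes")
}

#' Spearman correlations between all node pairs
#'
#' Average-rank transform per series followed by product-moment
#' correlation; two-sided p-values from the t approximation with n - 2
#' degrees of freedom. Constant series yield `NA` and are excluded from
#' the testing universe downstream.
#'
#' @param nodes A [series_nodes()] object (or a samples x nodes matrix).
#' @return data.frame of unordered pairs with `node_a`, `node_b`, `rho`,
#'   `p`.
#' @export
spearman_all_pairs <- function(nodes) {
  values <- if (inherits(nodes, "series_nodes")) nodes$values else nodes
  n <- nrow(values)
  if (n < 4) stop("need at least four overlapping samples")
  rk <- apply(values, 2, rank)  # average ranks on ties
  sds <- apply(rk, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(rk))
  rho[sds == 0, ] <- NA_real_
  rho[, sds == 0] <- NA_real_
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[ut]
  data.frame(
    node_a = colnames(values)[ut[, 1]],
    node_b = colnames(values)[ut[, 2]],
    rho = r,
    p = spearman_t_pvalue(r, n),
    stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Retain co-occurrence edges by the pcox-specific rule
#'
#' Adjusts the p-values of all tested pairs jointly (BH), then keeps an
#' edge iff `|rho| >= rho_min`, `q < q_max`, at least one endpoint is a
#' PCOX node of a dominant species cluster, and the edge does not link a
#' pcox node to the whole-community node of a corresponding cluster:
#' under `scope = "self_cluster"` only the edge's own cluster is excluded
#' (a pcox node may link to other clusters' whole-community nodes); under
#' `scope = "any_dominant"` the whole-community node of every dominant
#' cluster is off limits.
#'
#' @param edges Output of [spearman_all_pairs()].
#' @param nodes The matching [series_nodes()] object.
#' @param dominant Character vector of dominant pcox cluster ids (see
#'   [dominant_clusters()]).
#' @param rho_min Minimum `|rho|` (inclusive).
#' @param q_max Maximum adjusted p (strict).
#' @param scope Exclusion scope, see above.
#'
#' @return List of class `"cox_network"`: `nodes`, `edges` (with `q` and
#'   `retained`), and `modules` (connected components of the retained
#'   graph; isolated nodes excluded).
#' @export
retain_edges <- function(edges, nodes, dominant, rho_min = 0.85,
                         q_max = 0.01,
                         scope = c("self_cluster", "any_dominant")) {
  scope <- match.arg(scope)
  info <- nodes$info
  edges$q <- NA_real_
  tested <- !is.na(edges$rho)
  edges$q[tested] <- bh_adjust(edges$p[tested])

  typ <- setNames(info$node_type, info$node_id)
  clu <- setNames(info$cluster_id, info$node_id)
  ta <- typ[edges$node_a]; tb <- typ[edges$node_b]
  ca <- clu[edges$node_a]; cb <- clu[edges$node_b]
  pcox_dom_a <- ta == "PCOX" & ca %in% dominant
  pcox_dom_b <- tb == "PCOX" & cb %in% dominant

  stat_ok <- tested & abs(edges$rho) >= rho_min & edges$q < q_max
  involves <- pcox_dom_a | pcox_dom_b
  if (scope == "self_cluster") {
    excl <- (pcox_dom_a & tb == "WHOLE" & !is.na(cb) & cb == ca) |
            (pcox_dom_b & ta == "WHOLE" & !is.na(ca) & ca == cb)
  } else {
    excl <- (pcox_dom_a & tb == "WHOLE" & cb %in% dominant) |
            (pcox_dom_b & ta == "WHOLE" & ca %in% dominant)
  }
  edges$retained <- stat_ok & involves & !excl

  structure(list(nodes = info, edges = edges,
                 modules = find_modules(edges)),
            class = "cox_network")
}

#' Connected components of the retained edge set
#'
#' @param edges data.frame with `node_a`, `node_b`, `retained`.
#' @return List of character vectors, one per module (component); isolated
#'   nodes are excluded.
#' @export
find_modules <- function(edges) {
  kept <- edges[edges$retained %in% TRUE, , drop = FALSE]
  if (nrow(kept) == 0) return(list())
  g <- igraph::graph_from_data_frame(kept[, c("node_a", "node_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  unname(lapply(seq_len(comp$no), function(i)
    sort(names(comp$membership)[comp$membership == i])))
}

#' @export
print.cox_network <- function(x, ...) {
  kept <- sum(x$edges$retained)
  nn <- length(unique(unlist(x$modules)))
  cat("co-occurrence network:", nn, "connected nodes,", kept,
      "retained edges,", length(x$modules), "modules\n")
  invisible(x)
}
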