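# Brute-force reference implementations used to cross-check the package.
# Each oracle is written from first principles, independently of the code
# path it validates.

# average ranks computed by position averaging, no rank()
oracle_ranks <- function(v) {
  s <- sort(v)
  vapply(v, function(z) mean(which(s == z)), numeric(1))
}

# Spearman rho as Pearson on hand-computed average ranks (sum formulas)
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  n <- length(x)
  sxy <- sum(rx * ry) - n * mean(rx) * mean(ry)
  sxx <- sum(rx^2) - n * mean(rx)^2
  syy <- sum(ry^2) - n * mean(ry)^2
  sxy / sqrt(sxx * syy)
}

# Benjamini-Hochberg step-up by explicit minimum over larger ranks
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# connected components by depth-first traversal over an edge list
oracle_components <- function(node_a, node_b) {
  nodes <- unique(c(node_a, node_b))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(node_a)) {
    adj[[node_a[i]]] <- c(adj[[node_a[i]]], node_b[i])
    adj[[node_b[i]]] <- c(adj[[node_b[i]]], node_a[i])
  }
  seen <- character(0)
  comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    stack <- start
    comp <- character(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v %in% comp) next
      comp <- c(comp, v)
      stack <- c(stack, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# clade-enumeration monophyly oracle on a rooted tree: the smallest clade
# containing candidate and reference must hold no form II reference
oracle_monophyly <- function(rooted, cand, form1, form2) {
  ntip <- ape::Ntip(rooted)
  clades <- lapply(seq_len(ntip + rooted$Nnode), function(nd) {
    if (nd <= ntip) rooted$tip.label[nd]
    else ape::extract.clade(rooted, nd)$tip.label
  })
  hit <- Filter(function(cl) all(c(cand, form1) %in% cl), clades)
  smallest <- hit[[which.min(lengths(hit))]]
  !any(form2 %in% smallest)
}

# naive agglomerative clustering on an ANI matrix: merge the closest pair
# while the linkage distance stays strictly below dthr
oracle_agglomerate <- function(ani, dthr, linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  ids <- rownames(ani)
  clusters <- as.list(ids)
  d <- 100 - ani
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      dij <- if (linkage == "single") min(cross) else mean(cross)
      if (dij < bestd) { bestd <- dij; best <- c(i, j) }
    }
    if (bestd >= dthr) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[1]]])
    clusters[[best[1]]] <- NULL
  }
  lab <- setNames(integer(length(ids)), ids)
  for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
  lab
}

# partition comparison up to relabeling
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
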