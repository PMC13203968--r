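#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = sum|u - v| / sum(u + v)` over features; a pair of all-zero
#' samples gets distance 0 by convention.
#'
#' @param abundances Samples x features matrix of nonnegative abundances.
#' @return A `dist` object over the sample rows.
#' @export
bray_curtis <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  d <- suppressWarnings(vegan::vegdist(abundances, method = "bray"))
  d[is.na(d)] <- 0  # all-zero pairs
  d
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of a distance matrix cut at `k` groups.
#'
#' @param dist A `dist` object or symmetric matrix.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param linkage Merge rule (`"complete"`, the base default, `"average"`,
#'   or `"ward"`).
#' @return Integer vector of cluster labels named by sample.
#' @export
hcluster <- function(dist, k, linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  if (linkage == "ward") linkage <- "ward.D2"
  if (!inherits(dist, "dist")) dist <- stats::as.dist(dist)
  n <- attr(dist, "Size")
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples")
  stats::cutree(stats::hclust(dist, method = linkage), k = k)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance; 1 iff the partitions are
#' identical up to relabeling. Degenerate pairs (both partitions trivial
#' in the same way) return 1.
#'
#' @param a,b Integer label vectors of equal length.
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  ka <- max(a); kb <- max(b)
  tab <- tabulate((a - 1L) * kb + b, ka * kb)
  n <- length(a)
  sij <- sum(tab * (tab - 1)) / 2
  sa <- sum(tabulate(a, ka) * (tabulate(a, ka) - 1)) / 2
  sb <- sum(tabulate(b, kb) * (tabulate(b, kb) - 1)) / 2
  ntot <- n * (n - 1) / 2
  expected <- sa * sb / ntot
  mx <- (sa + sb) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

agreement_ari <- adjusted_rand

#' Choose the number of sample clusters by subsample stability
#'
#' For each candidate `k`, repeatedly draws random subsamples (without
#' replacement) of a fixed fraction of the samples, clusters each
#' subsample hierarchically on Euclidean distance, and scores the
#' agreement of every pair of replicate partitions as the adjusted Rand
#' index restricted to their shared samples. The chosen `k` maximizes the
#' mean agreement; ties break toward the smallest `k`.
#'
#' @param data Samples x features matrix (e.g. relative abundances).
#' @param k_range Candidate cluster numbers.
#' @param reps Number of subsample replicates per `k`.
#' @param frac Fraction of samples per subsample.
#' @param linkage Passed to [hcluster()].
#' @param seed Optional RNG seed for reproducibility.
#'
#' @return List of class `"stability_report"`: `table` (per-k mean
#'   agreement and dispersion) and `chosen_k`.
#' @export
stability_select_k <- function(data, k_range = 5:10, reps = 1000,
                               frac = 0.70,
                               linkage = c("complete", "average", "ward"),
                               seed = NULL) {
  linkage <- match.arg(linkage)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  m <- as.integer(ceiling(frac * n))
  if (m < max(k_range))
    stop("subsample size ", m, " is below max(k_range)")
  D <- as.matrix(stats::dist(data))

  member <- matrix(FALSE, reps, n)
  labs <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, m))
    member[r, idx] <- TRUE
    hc <- stats::hclust(stats::as.dist(D[idx, idx, drop = FALSE]),
                        method = if (linkage == "ward") "ward.D2" else linkage)
    lab <- stats::cutree(hc, k = k_range)  # m x length(k_range)
    full <- matrix(NA_integer_, n, length(k_range))
    full[idx, ] <- lab
    labs[[r]] <- full
  }

  pairs <- utils::combn(reps, 2)
  agree <- matrix(NA_real_, ncol(pairs), length(k_range))
  for (p in seq_len(ncol(pairs))) {
    r1 <- pairs[1, p]; r2 <- pairs[2, p]
    shared <- which(member[r1, ] & member[r2, ])
    for (j in seq_along(k_range))
      agree[p, j] <- agreement_ari(labs[[r1]][shared, j],
                                   labs[[r2]][shared, j])
  }
  tab <- data.frame(k = k_range,
                    mean_agreement = colMeans(agree),
                    sd_agreement = apply(agree, 2, stats::sd))
  structure(list(table = tab,
                 chosen_k = k_range[which.max(tab$mean_agreement)],
                 reps = reps, frac = frac),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Subsample stability (", x$reps, " replicates, frac ",
      x$frac, "):\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Correlates the strictly-upper-triangle entries of two distance matrices
#' and assesses significance by jointly permuting the rows/columns of the
#' second matrix; the p-value is one-sided for a positive relationship,
#' `(1 + #\{r* >= r\}) / (1 + n_perm)`.
#'
#' @param d1,d2 `dist` objects (or symmetric matrices) over the same
#'   samples, in the same order.
#' @param n_perm Number of permutations.
#' @param method Correlation flavor, `"pearson"` (default) or
#'   `"spearman"`.
#' @param seed Optional RNG seed.
#'
#' @return List with `r`, `p`, `n_perm`, `method`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999,
                        method = c("pearson", "spearman"), seed = NULL) {
  method <- match.arg(method)
  if (!inherits(d1, "dist")) d1 <- stats::as.dist(d1)
  if (!inherits(d2, "dist")) d2 <- stats::as.dist(d2)
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices cover different sample sets")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrices cover different sample sets")
  if (!is.null(seed)) set.seed(seed)
  res <- vegan::mantel(d1, d2, method = method, permutations = n_perm)
  list(r = unname(res$statistic), p = res$signif,
       n_perm = n_perm, method = method)
}

#' All-pairs Spearman correlations among environmental parameters
#'
#' @param meta data.frame of per-sample metadata; all numeric columns are
#'   correlated pairwise (missing values dropped per pair).
#' @return List with matrices `rho` and `p` (two-sided t approximation,
#'   `NA` for constant columns).
#' @export
env_pairwise <- function(meta) {
  num <- meta[vapply(meta, is.numeric, logical(1))]
  if (ncol(num) < 2) stop("need at least two numeric columns")
  if (nrow(num) < 4) stop("need at least four samples")
  v <- ncol(num)
  rho <- p <- matrix(NA_real_, v, v, dimnames = list(names(num), names(num)))
  for (i in seq_len(v)) for (j in seq_len(v)) {
    ok <- stats::complete.cases(num[[i]], num[[j]])
    x <- num[[i]][ok]; y <- num[[j]][ok]
    if (length(x) < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y, method = "spearman")
    rho[i, j] <- r
    p[i, j] <- spearman_t_pvalue(r, length(x))
  }
  list(rho = rho, p = p)
}

# two-sided p-value for Spearman rho via the t approximation, n - 2 df
spearman_t_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  ifelse(abs(r) >= 1, 0,
         2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2))
}
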