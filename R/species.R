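#' Genome quality score
#'
#' `quality = completeness - 5 * contamination`, both in percent.
#'
#' @param completeness Percent in \[0, 100\].
#' @param contamination Percent >= 0.
#' @return Numeric quality score (may be negative).
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100))
    stop("completeness must be in [0, 100]")
  if (any(contamination < 0)) stop("contamination must be >= 0")
  completeness - 5 * contamination
}

#' Cluster genomes into species at an ANI threshold
#'
#' Agglomerative clustering on distance `100 - ANI`; clusters merge while
#' the linkage distance stays strictly below `100 - ani_threshold`, so the
#' species boundary "ANI > 95 percent" is exclusive. Each cluster's
#' representative is its highest-quality member, except that in clusters
#' containing pcox-CO oxidizer genomes the highest-quality pcox member is
#' chosen even when a non-pcox member scores higher. Ties break by
#' lexicographic genome id.
#'
#' @param ani Square symmetric ANI matrix in percent with genome ids as
#'   dimnames and diagonal 100.
#' @param quality data.frame with `genome_id` and either `quality` or
#'   `completeness` + `contamination` columns.
#' @param pcox_genomes Character vector of genome ids flagged as pcox-CO
#'   oxidizers.
#' @param config A [screen_config()] (supplies `ani_threshold`, `linkage`).
#'
#' @return data.frame of class `"species_clusters"` with columns
#'   `genome_id`, `cluster_id`, `is_pcox`, `quality`, `representative`.
#' @export
cluster_species <- function(ani, quality, pcox_genomes = character(0),
                            config = screen_config()) {
  ids <- rownames(ani)
  if (is.null(ids) || !identical(ids, colnames(ani)))
    stop("ANI matrix needs matching row/column genome ids")
  if (!isTRUE(all.equal(ani, t(ani), tolerance = 1e-8)))
    stop("ANI matrix must be symmetric")
  if (any(abs(diag(ani) - 100) > 1e-8))
    stop("ANI matrix diagonal must be 100")
  if (!is.null(quality$quality)) {
    q <- setNames(quality$quality, quality$genome_id)
  } else {
    q <- setNames(quality_score(quality$completeness, quality$contamination),
                  quality$genome_id)
  }
  if (!all(ids %in% names(q))) stop("quality missing for some genomes")
  q <- q[ids]

  dthr <- 100 - config$ani_threshold
  if (length(ids) == 1L) {
    labs <- setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(100 - ani),
                        method = config$linkage)
    below <- hc$height[hc$height < dthr]
    labs <- if (length(below)) stats::cutree(hc, h = max(below)) else
      stats::cutree(hc, k = length(ids))
  }
  out <- data.frame(genome_id = ids,
                    cluster_id = sprintf("SC%03d", labs),
                    is_pcox = ids %in% pcox_genomes,
                    quality = unname(q),
                    stringsAsFactors = FALSE)
  out$representative <- FALSE
  for (cl in unique(out$cluster_id)) {
    mem <- out[out$cluster_id == cl, ]
    pool <- if (any(mem$is_pcox)) mem[mem$is_pcox, ] else mem
    pool <- pool[order(-pool$quality, pool$genome_id), ]
    out$representative[out$genome_id == pool$genome_id[1]] <- TRUE
  }
  class(out) <- c("species_clusters", "data.frame")
  out
}
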