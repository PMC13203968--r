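#' Quality-trim a read
#'
#' Removes maximal leading and trailing runs of bases whose Phred quality
#' falls below `qmin`, then applies the length filter. Idempotent.
#'
#' @param sequence Read sequence (single string).
#' @param qualities Integer vector of Phred scores, one per base.
#' @param qmin Quality threshold; terminal bases with quality < `qmin` are
#'   trimmed.
#' @param minlen Minimum retained length in bp.
#'
#' @return List with `sequence` and `qualities` of the trimmed read, or
#'   `NULL` when fewer than `minlen` bases survive.
#' @export
qc_trim <- function(sequence, qualities, qmin = 20L, minlen = 60L) {
  n <- nchar(sequence)
  if (length(qualities) != n)
    stop("sequence and quality lengths differ")
  good <- which(qualities >= qmin)
  if (!length(good)) return(NULL)
  from <- good[1]; to <- good[length(good)]
  if (to - from + 1 < minlen) return(NULL)
  list(sequence = substring(sequence, from, to),
       qualities = qualities[from:to])
}

#' Alignment-record retention filter
#'
#' A record is retained iff identity
#' `(aligned_length - edit_distance) / aligned_length >= min_identity`,
#' `aligned_length >= min_aligned` bp, and the fraction of the read covered
#' by the alignment `aligned_length / read_length >= min_fraction`. All
#' boundaries are inclusive.
#'
#' @param alignments data.frame with columns `read_length`,
#'   `aligned_length`, `edit_distance` (see [read_alignments_tsv()]).
#' @param min_identity,min_aligned,min_fraction Thresholds.
#'
#' @return Logical vector, one entry per record.
#' @export
filter_alignments <- function(alignments, min_identity = 0.95,
                              min_aligned = 80, min_fraction = 0.80) {
  al <- alignments$aligned_length
  ed <- alignments$edit_distance
  rl <- alignments$read_length
  if (any(ed < 0 | ed > al | al > rl))
    stop("need 0 <= edit_distance <= aligned_length <= read_length")
  (al - ed) / al >= min_identity & al >= min_aligned &
    al / rl >= min_fraction
}

#' Reads per kilobase per million (RPKM)
#'
#' @param count Mapped-read count (vectorized).
#' @param feature_length_bp Feature length in bp (> 0).
#' @param total_reads Library size, i.e. QC-passed reads of the sample
#'   (> 0).
#' @return `count / (feature_length_bp/1000) / (total_reads/1e6)`.
#' @export
rpkm <- function(count, feature_length_bp, total_reads) {
  if (any(feature_length_bp <= 0)) stop("feature length must be > 0")
  if (any(total_reads <= 0)) stop("total reads must be > 0")
  count / (feature_length_bp / 1000) / (total_reads / 1e6)
}

#' Mapped-read recruitment
#'
#' @param mapped_reads,total_reads Counts with
#'   `0 <= mapped_reads <= total_reads`.
#' @return Proportion of reads mapped.
#' @export
read_recruitment <- function(mapped_reads, total_reads) {
  if (any(mapped_reads < 0) || any(mapped_reads > total_reads))
    stop("need 0 <= mapped_reads <= total_reads")
  mapped_reads / total_reads
}

#' Per-cluster marker and operon RPKM matrices
#'
#' Converts per-feature counts into the two per-cluster RPKM summaries the
#' relative-abundance equations consume: the mean RPKM over the
#' single-copy marker genes present in each representative genome, and the
#' RPKM of its coxMSL operon. Clusters whose representative carries none
#' of the marker genes are excluded from both.
#'
#' @param counts data.frame (`sample_id`, `feature_id`, `count`).
#'   Features absent from a sample count 0.
#' @param features data.frame (`feature_id`, `cluster_id`,
#'   `feature_type` in `{"marker", "operon"}`, `length_bp`). Marker rows
#'   may carry a `cog_id`.
#' @param totals data.frame (`sample_id`, `total_reads`) with the
#'   QC-passed library sizes.
#'
#' @return List with matrices `marker_rpkm` (samples x clusters, mean
#'   marker RPKM, the x_i of the whole-community equation) and
#'   `coxmsl_rpkm` (samples x clusters, 0 where a cluster has no operon
#'   feature), plus `excluded_clusters`.
#' @export
cluster_rpkm <- function(counts, features, totals) {
  stopifnot(all(c("sample_id", "feature_id", "count") %in% names(counts)),
            all(c("feature_id", "cluster_id", "feature_type",
                  "length_bp") %in% names(features)))
  samples <- sort(unique(totals$sample_id))
  tot <- setNames(totals$total_reads, totals$sample_id)[samples]
  orphan <- setdiff(counts$feature_id, features$feature_id)
  if (length(orphan))
    stop("counts reference unknown features: ",
         paste(utils::head(orphan, 5), collapse = ", "))

  has_marker <- unique(features$cluster_id[features$feature_type == "marker"])
  all_clusters <- unique(features$cluster_id)
  excluded <- setdiff(all_clusters, has_marker)
  clusters <- sort(has_marker)

  cmat <- matrix(0, length(samples), nrow(features),
                 dimnames = list(samples, features$feature_id))
  idx <- cbind(match(counts$sample_id, samples),
               match(counts$feature_id, features$feature_id))
  keep <- !is.na(idx[, 1])
  cmat[idx[keep, , drop = FALSE]] <- counts$count[keep]
  rmat <- rpkm(cmat, rep(features$length_bp, each = length(samples)),
               rep(tot, times = nrow(features)))

  marker_rpkm <- matrix(NA_real_, length(samples), length(clusters),
                        dimnames = list(samples, clusters))
  coxmsl_rpkm <- matrix(0, length(samples), length(clusters),
                        dimnames = list(samples, clusters))
  for (cl in clusters) {
    mk <- features$feature_id[features$cluster_id == cl &
                              features$feature_type == "marker"]
    marker_rpkm[, cl] <- rowMeans(rmat[, mk, drop = FALSE])
    op <- features$feature_id[features$cluster_id == cl &
                              features$feature_type == "operon"]
    if (length(op))
      coxmsl_rpkm[, cl] <- rowSums(rmat[, op, drop = FALSE])
  }
  list(marker_rpkm = marker_rpkm, coxmsl_rpkm = coxmsl_rpkm,
       excluded_clusters = excluded)
}

#' Whole-community relative abundance
#'
#' Row-normalizes the per-cluster mean marker RPKM: the relative abundance
#' of cluster i in a sample is its mean marker RPKM divided by the sum
#' over all clusters. Samples with an all-zero row get `NA` (undefined).
#'
#' @param marker_rpkm Samples x clusters matrix of mean marker RPKM
#'   (nonnegative).
#' @return Matrix of the same shape; rows sum to 1 where defined.
#' @export
relative_abundance <- function(marker_rpkm) {
  if (any(marker_rpkm < 0)) stop("marker RPKM must be nonnegative")
  s <- rowSums(marker_rpkm)
  out <- marker_rpkm / s
  out[s == 0, ] <- NA_real_
  out
}

#' Operon-based (pcox) relative abundance
#'
#' The pcox relative abundance of cluster i is the RPKM of its coxMSL
#' operon divided by the whole-community denominator, i.e. the sum of mean
#' marker RPKM over all clusters — not the sum of operon RPKM.
#'
#' @param coxmsl_rpkm Samples x clusters matrix of operon RPKM.
#' @param marker_rpkm Samples x clusters matrix of mean marker RPKM
#'   (supplies the denominator).
#' @return Matrix of pcox relative abundances (`NA` rows where the
#'   denominator is zero).
#' @export
cox_relative_abundance <- function(coxmsl_rpkm, marker_rpkm) {
  if (any(coxmsl_rpkm < 0) || any(marker_rpkm < 0))
    stop("RPKM values must be nonnegative")
  s <- rowSums(marker_rpkm)
  out <- coxmsl_rpkm / s
  out[s == 0, ] <- NA_real_
  out
}

#' Dominant pcox species clusters
#'
#' A species cluster is dominant when its group-wise mean pcox relative
#' abundance reaches `threshold` (inclusive) in at least one sample group
#' (metagenomic cluster).
#'
#' @param pcox_abundance Samples x clusters matrix of pcox relative
#'   abundances.
#' @param sample_groups Vector of group labels, one per row (named by
#'   sample or in row order).
#' @param threshold Dominance threshold on the relative-abundance scale
#'   (default 0.001 = 0.1 percent).
#' @return Character vector of dominant cluster ids.
#' @export
dominant_clusters <- function(pcox_abundance, sample_groups,
                              threshold = 0.001) {
  if (length(sample_groups) != nrow(pcox_abundance))
    stop("one group label per sample row required")
  groups <- as.character(sample_groups)
  gm <- vapply(unique(groups), function(g)
    colMeans(pcox_abundance[groups == g, , drop = FALSE]),
    numeric(ncol(pcox_abundance)))
  gm <- matrix(gm, nrow = ncol(pcox_abundance))  # clusters x groups
  colnames(pcox_abundance)[apply(gm >= threshold, 1, any)]
}
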