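#' COGs exclusive to pcox-CO oxidizer genomes of one species cluster
#'
#' The union of COGs seen in any pcox genome minus the union seen in any
#' coxL-lacking genome. Profiles must already exclude genes inside the
#' coxMSL operon. Absence is strict: a single occurrence in a lacking
#' genome disqualifies a COG.
#'
#' @param profiles Long-format data.frame for one cluster with columns
#'   `genome_id`, `is_pcox`, `cog_id` (one row per genome-COG incidence;
#'   genomes with no COGs may appear with `cog_id = NA`).
#' @return Character vector of exclusive COG ids.
#' @export
exclusive_cogs <- function(profiles) {
  if (nrow(profiles) == 0) stop("empty cluster profile")
  pc <- unique(profiles$genome_id[profiles$is_pcox])
  lk <- unique(profiles$genome_id[!profiles$is_pcox])
  if (length(pc) == 0 || length(lk) == 0)
    stop("cluster needs at least one pcox and one coxL-lacking genome")
  cg <- profiles[!is.na(profiles$cog_id), ]
  sort(setdiff(unique(cg$cog_id[cg$is_pcox]),
               unique(cg$cog_id[!cg$is_pcox])))
}

#' Cross-cluster recurrence of exclusive COGs
#'
#' Computes the exclusive COG set of every species cluster containing both
#' pcox and coxL-lacking genomes (clusters with no lacking contingent are
#' skipped for exclusivity but still contribute genome counts), then
#' tabulates COGs that are exclusive in at least `min_clusters` clusters,
#' with per-cluster detection counts and proportions in both genome
#' groups.
#'
#' @param profiles Long-format data.frame over all clusters with columns
#'   `genome_id`, `cluster_id`, `is_pcox`, `cog_id`.
#' @param min_clusters Minimum number of clusters a COG must be exclusive
#'   in to enter the recurrence table.
#'
#' @return List of class `"pangenome_report"`: `exclusive` (named list of
#'   per-cluster exclusive COG sets), `recurring` (COG ids exclusive in >=
#'   `min_clusters` clusters), and `counts` (long data.frame `cog_id`,
#'   `cluster_id`, `n_pcox`, `n_lacking`, `count_pcox_with`,
#'   `count_lacking_with`, `prop_pcox`, `prop_lacking`).
#' @export
recurrence_table <- function(profiles, min_clusters = 2) {
  clusters <- unique(profiles$cluster_id)
  excl <- list()
  for (cl in clusters) {
    pr <- profiles[profiles$cluster_id == cl, , drop = FALSE]
    if (length(unique(pr$genome_id[pr$is_pcox])) == 0 ||
        length(unique(pr$genome_id[!pr$is_pcox])) == 0) next
    excl[[cl]] <- exclusive_cogs(pr)
  }
  tally <- table(unlist(excl))
  recurring <- sort(names(tally)[tally >= min_clusters])

  counts <- NULL
  if (length(recurring)) {
    rows <- list()
    for (cl in clusters) {
      pr <- profiles[profiles$cluster_id == cl, , drop = FALSE]
      pc_gen <- unique(pr$genome_id[pr$is_pcox])
      lk_gen <- unique(pr$genome_id[!pr$is_pcox])
      for (cog in recurring) {
        with_cog <- unique(pr$genome_id[!is.na(pr$cog_id) &
                                        pr$cog_id == cog])
        rows[[length(rows) + 1L]] <- data.frame(
          cog_id = cog, cluster_id = cl,
          n_pcox = length(pc_gen), n_lacking = length(lk_gen),
          count_pcox_with = sum(pc_gen %in% with_cog),
          count_lacking_with = sum(lk_gen %in% with_cog),
          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, rows)
    counts$prop_pcox <- ifelse(counts$n_pcox > 0,
                               counts$count_pcox_with / counts$n_pcox, NA)
    counts$prop_lacking <- ifelse(counts$n_lacking > 0,
                                  counts$count_lacking_with /
                                    counts$n_lacking, NA)
  }
  structure(list(exclusive = excl, recurring = recurring, counts = counts),
            class = "pangenome_report")
}
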