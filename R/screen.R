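#' Homology gate
#'
#' Retains query proteins with at least one hit at or below the configured
#' E-value. With several hits per query the minimum E-value decides.
#'
#' @param hits data.frame with at least `query_id` and `evalue` columns
#'   (BLAST-tabular dialect, see [read_blast_hits()]).
#' @param config A [screen_config()].
#'
#' @return Character vector of retained query ids.
#' @export
gate_homology <- function(hits, config = screen_config()) {
  if (nrow(hits) == 0) return(character(0))
  if (any(hits$evalue < 0)) stop("negative E-values are not allowed")
  keep <- hits$evalue <= config$evalue_max
  sort(unique(hits$query_id[keep]))
}

# Root a tree on the branch separating the form II references from the rest.
# If the references are not separable by a single edge, root on the parent
# edge of their most recent common ancestor (as read from the input tree).
root_on_form2 <- function(tree, form2_ref_ids) {
  if (is.character(tree) && length(tree) == 1L)
    tree <- ape::read.tree(text = tree)
  missing <- setdiff(form2_ref_ids, tree$tip.label)
  if (length(missing))
    stop("form II reference(s) not in tree: ", paste(missing, collapse = ", "))
  rooted <- tryCatch(
    ape::root(ape::unroot(tree), outgroup = form2_ref_ids,
              resolve.root = TRUE),
    error = function(e) NULL)
  if (!is.null(rooted)) return(rooted)
  if (length(form2_ref_ids) < 2L)
    stop("unresolvable outgroup: cannot root on the form II references")
  m <- ape::getMRCA(tree, form2_ref_ids)
  if (is.null(m) || m == ape::Ntip(tree) + 1L) {
    # the references' MRCA is the basal node: with a rooted input the
    # existing rooting already sits on the MRCA's parent position
    if (ape::is.rooted(tree)) return(tree)
    stop("unresolvable outgroup: form II references span the tree root")
  }
  ape::root(tree, node = m, resolve.root = TRUE)
}

# tip labels descending from each internal node of a rooted tree
node_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  # postorder guarantees children before parents
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Monophyly gate
#'
#' Roots the tree on the branch separating the form II references (outgroup
#' contract; if they are not separable by one edge, on the parent edge of
#' their most recent common ancestor) and then asks, for each candidate,
#' whether the smallest clade containing both the candidate and the form I
#' reference is free of form II references.
#'
#' @param tree A `phylo` object or newick string.
#' @param candidate_ids Character vector of candidate tip labels.
#' @param form1_ref_id Tip label of the form I reference.
#' @param form2_ref_ids Tip labels of the form II references (outgroup).
#'
#' @return Named logical vector over `candidate_ids`. Candidates absent
#'   from the tree fail with a warning rather than an error.
#' @export
gate_monophyly <- function(tree, candidate_ids, form1_ref_id, form2_ref_ids) {
  if (length(form2_ref_ids) == 0) stop("need at least one form II reference")
  rooted <- root_on_form2(tree, form2_ref_ids)
  if (!form1_ref_id %in% rooted$tip.label)
    stop("form I reference '", form1_ref_id, "' is not a leaf of the tree")
  res <- setNames(rep(FALSE, length(candidate_ids)), candidate_ids)
  absent <- setdiff(candidate_ids, rooted$tip.label)
  if (length(absent))
    warning("candidate(s) not in tree treated as failing: ",
            paste(absent, collapse = ", "))
  present <- setdiff(candidate_ids, absent)
  if (!length(present)) return(res)
  sets <- node_tip_sets(rooted)
  for (cand in present) {
    if (cand == form1_ref_id) { res[cand] <- TRUE; next }
    m <- ape::getMRCA(rooted, c(cand, form1_ref_id))
    res[cand] <- !any(form2_ref_ids %in% sets[[m]])
  }
  res
}

#' Detect a coxMSL operon upstream of a form I coxL gene
#'
#' Scans up to `upstream_window` genes upstream of coxL in transcription
#' direction (decreasing rank on the + strand, increasing on -), restricted
#' to the coxL contig and, by default, the coxL strand. An operon is called
#' iff a coxM (COG1319) gene and a coxS (COG2080) gene occur inside the
#' window with transcription-direction order coxM, then coxS, then coxL.
#' Non-cox genes may intervene unless
#' `config$allow_intervening_genes = FALSE`, in which case coxS must be
#' adjacent to coxL and coxM adjacent to coxS. Among multiple valid
#' assignments the genes nearest coxL win.
#'
#' @param genes Gene table data.frame (columns `gene_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `strand`, `rank`, `cog_id`,
#'   `protein_id`).
#' @param coxL_gene_id Gene id of the candidate coxL.
#' @param config A [screen_config()].
#'
#' @return A one-row data.frame (`genome_id`, `contig_id`, `strand`,
#'   `coxM_gene_id`, `coxS_gene_id`, `coxL_gene_id`, `offset_m_s`,
#'   `offset_s_l` — intervening gene counts), or `NULL` when no operon is
#'   found.
#' @export
detect_coxmsl_operon <- function(genes, coxL_gene_id,
                                 config = screen_config()) {
  i <- match(coxL_gene_id, genes$gene_id)
  if (is.na(i)) stop("unknown gene id: ", coxL_gene_id)
  L <- genes[i, ]
  same <- genes[genes$genome_id == L$genome_id &
                genes$contig_id == L$contig_id, ]
  if (config$require_same_strand) same <- same[same$strand == L$strand, ]
  # distance in genes upstream of coxL, in transcription direction
  updist <- if (L$strand == "+") L$rank - same$rank else same$rank - L$rank
  win <- same[updist >= 1 & updist <= config$upstream_window, ]
  win$updist <- updist[updist >= 1 & updist <= config$upstream_window]
  s_cands <- win[!is.na(win$cog_id) & win$cog_id == config$coxS_cog, ]
  m_cands <- win[!is.na(win$cog_id) & win$cog_id == config$coxM_cog, ]
  if (nrow(s_cands) == 0 || nrow(m_cands) == 0) return(NULL)
  # nearest-to-coxL assignment: smallest S distance, then smallest M distance
  s_cands <- s_cands[order(s_cands$updist), ]
  for (si in seq_len(nrow(s_cands))) {
    s <- s_cands[si, ]
    mm <- m_cands[m_cands$updist > s$updist, ]  # coxM upstream of coxS
    if (nrow(mm) == 0) next
    mm <- mm[order(mm$updist), ]
    m <- mm[1, ]
    if (!config$allow_intervening_genes &&
        (s$updist != 1L || m$updist != s$updist + 1L)) next
    return(data.frame(
      genome_id = L$genome_id, contig_id = L$contig_id, strand = L$strand,
      coxM_gene_id = m$gene_id, coxS_gene_id = s$gene_id,
      coxL_gene_id = L$gene_id,
      offset_m_s = m$updist - s$updist - 1L,
      offset_s_l = s$updist - 1L,
      stringsAsFactors = FALSE))
  }
  NULL
}

#' Screen genomes for form I coxL and pcox-CO oxidizers
#'
#' Applies the gates in order homology -> motif (FORM1_KNOWN) -> monophyly
#' -> operon and reports the funnel of surviving genes and genomes. A
#' genome is called a pcox-CO oxidizer iff at least one of its coxL
#' candidates sits in a coxMSL operon.
#'
#' @param genes Gene table covering all screened genomes.
#' @param hits Homology hit table (`query_id` keyed by protein id).
#' @param motif_calls Output of [extract_motif_window()] (or any data.frame
#'   with `protein_id` and `motif_class`).
#' @param tree Phylogeny containing the reference leaves and candidates
#'   (tips named by protein id).
#' @param form1_ref_id,form2_ref_ids Reference tip labels for
#'   [gate_monophyly()].
#' @param config A [screen_config()].
#'
#' @return A list of class `"cox_screen"`: `candidates` (per-protein gate
#'   booleans), `operons`, `pcox_genomes`, and `funnel` (stage x
#'   gene/genome counts).
#' @export
screen_genomes <- function(genes, hits, motif_calls, tree,
                           form1_ref_id, form2_ref_ids,
                           config = screen_config()) {
  prot2gene <- genes[!is.na(genes$protein_id) & genes$protein_id != "",
                     c("protein_id", "gene_id", "genome_id")]
  pass_hom <- gate_homology(hits, config)
  orphans <- setdiff(pass_hom, prot2gene$protein_id)
  if (length(orphans))
    stop("hit query ids with no gene record: ",
         paste(utils::head(orphans, 5), collapse = ", "))

  cand <- prot2gene[prot2gene$protein_id %in% pass_hom, , drop = FALSE]
  cand$passed_homology <- rep(TRUE, nrow(cand))
  mc <- motif_calls$motif_class[match(cand$protein_id,
                                      motif_calls$protein_id)]
  cand$motif_class <- ifelse(is.na(mc), "NONE", mc)
  cand$passed_motif <- cand$motif_class == "FORM1_KNOWN"

  cand$passed_monophyly <- rep(FALSE, nrow(cand))
  mot_ids <- cand$protein_id[cand$passed_motif]
  if (length(mot_ids)) {
    mono <- gate_monophyly(tree, mot_ids, form1_ref_id, form2_ref_ids)
    cand$passed_monophyly[match(names(mono), cand$protein_id)] <- mono
  }

  cand$has_operon <- rep(FALSE, nrow(cand))
  operons <- list()
  for (pid in cand$protein_id[cand$passed_monophyly]) {
    gid <- cand$gene_id[cand$protein_id == pid]
    op <- detect_coxmsl_operon(genes, gid, config)
    if (!is.null(op)) {
      cand$has_operon[cand$protein_id == pid] <- TRUE
      op$protein_id <- pid
      operons[[length(operons) + 1L]] <- op
    }
  }
  operons <- if (length(operons)) do.call(rbind, operons) else
    data.frame(genome_id = character(0), contig_id = character(0),
               strand = character(0), coxM_gene_id = character(0),
               coxS_gene_id = character(0), coxL_gene_id = character(0),
               offset_m_s = integer(0), offset_s_l = integer(0),
               protein_id = character(0), stringsAsFactors = FALSE)

  stage_counts <- function(flag) c(
    genes = sum(flag),
    genomes = length(unique(cand$genome_id[flag])))
  funnel <- rbind(
    homology = stage_counts(cand$passed_homology),
    motif = stage_counts(cand$passed_motif),
    monophyly = stage_counts(cand$passed_monophyly),
    operon = stage_counts(cand$has_operon))
  funnel <- data.frame(stage = rownames(funnel), funnel, row.names = NULL)

  structure(list(
    candidates = cand, operons = operons,
    pcox_genomes = sort(unique(cand$genome_id[cand$has_operon])),
    funnel = funnel, config = config
  ), class = "cox_screen")
}

#' @export
print.cox_screen <- function(x, ...) {
  cat("coxL screening funnel (genes / genomes):\n")
  for (i in seq_len(nrow(x$funnel)))
    cat(sprintf("  %-10s %5d / %d\n", x$funnel$stage[i],
                x$funnel$genes[i], x$funnel$genomes[i]))
  cat("pcox-CO oxidizer genomes:", length(x$pcox_genomes), "\n")
  invisible(x)
}
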