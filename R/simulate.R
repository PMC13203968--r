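#' Simulation specification
#'
#' Collects every parameter of the synthetic-data generators in one
#' validated list. The defaults define the package's standard study
#' conditions at desk scale: a genome collection of 5 species clusters x 4
#' genomes with all four decoy classes, a metagenome collection of 90
#' samples in 6 planted groups separated by a factor of 5 relative to the
#' within-group noise, and a qPCR plan with a typical 85 percent
#' amplification efficiency.
#'
#' @param seed Master RNG seed; every generator derives its stream from
#'   it, so identical specs give identical outputs.
#' @param n_species_clusters,genomes_per_cluster,p_pcox Genome-collection
#'   shape and the per-genome probability of planting a coxMSL operon.
#' @param decoy_classes Decoy plan for non-pcox genomes, cycled over
#'   `form2` (coxSLM locus with the form II motif), `motif_only` (genuine
#'   motif, no operon), `order_violation` (coxS before coxM upstream of
#'   coxL) and `wrong_strand` (coxM/coxS on the opposite strand).
#' @param ani_within,ani_between Percent ANI ranges inside and between
#'   planted species clusters (within must sit strictly above between).
#' @param n_taxa,pcox_taxa Community size and how many leading taxa carry
#'   pcox series.
#' @param n_samples,n_groups,separation,noise_sd Sample count, planted
#'   group count, the between/within Euclidean distance ratio of the
#'   planted groups, and the abundance-scale within-group noise sd.
#' @param pcox_link_sd Log-scale noise linking a taxon's pcox series to
#'   its whole-community series.
#' @param env_coupling Correlation-like coupling of environmental
#'   covariates to the planted group structure (0 = independent).
#' @param planted_pairs Optional data.frame (`node_a`, `node_b`, `rho`)
#'   of node pairs whose sample Spearman correlation is driven to within
#'   0.03 of the target by rank blending.
#' @param count_taxa,count_samples,n_markers,marker_length,library_size,
#'   depth_range Feature-count model: taxa each carry `n_markers`
#'   single-copy markers and one coxMSL operon of marker-like length;
#'   counts are Poisson with rate depth x length_kb x library-millions.
#' @param read_length,subthreshold_fraction Alignment-record model: the
#'   planted fraction of records that fails the retention filters.
#' @param qpcr_efficiency,qpcr_intercept,qpcr_dilutions,qpcr_noise_sd,
#'   qpcr_replicates qPCR plan (efficiency in percent; Cq noise sd in
#'   cycles).
#'
#' @return List of class `"sim_spec"`.
#' @export
sim_spec <- function(seed = 20260423,
                     n_species_clusters = 5, genomes_per_cluster = 4,
                     p_pcox = 0.5,
                     decoy_classes = c("form2", "motif_only",
                                       "order_violation", "wrong_strand"),
                     ani_within = c(96, 99.5), ani_between = c(80, 90),
                     n_taxa = 40, pcox_taxa = 10,
                     n_samples = 90, n_groups = 6,
                     separation = 5, noise_sd = 0.1,
                     pcox_link_sd = 0.6, env_coupling = 0.8,
                     planted_pairs = NULL,
                     count_taxa = 20, count_samples = 12, n_markers = 14,
                     marker_length = 900, library_size = 5e6,
                     depth_range = c(2000, 20000),
                     read_length = 100, subthreshold_fraction = 0.3,
                     qpcr_efficiency = 85, qpcr_intercept = 38,
                     qpcr_dilutions = 6, qpcr_noise_sd = 0.1,
                     qpcr_replicates = 3) {
  stopifnot(p_pcox >= 0, p_pcox <= 1,
            min(ani_within) > max(ani_between),
            subthreshold_fraction >= 0, subthreshold_fraction <= 1,
            n_groups >= 1, n_taxa >= n_groups, pcox_taxa <= n_taxa,
            qpcr_dilutions >= 3)
  spec <- as.list(environment())
  structure(spec, class = "sim_spec")
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(len) paste(sample(aa_alphabet(), len,
                                           replace = TRUE), collapse = "")

# embed a 7-mer at 1-based position pos within a random protein of length len
protein_with_motif <- function(motif, len = 60, pos = NULL) {
  if (is.null(pos)) pos <- sample(10:(len - 16), 1)
  left <- if (pos > 1) rand_protein(pos - 1) else ""
  right <- rand_protein(len - pos - 6)
  list(sequence = paste0(left, motif, right), pos = pos)
}

fold_newick <- function(ids) {
  out <- ids[1]
  for (i in seq_along(ids)[-1]) out <- paste0("(", out, ",", ids[i], ")")
  out
}

#' Generate a synthetic annotated genome collection with planted truth
#'
#' pcox genomes carry one coxMSL operon (coxM = COG1319, coxS = COG2080,
#' then a coxL whose protein holds a genuine form I motif at a random
#' interior position); non-pcox genomes cycle through the spec's decoy
#' classes. Also emits a gapped alignment of all CoxL-like proteins
#' against a form I reference, a homology hit table, a phylogeny with a
#' form I clade and a form II outgroup, a block-structured ANI matrix and
#' genome qualities.
#'
#' @param spec A [sim_spec()].
#' @return List of class `"sim_genomes"`: `genes`, `proteins` (named
#'   character vector), `alignment` (gapped, named), `hits`, `tree`
#'   (`phylo`), `ani`, `quality`, `form1_ref_id`, `form2_ref_ids`,
#'   `window_start`, and `truth` (pcox genomes, decoy table, planted
#'   cluster labels).
#' @export
sim_genomes <- function(spec = sim_spec()) {
  set.seed(spec$seed)
  n_cl <- spec$n_species_clusters
  gpc <- spec$genomes_per_cluster
  genome_ids <- as.vector(t(outer(seq_len(n_cl), seq_len(gpc),
                                  function(c, g) sprintf("G%02d_%02d", c, g))))
  cluster_of <- rep(seq_len(n_cl), each = gpc)
  is_pcox <- stats::rbinom(length(genome_ids), 1, spec$p_pcox) == 1
  decoy <- rep(NA_character_, length(genome_ids))
  decoy[!is_pcox] <- rep(spec$decoy_classes, length.out = sum(!is_pcox))

  genes <- list(); proteins <- c(); hits <- list()
  cand_meta <- list()  # cox-like proteins for alignment/tree
  filler_cog <- function() sprintf("COG%04d", sample(3000:4999, 1))

  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[gi]
    n_fill <- 12L
    # roles in genomic coordinate order
    strand_op <- sample(c("+", "-"), 1)
    roles <- rep("fill", n_fill)
    if (is_pcox[gi]) {
      block <- if (strand_op == "+") c("M", "S", "L") else c("L", "S", "M")
      if (stats::runif(1) < 0.3)  # exercise an intervening gene
        block <- append(block, "fill", after = 1L)
      at <- sample(3:(n_fill - 3), 1)
      roles <- append(roles, block, after = at)
      strands <- ifelse(roles %in% c("M", "S", "L"), strand_op,
                        sample(c("+", "-"), length(roles), replace = TRUE))
    } else if (decoy[gi] == "form2") {
      block <- if (strand_op == "+") c("S", "L", "M") else c("M", "L", "S")
      at <- sample(3:(n_fill - 3), 1)
      roles <- append(roles, block, after = at)
      strands <- ifelse(roles %in% c("M", "S", "L"), strand_op,
                        sample(c("+", "-"), length(roles), replace = TRUE))
    } else if (decoy[gi] == "motif_only") {
      at <- sample(3:(n_fill - 3), 1)
      roles <- append(roles, "L", after = at)
      strands <- ifelse(roles == "L", strand_op,
                        sample(c("+", "-"), length(roles), replace = TRUE))
    } else if (decoy[gi] == "order_violation") {
      block <- if (strand_op == "+") c("S", "M", "L") else c("L", "M", "S")
      at <- sample(3:(n_fill - 3), 1)
      roles <- append(roles, block, after = at)
      strands <- ifelse(roles %in% c("M", "S", "L"), strand_op,
                        sample(c("+", "-"), length(roles), replace = TRUE))
    } else { # wrong_strand
      block <- if (strand_op == "+") c("M", "S", "L") else c("L", "S", "M")
      at <- sample(3:(n_fill - 3), 1)
      roles <- append(roles, block, after = at)
      anti <- if (strand_op == "+") "-" else "+"
      strands <- ifelse(roles == "L", strand_op,
                 ifelse(roles %in% c("M", "S"), anti,
                        sample(c("+", "-"), length(roles), replace = TRUE)))
    }
    n <- length(roles)
    start <- 1L + (seq_len(n) - 1L) * 1100L
    g <- data.frame(
      gene_id = sprintf("%s_g%03d", gid, seq_len(n)),
      genome_id = gid, contig_id = paste0(gid, "_c1"),
      start = start, end = start + 999L,
      strand = strands, rank = seq_len(n),
      cog_id = vapply(roles, function(r) switch(
        r, M = "COG1319", S = "COG2080", L = NA_character_,
        filler_cog()), character(1)),
      protein_id = NA_character_, stringsAsFactors = FALSE)

    li <- which(roles == "L")
    if (length(li)) {
      pid <- paste0(gid, "_coxL")
      g$protein_id[li] <- pid
      motif <- if (!is_pcox[gi] && decoy[gi] == "form2") "AYRGAGR" else
        sample(setdiff(known_form1_motifs(), "AYRCSLR"), 1)
      pm <- protein_with_motif(motif)
      proteins[pid] <- pm$sequence
      cand_meta[[pid]] <- list(motif = motif, pos = pm$pos,
                               form2 = identical(motif, "AYRGAGR"))
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = pid, subject_id = "form1_ref",
        evalue = 10^stats::runif(1, -60, -20),
        bitscore = stats::runif(1, 200, 600), stringsAsFactors = FALSE)
    }
    # one junk protein per genome that fails the homology gate
    ji <- which(roles == "fill")[1]
    jid <- paste0(gid, "_junk")
    g$protein_id[ji] <- jid
    proteins[jid] <- rand_protein(60)
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = jid, subject_id = "form1_ref",
      evalue = 10^stats::runif(1, -3, 0),
      bitscore = stats::runif(1, 20, 40), stringsAsFactors = FALSE)
    genes[[gi]] <- g
  }
  genes <- do.call(rbind, genes)
  hits <- do.call(rbind, hits)

  # references and gapped alignment of all CoxL-like proteins
  window_start <- 25L
  ref1 <- protein_with_motif("AYACSFR", pos = window_start)
  refs2 <- c("form2_ref1", "form2_ref2", "form2_ref3")
  ref2_seqs <- lapply(refs2, function(x) protein_with_motif("AYRGAGR"))
  aln_members <- c(list(form1_ref = ref1), setNames(ref2_seqs, refs2))
  for (pid in names(cand_meta))
    aln_members[[pid]] <- list(sequence = proteins[[pid]],
                               pos = cand_meta[[pid]]$pos)
  lefts <- vapply(aln_members, function(m) m$pos - 1L, integer(1))
  rights <- vapply(aln_members, function(m)
    nchar(m$sequence) - m$pos - 6L, integer(1))
  Lmax <- max(lefts); Rmax <- max(rights)
  alignment <- vapply(aln_members, function(m) {
    paste0(strrep("-", Lmax - (m$pos - 1L)),
           substring(m$sequence, 1, m$pos - 1L),
           substring(m$sequence, m$pos, m$pos + 6L),
           substring(m$sequence, m$pos + 7L),
           strrep("-", Rmax - (nchar(m$sequence) - m$pos - 6L)))
  }, character(1))
  # gaps do not shift ungapped coordinates: the reference window still
  # starts at its own motif position
  ref_window_start <- window_start

  # tree: form I clade holds the reference plus all non-form2 candidates
  f1_tips <- c("form1_ref",
               names(cand_meta)[!vapply(cand_meta, `[[`, logical(1),
                                        "form2")])
  f2_decoys <- names(cand_meta)[vapply(cand_meta, `[[`, logical(1),
                                       "form2")]
  f2_clade <- fold_newick(refs2)
  if (length(f2_decoys))
    f2_clade <- paste0("(", f2_clade, ",", fold_newick(f2_decoys), ")")
  nwk <- paste0("(", fold_newick(f1_tips), ",", f2_clade, ");")
  tree <- ape::read.tree(text = nwk)

  # block-structured ANI matrix
  ng <- length(genome_ids)
  ani <- matrix(stats::runif(ng * ng, spec$ani_between[1],
                             spec$ani_between[2]), ng, ng)
  for (cl in seq_len(n_cl)) {
    idx <- which(cluster_of == cl)
    ani[idx, idx] <- stats::runif(length(idx)^2, spec$ani_within[1],
                                  spec$ani_within[2])
  }
  ani[lower.tri(ani)] <- t(ani)[lower.tri(ani)]
  diag(ani) <- 100
  dimnames(ani) <- list(genome_ids, genome_ids)

  quality <- data.frame(
    genome_id = genome_ids,
    completeness = stats::runif(ng, 80, 100),
    contamination = stats::runif(ng, 0, 3), stringsAsFactors = FALSE)
  quality$quality <- quality_score(quality$completeness,
                                   quality$contamination)

  structure(list(
    genes = genes, proteins = proteins, alignment = alignment,
    hits = hits, tree = tree, ani = ani, quality = quality,
    form1_ref_id = "form1_ref", form2_ref_ids = refs2,
    window_start = ref_window_start,
    truth = list(pcox_genomes = sort(genome_ids[is_pcox]),
                 decoys = data.frame(genome_id = genome_ids[!is_pcox],
                                     class = decoy[!is_pcox],
                                     stringsAsFactors = FALSE),
                 clusters = setNames(cluster_of, genome_ids))
  ), class = "sim_genomes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate per-feature counts with one marker-like operon per genome
#'
#' Every taxon carries `n_markers` single-copy marker genes and one coxMSL
#' operon, all of length `marker_length`, so the operon-based relative
#' abundance should track the marker-based one up to Poisson noise.
#'
#' @param spec A [sim_spec()].
#' @return List of class `"sim_counts"`: `counts`, `features`, `totals`
#'   and `truth` (the per-sample, per-taxon coverage rates).
#' @export
sim_feature_counts <- function(spec = sim_spec()) {
  set.seed(spec$seed + 1L)
  taxa <- sprintf("SC%03d", seq_len(spec$count_taxa))
  samples <- sprintf("S%03d", seq_len(spec$count_samples))
  feat <- do.call(rbind, lapply(taxa, function(t) rbind(
    data.frame(feature_id = sprintf("%s_mk%02d", t,
                                    seq_len(spec$n_markers)),
               cluster_id = t, feature_type = "marker",
               length_bp = spec$marker_length, stringsAsFactors = FALSE),
    data.frame(feature_id = paste0(t, "_coxMSL"), cluster_id = t,
               feature_type = "operon", length_bp = spec$marker_length,
               stringsAsFactors = FALSE))))
  depth <- matrix(stats::runif(length(samples) * length(taxa),
                               spec$depth_range[1], spec$depth_range[2]),
                  length(samples), length(taxa),
                  dimnames = list(samples, taxa))
  lam <- sweep(depth[, feat$cluster_id, drop = FALSE], 2,
               feat$length_bp / 1000, `*`) * (spec$library_size / 1e6)
  counts <- data.frame(
    sample_id = rep(samples, times = nrow(feat)),
    feature_id = rep(feat$feature_id, each = length(samples)),
    count = stats::rpois(length(samples) * nrow(feat), as.vector(lam)),
    stringsAsFactors = FALSE)
  totals <- data.frame(sample_id = samples,
                       total_reads = spec$library_size,
                       stringsAsFactors = FALSE)
  structure(list(counts = counts, features = feat, totals = totals,
                 truth = list(depth = depth)), class = "sim_counts")
}

#' Generate alignment records with a planted failing fraction
#'
#' A fraction `subthreshold_fraction` of records is planted to fail
#' exactly one retention filter (low identity, short alignment, or low
#' mapped fraction); the rest pass all three.
#'
#' @param spec A [sim_spec()].
#' @param n Number of records.
#' @return List of class `"sim_alignments"`: `records` (data.frame) and
#'   `truth` (logical `expected_fail` plus failure `mode`).
#' @export
sim_alignment_records <- function(spec = sim_spec(), n = 2000) {
  set.seed(spec$seed + 2L)
  rl <- spec$read_length
  fail <- stats::runif(n) < spec$subthreshold_fraction
  mode <- rep("pass", n)
  mode[fail] <- sample(c("identity", "length", "fraction"), sum(fail),
                       replace = TRUE)
  aligned <- integer(n); read_len <- integer(n); edit <- integer(n)
  for (i in seq_len(n)) {
    switch(mode[i],
      pass = {
        aligned[i] <- sample(max(80, ceiling(0.8 * rl)):rl, 1)
        read_len[i] <- rl
        edit[i] <- sample(0:floor(0.02 * aligned[i]), 1)
      },
      identity = {
        aligned[i] <- sample(max(80, ceiling(0.8 * rl)):rl, 1)
        read_len[i] <- rl
        edit[i] <- ceiling(0.07 * aligned[i])
      },
      length = {
        aligned[i] <- sample(60:79, 1)
        read_len[i] <- aligned[i]   # fraction 1, only length fails
        edit[i] <- 0L
      },
      fraction = {
        aligned[i] <- 80L
        read_len[i] <- sample(105:130, 1)  # fraction < 0.77
        edit[i] <- 0L
      })
  }
  records <- data.frame(
    read_id = sprintf("r%05d", seq_len(n)),
    reference_id = rep("ref", n), feature_id = rep(NA_character_, n),
    read_length = read_len, aligned_length = aligned,
    edit_distance = edit, stringsAsFactors = FALSE)
  structure(list(records = records,
                 truth = list(expected_fail = fail, mode = mode)),
            class = "sim_alignments")
}

#' Generate reads with planted low-quality ends
#'
#' @param spec A [sim_spec()].
#' @param n Number of reads.
#' @return List with `reads` (list of read records) and `truth`
#'   (`trimmed_length`, `retained` under qmin 20 / minlen 60).
#' @export
sim_reads <- function(spec = sim_spec(), n = 200) {
  set.seed(spec$seed + 5L)
  rl <- spec$read_length
  reads <- vector("list", n)
  tl <- integer(n)
  for (i in seq_len(n)) {
    left <- sample(0:30, 1); right <- sample(0:30, 1)
    mid <- rl - left - right
    q <- c(rep(10L, left), sample(28:38, mid, replace = TRUE),
           rep(8L, right))
    reads[[i]] <- list(read_id = sprintf("q%04d", i),
                       sequence = paste(sample(c("A", "C", "G", "T"), rl,
                                               replace = TRUE),
                                        collapse = ""),
                       qualities = q)
    tl[i] <- mid
  }
  list(reads = reads, truth = list(trimmed_length = tl,
                                   retained = tl >= 60))
}

# blend node_b's ranks toward node_a's until the sample Spearman
# correlation reaches the target within tol; preserves node_b's marginal
achieve_spearman <- function(x, y, rho, tol = 0.03) {
  rx <- scale(rank(x)); ry <- scale(rank(y))
  best <- NULL; best_err <- Inf
  for (l in seq(0, 1, by = 0.0025)) {
    blend <- l * rx + (1 - l) * ry
    ynew <- sort(y)[rank(blend, ties.method = "first")]
    err <- abs(stats::cor(x, ynew, method = "spearman") - rho)
    if (err < best_err) { best_err <- err; best <- ynew }
    if (err <= tol / 3) break
  }
  list(values = best,
       achieved = stats::cor(x, best, method = "spearman"))
}

#' Generate a synthetic metagenome community with planted structure
#'
#' Whole-community relative abundances carry `n_groups` planted sample
#' groups: each group up-weights its own disjoint block of taxa by
#' `separation * noise_sd` on the log scale. pcox series follow their
#' taxon's whole-community series through a log-normal link, and
#' environmental covariates are coupled to the group structure. Planted
#' node pairs are rank-blended to a target sample Spearman correlation
#' (within 0.03).
#'
#' @param spec A [sim_spec()].
#' @return List of class `"sim_community"`: `whole`, `pcox`, `meta`, and
#'   `truth` (`groups`, `planted` with achieved correlations,
#'   `pcox_ratio`).
#' @export
sim_community <- function(spec = sim_spec()) {
  set.seed(spec$seed + 3L)
  n <- spec$n_samples; nt <- spec$n_taxa; ng <- spec$n_groups
  taxa <- sprintf("SC%03d", seq_len(nt))
  samples <- sprintf("S%03d", seq_len(n))
  groups <- rep_len(seq_len(ng), n)

  # group centroids are separated blocks in abundance space: the offset
  # delta is chosen so that the between-centroid distance equals
  # `separation` times the expected within-group pair distance
  # (sigma * sqrt(2 * n_taxa)), making the separation factor the
  # between/within Euclidean distance ratio by construction
  sd_e <- spec$noise_sd
  bsize <- floor(nt / ng)
  block_of <- rep(NA_integer_, nt)
  if (ng > 1)
    block_of[seq_len(bsize * ng)] <- rep(seq_len(ng), each = bsize)
  delta <- if (ng > 1) spec$separation * sd_e * sqrt(nt / bsize) else 0
  base <- stats::runif(nt, 0.5, 1.5)
  raw <- matrix(stats::rnorm(n * nt, 0, sd_e), n, nt)
  raw <- sweep(raw, 2, base, `+`)
  if (ng > 1)
    for (g in seq_len(ng))
      raw[groups == g, which(block_of == g)] <-
        raw[groups == g, which(block_of == g)] + delta
  raw <- pmax(raw, 0)
  whole <- raw / rowSums(raw)
  dimnames(whole) <- list(samples, taxa)

  ratio <- stats::runif(spec$pcox_taxa, 0.1, 0.6)
  pcox <- whole[, seq_len(spec$pcox_taxa), drop = FALSE] *
    rep(ratio, each = n) *
    exp(matrix(stats::rnorm(n * spec$pcox_taxa, 0, spec$pcox_link_sd),
               n, spec$pcox_taxa))
  colnames(pcox) <- taxa[seq_len(spec$pcox_taxa)]

  # environmental covariates coupled to the group structure
  cp <- spec$env_coupling
  zmix <- function(gvals) {
    z <- cp * gvals[groups] + sqrt(max(0, 1 - cp^2)) * stats::rnorm(n)
    if (ng == 1) z <- stats::rnorm(n)
    z
  }
  gv <- function() stats::rnorm(ng)
  meta <- data.frame(
    sample_id = samples,
    depth = round(pmax(1, 10^(2 + 1.0 * zmix(gv())))),
    latitude = pmax(-80, pmin(80, 35 * zmix(gv()))),
    longitude = stats::runif(n, -180, 180),
    temperature = 15 + 8 * zmix(gv()),
    salinity = 34 + 1.5 * zmix(gv()),
    oxygen = pmax(0, 200 + 80 * zmix(gv())),
    total_reads = round(stats::runif(n, 0.8, 1.2) * spec$library_size),
    stringsAsFactors = FALSE)

  planted <- NULL
  if (!is.null(spec$planted_pairs) && nrow(spec$planted_pairs)) {
    planted <- spec$planted_pairs
    planted$achieved <- NA_real_
    getcol <- function(id) {
      if (grepl("_CO$", id)) pcox[, sub("_CO$", "", id)]
      else if (id %in% colnames(whole)) whole[, id]
      else if (id %in% names(meta)) meta[[id]]
      else stop("unknown planted node: ", id)
    }
    setcol <- function(id, v) {
      if (grepl("_CO$", id)) pcox[, sub("_CO$", "", id)] <<- v
      else if (id %in% colnames(whole)) whole[, id] <<- v
      else meta[[id]] <<- v
    }
    for (i in seq_len(nrow(planted))) {
      a <- getcol(planted$node_a[i]); b <- getcol(planted$node_b[i])
      res <- achieve_spearman(a, b, planted$rho[i])
      setcol(planted$node_b[i], res$values)
      planted$achieved[i] <- res$achieved
    }
  }

  structure(list(whole = whole, pcox = pcox, meta = meta,
                 truth = list(groups = setNames(groups, samples),
                              planted = planted, pcox_ratio = ratio)),
            class = "sim_community")
}

#' Generate a qPCR dilution series and replicate copy densities
#'
#' Cq values follow `intercept + slope * log10(copies)` with Gaussian
#' noise, the slope fixed by the spec's true amplification efficiency:
#' `slope = -1 / log10(1 + eff/100)`.
#'
#' @param spec A [sim_spec()].
#' @param targets Optional named numeric vector of true copy densities
#'   (cp/mL) for replicate tables.
#' @return List of class `"sim_qpcr"`: `series` (`log10_copies`, `cq`),
#'   `replicates` (named list of replicate vectors), `truth` (`slope`,
#'   `intercept`, `efficiency`).
#' @export
sim_qpcr <- function(spec = sim_spec(),
                     targets = c(coxL_A = 2.4e4, coxL_B = 2.9e4,
                                 coxL_C = 4.8e4, coxL_D = 2.5e3,
                                 s16 = 1.2e6)) {
  set.seed(spec$seed + 4L)
  slope <- -1 / log10(1 + spec$qpcr_efficiency / 100)
  lc <- rev(seq_len(spec$qpcr_dilutions))
  cq <- spec$qpcr_intercept + slope * lc +
    stats::rnorm(length(lc), 0, spec$qpcr_noise_sd)
  reps <- lapply(targets, function(m)
    pmax(0, m * (1 + stats::rnorm(spec$qpcr_replicates, 0, 0.1))))
  structure(list(series = data.frame(log10_copies = lc, cq = cq),
                 replicates = reps,
                 truth = list(slope = slope,
                              intercept = spec$qpcr_intercept,
                              efficiency = spec$qpcr_efficiency)),
            class = "sim_qpcr")
}
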