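#' Known form I CoxL active-site motifs
#'
#' The seven-residue active-site windows accepted as genuine form I motifs.
#' All are homologs of the canonical AYXCSFR pattern; AYRCSLR carries a
#' substitution in the CSFR core and can be excluded via
#' [screen_config()]`$include_AYRCSLR`.
#'
#' @return Character vector of six 7-mers.
#' @export
known_form1_motifs <- function() {
  c("AYACSFR", "AYRCSFR", "SYRCSFR", "AYRCSLR", "AYSCSFR", "SYACSFR")
}

#' Screening configuration
#'
#' Bundles every threshold of the form I coxL screen: the homology E-value
#' cutoff, the accepted active-site motif set, the form II motif, the operon
#' search window (in genes, not bases), strand handling, and the
#' species-boundary ANI threshold.
#'
#' @param evalue_max Maximum E-value for the homology gate (inclusive).
#' @param known_motifs Character vector of accepted 7-mer motifs.
#' @param include_AYRCSLR Keep the AYRCSLR motif in the accepted set?
#' @param form2_motif The form II active-site 7-mer.
#' @param upstream_window Number of genes upstream of coxL scanned for
#'   coxM/coxS.
#' @param require_same_strand Must coxM and coxS share the coxL strand?
#' @param allow_intervening_genes May non-cox genes sit between coxM, coxS
#'   and coxL inside the window?
#' @param coxM_cog,coxS_cog COG identifiers recognised as coxM and coxS.
#' @param ani_threshold Species-boundary ANI in percent; genomes merge when
#'   ANI exceeds this value (strictly).
#' @param linkage Agglomeration rule for ANI clustering.
#'
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(evalue_max = 1e-5,
                          known_motifs = known_form1_motifs(),
                          include_AYRCSLR = TRUE,
                          form2_motif = "AYRGAGR",
                          upstream_window = 5L,
                          require_same_strand = TRUE,
                          allow_intervening_genes = TRUE,
                          coxM_cog = "COG1319",
                          coxS_cog = "COG2080",
                          ani_threshold = 95,
                          linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(evalue_max >= 0, upstream_window >= 1,
            ani_threshold > 0, ani_threshold <= 100,
            all(nchar(known_motifs) == 7), nchar(form2_motif) == 7)
  if (!include_AYRCSLR) known_motifs <- setdiff(known_motifs, "AYRCSLR")
  structure(list(
    evalue_max = evalue_max, known_motifs = known_motifs,
    include_AYRCSLR = include_AYRCSLR, form2_motif = form2_motif,
    upstream_window = as.integer(upstream_window),
    require_same_strand = require_same_strand,
    allow_intervening_genes = allow_intervening_genes,
    coxM_cog = coxM_cog, coxS_cog = coxS_cog,
    ani_threshold = ani_threshold, linkage = linkage
  ), class = "screen_config")
}

#' Classify a 7-residue active-site window
#'
#' @param window Character vector of 7-mers (uppercase, no gaps).
#' @param config A [screen_config()].
#'
#' @return Character vector with levels `FORM1_KNOWN` (window in the
#'   accepted set), `FORM2` (the form II motif), `FORM1_LIKE_VARIANT`
#'   (matches `[AS]Y.CS.R` but is not accepted, e.g. the AYRCSSR / AYRCSCR
#'   point variants), or `NONE`.
#' @export
classify_motif <- function(window, config = screen_config()) {
  if (any(is.na(window)) || any(nchar(window) != 7))
    stop("motif windows must be 7 residues long")
  out <- rep("NONE", length(window))
  out[grepl("^[AS]Y.CS.R$", window)] <- "FORM1_LIKE_VARIANT"
  out[window == config$form2_motif] <- "FORM2"
  out[window %in% config$known_motifs] <- "FORM1_KNOWN"
  out
}

#' Extract active-site windows from a gapped protein alignment
#'
#' Locates the alignment columns spanned by seven consecutive ungapped
#' residues of a reference sequence (the active-site window) and reads each
#' sequence's residues across those columns. A sequence whose de-gapped
#' slice is not exactly seven residues long (an insertion or deletion
#' relative to the reference window) gets an empty window and motif class
#' `NONE`.
#'
#' @param alignment An [Biostrings::AAStringSet] of equal-length gapped
#'   sequences (or a named character vector), `-` and `.` as gaps.
#' @param reference_id Name of the reference sequence in the alignment.
#' @param reference_window_start 1-based ungapped position of the window's
#'   first residue in the reference.
#' @param config A [screen_config()], used to classify the windows.
#'
#' @return A data.frame with columns `protein_id`, `window` (`""` when the
#'   slice de-gaps to a length other than 7) and `motif_class`.
#' @export
extract_motif_window <- function(alignment, reference_id,
                                 reference_window_start,
                                 config = screen_config()) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "XStringSet"))
    alignment <- as.character(alignment)
  if (is.null(names(alignment)))
    stop("alignment sequences must be named")
  if (!reference_id %in% names(alignment))
    stop("reference sequence '", reference_id, "' not found in alignment")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L)
    stop("alignment sequences must all have the same gapped length")

  ref <- strsplit(alignment[[reference_id]], "")[[1]]
  res_cols <- which(!ref %in% c("-", "."))
  if (reference_window_start < 1 ||
      reference_window_start + 6 > length(res_cols))
    stop("window extends beyond the reference's ungapped length")
  cols <- res_cols[reference_window_start:(reference_window_start + 6)]
  # contiguous column span: insertions in other sequences relative to the
  # reference fall inside the slice and disqualify the window after de-gapping
  span <- seq(min(cols), max(cols))

  windows <- vapply(alignment, function(s) {
    slice <- substring(s, span[1], span[length(span)])
    gsub("[-.]", "", slice)
  }, character(1))
  ok <- nchar(windows) == 7
  data.frame(
    protein_id = names(alignment),
    window = ifelse(ok, toupper(windows), ""),
    motif_class = ifelse(ok, classify_motif(
      ifelse(ok, toupper(windows), strrep("X", 7)), config), "NONE"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
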