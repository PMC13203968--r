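#' Read a gene table
#'
#' TSV with header columns `gene_id`, `genome_id`, `contig_id`, `start`,
#' `end`, `strand`, `rank`, `cog_id`, `protein_id`. Coordinates are
#' 1-based inclusive; `rank` is the gene's position along its contig in
#' coordinate order.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = list(gene_id = "character",
                                           genome_id = "character",
                                           contig_id = "character",
                                           cog_id = "character",
                                           protein_id = "character"))
  validate_gene_table(g)
  g
}

validate_gene_table <- function(g) {
  need <- c("gene_id", "genome_id", "contig_id", "start", "end", "strand",
            "rank")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("gene table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(g$start > g$end)) stop("gene with start > end")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  sp <- split(g$rank, paste(g$genome_id, g$contig_id))
  bad <- vapply(sp, function(r) any(duplicated(r)), logical(1))
  if (any(bad)) stop("duplicated ranks within a contig")
  invisible(g)
}

#' Read a BLAST-tabular hit table
#'
#' 12-column outfmt-6 dialect (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), no header.
#'
#' @param path File path.
#' @return data.frame with `query_id`, `subject_id`, `evalue`, `bitscore`
#'   (plus the remaining standard columns).
#' @export
read_blast_hits <- function(path) {
  h <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(h) != 12) stop("expected 12 BLAST outfmt-6 columns")
  names(h) <- c("query_id", "subject_id", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")
  if (any(h$evalue < 0)) stop("negative E-value in hit table")
  h
}

#' Read a square ANI matrix
#'
#' TSV with genome ids as both header row and first column.
#'
#' @param path File path.
#' @return Numeric matrix with genome-id dimnames.
#' @export
read_ani_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Read alignment records from the 6-column TSV dialect
#'
#' Columns: `read_id`, `reference_id`, `feature_id`, `read_length`,
#' `aligned_length`, `edit_distance` (header required).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_alignments_tsv <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "reference_id", "feature_id", "read_length",
            "aligned_length", "edit_distance")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("alignment table lacks columns: ",
                         paste(miss, collapse = ", "))
  a
}

#' Read alignment records from a SAM file
#'
#' Converts the SAM to BAM (Rsamtools) and maps each mapped record onto
#' the package's alignment tuple: `read_length` is the stored sequence
#' length, `aligned_length` the number of read bases in aligned CIGAR
#' operations (M/=/X/I), and `edit_distance` the NM tag.
#'
#' @param path Path to a SAM file with a header.
#' @return data.frame as [read_alignments_tsv()] (`feature_id` is the
#'   reference name).
#' @export
read_alignments_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "cigar",
                                        "qwidth"),
                               tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  ok <- !is.na(x$cigar)
  aligned <- vapply(x$cigar[ok], cigar_read_aligned, integer(1),
                    USE.NAMES = FALSE)
  nm <- x$tag$NM[ok]
  nm[is.na(nm)] <- 0L
  data.frame(read_id = x$qname[ok],
             reference_id = as.character(x$rname[ok]),
             feature_id = as.character(x$rname[ok]),
             read_length = x$qwidth[ok],
             aligned_length = aligned,
             edit_distance = nm,
             stringsAsFactors = FALSE)
}

# read bases consumed by aligned CIGAR operations (M/=/X/I)
cigar_read_aligned <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(len[op %in% c("M", "=", "X", "I")])
}

#' Read a FASTQ file into read records
#'
#' @param path File path.
#' @return List of records, each with `read_id`, `sequence`, `qualities`
#'   (integer Phred scores).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  quals <- S4Vectors::mcols(x)$qualities
  lapply(seq_along(x), function(i) list(
    read_id = names(x)[i],
    sequence = as.character(x[[i]]),
    qualities = as.integer(charToRaw(as.character(quals[[i]]))) - 33L))
}

#' Write a square matrix as TSV with row and column ids
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
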