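# Promoter (5'-flanking) extraction from a genome plus gene annotation.
#
# The TSS is the first transcribed base (0-based position `tss`); the
# upstream window excludes the TSS base itself. Plus strand: the promoter is
# genome[tss - upstream_bp, tss). Minus strand: the reverse complement of
# genome[tss + 1, tss + 1 + upstream_bp). Windows truncated at a contig edge
# are returned shorter with a warning; windows that fall entirely off the
# contig are errors.

#' Build a gene annotation record
#'
#' @param gene_id Gene identifier.
#' @param chrom Contig/chromosome name (must match a genome FASTA record id).
#' @param tss 0-based position of the transcription start site.
#' @param strand \code{"+"} or \code{"-"}.
#' @return A one-row data.frame with columns gene_id, chrom, tss, strand.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand) {
  stopifnot(length(gene_id) == 1L, nzchar(gene_id),
            length(tss) == 1L, tss >= 0, strand %in% c("+", "-"))
  data.frame(gene_id = gene_id, chrom = chrom, tss = as.integer(tss),
             strand = strand, stringsAsFactors = FALSE)
}

#' Read gene annotation from BED6 or GFF3
#'
#' Coordinates are converted to the package's internal 0-based convention:
#' for a plus-strand feature the TSS is the first base of the feature, for a
#' minus-strand feature the last. Import is done with
#' \code{rtracklayer::import}, so standard BED and GFF3 dialects are
#' accepted.
#'
#' @param path Path to a BED or GFF3 file.
#' @param format \code{"BED"} or \code{"GFF3"} (default guessed from the
#'   file extension).
#' @return A data.frame with columns gene_id, chrom, tss, strand.
#' @export
read_annotation <- function(path, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
      "GFF3" else "BED"
  }
  gr <- rtracklayer::import(path, format = if (format == "BED") "BED" else "GFF3")
  if (length(gr) == 0L) stop("no annotation records in ", path, call. = FALSE)
  df <- as.data.frame(gr)
  ids <- if (format == "BED") {
    as.character(df$name)
  } else {
    if (!is.null(df$gene_id)) as.character(df$gene_id)
    else if (!is.null(df$Name)) as.character(df$Name)
    else as.character(df$ID)
  }
  if (any(is.na(ids) | !nzchar(ids)))
    stop("annotation records without a usable gene id in ", path, call. = FALSE)
  strand <- as.character(df$strand)
  if (any(!strand %in% c("+", "-")))
    stop("annotation records must be stranded (+/-)", call. = FALSE)
  tss0 <- ifelse(strand == "+", df$start - 1L, df$end - 1L)  # import is 1-based
  data.frame(gene_id = ids, chrom = as.character(df$seqnames),
             tss = as.integer(tss0), strand = strand,
             stringsAsFactors = FALSE)
}

#' Extract a 5'-flanking promoter sequence
#'
#' Returns the \code{upstream_bp} bases immediately 5' of the TSS, read
#' 5'-to-3' on the gene's own strand (so minus-strand promoters are
#' reverse-complemented). The result id is \code{"<gene_id>_promoter"}.
#'
#' @param genome Named list of \code{dna_seq} objects (names = chrom), as
#'   returned by \code{\link{read_fasta}}.
#' @param ann A one-row annotation data.frame (see
#'   \code{\link{gene_annotation}}).
#' @param upstream_bp Number of upstream bases (default 600).
#' @return A \code{dna_seq}; shorter than \code{upstream_bp} (with a
#'   warning) when the window is truncated at a contig edge.
#' @export
extract_promoter <- function(genome, ann, upstream_bp = 600L) {
  stopifnot(is.data.frame(ann), nrow(ann) == 1L, upstream_bp >= 1L)
  chrom <- ann$chrom
  if (!chrom %in% names(genome))
    stop("chrom '", chrom, "' not present in genome", call. = FALSE)
  contig <- genome[[chrom]]
  n <- contig$length
  tss <- as.integer(ann$tss)
  if (tss < 0L || tss >= n)
    stop(sprintf("tss %d outside contig '%s' (length %d)", tss, chrom, n),
         call. = FALSE)
  if (ann$strand == "+") {
    start0 <- tss - upstream_bp          # 0-based inclusive
    end0 <- tss                          # 0-based exclusive
    if (end0 <= 0L)
      stop("upstream window entirely off contig for gene ", ann$gene_id,
           call. = FALSE)
    if (start0 < 0L) {
      warning(sprintf("promoter of %s truncated at contig start (%d bp)",
                      ann$gene_id, end0))
      start0 <- 0L
    }
    s <- substr(contig$seq, start0 + 1L, end0)
  } else {
    start0 <- tss + 1L
    end0 <- tss + 1L + upstream_bp
    if (start0 >= n)
      stop("upstream window entirely off contig for gene ", ann$gene_id,
           call. = FALSE)
    if (end0 > n) {
      warning(sprintf("promoter of %s truncated at contig end (%d bp)",
                      ann$gene_id, n - start0))
      end0 <- n
    }
    s <- reverse_complement(substr(contig$seq, start0 + 1L, end0))
  }
  dna_seq(paste0(ann$gene_id, "_promoter"), s)
}

#' Write a promoter manifest TSV
#'
#' One row per extracted promoter: gene_id, chrom, start, end (0-based
#' half-open on the plus strand of the contig), strand and length.
#'
#' @param anns Annotation data.frame (one row per gene).
#' @param promoters List of extracted \code{dna_seq} promoters, same order.
#' @param path Output TSV path.
#' @param upstream_bp Window size used at extraction.
#' @return \code{path}, invisibly.
#' @export
write_promoter_manifest <- function(anns, promoters, path, upstream_bp = 600L) {
  len <- vapply(promoters, function(p) p$length, integer(1))
  start0 <- ifelse(anns$strand == "+", anns$tss - len, anns$tss + 1L)
  end0 <- ifelse(anns$strand == "+", anns$tss, anns$tss + 1L + len)
  df <- data.frame(gene_id = anns$gene_id, chrom = anns$chrom,
                   start = start0, end = end0, strand = anns$strand,
                   length = len)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
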