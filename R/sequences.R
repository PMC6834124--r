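# Sequence containers and FASTA I/O.
#
# Internally a sequence is a light S3 object: list(id, seq, length) with
# class "rna_seq" or "dna_seq". All coordinates elsewhere in the package are
# 0-based half-open unless a function says otherwise.

RNA_ALPHABET <- c("A", "C", "G", "U")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a validated RNA sequence
#'
#' Normalizes to uppercase and converts T to U, then checks the alphabet is
#' strictly \code{A/C/G/U}.
#'
#' @param id Record identifier (single string).
#' @param seq Nucleotide string.
#' @return An object of class \code{rna_seq}: list with \code{id},
#'   \code{seq}, \code{length}.
#' @examples
#' rna_seq("x", "acgt")$seq  # "ACGU"
#' @export
rna_seq <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  s <- chartr("T", "U", toupper(as.character(seq)))
  check_alphabet(s, RNA_ALPHABET, id)
  structure(list(id = id, seq = s, length = nchar(s)),
            class = c("rna_seq", "bio_seq"))
}

#' Construct a validated DNA sequence
#'
#' Uppercases and checks the alphabet is strictly \code{A/C/G/T/N}.
#' \code{N} bases are tolerated (ambiguous positions are skipped by the
#' window and triplex scanners) but their presence is flagged.
#'
#' @inheritParams rna_seq
#' @return An object of class \code{dna_seq} with an added logical
#'   \code{has_n} element.
#' @export
dna_seq <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  s <- toupper(as.character(seq))
  check_alphabet(s, DNA_ALPHABET, id)
  structure(list(id = id, seq = s, length = nchar(s),
                 has_n = grepl("N", s, fixed = TRUE)),
            class = c("dna_seq", "bio_seq"))
}

check_alphabet <- function(s, alphabet, id) {
  if (nchar(s) < 1L) stop("sequence '", id, "' is empty", call. = FALSE)
  bad <- regexpr(sprintf("[^%s]", paste(alphabet, collapse = "")), s)
  if (bad > 0L) {
    stop(sprintf(
      "invalid character '%s' in record '%s' at offset %d (allowed: %s)",
      substr(s, bad, bad), id, as.integer(bad),
      paste(alphabet, collapse = "")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.bio_seq <- function(x, ...) {
  kind <- if (inherits(x, "rna_seq")) "RNA" else "DNA"
  shown <- if (x$length > 60L) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(sprintf("<%s> %s (%d nt)\n%s\n", kind, x$id, x$length, shown))
  invisible(x)
}

#' Extract the raw sequence string
#' @param x A \code{rna_seq}/\code{dna_seq} object or character scalar.
#' @return A character scalar.
#' @export
seq_string <- function(x) {
  if (inherits(x, "bio_seq")) x$seq else as.character(x)
}

#' Read a FASTA file into validated sequence objects
#'
#' Order of records is preserved; sequences are uppercased and, for
#' \code{alphabet = "RNA"}, T is converted to U.
#'
#' @param path Path to a FASTA file.
#' @param alphabet \code{"DNA"} or \code{"RNA"}.
#' @return A named list of \code{dna_seq} or \code{rna_seq} objects.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  ctor <- if (alphabet == "RNA") rna_seq else dna_seq
  out <- mapply(ctor, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  names(out) <- ids
  out
}

#' Write sequence objects to a FASTA file
#'
#' @param seqs A list of \code{bio_seq} objects (or a single one).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "bio_seq")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) {
    body <- substring(s$seq, seq(1L, s$length, by = width),
                      pmin(seq(1L, s$length, by = width) + width - 1L, s$length))
    c(paste0(">", s$id), body)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' An involution: \code{reverse_complement(reverse_complement(x))} equals
#' \code{x}. \code{N} complements to \code{N}.
#'
#' @param seq A \code{dna_seq} object or DNA character scalar.
#' @return Same type as the input (id gains a \code{_rc} suffix for
#'   \code{dna_seq} input).
#' @export
reverse_complement <- function(seq) {
  s <- seq_string(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (inherits(seq, "dna_seq")) dna_seq(paste0(seq$id, "_rc"), rc) else rc
}
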