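# FASTA input/output.  One file = one genome: assemblies are searched as
# wholes, so all records in a file are aggregated into a single genome record
# in file order.

.NT_ALLOWED <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.AA_ALLOWED <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Construct a genome record
#'
#' A genome record holds the ordered residue sequences of one genome (or one
#' proteome), its identifier and its alphabet.  Sequence order is stable: it
#' is the order of the records in the source FASTA file.
#'
#' @param genome_id Non-empty identifier, unique within one database build.
#' @param sequences Character vector of uppercase residue sequences.
#' @param alphabet `"nucleotide"` or `"aminoacid"`.
#' @param source_path Optional path the record was read from.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, sequences, alphabet = "nucleotide",
                          source_path = NA_character_) {
  alphabet <- .check_alphabet(alphabet)
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  structure(
    list(genome_id = genome_id, sequences = as.character(sequences),
         alphabet = alphabet, source_path = source_path),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d sequence(s), %s residues, %s\n",
              x$genome_id, length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ","), x$alphabet))
  invisible(x)
}

.file_stem <- function(path) {
  b <- basename(path)
  b <- sub("\\.gz$", "", b)
  tools::file_path_sans_ext(b)
}

#' Read a (possibly gzip-compressed) FASTA file as one genome
#'
#' All records in the file are aggregated, in file order, into a single
#' [genome_record()]; the genome identifier defaults to the file stem.
#' Residues are uppercased and, for amino-acid input, `*` stop codons are
#' stripped.  Residues outside the alphabet (IUPAC nucleotide codes, or the
#' 20 canonical amino acids plus `X`) are fatal when `strict = TRUE`;
#' otherwise they are reported with their position and replaced by the
#' excluded placeholder (`N`/`X`) so that k-mer extraction skips them.
#'
#' @param path FASTA or gzip-FASTA file.
#' @param alphabet `"nucleotide"` or `"aminoacid"`.
#' @param genome_id Identifier override; default is the file stem.
#' @param strict Fail on out-of-alphabet residues instead of masking them.
#' @return A [genome_record()].
#' @export
read_fasta <- function(path, alphabet = "nucleotide", genome_id = NULL,
                       strict = TRUE) {
  alphabet <- .check_alphabet(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (alphabet == "aminoacid") seqs <- gsub("*", "", seqs, fixed = TRUE)
  if (any(!nzchar(seqs)) && all(!nzchar(seqs))) stop("empty FASTA file: ", path)

  allowed <- if (alphabet == "nucleotide") .NT_ALLOWED else .AA_ALLOWED
  mask <- if (alphabet == "nucleotide") "N" else "X"
  bad_re <- paste0("[^", paste(allowed, collapse = ""), "]")
  for (i in seq_along(seqs)) {
    hit <- regexpr(bad_re, seqs[i])
    if (hit > 0L) {
      msg <- sprintf("residue '%s' outside %s alphabet at sequence %d position %d in %s",
                     substr(seqs[i], hit, hit), alphabet, i, hit, path)
      if (strict) stop(msg)
      warning(msg, "; masking all such residues", call. = FALSE)
      seqs[i] <- gsub(bad_re, mask, seqs[i])
    }
  }
  genome_record(genome_id %||% .file_stem(path), seqs, alphabet, path)
}

#' Write a genome record to FASTA
#'
#' Sequences are written in record order as `<genome_id>_<i>` entries, wrapped
#' at `width` columns.  `read_fasta(write_fasta(x))` reproduces the sequences
#' exactly.
#'
#' @param record A [genome_record()].
#' @param path Output path (a `.gz` suffix triggers gzip compression).
#' @param width Line-wrapping width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(record, path, width = 70L) {
  stopifnot(inherits(record, "genome_record"))
  set <- Biostrings::BStringSet(record$sequences)
  names(set) <- sprintf("%s_%d", record$genome_id, seq_along(record$sequences))
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
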