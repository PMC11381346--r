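# Canonical k-mer multisets: the weighted sets every sketch summarises.

.AA_ORDER <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.NT_ORDER <- c("A", "C", "G", "T")

#' Extract the canonical k-mer multiset of a genome record
#'
#' Slides a width-`k` window over each sequence independently (windows never
#' span sequence boundaries).  Windows containing an excluded residue (`N` or
#' any other ambiguity code for nucleotides, `X` for amino acids) are skipped.
#' Nucleotide k-mers are canonicalised to the lexicographic minimum of the
#' forward k-mer and its reverse complement, so the multiset is identical for
#' a sequence and its reverse complement; amino-acid k-mers are used as-is.
#'
#' Tokens are packed integers (2 bits per base; base-20 positional code for
#' amino acids), which bounds `k` at 26 (nucleotide) and 12 (amino acid) so
#' that tokens remain exactly representable.  Both default search k values
#' (16 for bacterial genomes, 21 for fungal, 7 and 5 for proteomes) fit.
#'
#' @param record A [genome_record()].
#' @param k K-mer length.
#' @return An object of class `kmer_multiset` with fields `k`, `alphabet`,
#'   `tokens` (sorted packed k-mers), `counts` and `total_count`.  Sequences
#'   shorter than `k` contribute nothing; a record with no admissible window
#'   yields an empty multiset with `total_count = 0`.
#' @export
extract_kmers <- function(record, k) {
  stopifnot(inherits(record, "genome_record"))
  k <- as.integer(k)
  kmax <- .kmax(record$alphabet)
  if (k < 1L || k > kmax)
    stop(sprintf("k must be in [1, %d] for %s input", kmax, record$alphabet))
  res <- kmer_count_cpp(record$sequences, k, record$alphabet == "aminoacid")
  structure(
    list(k = k, alphabet = record$alphabet, tokens = res$tokens,
         counts = res$counts, total_count = res$total),
    class = "kmer_multiset"
  )
}

#' @export
print.kmer_multiset <- function(x, ...) {
  cat(sprintf("<kmer_multiset> k=%d (%s): %s distinct k-mers, total count %s\n",
              x$k, x$alphabet, format(length(x$tokens), big.mark = ","),
              format(x$total_count, big.mark = ",")))
  invisible(x)
}

#' Normalised k-mer weights
#'
#' Converts a k-mer multiset into the weighted set consumed by weighted
#' sketching: each k-mer's weight is its count divided by the total count, so
#' the weights sum to one.
#'
#' @param ms A [extract_kmers()] multiset with `total_count > 0`.
#' @return A tibble with columns `token`, `kmer` (decoded string), `count`
#'   and `weight`.
#' @export
normalize_weights <- function(ms) {
  stopifnot(inherits(ms, "kmer_multiset"))
  if (ms$total_count <= 0) stop("cannot normalise an empty k-mer multiset")
  tibble(
    token = ms$tokens,
    kmer = kmer_decode(ms$tokens, ms$k, ms$alphabet),
    count = ms$counts,
    weight = ms$counts / ms$total_count
  )
}

#' Decode packed k-mer tokens to strings
#'
#' @param tokens Numeric vector of packed tokens.
#' @param k K-mer length used at packing time.
#' @param alphabet `"nucleotide"` or `"aminoacid"`.
#' @return Character vector of k-mers (canonical form for nucleotides).
#' @export
kmer_decode <- function(tokens, k, alphabet = "nucleotide") {
  alphabet <- .check_alphabet(alphabet)
  base <- if (alphabet == "nucleotide") 4 else 20
  letters <- if (alphabet == "nucleotide") .NT_ORDER else .AA_ORDER
  out <- character(length(tokens))
  t <- as.numeric(tokens)
  chars <- matrix("", nrow = length(tokens), ncol = k)
  for (i in k:1) {
    d <- t %% base
    chars[, i] <- letters[d + 1]
    t <- (t - d) / base
  }
  apply(chars, 1L, paste0, collapse = "")
}

#' Encode k-mer strings to packed tokens
#'
#' Inverse of [kmer_decode()]; nucleotide k-mers are canonicalised.
#'
#' @inheritParams kmer_decode
#' @param kmers Character vector of k-mers (equal lengths).
#' @return Numeric vector of packed tokens.
#' @export
kmer_encode <- function(kmers, alphabet = "nucleotide") {
  alphabet <- .check_alphabet(alphabet)
  k <- unique(nchar(kmers))
  stopifnot(length(k) == 1L)
  rec <- genome_record("tmp", kmers, alphabet)
  ms <- extract_kmers(rec, k)
  stats::setNames(ms$tokens, kmer_decode(ms$tokens, k, alphabet))
}
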