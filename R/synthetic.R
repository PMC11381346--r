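# Synthetic genomes/proteomes with controlled relatedness and completeness.
# Substitution-only mutation keeps the expected ANI of a mutant analytically
# at 1 - rate, so every benchmark has a known truth.

#' Generate a random genome
#'
#' I.i.d. nucleotide sequence with `P(G) + P(C) = gc`, fully determined by
#' `seed`.
#'
#' @param length Genome length (>= 1).
#' @param gc GC content in (0, 1).
#' @param seed Integer seed.
#' @param genome_id Identifier for the record.
#' @return A [genome_record()] with one sequence.
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, genome_id = "synth") {
  stopifnot(length >= 1, gc > 0, gc < 1)
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  genome_record(genome_id, seq, "nucleotide")
}

#' Mutation/fragmentation specification
#'
#' @param substitution_rate Per-site substitution probability in \[0, 1); the
#'   expected ANI of a mutant is `1 - substitution_rate` (substitutions only,
#'   no indels).
#' @param completeness Fraction of the genome retained, in (0, 1\];
#'   incompleteness removes random contiguous blocks, mimicking MAG
#'   fragmentation.
#' @param seed Integer seed.
#' @param n_replicates Replicate count consumed by sweep helpers.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(substitution_rate = 0, completeness = 1, seed = 1L,
                          n_replicates = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            completeness > 0, completeness <= 1)
  structure(list(substitution_rate = substitution_rate,
                 completeness = completeness, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "mutation_spec")
}

#' Mutate (and optionally fragment) a genome
#'
#' Each site is substituted independently with probability
#' `spec$substitution_rate` to a uniformly chosen different base.  If
#' `completeness < 1`, random contiguous blocks totalling
#' `(1 - completeness)` of the genome are removed and the surviving fragments
#' become separate sequences (contigs).
#'
#' @param g A nucleotide [genome_record()].
#' @param spec A [mutation_spec()] (or pass `rate`/`completeness`/`seed`).
#' @param rate,completeness,seed Shortcut arguments overriding `spec`.
#' @param suffix Appended to the parent id to form the mutant id.
#' @return A [genome_record()].
#' @export
mutate_genome <- function(g, spec = NULL, rate = NULL, completeness = NULL,
                          seed = NULL, suffix = "_mut") {
  stopifnot(inherits(g, "genome_record"), g$alphabet == "nucleotide")
  spec <- spec %||% mutation_spec()
  if (!is.null(rate)) spec$substitution_rate <- rate
  if (!is.null(completeness)) spec$completeness <- completeness
  if (!is.null(seed)) spec$seed <- as.integer(seed)

  seqs <- withr::with_seed(spec$seed, {
    out <- lapply(g$sequences, .mutate_seq, rate = spec$substitution_rate)
    if (spec$completeness < 1) out <- .fragment_seqs(out, spec$completeness)
    out
  })
  seqs <- unlist(seqs, use.names = FALSE)
  seqs <- seqs[nzchar(seqs)]
  if (length(seqs) == 0L) stop("completeness removed the entire genome")
  genome_record(paste0(g$genome_id, suffix), seqs, "nucleotide")
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    bases[hit] <- alt[cbind(match(bases[hit], rownames(alt)), pick)]
  }
  paste(bases, collapse = "")
}

# remove random contiguous blocks totalling (1 - completeness) of the genome
.fragment_seqs <- function(seqs, completeness) {
  total <- sum(nchar(seqs))
  drop_total <- round((1 - completeness) * total)
  n_blocks <- max(1L, min(10L, ceiling(10 * (1 - completeness))))
  sizes <- as.vector(stats::rmultinom(1, drop_total, rep(1 / n_blocks, n_blocks)))
  out <- seqs
  for (sz in sizes[sizes > 0]) {
    lens <- nchar(out)
    tgt <- sample.int(length(out), 1L, prob = lens / sum(lens))
    L <- lens[tgt]
    sz <- min(sz, L - 1L)
    if (sz <= 0) next
    start <- sample.int(L - sz + 1L, 1L)
    left <- substr(out[tgt], 1L, start - 1L)
    right <- substr(out[tgt], start + sz, L)
    out <- c(out[-tgt], left, right)
    out <- out[nzchar(out)]
  }
  out
}

#' Generate a random proteome-like record
#'
#' I.i.d. amino-acid sequences over the 20 canonical residues; related
#' proteomes are derived with [derive_proteome()].
#'
#' @param n_seqs Number of protein sequences.
#' @param seq_length Length of each sequence.
#' @param seed Integer seed.
#' @param genome_id Identifier.
#' @return An amino-acid [genome_record()].
#' @export
generate_proteome <- function(n_seqs = 50L, seq_length = 300L, seed = 1L,
                              genome_id = "synth_prot") {
  seqs <- withr::with_seed(seed, {
    replicate(n_seqs, paste(sample(.AA_ORDER, seq_length, replace = TRUE),
                            collapse = ""))
  })
  genome_record(genome_id, seqs, "aminoacid")
}

#' Derive a related proteome by segment sharing
#'
#' The child keeps a fraction `share` of the parent's sequences verbatim and
#' replaces the rest with fresh random sequences, so the amino-acid k-mer
#' Jaccard between parent and child is approximately `share / (2 - share)`.
#'
#' @param parent An amino-acid [genome_record()].
#' @param share Fraction of sequences copied, in \[0, 1\].
#' @param seed Integer seed.
#' @param suffix Id suffix.
#' @return An amino-acid [genome_record()].
#' @export
derive_proteome <- function(parent, share = 0.5, seed = 1L, suffix = "_rel") {
  stopifnot(inherits(parent, "genome_record"), parent$alphabet == "aminoacid",
            share >= 0, share <= 1)
  n <- length(parent$sequences)
  keep <- round(share * n)
  seqs <- withr::with_seed(seed, {
    idx <- if (keep > 0) sort(sample.int(n, keep)) else integer(0)
    fresh <- replicate(n - keep,
                       paste(sample(.AA_ORDER, nchar(parent$sequences[1]),
                                    replace = TRUE), collapse = ""))
    c(parent$sequences[idx], fresh)
  })
  genome_record(paste0(parent$genome_id, suffix), seqs, "aminoacid")
}

#' Synthetic genome collection with hierarchical relatedness
#'
#' The study-condition generator behind the search benchmarks.  Group parents
#' form a random-attachment tree: the first parent is a fresh random genome
#' and every later parent is a mutated copy (rate `parent_rate`) of a
#' randomly chosen earlier parent, so inter-group distances form a gradient
#' rather than a flat plateau (as in a real taxonomy, where relatedness spans
#' a continuum).  Each group consists of its parent plus `group_size - 1`
#' mutants at rate `group_rate`.
#'
#' @param n_groups Number of groups (species-like clusters).
#' @param group_size Genomes per group.
#' @param genome_length Length of the root genome.
#' @param parent_rate Substitution rate between a parent and its attachment
#'   point.
#' @param group_rate Substitution rate between a parent and its group members.
#' @param gc GC content of the root.
#' @param seed Master seed; all draws derive from it.
#' @return A list with `records` (list of [genome_record()]) and `truth`
#'   (tibble: `genome_id`, `group`, `role`).
#' @export
synth_genome_collection <- function(n_groups = 20L, group_size = 10L,
                                    genome_length = 2000L, parent_rate = 0.05,
                                    group_rate = 0.015, gc = 0.5, seed = 1L) {
  parents <- vector("list", n_groups)
  parents[[1]] <- generate_genome(genome_length, gc, seed = seed * 1000L + 1L,
                                  genome_id = "g001")
  attach_at <- withr::with_seed(seed * 1000L + 2L, {
    if (n_groups > 1) vapply(2:n_groups, function(i) sample.int(i - 1L, 1L),
                             integer(1))
    else integer(0)
  })
  for (i in seq_len(n_groups - 1L) + 1L) {
    parents[[i]] <- mutate_genome(parents[[attach_at[i - 1L]]],
                                  rate = parent_rate,
                                  seed = seed * 1000L + 10L + i,
                                  suffix = "")
    parents[[i]]$genome_id <- sprintf("g%03d", i)
  }
  records <- list()
  truth <- list()
  for (i in seq_len(n_groups)) {
    grp <- sprintf("grp%03d", i)
    mem <- vector("list", group_size)
    mem[[1]] <- parents[[i]]
    if (group_size > 1) {
      for (j in 2:group_size) {
        mem[[j]] <- mutate_genome(parents[[i]], rate = group_rate,
                                  seed = seed * 100000L + i * 100L + j,
                                  suffix = sprintf("_m%02d", j))
      }
    }
    records <- c(records, mem)
    truth[[i]] <- tibble(
      genome_id = vapply(mem, function(r) r$genome_id, character(1)),
      group = grp,
      role = c("parent", rep("mutant", group_size - 1L))
    )
  }
  list(records = records, truth = dplyr::bind_rows(truth))
}
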