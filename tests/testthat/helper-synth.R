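# Synthetic token multisets used across sketch and oracle tests.
mkms <- function(tokens, counts = NULL, k = 16L, alphabet = "nucleotide") {
  o <- order(tokens)
  tokens <- as.numeric(tokens)[o]
  counts <- if (is.null(counts)) rep(1L, length(tokens)) else as.integer(counts)[o]
  structure(list(k = k, alphabet = alphabet, tokens = tokens, counts = counts,
                 total_count = sum(counts)), class = "kmer_multiset")
}

# random small weighted multiset
rand_ms <- function(seed, universe = 200L, size = 40L, maxcount = 5L) {
  withr::with_seed(seed, {
    toks <- sample.int(universe, size)
    mkms(toks, sample.int(maxcount, size, replace = TRUE))
  })
}

# Naive Monte-Carlo ProbMinHash oracle, independent of the compiled path:
# per register every element draws Exp(weight) through R's own RNG (shared
# elements share draws); the register collision frequency estimates J_p.
pmh1_mc_jp <- function(ma, mb, m = 1e5, seed = 42) {
  withr::with_seed(seed, {
    toks <- union(ma$tokens, mb$tokens)
    wa <- stats::setNames(rep(0, length(toks)), toks)
    wb <- wa
    wa[as.character(ma$tokens)] <- ma$counts / ma$total_count
    wb[as.character(mb$tokens)] <- mb$counts / mb$total_count
    E <- matrix(stats::rexp(m * length(toks)), nrow = m)
    va <- sweep(E[, wa > 0, drop = FALSE], 2, wa[wa > 0], "/")
    vb <- sweep(E[, wb > 0, drop = FALSE], 2, wb[wb > 0], "/")
    argA <- toks[wa > 0][max.col(-va, ties.method = "first")]
    argB <- toks[wb > 0][max.col(-vb, ties.method = "first")]
    mean(argA == argB)
  })
}

# sketch_db from a list of genome records
records_db <- function(records, params) {
  sketch_db(lapply(records, sketch_genome, params = params))
}

# subset columns of a sketch_db
db_subset <- function(db, idx) {
  db$ids <- db$ids[idx]
  db$registers <- db$registers[, idx, drop = FALSE]
  db
}
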