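# Sketching: fixed-size register summaries of k-mer multisets, plus distance
# estimators and the exact brute-force oracles they are tested against.

.SKETCH_ALGOS <- c("probminhash3a", "superminhash", "oph_optimal", "oph_faster",
                   "setsketch")

#' Sketching parameters
#'
#' Bundles everything two sketches must share to be comparable: algorithm,
#' register count `m`, k-mer length, alphabet, hash seed and (for SetSketch)
#' the base `b`, rate `a` and truncation `q`.
#'
#' Defaults follow standard practice for whole-genome search: `m = 12000`
#' registers and `k = 16` at the nucleotide level for bacteria-sized genomes
#' (use `m = 48000`, `k = 21` for fungal genomes, `k = 7` for whole-proteome
#' and `k = 5` for universal-gene amino-acid search).  The SetSketch base
#' defaults to `b = 1.001` with `a = 20` and 16-bit registers
#' (`q = 2^16 - 2`), a regime where register saturation is negligible below
#' roughly a billion distinct k-mers.
#'
#' @param algo One of `"probminhash3a"` (weighted, default), `"superminhash"`,
#'   `"oph_optimal"`, `"oph_faster"`, `"setsketch"`.
#' @param m Number of registers (sketch size).
#' @param k K-mer length.
#' @param alphabet `"nucleotide"` or `"aminoacid"`.
#' @param seed Integer hash seed; recorded so databases are self-describing.
#' @param setsketch_b,setsketch_a,setsketch_q SetSketch base (> 1), rate (> 0)
#'   and register truncation.
#' @return An object of class `sketch_params`.
#' @export
sketch_params <- function(algo = "probminhash3a", m = 12000L, k = 16L,
                          alphabet = "nucleotide", seed = 1L,
                          setsketch_b = 1.001, setsketch_a = 20,
                          setsketch_q = 65534L) {
  algo <- match.arg(algo, .SKETCH_ALGOS)
  alphabet <- .check_alphabet(alphabet)
  m <- as.integer(m)
  k <- as.integer(k)
  stopifnot(m >= 1L, k >= 1L, k <= .kmax(alphabet),
            setsketch_b > 1, setsketch_a > 0, setsketch_q >= 1)
  structure(
    list(algo = algo, m = m, k = k, alphabet = alphabet, seed = as.integer(seed),
         setsketch_b = setsketch_b, setsketch_a = setsketch_a,
         setsketch_q = as.integer(setsketch_q)),
    class = "sketch_params"
  )
}

#' @export
print.sketch_params <- function(x, ...) {
  cat(sprintf("<sketch_params> %s: m=%d, k=%d, %s, seed=%d\n",
              x$algo, x$m, x$k, x$alphabet, x$seed))
  invisible(x)
}

.new_sketch <- function(registers, params, genome_id) {
  structure(
    list(algo = params$algo, m = params$m, k = params$k,
         alphabet = params$alphabet, seed = params$seed,
         setsketch_b = params$setsketch_b, setsketch_a = params$setsketch_a,
         setsketch_q = params$setsketch_q,
         registers = registers, genome_id = genome_id),
    class = "sketch_vector"
  )
}

#' @export
print.sketch_vector <- function(x, ...) {
  cat(sprintf("<sketch_vector> %s: %s, m=%d, k=%d (%s)\n",
              x$genome_id, x$algo, x$m, x$k, x$alphabet))
  invisible(x)
}

.check_ms <- function(ms, params) {
  stopifnot(inherits(ms, "kmer_multiset"))
  if (ms$total_count <= 0) stop("cannot sketch an empty k-mer multiset")
  if (ms$k != params$k || ms$alphabet != params$alphabet)
    stop("k-mer multiset (k=", ms$k, ", ", ms$alphabet,
         ") does not match sketch parameters (k=", params$k, ", ",
         params$alphabet, ")")
}

#' Sketch a k-mer multiset
#'
#' Dispatches on `params$algo`.  ProbMinHash3a uses the abundance-normalised
#' weights (register collision probability equals the probability Jaccard
#' index \eqn{J_p}); all other algorithms deliberately collapse the multiset
#' to its support and estimate the plain Jaccard index \eqn{J}.
#'
#' @param ms A non-empty [extract_kmers()] multiset.
#' @param params A [sketch_params()] object.
#' @param genome_id Identifier stored in the sketch.
#' @return A `sketch_vector` with `m` registers.
#' @export
sketch_kmers <- function(ms, params = sketch_params(), genome_id = "query") {
  .check_ms(ms, params)
  regs <- switch(params$algo,
    probminhash3a = sketch_pmh3a_cpp(ms$tokens, ms$counts, params$m, params$seed),
    superminhash = sketch_superminhash_cpp(ms$tokens, params$m, params$seed),
    oph_optimal = sketch_oph_cpp(ms$tokens, params$m, params$seed, FALSE),
    oph_faster = sketch_oph_cpp(ms$tokens, params$m, params$seed, TRUE),
    setsketch = sketch_setsketch_cpp(ms$tokens, params$m, params$seed,
                                     params$setsketch_b, params$setsketch_a,
                                     params$setsketch_q)
  )
  .new_sketch(regs, params, genome_id)
}

#' @rdname sketch_kmers
#' @export
sketch_probminhash3a <- function(ms, params = sketch_params(), genome_id = "query") {
  params$algo <- "probminhash3a"
  sketch_kmers(ms, params, genome_id)
}

#' @rdname sketch_kmers
#' @export
sketch_superminhash <- function(ms, params = sketch_params(), genome_id = "query") {
  params$algo <- "superminhash"
  sketch_kmers(ms, params, genome_id)
}

#' @rdname sketch_kmers
#' @param variant Densification rule: `"optimal"` (random-direction borrowing
#'   through a 2-universal re-hash) or `"faster"` (fixed-direction rotation
#'   with offset re-randomisation).
#' @export
sketch_oph_densified <- function(ms, params = sketch_params(),
                                 variant = c("optimal", "faster"),
                                 genome_id = "query") {
  variant <- match.arg(variant)
  params$algo <- if (variant == "optimal") "oph_optimal" else "oph_faster"
  sketch_kmers(ms, params, genome_id)
}

#' @rdname sketch_kmers
#' @export
sketch_setsketch <- function(ms, params = sketch_params(), genome_id = "query") {
  params$algo <- "setsketch"
  sketch_kmers(ms, params, genome_id)
}

#' Sketch a genome record directly
#'
#' Convenience wrapper: [extract_kmers()] then [sketch_kmers()], with the
#' genome id taken from the record.
#'
#' @inheritParams sketch_kmers
#' @param record A [genome_record()].
#' @export
sketch_genome <- function(record, params = sketch_params()) {
  sketch_kmers(extract_kmers(record, params$k), params, record$genome_id)
}

.comparable_fields <- c("algo", "m", "k", "alphabet", "seed",
                        "setsketch_b", "setsketch_a", "setsketch_q")

.check_comparable <- function(sa, sb) {
  for (f in .comparable_fields) {
    if (!identical(sa[[f]], sb[[f]]))
      stop("sketches are not comparable: '", f, "' differs (",
           sa[[f]], " vs ", sb[[f]], ")")
  }
  invisible(TRUE)
}

#' Estimate the distance between two sketches
#'
#' `register_match` returns `1 - (#equal registers)/m`, an unbiased estimate
#' of the probability Jaccard distance \eqn{1 - J_p} for ProbMinHash3a
#' sketches and of the Jaccard distance \eqn{1 - J} for SuperMinHash/OPH.
#' SetSketch sketches use either the LSH (register-equality with a
#' base-dependent correction) or the joint maximum-likelihood estimator of
#' \eqn{1 - J}; the JMLE is the default because it remains accurate when
#' \eqn{J < 0.01}.  Comparing sketches built under different parameters is a
#' hard error.
#'
#' @param sa,sb `sketch_vector` objects with identical parameters.
#' @param estimator `"register_match"`, `"setsketch_lsh"` or
#'   `"setsketch_jmle"`; default depends on the algorithm.
#' @return Distance in `[0, 1]`, symmetric in its arguments.
#' @export
estimate_distance <- function(sa, sb, estimator = NULL) {
  stopifnot(inherits(sa, "sketch_vector"), inherits(sb, "sketch_vector"))
  .check_comparable(sa, sb)
  estimator <- estimator %||% .default_estimator(sa$algo)
  estimator <- match.arg(estimator,
                         c("register_match", "setsketch_lsh", "setsketch_jmle"))
  if (estimator == "register_match" && sa$algo == "setsketch")
    stop("register_match is not defined for setsketch sketches")
  if (estimator != "register_match" && sa$algo != "setsketch")
    stop(estimator, " requires setsketch sketches")
  switch(estimator,
    register_match = dist_regmatch_cpp(sa$registers, sb$registers),
    setsketch_lsh = setsketch_lsh_cpp(sa$registers, sb$registers, sa$setsketch_b),
    setsketch_jmle = setsketch_jmle_cpp(sa$registers, sb$registers,
                                        sa$setsketch_b, sa$setsketch_a)
  )
}

.default_estimator <- function(algo) {
  if (algo == "setsketch") "setsketch_jmle" else "register_match"
}

#' SetSketch cardinality estimate
#'
#' Estimates the number of distinct elements summarised by a SetSketch from
#' its register values (the base-`b` analogue of the HyperLogLog raw
#' estimator).
#'
#' @param s A SetSketch `sketch_vector`.
#' @return Estimated support cardinality.
#' @export
setsketch_cardinality <- function(s) {
  stopifnot(inherits(s, "sketch_vector"), s$algo == "setsketch")
  setsketch_card_cpp(s$registers, s$setsketch_b, s$setsketch_a)
}

#' Exact probability Jaccard index between two k-mer multisets
#'
#' Brute-force oracle for ProbMinHash:
#' \deqn{J_P = \sum_{x: w_A(x) w_B(x) > 0}
#'       \Big(\sum_y \max(w_A(y)/w_A(x),\; w_B(y)/w_B(x))\Big)^{-1}}
#' with \eqn{w} the count-normalised weights.
#'
#' @param ma,mb Non-empty `kmer_multiset` objects with matching `k`/alphabet.
#' @return \eqn{J_P \in [0, 1]}.
#' @export
jp_exact <- function(ma, mb) {
  .check_pair(ma, mb)
  jp_exact_cpp(ma$tokens, ma$counts, mb$tokens, mb$counts)
}

#' Exact Jaccard index between two k-mer multisets
#'
#' \eqn{|A \cap B| / |A \cup B|} over the supports.
#'
#' @inheritParams jp_exact
#' @export
j_exact <- function(ma, mb) {
  .check_pair(ma, mb)
  j_exact_cpp(ma$tokens, mb$tokens)
}

.check_pair <- function(ma, mb) {
  stopifnot(inherits(ma, "kmer_multiset"), inherits(mb, "kmer_multiset"))
  if (ma$total_count <= 0 || mb$total_count <= 0)
    stop("exact Jaccard oracles require non-empty multisets")
  if (ma$k != mb$k || ma$alphabet != mb$alphabet)
    stop("multisets have mismatched k or alphabet")
}

# --- sketch databases -------------------------------------------------------

#' Bundle sketches into a database
#'
#' A sketch database is the register matrix (one column per genome) plus the
#' shared parameters and the ordered genome-id list; it is the unit the HNSW
#' index is built over and the unit persisted to disk.
#'
#' @param sketches List of comparable `sketch_vector` objects.
#' @return An object of class `sketch_db`.
#' @export
sketch_db <- function(sketches) {
  stopifnot(length(sketches) >= 1L)
  for (s in sketches[-1]) .check_comparable(sketches[[1]], s)
  ids <- vapply(sketches, function(s) s$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids in sketch database")
  p <- sketches[[1]]
  params <- sketch_params(p$algo, p$m, p$k, p$alphabet, p$seed,
                          p$setsketch_b, p$setsketch_a, p$setsketch_q)
  reg <- vapply(sketches, function(s) as.numeric(s$registers), numeric(p$m))
  structure(list(params = params, ids = ids,
                 registers = matrix(reg, nrow = p$m)),
            class = "sketch_db")
}

#' @export
print.sketch_db <- function(x, ...) {
  cat(sprintf("<sketch_db> %d genomes, %s, m=%d, k=%d (%s)\n",
              length(x$ids), x$params$algo, x$params$m, x$params$k,
              x$params$alphabet))
  invisible(x)
}

# extract one column of a sketch_db as a sketch_vector
.db_sketch <- function(db, i) {
  .new_sketch(db$registers[, i], db$params, db$ids[i])
}
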