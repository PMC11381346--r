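# Brute-force oracles and recall scoring.

#' Exhaustive k-nearest-neighbour search
#'
#' Evaluates the distance from the query to every database entry and returns
#' the top `K` by `(distance, genome_id)`.  In `"sketch"` mode the database
#' is a [sketch_db()] and distances use the sketch estimator; in
#' `"jp_exact"`/`"j_exact"` mode the database is a list of `kmer_multiset`s
#' and distances are the exact \eqn{1 - J_p} / \eqn{1 - J}.
#'
#' @param db A [sketch_db()] or a named list of `kmer_multiset`s.
#' @param query A `sketch_vector` or a `kmer_multiset` matching `mode`.
#' @param K Number of hits.
#' @param mode `"sketch"`, `"jp_exact"` or `"j_exact"`.
#' @param estimator Sketch-mode estimator override (see
#'   [estimate_distance()]).
#' @param query_id Id used in the output when the query carries none.
#' @return Tibble of hits: `query_id`, `hit_id`, `distance`, `rank`.
#' @export
brute_force_knn <- function(db, query, K = 10L,
                            mode = c("sketch", "jp_exact", "j_exact"),
                            estimator = NULL, query_id = NULL) {
  mode <- match.arg(mode)
  if (mode == "sketch") {
    stopifnot(inherits(db, "sketch_db"), inherits(query, "sketch_vector"))
    .check_comparable(db$params, query)
    estimator <- estimator %||% .default_estimator(db$params$algo)
    if (estimator == "register_match") {
      # vectorised register comparison, independent of the graph search path
      d <- 1 - colSums(db$registers == query$registers) / db$params$m
    } else {
      d <- vapply(seq_along(db$ids), function(i)
        estimate_distance(.db_sketch(db, i), query, estimator), numeric(1))
    }
    ids <- db$ids
    qid <- query_id %||% query$genome_id
  } else {
    stopifnot(is.list(db), length(db) >= 1L, inherits(query, "kmer_multiset"))
    fun <- if (mode == "jp_exact") jp_exact else j_exact
    d <- vapply(db, function(ms) 1 - fun(ms, query), numeric(1))
    ids <- names(db) %||% as.character(seq_along(db))
    qid <- query_id %||% "query"
  }
  ord <- order(d, ids, method = "radix")  # C-locale id ordering on ties
  kk <- min(K, length(ids))
  tibble(query_id = qid, hit_id = ids[ord[seq_len(kk)]],
         distance = d[ord[seq_len(kk)]], rank = seq_len(kk))
}

#' Score average recall of approximate vs exact hit lists
#'
#' Hits beyond `distance_cutoff` are unreliable for k-mer methods and are
#' dropped from both lists symmetrically before comparing (if 2 of 10 truth
#' hits fall beyond the cutoff, the top 8 of each list are compared); recall
#' per query is \eqn{|R' \cap R| / |R|} and the average is the mean over
#' queries with a non-empty truth set.
#'
#' @param approx,exact Hit tibbles (as from [knn_query()] /
#'   [brute_force_knn()]) covering the same queries, or lists of such tibbles.
#' @param K Depth of the comparison.
#' @param distance_cutoff Reliability cutoff on the distance (default 1 =
#'   keep everything).
#' @return An object of class `recall_result`: list with `K`,
#'   `per_query_recall`, `average_recall` and `n_filtered_hits`.
#' @export
score_recall <- function(approx, exact, K = 10L, distance_cutoff = 1) {
  approx <- .split_hits(approx)
  exact <- .split_hits(exact)
  if (!setequal(names(approx), names(exact)))
    stop("approx and exact hit lists cover different queries")
  qids <- names(exact)
  per <- rep(NA_real_, length(qids))
  names(per) <- qids
  nfilt <- 0L
  for (qi in seq_along(qids)) {
    R <- exact[[qids[qi]]]
    Rp <- approx[[qids[qi]]]
    R <- R[order(R$rank), ][seq_len(min(K, nrow(R))), ]
    Rp <- Rp[order(Rp$rank), ][seq_len(min(K, nrow(Rp))), ]
    keepR <- sum(R$distance <= distance_cutoff)
    keepRp <- sum(Rp$distance <= distance_cutoff)
    nfilt <- nfilt + (nrow(R) - keepR)
    L <- min(keepR, keepRp)
    if (L == 0L) next
    per[qi] <- length(intersect(head(Rp$hit_id, L), head(R$hit_id, L))) / L
  }
  structure(list(K = as.integer(K), per_query_recall = per,
                 average_recall = mean(per, na.rm = TRUE),
                 n_filtered_hits = nfilt),
            class = "recall_result")
}

.split_hits <- function(x) {
  if (is.data.frame(x)) split(x, x$query_id) else x
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("<recall_result> top-%d average recall %.4f over %d queries (%d hits cutoff-filtered)\n",
              x$K, x$average_recall, length(x$per_query_recall),
              x$n_filtered_hits))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.recall_result <- function(x, ...) {
  tibble(query_id = names(x$per_query_recall), recall = x$per_query_recall,
         K = x$K)
}

#' @exportS3Method generics::glance
glance.recall_result <- function(x, ...) {
  tibble(K = x$K, average_recall = x$average_recall,
         n_queries = length(x$per_query_recall),
         n_filtered_hits = x$n_filtered_hits)
}

#' Recall as a function of genome completeness
#'
#' Fragments each query genome to the given completeness levels, searches the
#' graph, and scores top-`K` recall against the known parent-group truth
#' (the fraction of the query's group members among its hits).
#'
#' @param graph An [hnsw_build()] result over a synthetic collection.
#' @param queries List of nucleotide [genome_record()] queries (typically the
#'   database genomes themselves or fresh mutants of them).
#' @param truth Tibble mapping `genome_id` to `group` for database genomes
#'   and queries alike (as from [synth_genome_collection()]).
#' @param completeness_grid Completeness fractions to sweep.
#' @param K Hits per query.
#' @param ef_search Beam width.
#' @param seed Seed for the fragmentation draws.
#' @return A tibble of class `completeness_sweep`: `completeness`,
#'   `average_recall`, `n_queries`.
#' @export
completeness_sweep <- function(graph, queries, truth,
                               completeness_grid = c(1, 0.9, 0.7, 0.5, 0.3),
                               K = 10L, ef_search = 128L, seed = 1L) {
  stopifnot(length(completeness_grid) >= 1L)
  p <- graph$db$params
  grp <- stats::setNames(truth$group, truth$genome_id)
  rows <- lapply(seq_along(completeness_grid), function(ci) {
    cc <- completeness_grid[ci]
    rec <- vapply(seq_along(queries), function(qi) {
      q <- queries[[qi]]
      if (cc < 1)
        q <- mutate_genome(q, rate = 0, completeness = cc,
                           seed = seed + 7919L * ci + qi, suffix = "")
      hits <- knn_query(graph, sketch_genome(q, p), K = K,
                        ef_search = ef_search)
      members <- truth$genome_id[truth$group == grp[[queries[[qi]]$genome_id]]]
      denom <- min(K, length(members))
      sum(hits$hit_id %in% members) / denom
    }, numeric(1))
    tibble(completeness = cc, average_recall = mean(rec),
           n_queries = length(queries))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("completeness_sweep", class(out))
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a completeness sweep
#'
#' @param object A [completeness_sweep()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.completeness_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$completeness,
                                       y = .data$average_recall)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse(labels = function(x) sprintf("%d%%", round(100 * x))) +
    ggplot2::labs(x = "genome completeness", y = "average top-K recall") +
    ggplot2::theme_minimal()
}
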