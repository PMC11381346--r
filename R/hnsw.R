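# Hierarchical navigable small world index over sketch distances.

#' HNSW construction parameters
#'
#' @param M Maximum neighbours per node per layer (layer 0 allows `2*M`).
#'   Useful values are roughly 20-200; small graphs tolerate less.
#' @param ef_construct Candidate-beam width while inserting; at least `M`
#'   (production builds use >= 1000, small benchmarks much less).
#' @param mL Level multiplier of the exponential layer assignment; defaults
#'   to `1/log(M)`.
#' @param seed Seed for the per-node level draws; combined with the node
#'   ordinal so that adding after a reload reproduces a single-session build.
#' @return An object of class `hnsw_params`.
#' @export
hnsw_params <- function(M = 24L, ef_construct = 1000L, mL = 1 / log(M),
                        seed = 1L) {
  M <- as.integer(M)
  ef_construct <- as.integer(ef_construct)
  stopifnot(M >= 2L, ef_construct >= M, mL > 0)
  structure(list(M = M, ef_construct = ef_construct, mL = mL,
                 seed = as.integer(seed)),
            class = "hnsw_params")
}

#' Layer assignment of a new node
#'
#' `floor(-log(u) * mL)` for a uniform draw `u`, i.e. geometric occupancy
#' decay with rate `exp(-1/mL)` per level.
#'
#' @param params An [hnsw_params()] object.
#' @param u Uniform draw in (0, 1).
#' @return Integer level >= 0.
#' @export
assign_level <- function(params, u) {
  stopifnot(all(u > 0), all(u < 1))
  as.integer(floor(-log(u) * params$mL))
}

.distspec <- function(db, distance) {
  list(tag = distance, b = db$params$setsketch_b, a = db$params$setsketch_a)
}

.check_distance_tag <- function(db, distance) {
  if (is.null(distance)) distance <- .default_estimator(db$params$algo)
  distance <- match.arg(distance,
                        c("register_match", "setsketch_lsh", "setsketch_jmle"))
  if ((distance == "register_match") == (db$params$algo == "setsketch"))
    stop("estimator '", distance, "' cannot be used with algorithm '",
         db$params$algo, "'")
  distance
}

#' Build an HNSW graph over a sketch database
#'
#' Inserts sketches in database order.  Each insertion runs a beam search of
#' width `ef_construct` per layer, selects up to `M` (`2*M` at layer 0)
#' neighbours with the "closer to the new node than to any already selected
#' neighbour" heuristic (nearest-first fill as fallback), and reverse-updates
#' the selected neighbours' lists with cap-respecting pruning.
#'
#' @param db A [sketch_db()].
#' @param params [hnsw_params()].
#' @param distance Distance estimator tag; defaults to the algorithm's
#'   canonical estimator (`register_match`, or `setsketch_jmle`).
#' @return An object of class `hnsw_graph`.
#' @export
hnsw_build <- function(db, params = hnsw_params(), distance = NULL) {
  stopifnot(inherits(db, "sketch_db"))
  distance <- .check_distance_tag(db, distance)
  raw <- hnsw_build_cpp(db$registers, params$M, params$ef_construct,
                        params$mL, params$seed, .distspec(db, distance))
  structure(list(db = db, params = params, distance = distance,
                 levels = raw$levels, entry = raw$entry,
                 max_level = raw$max_level, adjacency = raw$adjacency,
                 n = length(db$ids)),
            class = "hnsw_graph")
}

#' Insert additional sketches into an existing graph
#'
#' New nodes draw their levels from the graph seed and their ordinal, so
#' `hnsw_build` on all sketches and `hnsw_build` on a prefix followed by
#' `hnsw_insert` of the rest produce identical graphs.
#'
#' @param graph An [hnsw_build()] result.
#' @param sketches List of `sketch_vector`s, or a [sketch_db()] with matching
#'   parameters.
#' @return The updated `hnsw_graph`.
#' @export
hnsw_insert <- function(graph, sketches) {
  stopifnot(inherits(graph, "hnsw_graph"))
  ndb <- if (inherits(sketches, "sketch_db")) sketches else sketch_db(sketches)
  .check_comparable(graph$db$params, ndb$params)
  if (any(ndb$ids %in% graph$db$ids))
    stop("duplicate genome ids: ",
         paste(intersect(ndb$ids, graph$db$ids), collapse = ", "))
  n_old <- graph$n
  all_reg <- cbind(graph$db$registers, ndb$registers)
  gl <- list(levels = graph$levels, entry = graph$entry,
             max_level = graph$max_level, adjacency = graph$adjacency)
  raw <- hnsw_add_cpp(gl, all_reg, n_old, graph$params$M,
                      graph$params$ef_construct, graph$params$mL,
                      graph$params$seed, .distspec(graph$db, graph$distance))
  db <- graph$db
  db$registers <- all_reg
  db$ids <- c(db$ids, ndb$ids)
  structure(list(db = db, params = graph$params, distance = graph$distance,
                 levels = raw$levels, entry = raw$entry,
                 max_level = raw$max_level, adjacency = raw$adjacency,
                 n = length(db$ids)),
            class = "hnsw_graph")
}

#' @export
print.hnsw_graph <- function(x, ...) {
  occ <- table(factor(x$levels, levels = 0:x$max_level))
  occ <- rev(cumsum(rev(as.integer(occ))))  # nodes present at each layer
  cat(sprintf("<hnsw_graph> %d nodes, %d layer(s), M=%d, ef_construct=%d, %s\n",
              x$n, x$max_level + 1L, x$params$M, x$params$ef_construct,
              x$distance))
  cat("  layer occupancy:", paste(sprintf("L%d=%d", seq_along(occ) - 1L, occ),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Graph-level summary
#'
#' @param x An `hnsw_graph`.
#' @param ... Unused.
#' @return One-row tibble with node count, layers, parameters and mean
#'   layer-0 degree.
#' @exportS3Method generics::glance
glance.hnsw_graph <- function(x, ...) {
  deg <- vapply(x$adjacency[[1]], length, integer(1))
  tibble(n_nodes = x$n, n_layers = x$max_level + 1L, M = x$params$M,
         ef_construct = x$params$ef_construct, mL = x$params$mL,
         distance = x$distance, mean_degree_l0 = mean(deg))
}

#' Query an HNSW graph for nearest neighbours
#'
#' Greedy descent through the upper layers keeping the single closest node,
#' then a beam search of width `ef_search` at layer 0.  When
#' `ef_search >= n`, the beam covers the whole database and every node is
#' evaluated, which makes the result exactly the brute-force ranking.  The
#' graph is never modified by a query.
#'
#' @param graph An [hnsw_build()] result.
#' @param query A `sketch_vector` or a [sketch_db()] of queries built with
#'   the graph's sketch parameters.
#' @param K Number of neighbours to return (clamped to the database size).
#' @param ef_search Beam width, at least `K`; default `max(K, 64)`.
#' @return A tibble with columns `query_id`, `hit_id`, `distance`, `rank`,
#'   sorted ascending by `(distance, hit_id)` within query, ranks consecutive
#'   from 1.  The per-query number of distance evaluations is available as
#'   `attr(, "n_dist_evals")`.
#' @export
knn_query <- function(graph, query, K = 10L, ef_search = max(K, 64L)) {
  stopifnot(inherits(graph, "hnsw_graph"), K >= 1L)
  if (ef_search < K) stop("ef_search must be at least K")
  qdb <- if (inherits(query, "sketch_db")) query
         else if (inherits(query, "sketch_vector")) sketch_db(list(query))
         else stop("query must be a sketch_vector or sketch_db")
  .check_comparable(graph$db$params, qdb$params)
  gl <- list(levels = graph$levels, entry = graph$entry,
             max_level = graph$max_level, adjacency = graph$adjacency)
  raw <- hnsw_query_cpp(gl, graph$db$registers, qdb$registers, graph$db$ids,
                        as.integer(K), as.integer(ef_search),
                        .distspec(graph$db, graph$distance))
  kk <- nrow(raw$idx)
  out <- tibble(
    query_id = rep(qdb$ids, each = kk),
    hit_id = graph$db$ids[as.vector(raw$idx)],
    distance = as.vector(raw$dist),
    rank = rep(seq_len(kk), times = length(qdb$ids))
  )
  out <- out[!is.na(out$distance), , drop = FALSE]
  attr(out, "n_dist_evals") <- as.numeric(raw$n_dist_evals)
  out
}

# --- persistence ------------------------------------------------------------

.DB_FORMAT_VERSION <- 1L

#' Persist an HNSW database directory
#'
#' Writes four coupled artifacts: `manifest.json` (all sketch and graph
#' parameters, counts, format version), `ids.tsv` (ordinal, genome id,
#' source), `sketches.bin` (register matrix, little-endian doubles,
#' column-major) and `graph.bin` (levels, adjacency, entry point as
#' little-endian 32-bit integers).  `hnsw_load(hnsw_dump(g))` restores the
#' graph bit-exactly: any query returns identical hits afterwards.
#'
#' @param graph An `hnsw_graph`.
#' @param dir Output directory (created if needed).
#' @param extra Optional named list merged into the manifest (e.g. skipped
#'   genomes).
#' @return `dir`, invisibly.
#' @export
hnsw_dump <- function(graph, dir, extra = list()) {
  stopifnot(inherits(graph, "hnsw_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- graph$db$params
  manifest <- c(list(
    format_version = .DB_FORMAT_VERSION,
    n = graph$n, m = p$m, algo = p$algo, k = p$k, alphabet = p$alphabet,
    sketch_seed = p$seed, setsketch_b = p$setsketch_b,
    setsketch_a = p$setsketch_a, setsketch_q = p$setsketch_q,
    distance = graph$distance,
    M = graph$params$M, ef_construct = graph$params$ef_construct,
    mL = graph$params$mL, hnsw_seed = graph$params$seed,
    entry = graph$entry, max_level = graph$max_level
  ), extra)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  write.table(
    data.frame(ordinal = seq_len(graph$n), genome_id = graph$db$ids),
    file.path(dir, "ids.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  con <- file(file.path(dir, "sketches.bin"), "wb")
  writeBin(as.vector(graph$db$registers), con, size = 8L, endian = "little")
  close(con)
  flat <- integer(0)
  for (l in seq_along(graph$adjacency)) {
    for (i in seq_len(graph$n)) {
      nb <- graph$adjacency[[l]][[i]]
      flat <- c(flat, length(nb), nb)
    }
  }
  con <- file(file.path(dir, "graph.bin"), "wb")
  writeBin(c(.DB_FORMAT_VERSION, graph$n, graph$max_level, graph$entry,
             as.integer(graph$levels), flat),
           con, size = 4L, endian = "little")
  close(con)
  invisible(dir)
}

#' Load an HNSW database directory
#'
#' Validates the format version and the manifest/sketch size agreement and
#' reconstructs the graph written by [hnsw_dump()].
#'
#' @param dir Database directory.
#' @return An `hnsw_graph`.
#' @export
hnsw_load <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a database directory (no manifest.json): ", dir)
  man <- jsonlite::fromJSON(readLines(mf))
  if (!identical(as.integer(man$format_version), .DB_FORMAT_VERSION))
    stop("database format version mismatch: ", man$format_version)
  ids <- read.delim(file.path(dir, "ids.tsv"), colClasses = "character")$genome_id
  if (length(ids) != man$n) stop("manifest/id-table count disagreement")

  sz <- file.info(file.path(dir, "sketches.bin"))$size
  if (is.na(sz) || sz != 8 * man$m * man$n)
    stop("sketch file truncated or sized inconsistently with the manifest")
  con <- file(file.path(dir, "sketches.bin"), "rb")
  reg <- readBin(con, "double", n = man$m * man$n, size = 8L, endian = "little")
  close(con)

  con <- file(file.path(dir, "graph.bin"), "rb")
  hdr <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
  if (hdr[1] != .DB_FORMAT_VERSION || hdr[2] != man$n)
    stop("graph file header disagrees with the manifest")
  levels <- readBin(con, "integer", n = man$n, size = 4L, endian = "little")
  adjacency <- vector("list", hdr[3] + 1L)
  for (l in seq_len(hdr[3] + 1L)) {
    nodes <- vector("list", man$n)
    for (i in seq_len(man$n)) {
      len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
      nodes[[i]] <- if (len > 0)
        readBin(con, "integer", n = len, size = 4L, endian = "little")
      else integer(0)
    }
    adjacency[[l]] <- nodes
  }
  close(con)

  params <- sketch_params(man$algo, man$m, man$k, man$alphabet, man$sketch_seed,
                          as.numeric(man$setsketch_b),
                          as.numeric(man$setsketch_a),
                          as.integer(man$setsketch_q))
  db <- structure(list(params = params, ids = ids,
                       registers = matrix(reg, nrow = man$m)),
                  class = "sketch_db")
  structure(list(db = db,
                 params = hnsw_params(man$M, man$ef_construct, man$mL,
                                      man$hnsw_seed),
                 distance = man$distance, levels = levels, entry = hdr[4],
                 max_level = hdr[3], adjacency = adjacency, n = man$n),
            class = "hnsw_graph")
}
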