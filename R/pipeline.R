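# The three-step search pipeline: nucleotide -> whole proteome -> universal
# genes, with classification suggestions and database splitting.

#' Pipeline distance cutoffs and classification thresholds
#'
#' The nucleotide cutoff 0.9850 is the probability-Jaccard distance at which
#' the ANI proxy reaches 78% for k = 16; nucleotide k-mer methods lose
#' accuracy beyond it and the search escalates to the proteome graph.  The
#' proteome cutoff 0.9720 triggers escalation to the universal-gene graph,
#' and 0.9800 is the corresponding reliability cutoff for viral genomes
#' (used when nucleotide search is forced for recall filtering).
#' Classification suggestions use ANI >= 95% (same species), at least 5 of
#' the top 10 with AAI >= 65% (same genus), and top 5 of 10 with AAI >= 52%
#' (same family).
#'
#' The constructor self-checks that inverting the Mash equation at
#' ANI = 0.78, k = 16 reproduces the nucleotide cutoff to 4 decimal places
#' and refuses an inconsistent configuration.
#'
#' @param nt_distance_cutoff,aa_distance_cutoff,viral_nt_cutoff Escalation /
#'   reliability cutoffs on the sketch distance.
#' @param species_ani,genus_aai,family_aai Identity thresholds.
#' @param genus_votes Qualifying hits (out of the top 10) required for the
#'   genus suggestion.
#' @return An object of class `pipeline_thresholds`.
#' @export
pipeline_thresholds <- function(nt_distance_cutoff = 0.9850,
                                aa_distance_cutoff = 0.9720,
                                viral_nt_cutoff = 0.9800,
                                species_ani = 0.95, genus_aai = 0.65,
                                genus_votes = 5L, family_aai = 0.52) {
  derived <- round(1 - mash_inverse(0.78, 16), 4)
  if (!isTRUE(all.equal(derived, nt_distance_cutoff, tolerance = 1e-9)))
    stop("inconsistent threshold configuration: Mash inversion of 78% ANI at ",
         "k=16 gives distance ", derived, " but nt_distance_cutoff is ",
         nt_distance_cutoff)
  vals <- c(nt_distance_cutoff, aa_distance_cutoff, viral_nt_cutoff,
            species_ani, genus_aai, family_aai)
  stopifnot(all(vals >= 0 & vals <= 1))
  structure(list(nt_distance_cutoff = nt_distance_cutoff,
                 aa_distance_cutoff = aa_distance_cutoff,
                 viral_nt_cutoff = viral_nt_cutoff,
                 species_ani = species_ani, genus_aai = genus_aai,
                 genus_votes = as.integer(genus_votes),
                 family_aai = family_aai),
            class = "pipeline_thresholds")
}

.list_fastas <- function(dir) {
  f <- list.files(dir, pattern = "\\.(fa|fasta|fna|faa)(\\.gz)?$",
                  full.names = TRUE)
  sort(f)
}

#' Build an HNSW database directory from a folder of FASTA genomes
#'
#' Sketches every genome in `genome_dir` (one file = one genome, sorted path
#' order), inserts them into an HNSW graph and persists the database to
#' `out_dir`.  Genomes whose sequences yield no admissible k-mer window are
#' skipped with a warning and recorded in the manifest.
#'
#' @param genome_dir Directory of FASTA / gzip-FASTA files, one per genome.
#' @param out_dir Output database directory.
#' @param sparams [sketch_params()] (alphabet decides nt vs aa parsing).
#' @param hparams [hnsw_params()].
#' @param distance Distance estimator tag (default per algorithm).
#' @param verbose Log per-phase progress to stderr.
#' @return The built `hnsw_graph`, invisibly.
#' @export
tohnsw <- function(genome_dir, out_dir, sparams = sketch_params(),
                   hparams = hnsw_params(), distance = NULL, verbose = FALSE) {
  files <- .list_fastas(genome_dir)
  if (length(files) == 0L) stop("no FASTA files in ", genome_dir)
  say <- function(...) if (verbose) message(sprintf(...))
  say("sketching %d genomes (%s, m=%d, k=%d)", length(files), sparams$algo,
      sparams$m, sparams$k)
  sketches <- list()
  skipped <- character(0)
  for (f in files) {
    rec <- read_fasta(f, sparams$alphabet)
    ms <- extract_kmers(rec, sparams$k)
    if (ms$total_count <= 0) {
      warning("genome '", rec$genome_id, "' yields an empty k-mer multiset; skipped",
              call. = FALSE)
      skipped <- c(skipped, rec$genome_id)
      next
    }
    sketches[[length(sketches) + 1L]] <- sketch_kmers(ms, sparams, rec$genome_id)
  }
  if (length(sketches) == 0L) stop("no sketchable genomes in ", genome_dir)
  db <- sketch_db(sketches)
  say("building graph over %d sketches (M=%d, ef_construct=%d)",
      length(db$ids), hparams$M, hparams$ef_construct)
  graph <- hnsw_build(db, hparams, distance)
  hnsw_dump(graph, out_dir, extra = list(skipped = skipped))
  if (verbose) print(graph)
  invisible(graph)
}

#' Add genomes to an existing database directory
#'
#' New genomes are sketched with the manifest's parameters and inserted;
#' duplicate genome ids are rejected.  Adding after a reload reproduces the
#' single-session build exactly (levels are keyed to node ordinals).
#'
#' @param db_dir Existing database directory.
#' @param genome_dir Directory of FASTA files to add (may be empty).
#' @return The updated `hnsw_graph`, invisibly; the directory is re-dumped.
#' @export
add_genomes <- function(db_dir, genome_dir) {
  graph <- hnsw_load(db_dir)
  files <- .list_fastas(genome_dir)
  sparams <- graph$db$params
  sketches <- list()
  skipped <- character(0)
  for (f in files) {
    rec <- read_fasta(f, sparams$alphabet)
    ms <- extract_kmers(rec, sparams$k)
    if (ms$total_count <= 0) {
      warning("genome '", rec$genome_id, "' yields an empty k-mer multiset; skipped",
              call. = FALSE)
      skipped <- c(skipped, rec$genome_id)
      next
    }
    sketches[[length(sketches) + 1L]] <- sketch_kmers(ms, sparams, rec$genome_id)
  }
  if (length(sketches) > 0L) graph <- hnsw_insert(graph, sketches)
  hnsw_dump(graph, db_dir, extra = list(skipped = skipped))
  invisible(graph)
}

.as_graph <- function(x) {
  if (inherits(x, "hnsw_graph")) x else hnsw_load(x)
}

# annotate hits with the identity proxy at the level's k
.annotate_hits <- function(hits, k, cutoff) {
  j <- 1 - hits$distance
  hits$identity <- ifelse(j > 0, suppressWarnings(mash_transform(j, k)), NA_real_)
  hits$beyond_cutoff <- hits$distance > cutoff
  hits
}

# classification suggestion from the best available evidence
.classify <- function(nt_hits, aa_hits, thresholds, labels) {
  ev <- character(0)
  if (!is.null(nt_hits) && nrow(nt_hits) > 0) {
    top_ani <- nt_hits$identity[1]
    if (!is.na(top_ani) && top_ani >= thresholds$species_ani)
      return(list(suggestion = "same_species",
                  evidence = sprintf("top-1 ANI proxy %.3f >= %.2f", top_ani,
                                     thresholds$species_ani)))
    ev <- sprintf("top-1 ANI proxy %s < %.2f",
                  ifelse(is.na(top_ani), "NA", sprintf("%.3f", top_ani)),
                  thresholds$species_ani)
  }
  if (!is.null(aa_hits) && nrow(aa_hits) > 0) {
    top10 <- head(aa_hits, 10L)
    qual <- top10[!is.na(top10$identity) &
                    top10$identity >= thresholds$genus_aai, ]
    genus_ok <- FALSE
    lab_note <- "unlabeled"
    if (nrow(qual) >= thresholds$genus_votes) {
      if (!is.null(labels) && all(qual$hit_id %in% names(labels))) {
        votes <- table(vapply(labels[qual$hit_id], `[[`, character(1), "genus"))
        genus_ok <- max(votes) >= thresholds$genus_votes
        lab_note <- sprintf("labelled majority %s (%d votes)",
                            names(which.max(votes)), max(votes))
      } else {
        genus_ok <- TRUE
      }
    }
    if (genus_ok)
      return(list(suggestion = "same_genus_new_species",
                  evidence = sprintf("%d of top 10 AAI proxies >= %.2f (%s)",
                                     nrow(qual), thresholds$genus_aai, lab_note)))
    top5 <- head(top10, 5L)
    if (nrow(top5) == 5L && all(!is.na(top5$identity)) &&
        all(top5$identity >= thresholds$family_aai))
      return(list(suggestion = "same_family_new_genus",
                  evidence = sprintf("top 5 AAI proxies all >= %.2f",
                                     thresholds$family_aai)))
    ev <- c(ev, sprintf("genus/family AAI votes below thresholds (%.2f/%.2f)",
                        thresholds$genus_aai, thresholds$family_aai))
  }
  list(suggestion = "unclassified_at_family",
       evidence = paste(ev, collapse = "; "))
}

#' Three-step best-match search with classification suggestions
#'
#' Per query: (1) nucleotide search; if the best hit is within the
#' nucleotide distance cutoff the query is reported at the nucleotide level;
#' (2) otherwise proteome search, reported there if within the proteome
#' cutoff; (3) otherwise universal-gene search.  Hits are annotated with the
#' ANI/AAI proxy of the level's own k through the Mash equation; hits beyond
#' the level cutoff are retained but flagged `beyond_cutoff`.  The
#' classification suggestion (same species / same genus, new species / same
#' family, new genus / unclassified at family rank) follows the ANI >= 95%,
#' 5-of-10 AAI >= 65% and top-5 AAI >= 52% rules; genus votes use optional
#' taxonomy labels when provided and degrade to a count of qualifying hits
#' flagged "unlabeled" otherwise.  Suggestions are evidence, not
#' authoritative taxonomy.
#'
#' @param db_nt,db_aa,db_univ Database directories or `hnsw_graph` objects
#'   (aa and universal optional; the pipeline stops at the last feasible
#'   level with a warning).
#' @param queries_nt,queries_aa,queries_univ Named lists of
#'   [genome_record()]s (or directories of FASTA files) per level; query ids
#'   must match across levels.
#' @param K Hits per query.
#' @param ef_search Beam width.
#' @param thresholds [pipeline_thresholds()].
#' @param labels Optional data frame with columns `genome_id`, `genus` (and
#'   optionally `family`) for database genomes.
#' @param viral Viral mode: nucleotide search is skipped (amino-acid graphs
#'   are the reliable level for sparse viral databases) and the viral
#'   reliability cutoff applies if a nucleotide search is forced.
#' @return An object of class `search_report`: list with `$hits` (tibble:
#'   `query_id`, `level`, `rank`, `hit_id`, `distance`, `identity`,
#'   `beyond_cutoff`) and `$suggestions` (tibble: `query_id`, `level_used`,
#'   `suggestion`, `evidence`).
#' @export
request <- function(db_nt, queries_nt, db_aa = NULL, queries_aa = NULL,
                    db_univ = NULL, queries_univ = NULL, K = 10L,
                    ef_search = max(K, 64L),
                    thresholds = pipeline_thresholds(), labels = NULL,
                    viral = FALSE) {
  stopifnot(inherits(thresholds, "pipeline_thresholds"))
  gnt <- if (!is.null(db_nt)) .as_graph(db_nt) else NULL
  gaa <- if (!is.null(db_aa)) .as_graph(db_aa) else NULL
  gun <- if (!is.null(db_univ)) .as_graph(db_univ) else NULL
  qnt <- .as_query_records(queries_nt, "nucleotide")
  qaa <- .as_query_records(queries_aa, "aminoacid")
  qun <- .as_query_records(queries_univ, "aminoacid")
  if (viral && is.null(gaa))
    stop("viral mode requires an amino-acid database")

  lab_list <- NULL
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    lab_list <- lapply(seq_len(nrow(labels)), function(i) as.list(labels[i, ]))
    names(lab_list) <- labels$genome_id
  }

  qids <- names(if (viral) qaa else qnt)
  if (length(qids) == 0L) stop("no query genomes supplied")
  for (g in list(gnt, gaa, gun)) {
    if (!is.null(g) && K > g$n)
      warning("K exceeds database size; clamped to ", g$n, call. = FALSE)
  }

  hits_out <- list()
  sugg_out <- list()
  for (qid in qids) {
    nt_hits <- aa_hits <- un_hits <- NULL
    if (!viral && !is.null(gnt) && !is.null(qnt[[qid]])) {
      s <- sketch_genome(qnt[[qid]], gnt$db$params)
      nt_hits <- .annotate_hits(knn_query(gnt, s, K, ef_search),
                                gnt$db$params$k, thresholds$nt_distance_cutoff)
    }
    level <- "nucleotide"
    best_nt <- if (!is.null(nt_hits) && nrow(nt_hits)) nt_hits$distance[1] else Inf
    if (viral || best_nt > thresholds$nt_distance_cutoff) {
      if (!is.null(gaa) && !is.null(qaa[[qid]])) {
        s <- sketch_genome(qaa[[qid]], gaa$db$params)
        aa_hits <- .annotate_hits(knn_query(gaa, s, K, ef_search),
                                  gaa$db$params$k, thresholds$aa_distance_cutoff)
        level <- "proteome"
      } else if (!viral) {
        warning("query '", qid, "' escalates beyond the nucleotide level but ",
                "no proteome database/query is available; reporting nucleotide hits",
                call. = FALSE)
      }
      best_aa <- if (!is.null(aa_hits) && nrow(aa_hits)) aa_hits$distance[1] else Inf
      if (level == "proteome" && best_aa > thresholds$aa_distance_cutoff) {
        if (!is.null(gun) && !is.null(qun[[qid]])) {
          s <- sketch_genome(qun[[qid]], gun$db$params)
          un_hits <- .annotate_hits(knn_query(gun, s, K, ef_search),
                                    gun$db$params$k, thresholds$aa_distance_cutoff)
          level <- "universal"
        } else {
          warning("query '", qid, "' escalates beyond the proteome level but ",
                  "no universal-gene database/query is available; reporting proteome hits",
                  call. = FALSE)
        }
      }
    }
    lvl_hits <- switch(level, nucleotide = nt_hits, proteome = aa_hits,
                       universal = un_hits)
    cls <- .classify(if (!viral) nt_hits else NULL,
                     if (level == "universal") un_hits else aa_hits,
                     thresholds, lab_list)
    if (!is.null(lvl_hits) && nrow(lvl_hits)) {
      lvl_hits$level <- level
      hits_out[[qid]] <- lvl_hits[, c("query_id", "level", "rank", "hit_id",
                                      "distance", "identity", "beyond_cutoff")]
    }
    sugg_out[[qid]] <- tibble(query_id = qid, level_used = level,
                              suggestion = cls$suggestion,
                              evidence = cls$evidence)
  }
  structure(list(hits = dplyr::bind_rows(hits_out),
                 suggestions = dplyr::bind_rows(sugg_out),
                 thresholds = thresholds),
            class = "search_report")
}

.as_query_records <- function(x, alphabet) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- .list_fastas(x)
    x <- lapply(files, read_fasta, alphabet = alphabet)
  }
  stopifnot(all(vapply(x, inherits, logical(1), "genome_record")))
  stats::setNames(x, vapply(x, function(r) r$genome_id, character(1)))
}

#' @export
print.search_report <- function(x, ...) {
  cat(sprintf("<search_report> %d queries\n", nrow(x$suggestions)))
  print(x$suggestions, n = 10)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.search_report <- function(x, ...) x$hits

#' @exportS3Method generics::glance
glance.search_report <- function(x, ...) {
  dplyr::count(x$suggestions, .data$level_used, .data$suggestion)
}

# --- database splitting -----------------------------------------------------

#' Build a randomly split database
#'
#' Genomes are assigned to `n_pieces` by a seeded uniform draw and one
#' database is built per piece; a split manifest records the partition.
#'
#' @param genome_dir Directory of FASTA files.
#' @param n_pieces Number of pieces (>= 1, at most the genome count).
#' @param out_dir Parent directory; pieces land in `piece_1 ... piece_n`.
#' @param sparams,hparams,distance As in [tohnsw()].
#' @param seed Seed of the partition draw.
#' @return Character vector of piece directories, invisibly.
#' @export
split_build <- function(genome_dir, n_pieces, out_dir,
                        sparams = sketch_params(), hparams = hnsw_params(),
                        distance = NULL, seed = 1L) {
  files <- .list_fastas(genome_dir)
  if (length(files) == 0L) stop("no FASTA files in ", genome_dir)
  n_pieces <- as.integer(n_pieces)
  if (n_pieces < 1L || n_pieces > length(files))
    stop("n_pieces must be between 1 and the number of genomes")
  assign <- withr::with_seed(seed,
                             sample.int(n_pieces, length(files), replace = TRUE))
  # guarantee non-empty pieces (a piece with no genomes cannot form a graph)
  for (p in seq_len(n_pieces)) {
    if (!any(assign == p)) {
      big <- which.max(tabulate(assign, n_pieces))
      assign[which(assign == big)[1]] <- p
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dirs <- character(n_pieces)
  for (p in seq_len(n_pieces)) {
    piece_dir <- file.path(out_dir, sprintf("piece_%d", p))
    tmp <- file.path(out_dir, sprintf("input_%d", p))
    dir.create(tmp, showWarnings = FALSE)
    file.copy(files[assign == p], tmp)
    tohnsw(tmp, piece_dir, sparams, hparams, distance)
    unlink(tmp, recursive = TRUE)
    dirs[p] <- piece_dir
  }
  writeLines(jsonlite::toJSON(
    list(n_pieces = n_pieces, seed = seed,
         assignment = data.frame(genome = .file_stem(files), piece = assign)),
    auto_unbox = TRUE),
    file.path(out_dir, "split_manifest.json"))
  invisible(dirs)
}

#' Query a split database
#'
#' Each piece is queried for `per_piece_k` hits; the per-piece results are
#' pooled, sorted by `(distance, hit_id)` and truncated to `K`.  With
#' `per_piece_k >= K` (enforced) and an exhaustive beam, the pooled top `K`
#' equals the unsplit ranking exactly.
#'
#' @param pieces Character vector of piece directories or list of
#'   `hnsw_graph`s.
#' @param queries Named list of [genome_record()]s or a FASTA directory.
#' @param K Pooled hits per query.
#' @param per_piece_k Hits requested from each piece; must be >= `K`.
#' @param ef_search Beam width per piece (use >= piece size for exhaustive).
#' @return Tibble of pooled hits (`query_id`, `hit_id`, `distance`, `rank`).
#' @export
split_request <- function(pieces, queries, K = 10L, per_piece_k = K,
                          ef_search = max(K, 64L)) {
  if (per_piece_k < K)
    stop("per_piece_k must be at least K (pooled equivalence guarantee)")
  graphs <- lapply(pieces, .as_graph)
  for (g in graphs[-1]) .check_comparable(graphs[[1]]$db$params, g$db$params)
  qrec <- .as_query_records(queries, graphs[[1]]$db$params$alphabet)
  out <- list()
  for (qid in names(qrec)) {
    s <- sketch_genome(qrec[[qid]], graphs[[1]]$db$params)
    pooled <- dplyr::bind_rows(lapply(graphs, function(g)
      knn_query(g, s, K = min(per_piece_k, g$n), ef_search = ef_search)))
    pooled <- pooled[order(pooled$distance, pooled$hit_id, method = "radix"), ]
    kk <- min(K, nrow(pooled))
    pooled <- pooled[seq_len(kk), ]
    pooled$rank <- seq_len(kk)
    out[[qid]] <- pooled
  }
  dplyr::bind_rows(out)
}
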