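# shared small benchmark: 30 groups x 10 related genomes, m = 512 registers
local_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coll <- synth_genome_collection(n_groups = 30L, group_size = 10L,
                                      genome_length = 1500L, seed = 21L)
      p <- sketch_params(m = 512L, k = 16L, seed = 6L)
      cache <<- list(db = records_db(coll$records, p), coll = coll, p = p)
    }
    cache
  }
})

test_that("level assignment follows the exponential decay law", {
  p <- hnsw_params(M = 20L, ef_construct = 40L)
  expect_equal(assign_level(p, 1 - 1e-12), 0L)
  expect_equal(assign_level(p, exp(-0.5 / p$mL)), 0L)
  u <- withr::with_seed(4, runif(1e5))
  lv <- assign_level(p, u)
  frac1 <- mean(lv >= 1)  # P(level >= 1) = exp(-1/mL) = 1/M = 0.05
  expect_lt(abs(frac1 - 0.05), 3 * sqrt(0.05 * 0.95 / 1e5))
  tiny <- hnsw_params(M = 20L, ef_construct = 40L, mL = 1e-9)
  expect_true(all(assign_level(tiny, u[1:100]) == 0L))
})

test_that("empirical layer occupancy decays geometrically", {
  b <- local_bench()
  g <- hnsw_build(b$db, hnsw_params(M = 16L, ef_construct = 100L, seed = 2L))
  pgeq1 <- exp(-1 / g$params$mL)
  n1 <- sum(g$levels >= 1)
  expect_lt(abs(n1 / g$n - pgeq1), 3 * sqrt(pgeq1 * (1 - pgeq1) / g$n))
})

test_that("single-node and identical-sketch insertions behave degenerately", {
  b <- local_bench()
  one <- sketch_db(list(.db_sk <- sketchnav:::.db_sketch(b$db, 1)))
  g1 <- hnsw_build(one, hnsw_params(M = 4L, ef_construct = 8L))
  expect_equal(g1$entry, 1L)
  expect_equal(unname(lengths(g1$adjacency[[1]])), 0L)
  hits <- knn_query(g1, sketchnav:::.db_sketch(b$db, 1), K = 3)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$rank, 1L)
  expect_equal(hits$distance, 0)

  # duplicate sketch under a fresh id lands next to its twin at distance 0
  twin <- sketchnav:::.db_sketch(b$db, 5)
  twin$genome_id <- "twin"
  g2 <- hnsw_build(b$db, hnsw_params(M = 8L, ef_construct = 60L, seed = 2L))
  g2 <- hnsw_insert(g2, list(twin))
  nb <- g2$adjacency[[1]][[g2$n]]
  expect_true(5L %in% nb)
  hits <- knn_query(g2, twin, K = 2)
  expect_equal(hits$hit_id[1:2], c("g001_m05", "twin"))  # ties broken by id
  expect_equal(hits$distance[1:2], c(0, 0))
})

test_that("duplicate genome ids are rejected on insert", {
  b <- local_bench()
  g <- hnsw_build(db_subset(b$db, 1:20), hnsw_params(M = 4L, ef_construct = 8L))
  expect_error(hnsw_insert(g, list(sketchnav:::.db_sketch(b$db, 3))),
               "duplicate genome ids")
})

test_that("neighbour lists respect the caps 2M at layer 0 and M above", {
  b <- local_bench()
  g <- hnsw_build(b$db, hnsw_params(M = 6L, ef_construct = 80L, seed = 3L))
  expect_lte(max(lengths(g$adjacency[[1]])), 12L)
  for (l in seq_along(g$adjacency)[-1]) {
    expect_lte(max(lengths(g$adjacency[[l]])), 6L)
  }
})

test_that("layer-0 neighbourhoods overlap the true nearest sets", {
  b <- local_bench()
  idx <- 1:300
  db <- db_subset(b$db, idx)
  M <- 16L
  g <- hnsw_build(db, hnsw_params(M = M, ef_construct = 200L, seed = 11L))
  hit <- vapply(seq_len(300), function(i) {
    true_nn <- brute_force_knn(db, sketchnav:::.db_sketch(db, i),
                               K = 2L * M + 1L)
    true_nn <- true_nn$hit_id[true_nn$hit_id != db$ids[i]][seq_len(2L * M)]
    nb <- db$ids[g$adjacency[[1]][[i]]]
    length(intersect(nb, true_nn)) > 0
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("query equal to a database sketch returns itself first and never mutates the graph", {
  b <- local_bench()
  g <- hnsw_build(b$db, hnsw_params(M = 8L, ef_construct = 60L, seed = 2L))
  before <- g$adjacency
  hits <- knn_query(g, sketchnav:::.db_sketch(b$db, 42), K = 10)
  expect_equal(hits$hit_id[1], b$db$ids[42])
  expect_equal(hits$distance[1], 0)
  expect_equal(hits$rank, 1:10)
  expect_identical(g$adjacency, before)
  expect_error(knn_query(g, sketch_kmers(rand_ms(1), sketch_params(m = 64L)), K = 1),
               "not comparable")
})

test_that("recall against brute force is non-decreasing in the beam width", {
  b <- local_bench()
  g <- hnsw_build(b$db, hnsw_params(M = 16L, ef_construct = 150L, seed = 7L))
  bf <- dplyr::bind_rows(lapply(seq_len(g$n), function(i)
    brute_force_knn(b$db, sketchnav:::.db_sketch(b$db, i), K = 10L)))
  rec <- vapply(c(16L, 64L, 128L, 256L), function(ef) {
    hits <- knn_query(g, b$db, K = 10L, ef_search = ef)
    score_recall(hits, bf, K = 10L)$average_recall
  }, numeric(1))
  expect_true(all(diff(rec) >= -1e-9))
  expect_gte(rec[length(rec)], 0.95)
})

test_that("an exhaustive beam reproduces the brute-force ranking exactly", {
  b <- local_bench()
  db <- db_subset(b$db, 1:120)
  g <- hnsw_build(db, hnsw_params(M = 8L, ef_construct = 60L, seed = 5L))
  for (i in c(3L, 57L, 111L)) {
    q <- sketchnav:::.db_sketch(db, i)
    ex <- knn_query(g, q, K = 120L, ef_search = 120L)
    bf <- brute_force_knn(db, q, K = 120L)
    expect_equal(ex$hit_id, bf$hit_id)
    expect_equal(ex$distance, bf$distance)
    expect_setequal(ex$hit_id, db$ids)  # K = N returns a full permutation
  }
})

test_that("dump and load round-trip the database bit-exactly", {
  b <- local_bench()
  db <- db_subset(b$db, 1:150)
  g <- hnsw_build(db, hnsw_params(M = 8L, ef_construct = 60L, seed = 5L))
  d <- withr::local_tempdir()
  hnsw_dump(g, d)
  g2 <- hnsw_load(d)
  q <- sketchnav:::.db_sketch(b$db, 201)
  expect_identical(knn_query(g, q, K = 10), knn_query(g2, q, K = 10))
  expect_identical(g2$adjacency, g$adjacency)
  expect_identical(g2$db$registers, g$db$registers)

  # tampering with the manifest k must be caught, not silently accepted
  man <- jsonlite::fromJSON(file.path(d, "manifest.json"))
  man$m <- man$m + 1L
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE), file.path(d, "manifest.json"))
  expect_error(hnsw_load(d), "truncated|disagree")
})

test_that("building all at once equals building then adding, across a reload", {
  b <- local_bench()
  hp <- hnsw_params(M = 8L, ef_construct = 60L, seed = 5L)
  full <- hnsw_build(db_subset(b$db, 1:130), hp)
  part <- hnsw_build(db_subset(b$db, 1:120), hp)
  d <- withr::local_tempdir()
  hnsw_dump(part, d)
  part2 <- hnsw_load(d)
  part2 <- hnsw_insert(part2, lapply(121:130, function(i)
    sketchnav:::.db_sketch(b$db, i)))
  expect_identical(part2$adjacency, full$adjacency)
  expect_identical(part2$levels, full$levels)
  expect_identical(part2$entry, full$entry)
  q <- sketchnav:::.db_sketch(b$db, 250)
  expect_identical(knn_query(part2, q, K = 10), knn_query(full, q, K = 10))
})
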