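test_that("genome generation is seed-deterministic with the requested composition", {
  g1 <- generate_genome(1000L, seed = 5L)
  g2 <- generate_genome(1000L, seed = 5L)
  expect_identical(g1$sequences, g2$sequences)
  expect_false(identical(generate_genome(1000L, seed = 6L)$sequences,
                         g1$sequences))
  big <- generate_genome(1e5L, gc = 0.5, seed = 7L)
  gcf <- mean(strsplit(big$sequences, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcf - 0.5), 3 * sqrt(0.25 / 1e5))
  skew <- generate_genome(2e4L, gc = 0.3, seed = 8L)
  gcf2 <- mean(strsplit(skew$sequences, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcf2 - 0.3), 3 * sqrt(0.3 * 0.7 / 2e4))
  expect_error(generate_genome(100L, gc = 1), "gc")
})

test_that("mutation hits the expected number of sites and zero rate is the identity", {
  g <- generate_genome(1e5L, seed = 2L)
  expect_identical(mutate_genome(g, rate = 0, seed = 3L)$sequences, g$sequences)
  mut <- mutate_genome(g, rate = 0.05, seed = 3L)
  hamming <- sum(strsplit(g$sequences, "")[[1]] != strsplit(mut$sequences, "")[[1]])
  expect_lt(abs(hamming - 5000), 3 * sqrt(0.05 * 0.95 * 1e5))
  expect_equal(mut$genome_id, paste0(g$genome_id, "_mut"))
})

test_that("observed parent-mutant Jaccard follows the Mash-equation prediction", {
  rate <- 0.03
  k <- 16L
  pred <- {
    cc <- exp(-k * rate)
    cc / (2 - cc)
  }
  obs <- vapply(1:20, function(s) {
    g <- generate_genome(2e4L, seed = 100L + s)
    m <- mutate_genome(g, rate = rate, seed = 200L + s)
    j_exact(extract_kmers(g, k), extract_kmers(m, k))
  }, numeric(1))
  expect_lt(abs(mean(obs) - pred), 3 * stats::sd(obs))
})

test_that("fragmentation retains the requested completeness as contiguous blocks", {
  g <- generate_genome(2e4L, seed = 4L)
  for (cc in c(0.9, 0.5, 0.3)) {
    frag <- mutate_genome(g, rate = 0, completeness = cc, seed = 5L)
    kept <- sum(nchar(frag$sequences)) / 2e4
    expect_lt(abs(kept - cc), 0.02)
    expect_gt(length(frag$sequences), 1L)
  }
})

test_that("proteome derivation controls the shared-sequence fraction", {
  p <- generate_proteome(40L, 150L, seed = 9L)
  child <- derive_proteome(p, share = 0.6, seed = 10L)
  shared <- sum(child$sequences %in% p$sequences)
  expect_equal(shared, 24L)
  j <- j_exact(extract_kmers(p, 7L), extract_kmers(child, 7L))
  expect_lt(abs(j - 0.6 / (2 - 0.6)), 0.05)
})

test_that("brute force search ranks the query itself first and permutes all ids at K = N", {
  coll <- synth_genome_collection(n_groups = 6L, group_size = 5L,
                                  genome_length = 1200L, seed = 41L)
  p <- sketch_params(m = 512L, k = 16L, seed = 2L)
  db <- records_db(coll$records, p)
  q <- sketchnav:::.db_sketch(db, 13L)
  hits <- brute_force_knn(db, q, K = 30L)
  expect_equal(hits$hit_id[1], db$ids[13])
  expect_equal(hits$distance[1], 0)
  expect_setequal(hits$hit_id, db$ids)
  expect_equal(hits$rank, 1:30)
})

test_that("exact-oracle and sketch-mode brute force agree on the best match", {
  coll <- synth_genome_collection(n_groups = 20L, group_size = 10L,
                                  genome_length = 1500L, seed = 51L)
  p <- sketch_params(m = 12000L, k = 16L, seed = 4L)
  mss <- lapply(coll$records, extract_kmers, k = 16L)
  names(mss) <- vapply(coll$records, function(r) r$genome_id, character(1))
  db <- records_db(coll$records, p)
  # a top-1 swap between two database genomes whose exact distances differ by
  # less than the register-sampling noise is irreducible; count those as ties
  res <- vapply(seq(1, 200, by = 2), function(i) {
    top_exact <- brute_force_knn(mss[-i], mss[[i]], K = 1L, mode = "jp_exact")
    top_sketch <- brute_force_knn(db_subset(db, -i),
                                  sketchnav:::.db_sketch(db, i), K = 1L)
    if (top_exact$hit_id == top_sketch$hit_id) return(c(1, 1))
    d_best <- top_exact$distance
    d_win <- 1 - jp_exact(mss[[top_sketch$hit_id]], mss[[i]])
    tied <- (d_win - d_best) < 3 * sqrt(d_best * (1 - d_best) / p$m)
    c(0, as.numeric(tied))
  }, numeric(2))
  expect_gte(mean(res[1, ]), 0.95)                 # plain top-1 agreement
  expect_gte(mean(res[1, ] | res[2, ]), 0.99)      # agreement up to noise ties
})

test_that("recall scoring implements symmetric cutoff filtering", {
  mk <- function(ids, dist = seq_along(ids) / 20) {
    tibble::tibble(query_id = "q", hit_id = ids, distance = dist,
                   rank = seq_along(ids))
  }
  ids <- sprintf("h%02d", 1:10)
  expect_equal(score_recall(mk(ids), mk(ids), K = 10)$average_recall, 1)
  expect_equal(score_recall(mk(sprintf("x%02d", 1:10)), mk(ids),
                            K = 10)$average_recall, 0)
  # 8 of 10 shared, no cutoff: 0.8
  r <- score_recall(mk(c(ids[1:8], "y1", "y2")), mk(ids), K = 10)
  expect_equal(r$average_recall, 0.8)
  # last two hits beyond the cutoff: compare top 8 vs top 8
  far <- mk(ids, dist = c(seq(0.1, 0.8, by = 0.1), 0.99, 0.995))
  r2 <- score_recall(far, far, K = 10, distance_cutoff = 0.985)
  expect_equal(r2$average_recall, 1)
  expect_equal(r2$n_filtered_hits, 2L)
  expect_error(score_recall(mk(ids),
                            dplyr::mutate(mk(ids), query_id = "other")),
               "different queries")
})

test_that("recall degrades monotonically (within noise) as completeness drops", {
  coll <- synth_genome_collection(n_groups = 12L, group_size = 10L,
                                  genome_length = 2000L, seed = 61L)
  p <- sketch_params(m = 1024L, k = 16L, seed = 5L)
  db <- records_db(coll$records, p)
  g <- hnsw_build(db, hnsw_params(M = 16L, ef_construct = 150L, seed = 6L))
  queries <- coll$records[seq(1, 120, by = 4)]
  sweep <- completeness_sweep(g, queries, coll$truth,
                              completeness_grid = c(1, 0.9, 0.7, 0.5, 0.3),
                              K = 10L, seed = 8L)
  expect_s3_class(sweep, "completeness_sweep")
  expect_equal(nrow(sweep), 5L)
  # full completeness reproduces the unfragmented baseline
  base <- mean(vapply(queries, function(q) {
    hits <- knn_query(g, sketch_genome(q, p), K = 10L, ef_search = 128L)
    members <- coll$truth$genome_id[coll$truth$group ==
      coll$truth$group[coll$truth$genome_id == q$genome_id]]
    sum(hits$hit_id %in% members) / 10
  }, numeric(1)))
  expect_equal(sweep$average_recall[1], base)
  # non-increasing within one standard error of the binomial noise
  se <- sqrt(0.5 * 0.5 / (length(queries) * 10))
  expect_true(all(diff(sweep$average_recall) <= 3 * se))
  p_plot <- autoplot(sweep)
  expect_s3_class(p_plot, "ggplot")
})
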