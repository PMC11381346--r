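test_that("sketches are deterministic in (input, seed) and sensitive to the seed", {
  ms <- rand_ms(1, size = 120L)
  for (algo in c("probminhash3a", "superminhash", "oph_optimal", "oph_faster",
                 "setsketch")) {
    p <- sketch_params(algo = algo, m = 256L, seed = 7L)
    s1 <- sketch_kmers(ms, p)
    s2 <- sketch_kmers(ms, p)
    expect_identical(s1$registers, s2$registers)
    expect_length(s1$registers, 256L)
    p2 <- p
    p2$seed <- 8L
    expect_false(identical(sketch_kmers(ms, p2)$registers, s1$registers))
    expect_equal(estimate_distance(s1, s2), 0)
  }
})

test_that("disjoint supports estimate distance ~1, identical supports distance 0", {
  A <- mkms(1:3000)
  B <- mkms(10001:13000)
  for (algo in c("probminhash3a", "superminhash", "oph_optimal", "oph_faster")) {
    p <- sketch_params(algo = algo, m = 4096L, seed = 3L)
    expect_gte(estimate_distance(sketch_kmers(A, p), sketch_kmers(B, p)), 0.999)
  }
  p <- sketch_params(algo = "setsketch", m = 1024L, seed = 3L)
  expect_gte(estimate_distance(sketch_kmers(A, p), sketch_kmers(B, p)), 0.999)
})

test_that("register-match estimates are unbiased against exact set constructions", {
  # A = {1..2000}, B = {1001..3000}: J = 1/3 exactly
  A <- mkms(1:2000)
  B <- mkms(1001:3000)
  for (algo in c("superminhash", "oph_optimal", "oph_faster")) {
    est <- vapply(1:50, function(s) {
      p <- sketch_params(algo = algo, m = 2048L, seed = s)
      1 - estimate_distance(sketch_kmers(A, p), sketch_kmers(B, p))
    }, numeric(1))
    expect_lt(abs(mean(est) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 2048))
  }
  # SuperMinHash at J = 0.5: A = {1..150}, B = {51..200}, |A^B|/|AuB| = 100/200
  A2 <- mkms(1:150)
  B2 <- mkms(51:200)
  est <- vapply(1:50, function(s) {
    p <- sketch_params(algo = "superminhash", m = 2048L, seed = s)
    1 - estimate_distance(sketch_kmers(A2, p), sketch_kmers(B2, p))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 3 * sqrt(0.25 / 2048))
})

test_that("ProbMinHash3a register collisions track the exact probability Jaccard", {
  A <- rand_ms(11, universe = 3000L, size = 900L)
  B <- rand_ms(12, universe = 3000L, size = 900L)
  jp <- jp_exact(A, B)
  est <- vapply(1:50, function(s) {
    p <- sketch_params(m = 4096L, seed = s)
    1 - estimate_distance(sketch_kmers(A, p), sketch_kmers(B, p))
  }, numeric(1))
  expect_lt(abs(mean(est) - jp), 3 * sqrt(jp * (1 - jp) / 4096))
})

test_that("exact probability Jaccard oracle matches hand computation and Monte Carlo", {
  ms <- rand_ms(5)
  expect_equal(jp_exact(ms, ms), 1, tolerance = 1e-12)
  expect_equal(jp_exact(mkms(1:10), mkms(101:110)), 0)
  # {a:1, b:1} vs {a:1, c:1} -> 1/3 by direct evaluation of the double sum
  expect_equal(jp_exact(mkms(c(1, 2)), mkms(c(1, 3))), 1 / 3, tolerance = 1e-12)
  # cross-check with an independent naive ProbMinHash oracle at m = 1e5
  A <- mkms(c(1, 2, 5), counts = c(3, 1, 2))
  B <- mkms(c(1, 3, 5), counts = c(1, 2, 2))
  jp <- jp_exact(A, B)
  mc <- pmh1_mc_jp(A, B, m = 1e5)
  expect_lt(abs(mc - jp), 3 * sqrt(jp * (1 - jp) / 1e5))
})

test_that("exact Jaccard oracle follows set arithmetic", {
  expect_equal(j_exact(mkms(1:5), mkms(1:5)), 1)
  expect_equal(j_exact(mkms(1:5), mkms(6:10)), 0)
  ac_cg <- kmer_encode(c("AC", "CG"), "nucleotide")
  ac_gt <- kmer_encode(c("AC", "GT"), "nucleotide")  # GT -> AC: one token
  a <- mkms(ac_cg, k = 2L)
  b <- mkms(c(ac_cg[["AC"]], kmer_encode("TT", "nucleotide")), k = 2L)
  expect_equal(j_exact(a, b), 1 / 3)
})

test_that("SetSketch registers are bounded, mergeable and carry cardinality", {
  p <- sketch_params(algo = "setsketch", m = 4096L, seed = 5L)
  A <- mkms(1:5000)
  B <- mkms(2501:7500)
  sa <- sketch_kmers(A, p)
  sb <- sketch_kmers(B, p)
  expect_true(all(sa$registers >= 0 & sa$registers <= p$setsketch_q + 1))
  su <- sketch_kmers(mkms(1:7500), p)
  expect_identical(pmax(sa$registers, sb$registers), su$registers)
  big <- sketch_kmers(mkms(1:100000), p)
  expect_lt(abs(setsketch_cardinality(big) - 1e5) / 1e5, 0.05)
})

test_that("SetSketch JMLE stays accurate for Jaccard below 0.01", {
  # |A| = |B| = 10050 sharing 100 tokens: J = 100/20000 = 0.005 exactly
  A <- mkms(1:10050)
  B <- mkms(c(1:100, 20001:29950))
  expect_equal(j_exact(A, B), 0.005)
  res <- vapply(1:100, function(s) {
    p <- sketch_params(algo = "setsketch", m = 4096L, seed = s)
    sa <- sketch_kmers(A, p)
    sb <- sketch_kmers(B, p)
    c(lsh = 1 - estimate_distance(sa, sb, "setsketch_lsh"),
      jmle = 1 - estimate_distance(sa, sb, "setsketch_jmle"))
  }, numeric(2))
  se <- stats::sd(res["jmle", ]) / sqrt(ncol(res))
  expect_lt(abs(mean(res["jmle", ]) - 0.005), 3 * se)
  expect_lt(abs(mean(res["lsh", ]) - 0.005),
            3 * stats::sd(res["lsh", ]) / sqrt(ncol(res)))
  rmse <- function(x) sqrt(mean((x - 0.005)^2))
  expect_lte(rmse(res["jmle", ]), rmse(res["lsh", ]) * 1.05)
})

test_that("mismatched sketch parameters are a hard error, never a silent comparison", {
  ms <- rand_ms(2)
  s1 <- sketch_kmers(ms, sketch_params(m = 128L, seed = 1L))
  expect_error(estimate_distance(s1, sketch_kmers(ms, sketch_params(m = 256L, seed = 1L))),
               "not comparable")
  expect_error(estimate_distance(s1, sketch_kmers(ms, sketch_params(m = 128L, seed = 2L))),
               "not comparable")
  s_super <- sketch_kmers(ms, sketch_params(algo = "superminhash", m = 128L))
  expect_error(estimate_distance(s1, s_super), "not comparable")
  s_set <- sketch_kmers(ms, sketch_params(algo = "setsketch", m = 128L))
  expect_error(estimate_distance(s_set, s_set, "register_match"), "not defined")
  expect_error(estimate_distance(s1, s1, "setsketch_jmle"), "requires setsketch")
  empty <- mkms(numeric(0))
  expect_error(sketch_kmers(empty, sketch_params(m = 64L)), "empty")
})

test_that("weighting only affects ProbMinHash; other algorithms use the support", {
  toks <- withr::with_seed(31, sort(sample.int(5000, 400)))
  flat <- mkms(toks)
  weighted <- mkms(toks, counts = 1L + (toks %% 7L))
  for (algo in c("superminhash", "oph_optimal", "oph_faster", "setsketch")) {
    p <- sketch_params(algo = algo, m = 256L, seed = 4L)
    expect_identical(sketch_kmers(flat, p)$registers,
                     sketch_kmers(weighted, p)$registers)
  }
  p <- sketch_params(m = 256L, seed = 4L)
  expect_false(identical(sketch_kmers(flat, p)$registers,
                         sketch_kmers(weighted, p)$registers))
})
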