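test_that("canonical k-mer counting matches hand enumeration", {
  ms <- extract_kmers(genome_record("t", "ACGT"), 2)
  named <- stats::setNames(ms$counts, kmer_decode(ms$tokens, 2))
  expect_equal(named, c(AC = 2L, CG = 1L))  # GT canonicalises to AC
  expect_equal(ms$total_count, 3)

  ms2 <- extract_kmers(genome_record("t", "ACNGT"), 2)
  expect_equal(stats::setNames(ms2$counts, kmer_decode(ms2$tokens, 2)),
               c(AC = 2L))  # CN and NG windows skipped

  ms3 <- extract_kmers(genome_record("t", "ACG"), 4)  # shorter than k
  expect_equal(length(ms3$tokens), 0L)
  expect_equal(ms3$total_count, 0)
})

test_that("windows never span sequence boundaries", {
  joined <- extract_kmers(genome_record("t", "AAAATTTT"), 4)
  split <- extract_kmers(genome_record("t", c("AAAA", "TTTT")), 4)
  expect_lt(sum(split$counts), sum(joined$counts))
  expect_equal(sum(split$counts), 2)  # AAAA and TTTT only
})

test_that("nucleotide extraction is strand symmetric", {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (seed in 1:5) {
    g <- generate_genome(400, seed = seed)
    rc <- genome_record("rc", revcomp(g$sequences), "nucleotide")
    for (k in c(3L, 9L, 16L)) {
      a <- extract_kmers(g, k)
      b <- extract_kmers(rc, k)
      expect_identical(a$tokens, b$tokens)
      expect_identical(a$counts, b$counts)
    }
  }
})

test_that("removing sequences never increases any count", {
  g <- generate_genome(300, seed = 3)
  h <- generate_genome(300, seed = 4)
  both <- extract_kmers(genome_record("b", c(g$sequences, h$sequences)), 5)
  one <- extract_kmers(g, 5)
  idx <- match(one$tokens, both$tokens)
  expect_true(all(!is.na(idx)))
  expect_true(all(one$counts <= both$counts[idx]))
})

test_that("extraction is deterministic and k limits are enforced", {
  g <- generate_genome(500, seed = 9)
  expect_identical(extract_kmers(g, 16), extract_kmers(g, 16))
  expect_error(extract_kmers(g, 27), "k must be in")
  expect_error(extract_kmers(g, 0), "k must be in")
  p <- generate_proteome(2, 50, seed = 1)
  expect_error(extract_kmers(p, 13), "k must be in")
  expect_silent(extract_kmers(p, 12))
})

test_that("normalised weights sum to one and match counts", {
  ms <- extract_kmers(genome_record("t", "ACGT"), 2)
  w <- normalize_weights(ms)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_equal(stats::setNames(w$weight, w$kmer), c(AC = 2 / 3, CG = 1 / 3))

  single <- extract_kmers(genome_record("t", "AAAA"), 4)
  expect_equal(normalize_weights(single)$weight, 1)

  g <- generate_genome(1000, seed = 2)
  expect_equal(sum(normalize_weights(extract_kmers(g, 16))$weight), 1,
               tolerance = 1e-12)
  empty <- extract_kmers(genome_record("t", "AC"), 5)
  expect_error(normalize_weights(empty), "empty")
})

test_that("token encoding and decoding are mutually inverse", {
  enc <- kmer_encode(c("ACGT", "TTTT", "GATC"), "nucleotide")
  # TTTT canonicalises to AAAA; the others are their own reverse complements
  expect_setequal(kmer_decode(enc, 4), c("ACGT", "AAAA", "GATC"))
  aa <- kmer_encode(c("MKVLY", "ACDEF"), "aminoacid")
  expect_setequal(kmer_decode(aa, 5, "aminoacid"), c("MKVLY", "ACDEF"))
})
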