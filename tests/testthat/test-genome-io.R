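test_that("FASTA parsing normalises case and preserves record order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgt"), f)
  rec <- read_fasta(f, "nucleotide")
  expect_equal(rec$sequences, "ACGT")
  expect_equal(rec$genome_id, sub("\\.fa$", "", basename(f)))

  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "GGGG"), f2)
  expect_equal(read_fasta(f2)$sequences, c("ACGT", "GGGG"))
})

test_that("gzip-compressed FASTA parses identically to the plain file", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGTACGT", ">b", "TTTTGGGG"), f)
  fgz <- paste0(f, ".gz")
  con <- gzfile(fgz, "wb")
  writeLines(readLines(f), con)
  close(con)
  a <- read_fasta(f)
  b <- read_fasta(fgz)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$genome_id, b$genome_id)  # .gz stripped from the stem
})

test_that("multi-line wrapping and CRLF line endings do not change the parse", {
  f1 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGTACGTACGT"), f1)
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGTA", "CGTAC", "GT"), f2)
  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGTACGTACGT"), f3, sep = "\r\n")
  expect_identical(read_fasta(f1)$sequences, read_fasta(f2)$sequences)
  expect_identical(read_fasta(f1)$sequences, read_fasta(f3)$sequences)
})

test_that("round trip through write_fasta reproduces sequences exactly", {
  rec <- genome_record("x", c("ACGTNNRYACGT", "TTGA"), "nucleotide")
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(rec, f, width = 5L)
  back <- read_fasta(f, "nucleotide", genome_id = "x")
  expect_identical(back$sequences, rec$sequences)
})

test_that("amino-acid input strips stop codons and validates residues", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "mkvl*", ">p2", "ACDEFX"), f)
  rec <- read_fasta(f, "aminoacid")
  expect_equal(rec$sequences, c("MKVL", "ACDEFX"))
  expect_equal(rec$alphabet, "aminoacid")

  f2 <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p", "ACDEJ"), f2)  # J is not a canonical residue
  expect_error(read_fasta(f2, "aminoacid"), "outside")
  expect_warning(rec2 <- read_fasta(f2, "aminoacid", strict = FALSE), "masking")
  expect_equal(rec2$sequences, "ACDEX")
})

test_that("missing, empty and malformed inputs raise errors", {
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "no such file")
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">bad", "ACGQ"), f2)
  expect_error(read_fasta(f2, "nucleotide"), "outside")
})
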