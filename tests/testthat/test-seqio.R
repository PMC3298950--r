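test_that("alignment container enforces ploidy and alphabet invariants", {
  # identity case: 4 records, 2 diploid males, class A
  a <- aln_from_strings(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC"))
  expect_s3_class(a, "locus_alignment")
  expect_equal(nrow(a$seqs), 4)
  expect_equal(a$L, 10)

  # Z locus with a two-haplotype female is rejected
  meta <- flat_meta(4)
  meta$sex <- c("female", "female", "male", "male")
  expect_error(locus_alignment("z1", "Z", matrix("A", 4, 5), meta),
               "female")
  # unknown chromosome class
  expect_error(locus_alignment("x", "W", matrix("A", 4, 5), flat_meta(4)),
               "chrom_class")
  # ambiguity codes other than N are rejected
  expect_error(aln_from_strings(c("ACRT", "ACGT", "ACGT", "ACGT")),
               "disallowed")
  # N and gaps are fine
  expect_silent(aln_from_strings(c("AC-T", "ACNT", "ACGT", "ACGT")))
})

test_that("FASTA + metadata round-trip preserves everything", {
  ds <- simulate_dataset(single_population_design(n_ind = 15L, n_female = 0L,
                                                  loci = data.frame(
                                                    locus = "l1", chrom_class = "A",
                                                    length = 437L)),
                         seed = 101)
  a <- ds$alignments[[1]]
  expect_equal(nrow(a$seqs), 30)

  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  b <- read_locus(file.path(dir, "l1.fasta"),
                  file.path(dir, "samples.tsv"), file.path(dir, "loci.tsv"))
  expect_identical(unname(a$seqs), unname(b$seqs))
  expect_identical(a$meta$individual_id, b$meta$individual_id)
  expect_identical(a$meta$sex, b$meta$sex)
  expect_identical(a$chrom_class, b$chrom_class)
  # second round trip is byte-identical at the file level
  f2 <- file.path(dir, "again.fasta")
  write_locus(b, f2)
  expect_identical(readLines(file.path(dir, "l1.fasta")), readLines(f2))

  # unresolvable ids are an error, not a silent drop
  st <- utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  st <- st[st$individual_id != "pop1_i01", ]
  expect_error(read_locus(file.path(dir, "l1.fasta"), st,
                          file.path(dir, "loci.tsv")),
               "not resolvable")
})

test_that("trimming to the shortest sequence behaves and is idempotent", {
  m1 <- flat_meta(2, "p1")
  m2 <- flat_meta(2, "p2")
  a1 <- locus_alignment("loc", "A", matrix("A", 2, 440), m1)
  a2 <- locus_alignment("loc", "A", matrix("C", 2, 437), m2)
  tr <- trim_to_common_length(list(a1, a2))
  expect_equal(tr$L, 437)
  expect_equal(nrow(tr$seqs), 4)
  # equal lengths: nothing removed
  a3 <- locus_alignment("loc", "A", matrix("G", 2, 437), flat_meta(2, "p3"))
  expect_equal(trim_to_common_length(list(a2, a3))$L, 437)
  # idempotence
  expect_equal(trim_to_common_length(list(tr))$L, tr$L)
  expect_identical(trim_to_common_length(list(tr))$seqs, tr$seqs)
  expect_error(trim_to_common_length(list()), "empty")
})

test_that("complete_sites matches a brute-force column scan and ignores order", {
  a <- aln_from_strings(c("ACGT", "ACGT", "ACGT", "ACGT"))
  expect_equal(complete_sites(a), 1:4)
  b <- aln_from_strings(c("AC-T", "ACGT", "ACGT", "ACGT"))
  expect_equal(complete_sites(b), c(1, 2, 4))

  set.seed(31)
  for (i in 1:20) {
    r <- random_alignment(n = 6, L = 40, miss_rate = 0.08)
    brute <- Filter(function(j) all(r$seqs[, j] %in% c("A", "C", "G", "T")),
                    seq_len(r$L))
    expect_equal(complete_sites(r), as.integer(brute))
    perm <- sample(nrow(r$seqs))
    r2 <- locus_alignment("rand", "A", r$seqs[perm, ], r$meta[perm, ])
    expect_equal(complete_sites(r2), complete_sites(r))
  }
})
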