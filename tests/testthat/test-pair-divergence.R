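two_pop_aln <- function(strings1, strings2, chrom_class = "A") {
  meta <- rbind(flat_meta(length(strings1), "p1"),
                flat_meta(length(strings2), "p2"))
  seqs <- do.call(rbind, strsplit(c(strings1, strings2), ""))
  locus_alignment("pairloc", chrom_class, seqs, meta)
}

test_that("site classification handles the identity and fixed-difference cases", {
  a <- two_pop_aln(c("ACGTAC", "ACGTAC", "ACCTAC", "ACCTAC"),
                   c("ACGTAC", "ACGTAC", "ACCTAC", "ACCTAC"))
  same <- classify_pair_sites(a, "p1", "p1")
  expect_equal(same$fixed, 0)
  expect_equal(same$exclusive1 + same$exclusive2, 0)
  expect_equal(same$shared, summarize_population(a, "p1")$S)

  b <- two_pop_aln(c("AAAAAA", "AAAAAA"), c("AAAAAG", "AAAAAG"))
  ps <- classify_pair_sites(b, "p1", "p2")
  expect_equal(ps$fixed, 1)
  expect_equal(ps$dxy, 1 / 6)
  expect_error(classify_pair_sites(b, "p1", "p3"), "missing|< 2")
})

test_that("classification is symmetric and matches brute force; dxy >= fixed/L", {
  set.seed(55)
  for (i in 1:15) {
    s <- matrix(sample(c("A", "G"), 8 * 20, replace = TRUE), 8, 20)
    meta <- rbind(flat_meta(4, "p1"), flat_meta(4, "p2"))
    a <- locus_alignment("x", "A", s, meta)
    got <- classify_pair_sites(a, "p1", "p2")
    ref <- brute_classify(a, "p1", "p2")
    expect_equal(c(exclusive1 = got$exclusive1, exclusive2 = got$exclusive2,
                   shared = got$shared, fixed = got$fixed), ref)
    rev <- classify_pair_sites(a, "p2", "p1")
    expect_equal(rev$exclusive1, got$exclusive2)
    expect_equal(rev$exclusive2, got$exclusive1)
    expect_equal(rev$shared, got$shared)
    expect_equal(rev$fixed, got$fixed)
    expect_equal(rev$dxy, got$dxy)
    expect_gte(got$dxy, got$fixed / got$L_surveyed)
  }
})

test_that("deep isolation yields fixed differences exceeding shared polymorphisms", {
  # split at 4 x 2N generations, no migration
  p <- im_parameters(theta1 = 3, t_split = 4)
  set.seed(7)
  wins <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    g <- simulate_genealogy(8, 8, p)
    a <- drop_mutations(g, 3, 600)
    ps <- classify_pair_sites(a, "pop1", "pop2")
    if (ps$fixed > ps$shared) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.9)
})

test_that("outgroup divergence counts sites where the outgroup allele is absent", {
  meta <- rbind(flat_meta(4, "p1"),
                data.frame(individual_id = "og", species = "out",
                           population = "out", sex = "male", role = "outgroup",
                           hap_index = 1))
  # outgroup identical
  s <- matrix("A", 5, 20)
  a <- locus_alignment("og0", "A", s, meta)
  expect_equal(outgroup_divergence(a, "p1")$K, 0)
  # outgroup differs at 10 monomorphic sites
  s2 <- s; s2[5, 1:10] <- "T"
  b <- locus_alignment("og10", "A", s2, meta)
  expect_equal(outgroup_divergence(b, "p1")$K, 10)
  # outgroup allele segregating in the sample is not divergent
  s3 <- s; s3[5, 1] <- "T"; s3[1, 1] <- "T"
  expect_equal(outgroup_divergence(locus_alignment("og1", "A", s3, meta), "p1")$K, 0)
  # zero or several outgroup haplotypes are errors
  expect_error(outgroup_divergence(aln_from_strings(rep("ACGT", 4)), "p1"),
               "outgroup")
})

test_that("mean outgroup divergence tracks the expected branch mutations", {
  # single population plus outgroup joining at T_out; E[dxy to outgroup]
  # = theta * (T_out + 1) with equal ancestral size
  p <- im_parameters(theta1 = 4)
  meta <- rbind(flat_meta(6, "p1"),
                data.frame(individual_id = "og", species = "out",
                           population = "out", sex = "male", role = "outgroup",
                           hap_index = 1))
  set.seed(12)
  reps <- 500
  kk <- numeric(reps)
  for (i in seq_len(reps)) {
    g <- simulate_genealogy(6, 0, p, outgroup = TRUE, t_outgroup = 3)
    a <- drop_mutations(g, 4, 2000, meta = meta)
    sf <- a$seqs[a$meta$role == "ingroup", , drop = FALSE]
    so <- a$seqs[a$meta$role == "outgroup", ]
    kk[i] <- mean(apply(sf, 1, function(r) sum(r != so)))
  }
  expect_lt(abs(mean(kk) - 4 * (3 + 1)) / (4 * 4), 0.10)
})

test_that("pair summary table aggregates means, SEs and the pooled Fisher test", {
  sp <- do.call(rbind, lapply(1:5, function(i) {
    a <- two_pop_aln(c("AAAAAA", "AAAAAG"), c("AAAAAA", "AAAAAA"),
                     chrom_class = if (i <= 3) "A" else "Z")
    r <- classify_pair_sites(a, "p1", "p2")
    r$locus <- paste0("l", i)
    r
  }))
  tab <- pair_summary_table(sp)
  expect_equal(nrow(tab$per_class), 2)
  # equal spectra across loci: SE = 0
  expect_equal(tab$per_class$shared_se[tab$per_class$n_loci > 1], c(0, 0))
  one <- pair_summary_table(sp[1, , drop = FALSE])
  expect_true(is.na(one$per_class$shared_se))
})

test_that("the pooled fixed:shared contrast detects faster-Z style data", {
  # Z loci split twice as deep as autosomal loci; Fisher on pooled 2x2
  set.seed(99)
  pa <- im_parameters(theta1 = 3, t_split = 0.75)
  pz <- im_parameters(theta1 = 3, t_split = 3)
  reps <- 100
  hits <- 0
  for (r in seq_len(reps)) {
    spectra <- do.call(rbind, lapply(1:8, function(l) {
      cls <- if (l <= 4) "A" else "Z"
      g <- simulate_genealogy(8, 8, if (cls == "A") pa else pz)
      a <- drop_mutations(g, 3, 500, chrom_class = cls)
      out <- classify_pair_sites(a, "pop1", "pop2")
      out$locus <- paste0("l", l)
      out
    }))
    f <- pair_summary_table(spectra)$fixed_shared_fisher
    if (!is.na(f$p) && f$p < 0.05 &&
        f$fixed_z / max(f$shared_z, 0.5) > f$fixed_a / max(f$shared_a, 0.5))
      hits <- hits + 1
  }
  expect_gt(hits / reps, 0.5)
})
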