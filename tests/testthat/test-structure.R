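test_that("distance matrix matches brute-force double loop and handles loci sums", {
  a <- aln_from_strings(c("AAAA", "AAAT", "AATT", "ATTT"))
  D <- pairwise_distance_matrix(list(a))
  expect_true(isSymmetric(unname(D)))
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D[1, 4], 3)
  # identical haplotypes: zeros
  z <- aln_from_strings(rep("ACGT", 4))
  expect_true(all(pairwise_distance_matrix(list(z)) == 0))

  set.seed(61)
  for (i in 1:8) {
    alns <- list(random_alignment(6, 20, miss_rate = 0.05),
                 random_alignment(6, 15, miss_rate = 0.05))
    got <- pairwise_distance_matrix(alns)
    expect_equal(got, brute_dist(alns), ignore_attr = TRUE)
  }
})

test_that("Phi_ST hits the boundary cases and is order-invariant", {
  m <- locus_alignment("x", "A",
    do.call(rbind, strsplit(c("AAAA", "AAAA", "GGAA", "GGAA"), "")),
    rbind(flat_meta(2, "p1"), flat_meta(2, "p2")))
  D <- pairwise_distance_matrix(list(m))
  r <- pairwise_fst(D, attr(D, "meta")$population, n_perm = 100, seed = 2)
  expect_equal(r$fst, 1)
  expect_lte(r$fst, 1)
  expect_true(r$p_perm > 0 && r$p_perm <= 1)
  # reordering haplotypes leaves the statistic unchanged
  perm <- c(3, 1, 4, 2)
  r2 <- pairwise_fst(D[perm, perm], attr(D, "meta")$population[perm],
                     n_perm = 10, seed = 2)
  expect_equal(r2$fst, r$fst)
  expect_error(pairwise_fst(D, rep("p1", 4)), "two populations")
})

test_that("panmictic samples give Phi_ST near zero with uniform permutation p", {
  p <- im_parameters(theta1 = 5)
  set.seed(14)
  fst <- numeric(100)
  for (i in 1:100) {
    g <- simulate_genealogy(16, 0, p)
    a <- drop_mutations(g, 5, 500)
    D <- pairwise_distance_matrix(list(a))
    lab <- sample(rep(c("x", "y"), each = 8))
    fst[i] <- pairwise_fst(D, lab, n_perm = 60)$fst
  }
  expect_lt(abs(mean(fst)), 0.05)
})

test_that("Z-linked differentiation exceeds autosomal under equal-depth splits", {
  # the Z and A datasets share one split time in generations; Z at 0.75 Ne
  # is deeper in coalescent units, so the pooled Z-linked Phi_ST should win
  set.seed(33)
  des <- two_population_design(n_ind = 6L, n_female = 0L, t_split = 3,
                               theta_site = 0.004)
  reps <- 200
  seeds <- sample.int(2^31 - 2, reps)
  fz <- fa <- numeric(reps)
  for (i in seq_len(reps)) {
    ds <- simulate_dataset(des, seed = seeds[i])
    fst_of <- function(cls) {
      alns <- Filter(function(a) a$chrom_class == cls, ds$alignments)
      D <- pairwise_distance_matrix(alns)
      fasterz:::.phi_decomp(D, attr(D, "meta")$population)$phi_st
    }
    fz[i] <- fst_of("Z"); fa[i] <- fst_of("A")
  }
  # Z deeper in coalescent units: expected differentiation is strictly
  # higher, and with only 5 + 6 loci per dataset the per-replicate ordering
  # still favours Z in a clear majority
  expect_gt(mean(fz - fa), 0)
  expect_lt(paired_t(fz, fa)$p, 1e-6)
  expect_gt(mean(fz > fa), 0.6)
})

test_that("four-level AMOVA satisfies its algebraic identities", {
  des <- flycatcher_design()
  des$populations$n_ind <- rep(3L, 6)
  des$populations$n_female <- c(0L, 0L, 0L, 1L, 0L, 1L)
  ds <- simulate_dataset(des, seed = 19)
  for (cls in c("Z", "A")) {
    alns <- Filter(function(a) a$chrom_class == cls, ds$alignments)
    D <- pairwise_distance_matrix(alns)
    dm <- attr(D, "meta")
    am <- amova(D, data.frame(species = dm$species, population = dm$population,
                              individual = dm$individual_id),
                n_perm = 50, seed = 4)
    expect_equal(sum(am$sigma2[1:4]), am$sigma2[5], tolerance = 1e-9)
    expect_equal(sum(am$percent[1:4]), 100, tolerance = 0.01)
    expect_equal(sum(am$df[1:4]), nrow(D) - 1)
    expect_equal(sum(am$SS[1:4]), am$SS[5], tolerance = 1e-9)
  }
})

test_that("AMOVA attributes variance to the level that generated it", {
  # populations internally monomorphic, species maximally distinct
  mk <- function(base, pop, sp) {
    s <- matrix(base, 4, 12)
    locus_alignment("l", "A", s, flat_meta(4, pop, species = sp))
  }
  a <- mk("A", "p1", "s1"); b <- mk("A", "p2", "s1")
  c2 <- mk("G", "p3", "s2"); d <- mk("G", "p4", "s2")
  seqs <- rbind(a$seqs, b$seqs, c2$seqs, d$seqs)
  meta <- rbind(a$meta, b$meta, c2$meta, d$meta)
  aln <- locus_alignment("l", "A", seqs, meta)
  D <- pairwise_distance_matrix(list(aln))
  dm <- attr(D, "meta")
  am <- amova(D, data.frame(species = dm$species, population = dm$population,
                            individual = dm$individual_id), n_perm = 0)
  expect_equal(am$percent[1], 100, tolerance = 1e-9)
  expect_equal(am$sigma2[2:4], rep(0, 3), tolerance = 1e-12)

  # two-level decomposition coincides with pairwise_fst on a two-pop design
  idx <- dm$population %in% c("p2", "p3")
  f <- pairwise_fst(D[idx, idx], dm$population[idx], n_perm = 10, seed = 1)
  dec <- fasterz:::.phi_decomp(D[idx, idx], dm$population[idx])
  expect_equal(f$fst, dec$phi_st)
  # fully monomorphic input has no variance to partition
  expect_error(pairwise_fst(matrix(0, 4, 4), c("a", "a", "b", "b"), n_perm = 5),
               "no molecular variance")
})

test_that("panmictic labels produce near-zero between-species percentages", {
  p <- im_parameters(theta1 = 6)
  set.seed(26)
  pct <- numeric(60)
  for (i in seq_len(60)) {
    g <- simulate_genealogy(24, 0, p)
    a <- drop_mutations(g, 6, 800)
    D <- pairwise_distance_matrix(list(a))
    n <- nrow(D)
    hier <- data.frame(species = rep(c("s1", "s2"), each = n / 2),
                       population = rep(c("p1", "p2", "p3", "p4"), each = n / 4),
                       individual = attr(D, "meta")$individual_id)
    am <- amova(D, hier, n_perm = 0)
    pct[i] <- am$percent[1]
  }
  expect_lt(abs(mean(pct)), 5)
})
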