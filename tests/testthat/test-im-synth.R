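test_that("pairwise coalescent expectations hold in mutational units", {
  p <- im_parameters(theta1 = 5)
  set.seed(1)
  tm <- replicate(4000, genealogy_summary(simulate_genealogy(2, 0, p))$tmrca)
  # E[TMRCA] = 1 in 2N units, i.e. theta/2 expected pairwise mutations
  expect_lt(abs(mean(tm) - 1), 0.05)
  d <- replicate(3000, {
    g <- simulate_genealogy(2, 0, p)
    a <- drop_mutations(g, 5, 2000)
    sum(a$seqs[1, ] != a$seqs[2, ])
  })
  expect_lt(abs(mean(d) - 5) / 5, 0.05)
})

test_that("degenerate limits of the IM model behave", {
  # t_split = 0 equals one panmictic population at thetaA
  p0 <- im_parameters(theta1 = 2, thetaA = 6, t_split = 0)
  set.seed(3)
  tm <- replicate(2000, genealogy_summary(simulate_genealogy(3, 3, p0))$tmrca)
  # panmictic n=6 at relative size 3: E[TMRCA] = 3 * 2 * (1 - 1/6)
  expect_lt(abs(mean(tm) - 3 * 2 * (1 - 1 / 6)) / 5, 0.05)

  # m = 0, deep split: all cross-population coalescences at t >= t_split
  p1 <- im_parameters(theta1 = 2, t_split = 3)
  for (i in 1:40) {
    g <- simulate_genealogy(4, 4, p1)
    expect_gte(tip_pair_tmrca(g, 1, 5), 3)
    expect_lt(tip_pair_tmrca(g, 1, 2), Inf)
  }

  # non-terminating configuration errors out
  bad <- im_parameters(theta1 = 2, t_split = Inf)
  expect_error(simulate_genealogy(2, 2, bad), "non-terminating")
})

test_that("migration keeps shared polymorphism alive at deep splits", {
  set.seed(13)
  reps <- 150
  shared_iso <- shared_mig <- numeric(reps)
  for (i in seq_len(reps)) {
    gi <- simulate_genealogy(8, 8, im_parameters(theta1 = 4, t_split = 3))
    gm <- simulate_genealogy(8, 8, im_parameters(theta1 = 4, t_split = 3,
                                                 m1 = 2, m2 = 2))
    shared_iso[i] <- classify_pair_sites(drop_mutations(gi, 4, 800),
                                         "pop1", "pop2")$shared
    shared_mig[i] <- classify_pair_sites(drop_mutations(gm, 4, 800),
                                         "pop1", "pop2")$shared
  }
  expect_gt(mean(shared_mig), mean(shared_iso) * 2)
})

test_that("datasets respect the sampling design and are seed-reproducible", {
  des <- single_population_design(n_ind = 10L, n_female = 4L)
  ds1 <- simulate_dataset(des, seed = 42)
  ds2 <- simulate_dataset(des, seed = 42)
  ds3 <- simulate_dataset(des, seed = 43)
  for (l in names(ds1$alignments))
    expect_identical(ds1$alignments[[l]]$seqs, ds2$alignments[[l]]$seqs)
  expect_false(identical(ds1$alignments[[1]]$seqs, ds3$alignments[[1]]$seqs))

  # Z loci: one haplotype per female, two per male; A loci: two each
  az <- ds1$alignments[["Chdz"]]
  expect_equal(nrow(az$seqs), 4 * 1 + 6 * 2)
  cnt <- table(az$meta$individual_id)
  sex <- tapply(az$meta$sex, az$meta$individual_id, `[`, 1)
  expect_true(all(cnt[sex == "female"] == 1))
  expect_true(all(cnt[sex == "male"] == 2))
  aa <- ds1$alignments[["Acly-16"]]
  expect_equal(nrow(aa$seqs), 20)

  # byte-identical FASTA under a fixed seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds1, d1); write_dataset(ds2, d2)
  f <- "Chdz.fasta"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("an outgroup haplotype is carried through the design", {
  des <- flycatcher_design()
  des$populations$n_ind <- rep(2L, 6)
  des$populations$n_female <- rep(0L, 6)
  ds <- simulate_dataset(des, seed = 5)
  a <- ds$alignments[[1]]
  expect_equal(sum(a$meta$role == "outgroup"), 1)
  expect_equal(nrow(summarize_population(a, "A-Mar")), 1)
})

test_that("unit conversions round-trip and match constructed identities", {
  # theta chosen so Ne = 250,000 at mu = 1.35e-9, L = 500
  mu <- 1.35e-9; L <- 500
  th <- 4 * 250000 * mu * L
  expect_equal(demographic_units(th, mu = mu, L = L)$Ne, 250000)
  # Z-linked: Ne = theta / (3 mu L)
  thz <- 3 * 250000 * 1.45e-9 * L
  expect_equal(demographic_units(thz, mu = 1.45e-9, L = L, h = 0.75)$Ne, 250000)

  dem <- demographic_units(th, t = 1.8, m = 0.4, mu = mu, L = L)
  back <- scaled_units(dem$Ne, dem$t_years, dem$m_per_gen, mu = mu, L = L)
  expect_equal(back$theta, th, tolerance = 1e-12)
  expect_equal(back$t, 1.8, tolerance = 1e-12)
  expect_equal(back$m, 0.4, tolerance = 1e-12)

  # demographic scales comparable to published flycatcher estimates give
  # plausible coalescent-scale values (shape check only)
  sc <- scaled_units(Ne = 250000, t_years = 1e6, mu = mu, L = 556)
  expect_gt(sc$t, 0.5); expect_lt(sc$t, 10)
  expect_error(demographic_units(1, mu = 0, L = 10), "positive")
})

test_that("neutral Z:A theta ratio sits at the 0.75 expectation (reduced run)", {
  des <- single_population_design()
  set.seed(4)
  n <- 120
  seeds <- sample.int(2^31 - 2, n)
  rz <- ra <- numeric(n)
  for (i in seq_len(n)) {
    ds <- simulate_dataset(des, seed = seeds[i])
    sm <- do.call(rbind, lapply(ds$alignments, function(a)
      summarize_population(a, "pop1")))
    rz[i] <- pooled_diversity(sm[sm$chrom_class == "Z", ])$theta_w
    ra[i] <- pooled_diversity(sm[sm$chrom_class == "A", ])$theta_w
  }
  expect_lt(abs(mean(rz) / mean(ra) - 0.75), 0.05)
})
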