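published_totals <- function() {
  utils::read.table(system.file("extdata", "flycatcher_polymorphism_totals.tsv",
                                package = "fasterz"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

test_that("polymorphic-site Fisher test reproduces published p-values", {
  tot <- published_totals()
  p <- mapply(polymorphic_site_fisher, tot$S_z, tot$L_z, tot$S_a, tot$L_a)
  # every per-population p matches the printed value to its precision
  expect_equal(signif(p, 2),
               c(0.048, 0.0013, 0.050, 0.060, 0.065, 0.0072),
               tolerance = 0.02)
  expect_equal(signif(p[1], 2), 0.048)
  expect_equal(signif(p[2], 2), 0.0013)
  # equal frequencies give p = 1; row swap leaves p unchanged
  expect_equal(polymorphic_site_fisher(10, 100, 10, 100), 1)
  expect_equal(polymorphic_site_fisher(33, 3624, 43, 2956),
               polymorphic_site_fisher(43, 2956, 33, 3624))
  expect_error(polymorphic_site_fisher(-1, 10, 1, 10), "non-negative")
  expect_error(polymorphic_site_fisher(11, 10, 1, 10), "exceed")
})

test_that("Fisher's exact test holds its size on independent-site null data", {
  set.seed(20)
  reps <- 1000
  rej <- 0
  for (i in seq_len(reps)) {
    sz <- stats::rbinom(1, 3600, 0.01)
    sa <- stats::rbinom(1, 2950, 0.01)
    if (polymorphic_site_fisher(sz, 3600, sa, 2950) <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

test_that("Z:A ratio machinery and its t-test behave", {
  mk <- function(locus, cls, S, n, L) {
    data.frame(population = "p", locus = locus, chrom_class = cls,
               n = n, L_surveyed = L, S = S, singletons = 0,
               k = S * 0.1, pi = S * 0.1 / L, theta_w = S / (harmonic_a1(n) * L),
               tajima_d = NA_real_)
  }
  # construct ratios exactly 0.75: theta_z = 0.75 * theta_a_pooled
  aS <- 20; n <- 20; La <- 1000
  a_sum <- mk("a1", "A", aS, n, La)
  th_a <- pooled_diversity(a_sum)$theta_w
  z_sum <- do.call(rbind, lapply(1:3, function(i) {
    row <- mk(paste0("z", i), "Z", 1, n, 500)
    row$theta_w <- 0.75 * th_a
    row
  }))
  rr <- za_theta_ratios(z_sum, a_sum)
  expect_equal(unname(rr$ratios), rep(0.75, 3))
  expect_equal(rr$t_stat, 0)
  expect_equal(rr$p, 1)
  expect_equal(rr$df, 2)

  # textbook one-sample t formula on heterogeneous ratios
  z2 <- z_sum
  z2$theta_w <- c(0, 0.8, 0.089) * th_a
  rr2 <- za_theta_ratios(z2, a_sum)
  x <- c(0, 0.8, 0.089)
  t_ref <- (mean(x) - 0.75) / (stats::sd(x) / sqrt(3))
  expect_equal(rr2$t_stat, t_ref)
  expect_error(za_theta_ratios(z_sum[1, ], a_sum), ">= 2")
})

test_that("Fisher's combined probability reproduces the published statistic", {
  p6 <- c(0.048, 0.0013, 0.050, 0.0072, 0.060, 0.064)
  fc <- fishers_combined(p6)
  expect_equal(round(fc$chi2, 2), 46.35)
  expect_equal(fc$df, 12)
  expect_lt(fc$p, 1e-4)
  # degenerate and invalid inputs
  expect_equal(fishers_combined(1)$chi2, 0)
  expect_equal(fishers_combined(1)$df, 2)
  expect_error(fishers_combined(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fishers_combined(c(0.5, 1.2)), "\\(0, 1\\]")
  # permutation invariance and additivity over disjoint sets
  expect_equal(fishers_combined(rev(p6))$chi2, fc$chi2)
  expect_equal(fishers_combined(p6[1:3])$chi2 + fishers_combined(p6[4:6])$chi2,
               fc$chi2)
})

test_that("paired t on the published F_ST matrix matches the printed tests", {
  fst <- utils::read.table(system.file("extdata", "flycatcher_fst_published.tsv",
                                       package = "fasterz"),
                           sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  all15 <- paired_t(fst$fst_z, fst$fst_a)
  expect_equal(all15$df, 14)
  expect_equal(all15$t, 7.05, tolerance = 0.005)
  btw <- fst[!fst$same_species, ]
  t13 <- paired_t(btw$fst_z, btw$fst_a)
  expect_equal(t13$df, 12)
  expect_equal(t13$t, 10.1, tolerance = 0.005)
  expect_error(paired_t(1:3, 1:3), "zero")
  expect_error(paired_t(1:3, 1:4), "length")
})

test_that("the battery wires the pieces together over a simulated dataset", {
  ds <- simulate_dataset(single_population_design(n_ind = 8L, n_female = 4L),
                         seed = 3)
  sm <- do.call(rbind, lapply(ds$alignments, function(a)
    summarize_population(a, "pop1")))
  bat <- za_test_battery(sm)
  expect_equal(nrow(bat$per_population), 1)
  expect_true(bat$per_population$fisher_p > 0 && bat$per_population$fisher_p <= 1)
  expect_equal(bat$combined$df, 2)
})
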