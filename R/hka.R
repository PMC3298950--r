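#' Assemble per-locus inputs for the multilocus HKA test
#'
#' Each locus contributes within-species segregating sites and a divergence
#' count.  Two modes are supported, reflecting how the divergence column can
#' be built: \emph{outgroup mode} (n2 = 1: divergence of the focal species
#' against a single outgroup haplotype, the second species contributing no
#' polymorphism compartment, relative size f fixed at 1) and
#' \emph{two-species mode} (n2 >= 2: polymorphism in both species plus the
#' mean between-species divergence).  The inheritance scalar h (1 for
#' autosomal, 0.75 for Z-linked loci) multiplies theta in every expectation.
#'
#' @param locus character vector of locus names.
#' @param n1 sample sizes in species 1.
#' @param S1 segregating sites in species 1.
#' @param D divergence counts (mean pairwise divergence; may be fractional).
#' @param n2 sample sizes in species 2 (1 = outgroup mode).
#' @param S2 segregating sites in species 2 (0 in outgroup mode).
#' @param h inheritance scalars, 1.0 or 0.75 per locus.
#' @return a validated data frame of class \code{hka_inputs}.
#' @export
hka_inputs <- function(locus, n1, S1, D, n2 = 1L, S2 = 0L, h = 1) {
  d <- data.frame(locus = as.character(locus), n1 = n1, S1 = S1, D = D,
                  n2 = n2, S2 = S2, h = h, stringsAsFactors = FALSE)
  if (any(d$n1 < 2)) stop("n1 must be >= 2 at every locus")
  if (any(d$n2 < 1)) stop("n2 must be >= 1 at every locus")
  if (any(d$S1 < 0 | d$S2 < 0 | d$D < 0)) stop("counts must be non-negative")
  if (any(d$n2 == 1 & d$S2 > 0)) stop("S2 must be 0 where n2 = 1")
  if (!all(d$h %in% c(1, 0.75))) stop("h must be 1.0 or 0.75")
  class(d) <- c("hka_inputs", class(d))
  d
}

# expectations and variances of the 1987 goodness-of-fit statistic;
# phi = theta * h per locus
.hka_x2 <- function(d, phi, T, f, two_species) {
  a1_1 <- vapply(d$n1, harmonic_a1, 0)
  a2_1 <- vapply(d$n1, harmonic_a2, 0)
  eS1 <- phi * a1_1
  vS1 <- eS1 + phi^2 * a2_1
  eD <- phi * (T + (1 + f) / 2)
  vD <- eD + (phi * (1 + f) / 2)^2
  x2 <- sum(ifelse(vS1 > 0, (d$S1 - eS1)^2 / vS1, 0)) +
        sum(ifelse(vD > 0, (d$D - eD)^2 / vD, 0))
  if (two_species) {
    a1_2 <- vapply(pmax(d$n2, 2), harmonic_a1, 0) * (d$n2 >= 2)
    a2_2 <- vapply(pmax(d$n2, 2), harmonic_a2, 0) * (d$n2 >= 2)
    eS2 <- f * phi * a1_2
    vS2 <- eS2 + (f * phi)^2 * a2_2
    x2 <- x2 + sum(ifelse(vS2 > 0, (d$S2 - eS2)^2 / vS2, 0))
  }
  x2
}

# moment solution in outgroup mode (f = 1): phi_i(T) closed-form given T,
# one monotone equation for T.  S1, D may be matrices (loci x replicates)
# for the vectorized null refit; returns list(T, phi, x2 when requested).
.hka_fit_outgroup <- function(a1_1, a2_1, S1, D, n_iter = 64L) {
  S1 <- as.matrix(S1); D <- as.matrix(D)
  tot <- S1 + D
  s1sum <- colSums(S1)
  lo <- rep(0, ncol(S1))
  hi <- rep(1, ncol(S1))
  g_hi <- .hka_g_at(hi, tot, a1_1, s1sum)
  for (i in 1:60) {
    grow <- g_hi > 0
    if (!any(grow)) break
    hi[grow] <- hi[grow] * 4
    g_hi <- .hka_g_at(hi, tot, a1_1, s1sum)
  }
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    gm <- .hka_g_at(mid, tot, a1_1, s1sum)
    up <- gm > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  T <- (lo + hi) / 2
  # clamp to 0 where even T = 0 under-predicts polymorphism
  g0 <- .hka_g_at(rep(0, ncol(S1)), tot, a1_1, s1sum)
  T[g0 <= 0] <- 0
  phi <- tot / (outer(a1_1, rep(1, length(T))) +
                matrix(T + 1, nrow(tot), length(T), byrow = TRUE))
  list(T = T, phi = phi)
}

# vectorized g(T) with per-column T
.hka_g_at <- function(T, tot, a1_1, s1sum) {
  den <- outer(a1_1, rep(1, length(T))) + matrix(T + 1, length(a1_1), length(T), byrow = TRUE)
  colSums(tot * a1_1 / den) - s1sum
}

# vectorized X2 in outgroup mode for matrices of replicates
.hka_x2_outgroup_mat <- function(a1_1, a2_1, S1, D, phi, T) {
  Tm <- matrix(T, nrow(S1), ncol(S1), byrow = TRUE)
  eS1 <- phi * a1_1
  vS1 <- eS1 + phi^2 * a2_1
  eD <- phi * (Tm + 1)
  vD <- eD + phi^2
  x1 <- (S1 - eS1)^2 / vS1; x1[vS1 == 0] <- 0
  x2 <- (D - eD)^2 / vD; x2[vD == 0] <- 0
  colSums(x1) + colSums(x2)
}

#' Fit the multilocus HKA model
#'
#' Estimates the per-locus mutation parameters theta_i, the scaled
#' divergence time T and (in two-species mode) the relative size f of
#' species 2 by solving the classical method-of-moments system: theta_i
#' follows in closed form given (T, f) from each locus's total counts, and
#' the pooled polymorphism constraints determine (T, f).  The goodness-of-fit
#' statistic X2 sums (obs - exp)^2 / var over all compartments with the
#' standard variances E + (theta h ...)^2.  Deterministic given the inputs.
#'
#' Expectations per locus (phi = theta * h): E[S1] = phi a1(n1),
#' E[S2] = f phi a1(n2), E[D] = phi (T + (1 + f)/2).
#'
#' @param inputs an \code{\link{hka_inputs}} data frame with >= 2 loci.
#' @return an object of class \code{hka_result}: list with \code{theta}
#'   (per locus), \code{phi}, \code{T}, \code{f}, \code{X2_obs},
#'   \code{two_species}, \code{inputs}.
#' @export
fit_hka <- function(inputs) {
  d <- inputs
  if (nrow(d) < 2) stop("the multilocus HKA test needs >= 2 loci")
  if (all(d$S1 + d$S2 + d$D == 0)) stop("all-zero data: nothing to fit")
  two_species <- any(d$n2 >= 2)
  a1_1 <- vapply(d$n1, harmonic_a1, 0)
  a2_1 <- vapply(d$n1, harmonic_a2, 0)

  if (!two_species) {
    sol <- .hka_fit_outgroup(a1_1, a2_1, d$S1, d$D)
    T <- sol$T[1]; f <- 1; phi <- drop(sol$phi)
  } else {
    a1_2 <- ifelse(d$n2 >= 2, vapply(pmax(d$n2, 2), harmonic_a1, 0), 0)
    tot <- d$S1 + d$S2 + d$D
    obj <- function(par) {
      T <- exp(par[1]); f <- exp(par[2])
      phi <- tot / (a1_1 + f * a1_2 + T + (1 + f) / 2)
      r1 <- sum(phi * a1_1) - sum(d$S1)
      r2 <- sum(f * phi * a1_2) - sum(d$S2)
      r1^2 + r2^2
    }
    # moment-style starting values
    f0 <- max(sum(d$S2) / max(sum(d$S1), 1e-8), 1e-3) * sum(a1_1) / max(sum(a1_2), 1e-8)
    T0 <- max(sum(d$D) / max(sum(d$S1 / a1_1), 1e-8), 1e-3)
    fit <- stats::optim(c(log(T0), log(max(f0, 1e-3))), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    T <- exp(fit$par[1]); f <- exp(fit$par[2])
    phi <- tot / (a1_1 + f * a1_2 + T + (1 + f) / 2)
  }
  structure(list(theta = stats::setNames(phi / d$h, d$locus), phi = phi,
                 T = T, f = f,
                 X2_obs = .hka_x2(d, phi, T, f, two_species),
                 two_species = two_species, inputs = d,
                 p_sim = NA_real_, n_sims = 0L),
            class = "hka_result")
}

#' @export
print.hka_result <- function(x, ...) {
  cat(sprintf("multilocus HKA fit (%s mode): %d loci\n",
              if (x$two_species) "two-species" else "outgroup", nrow(x$inputs)))
  cat(sprintf("  T = %.4g, f = %.4g, X2 = %.4g\n", x$T, x$f, x$X2_obs))
  if (x$n_sims > 0)
    cat(sprintf("  p = %.4g (%d coalescent simulations)\n", x$p_sim, x$n_sims))
  invisible(x)
}

#' Significance of the HKA statistic by neutral coalescent simulation
#'
#' Simulates \code{n_sims} neutral datasets at the fitted parameters
#' (matched sample sizes and inheritance-scaled thetas per locus), refits
#' the model to each, and reports the proportion of simulated X2 statistics
#' at least as large as the observed one.  Bit-reproducible under a fixed
#' seed.
#'
#' @param result an \code{\link{fit_hka}} result.
#' @param n_sims number of neutral simulated datasets; fewer than 100 gives
#'   a warning (poor p resolution).
#' @param seed optional integer seed.
#' @return the result with \code{p_sim}, \code{n_sims} and \code{X2_sim}
#'   filled in.
#' @export
hka_pvalue <- function(result, n_sims = 10000L, seed = NULL) {
  if (!inherits(result, "hka_result")) stop("need a fit_hka() result")
  if (n_sims < 100) warning("n_sims < 100: p-value resolution is poor")
  if (!is.null(seed)) set.seed(seed)
  d <- result$inputs
  sims <- .hka_null_counts_cpp(as.integer(n_sims), as.integer(d$n1),
                               as.integer(d$n2), result$phi,
                               result$T, result$f)
  a1_1 <- vapply(d$n1, harmonic_a1, 0)
  a2_1 <- vapply(d$n1, harmonic_a2, 0)
  if (!result$two_species) {
    ref <- .hka_fit_outgroup(a1_1, a2_1, sims$S1, sims$D)
    x2 <- .hka_x2_outgroup_mat(a1_1, a2_1, sims$S1, sims$D, ref$phi, ref$T)
  } else {
    x2 <- vapply(seq_len(n_sims), function(j) {
      dj <- d; dj$S1 <- sims$S1[, j]; dj$S2 <- sims$S2[, j]; dj$D <- sims$D[, j]
      if (all(dj$S1 + dj$S2 + dj$D == 0)) return(0)
      fj <- fit_hka(dj)
      fj$X2_obs
    }, 0)
  }
  result$p_sim <- mean(x2 >= result$X2_obs)
  result$n_sims <- as.integer(n_sims)
  result$X2_sim <- x2
  result
}

#' Build HKA inputs from alignments
#'
#' Convenience bridge from \code{\link{locus_alignment}} objects: S1 from
#' the focal population's segregating sites, D from
#' \code{\link{outgroup_divergence}} (outgroup mode) or from the mean
#' between-species divergence count (two-species mode).
#'
#' @param alignments list of \code{\link{locus_alignment}} objects carrying
#'   the focal population and either an outgroup haplotype or a second
#'   population.
#' @param population focal population label.
#' @param population2 optional second population (two-species mode).
#' @return an \code{\link{hka_inputs}} data frame.
#' @export
hka_inputs_from_alignments <- function(alignments, population, population2 = NULL) {
  rows <- lapply(alignments, function(a) {
    s1 <- summarize_population(a, population)
    h <- if (a$chrom_class == "Z") 0.75 else 1
    if (is.null(population2)) {
      # mean pairwise difference of the sample to the outgroup haplotype:
      # the statistic whose expectation is phi (T + 1), matching the null
      # simulator (the K site count systematically undershoots it at
      # shallow divergence because segregating sites are excluded)
      m <- a$meta
      og <- which(m$role == "outgroup")
      if (length(og) != 1) stop("exactly one outgroup haplotype required")
      rf <- which(m$population == population & m$role == "ingroup")
      cs <- complete_sites(a, c(rf, og))
      sf <- a$seqs[rf, cs, drop = FALSE]
      so <- a$seqs[og, cs]
      dxy_out <- mean(apply(sf, 1, function(r) sum(r != so)))
      data.frame(locus = a$locus_name, n1 = s1$n, S1 = s1$S, D = dxy_out,
                 n2 = 1L, S2 = 0L, h = h, stringsAsFactors = FALSE)
    } else {
      s2 <- summarize_population(a, population2)
      ps <- classify_pair_sites(a, population, population2)
      data.frame(locus = a$locus_name, n1 = s1$n, S1 = s1$S,
                 D = ps$dxy_count, n2 = s2$n, S2 = s2$S, h = h,
                 stringsAsFactors = FALSE)
    }
  })
  d <- do.call(rbind, rows)
  hka_inputs(d$locus, d$n1, d$S1, d$D, d$n2, d$S2, d$h)
}
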