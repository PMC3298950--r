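#' Fisher's exact test on polymorphic-site frequencies
#'
#' Two-sided Fisher's exact test of the 2x2 table contrasting the pooled
#' number of polymorphic versus monomorphic sites between the Z-linked and
#' autosomal compartments, [[S_z, L_z - S_z], [S_a, L_a - S_a]].
#' Two-sidedness follows the probability-mass convention (the p-value sums
#' all tables whose point probability does not exceed the observed one).
#'
#' @param S_z,L_z segregating sites and surveyed length, Z-linked pool.
#' @param S_a,L_a same for the autosomal pool.
#' @return the two-sided p-value.
#' @export
polymorphic_site_fisher <- function(S_z, L_z, S_a, L_a) {
  for (v in c(S_z, L_z, S_a, L_a))
    if (length(v) != 1 || is.na(v) || v < 0) stop("counts must be non-negative")
  if (S_z > L_z || S_a > L_a) stop("S cannot exceed L")
  tb <- matrix(c(S_z, L_z - S_z, S_a, L_a - S_a), 2, byrow = TRUE)
  stats::fisher.test(tb)$p.value
}

#' Z:autosome diversity ratios with a one-sample test against 0.75
#'
#' Divides each Z-linked locus's diversity (Watterson's theta by default,
#' or pi) by the pooled diversity of all autosomal loci, and tests the
#' per-locus ratios against the neutral expectation of 0.75 (Z-linked loci
#' at three quarters of the autosomal effective size under a balanced sex
#' ratio and equal mutation rates) with a two-sided one-sample t-test.
#'
#' @param z_summaries per-locus summaries (rows of
#'   \code{\link{summarize_population}}) for the Z-linked loci of one
#'   population; at least 2 rows.
#' @param a_summaries same for the autosomal loci; at least 1 row.
#' @param statistic "theta_w" or "pi".
#' @param mu0 null ratio, default 0.75.
#' @return an object of class \code{za_ratio_result}: list with
#'   \code{ratios} (named per Z locus), \code{a_pooled}, \code{statistic},
#'   \code{t_stat}, \code{df}, \code{p}.
#' @export
za_theta_ratios <- function(z_summaries, a_summaries,
                            statistic = c("theta_w", "pi"), mu0 = 0.75) {
  statistic <- match.arg(statistic)
  if (nrow(z_summaries) < 2) stop("need >= 2 Z-linked loci")
  if (nrow(a_summaries) < 1) stop("need >= 1 autosomal locus")
  pooled <- pooled_diversity(a_summaries)
  a_val <- if (statistic == "theta_w") pooled$theta_w else pooled$pi
  if (a_val == 0) stop("pooled autosomal diversity is zero; ratios undefined")
  ratios <- stats::setNames(z_summaries[[statistic]] / a_val, z_summaries$locus)
  if (stats::sd(ratios) == 0) {
    # degenerate case: all ratios identical; on the null value this is a
    # perfect agreement (t = 0, p = 1), off it the departure is infinite
    t_stat <- if (ratios[1] == mu0) 0 else sign(ratios[1] - mu0) * Inf
    df <- length(ratios) - 1L
    p <- if (ratios[1] == mu0) 1 else 0
  } else {
    tt <- stats::t.test(ratios, mu = mu0)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  structure(list(ratios = ratios, a_pooled = a_val, statistic = statistic,
                 mu0 = mu0, t_stat = t_stat, df = df, p = p),
            class = "za_ratio_result")
}

#' @export
print.za_ratio_result <- function(x, ...) {
  cat(sprintf("Z:A %s ratios (pooled autosomal %s = %.4g)\n",
              x$statistic, x$statistic, x$a_pooled))
  print(round(x$ratios, 3))
  cat(sprintf("one-sample t vs %.2f: t = %.3f, df = %d, p = %.4g\n",
              x$mu0, x$t_stat, x$df, x$p))
  invisible(x)
}

#' Fisher's combined probability test
#'
#' chi2 = -2 * sum(log(p_i)) referred to a chi-square distribution with
#' 2k degrees of freedom.
#'
#' @param pvals vector of p-values, each in (0, 1].
#' @return list with \code{chi2}, \code{df}, \code{p} and \code{inputs}.
#' @export
fishers_combined <- function(pvals) {
  if (!length(pvals) || any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("all p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), inputs = pvals)
}

#' Paired t-test
#'
#' Standard paired t on the differences x - y with n - 1 degrees of
#' freedom, two-sided.  Used to contrast per-pair F_ST between the Z-linked
#' and autosomal datasets.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_diff}.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need >= 2 pairs")
  if (all(x - y == 0)) stop("all differences are zero; t is undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' The full Z-versus-autosome test battery for a set of populations
#'
#' Runs, per population: the pooled polymorphic-site Fisher test and the
#' Z:A ratio t-test; then combines the per-population Fisher p-values with
#' Fisher's combined probability test.
#'
#' @param summaries stacked \code{\link{summarize_population}} rows covering
#'   Z and A loci for each population.
#' @param statistic ratio statistic, "theta_w" or "pi".
#' @return list with \code{per_population} (data frame with S/L pools,
#'   fisher_p, ratio t/df/p), \code{combined} (Fisher's combined test on the
#'   per-population fisher p-values).
#' @export
za_test_battery <- function(summaries, statistic = "theta_w") {
  pops <- unique(summaries$population)
  rows <- lapply(pops, function(p) {
    z <- summaries[summaries$population == p & summaries$chrom_class == "Z", ]
    a <- summaries[summaries$population == p & summaries$chrom_class == "A", ]
    if (!nrow(z) || !nrow(a)) return(NULL)
    fp <- polymorphic_site_fisher(sum(z$S), sum(z$L_surveyed),
                                  sum(a$S), sum(a$L_surveyed))
    rr <- if (nrow(z) >= 2) za_theta_ratios(z, a, statistic) else NULL
    data.frame(population = p,
               S_z = sum(z$S), L_z = sum(z$L_surveyed),
               S_a = sum(a$S), L_a = sum(a$L_surveyed),
               fisher_p = fp,
               mean_ratio = if (is.null(rr)) NA_real_ else mean(rr$ratios),
               ratio_t = if (is.null(rr)) NA_real_ else rr$t_stat,
               ratio_df = if (is.null(rr)) NA_integer_ else rr$df,
               ratio_p = if (is.null(rr)) NA_real_ else rr$p,
               stringsAsFactors = FALSE)
  })
  per_pop <- do.call(rbind, rows)
  combined <- if (!is.null(per_pop) && nrow(per_pop))
    fishers_combined(per_pop$fisher_p) else NULL
  list(per_population = per_pop, combined = combined)
}
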