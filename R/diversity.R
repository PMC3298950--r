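#' Tajima's D normalizing coefficients
#'
#' The standard coefficients a1, a2, b1, b2, c1, c2, e1, e2, all functions
#' of the sample size only, used to normalize the difference between the
#' pairwise-difference and segregating-sites estimators of theta.
#'
#' @param n number of sequences, n >= 4.
#' @return named list with components a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_coefficients <- function(n) {
  if (n < 4) stop("Tajima's D requires n >= 4")
  a1 <- harmonic_a1(n); a2 <- harmonic_a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Watterson's estimator of theta per site
#'
#' theta_W = S / (a1(n) * L): the population mutation rate estimated from
#' the number of segregating sites in a sample of n sequences surveyed over
#' L complete sites.
#'
#' @param S number of segregating sites.
#' @param n number of sequences (>= 2).
#' @param L number of sites surveyed (> 0).
#' @return per-site theta estimate.
#' @export
watterson_theta <- function(S, n, L) {
  S <- .check_count(S, "S")
  if (n < 2) stop("Watterson's estimator requires n >= 2")
  if (L <= 0) stop("L must be positive")
  S / (harmonic_a1(n) * L)
}

#' Allele counts at segregating sites
#'
#' Scans the complete sites of one population's haplotypes and returns the
#' allele counts at every segregating column (biallelic and multiallelic
#' sites are both reported).
#'
#' @param alignment a \code{\link{locus_alignment}}.
#' @param population population label.
#' @return list with components \code{site} (integer column indices) and
#'   \code{counts} (list of named allele-count vectors), plus
#'   \code{n} haplotypes and \code{sites_surveyed}.
#' @export
site_spectrum <- function(alignment, population) {
  rows <- which(alignment$meta$population == population &
                alignment$meta$role == "ingroup")
  if (!length(rows)) stop("population '", population, "' absent from alignment")
  if (length(rows) < 2) stop("need >= 2 haplotypes in population '", population, "'")
  cs <- complete_sites(alignment, rows)
  s <- alignment$seqs[rows, cs, drop = FALSE]
  seg <- which(colSums(s != s[rep(1, nrow(s)), , drop = FALSE]) > 0)
  counts <- lapply(seg, function(j) {
    tb <- table(s[, j])
    stats::setNames(as.integer(tb), names(tb))
  })
  list(site = cs[seg], counts = counts, n = length(rows), sites_surveyed = length(cs))
}

# mean pairwise differences and pi from an allele-count spectrum
.k_from_spectrum <- function(spec) {
  n <- spec$n
  if (!length(spec$counts)) return(0)
  sum(vapply(spec$counts, function(cn) 1 - sum(cn * (cn - 1)) / (n * (n - 1)), 0))
}

#' Nucleotide diversity
#'
#' k is the mean number of pairwise differences over all n(n-1)/2 haplotype
#' pairs of the population restricted to complete sites, and pi = k /
#' L_surveyed is the per-site nucleotide diversity.  Any allele mismatch
#' counts one difference per site, so multiallelic sites are handled the
#' same way as biallelic ones.
#'
#' @inheritParams site_spectrum
#' @return list with components \code{k}, \code{pi} and \code{L_surveyed}.
#' @export
nucleotide_diversity <- function(alignment, population) {
  spec <- site_spectrum(alignment, population)
  k <- .k_from_spectrum(spec)
  if (spec$sites_surveyed == 0) stop("no complete sites to survey")
  list(k = k, pi = k / spec$sites_surveyed, L_surveyed = spec$sites_surveyed)
}

#' Tajima's D
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1)), the normalized difference
#' between the pairwise-difference and segregating-sites views of the
#' frequency spectrum.  Undefined (NA) when S = 0, which report writers
#' render as a dash.
#'
#' @param S number of segregating sites.
#' @param k mean pairwise differences (absolute, per sequence pair).
#' @param n number of sequences (>= 4).
#' @return numeric D, or NA_real_ when S = 0.
#' @export
tajimas_d <- function(S, k, n) {
  S <- .check_count(S, "S")
  if (n < 4) stop("Tajima's D requires n >= 4")
  if (S == 0) return(NA_real_)
  co <- tajima_coefficients(n)
  (k - S / co$a1) / sqrt(co$e1 * S + co$e2 * S * (S - 1))
}

#' Per-population, per-locus polymorphism summary
#'
#' Assembles sample size, surveyed length, segregating sites, singleton
#' sites (folded definition: exactly one haplotype differs from all
#' others), mean pairwise differences, pi, Watterson's theta and Tajima's D,
#' all computed on one common complete-site set.
#'
#' @inheritParams site_spectrum
#' @return a one-row data frame of class \code{polymorphism_summary} with
#'   columns population, locus, chrom_class, n, L_surveyed, S, singletons,
#'   k, pi, theta_w, tajima_d.
#' @export
summarize_population <- function(alignment, population) {
  spec <- site_spectrum(alignment, population)
  n <- spec$n
  S <- length(spec$site)
  singletons <- sum(vapply(spec$counts, function(cn) (n - max(cn)) == 1, NA))
  k <- .k_from_spectrum(spec)
  L <- spec$sites_surveyed
  out <- data.frame(population = population,
                    locus = alignment$locus_name,
                    chrom_class = alignment$chrom_class,
                    n = n, L_surveyed = L, S = S, singletons = singletons,
                    k = k,
                    pi = if (L > 0) k / L else NA_real_,
                    theta_w = if (L > 0) watterson_theta(S, n, L) else NA_real_,
                    tajima_d = if (n >= 4) tajimas_d(S, k, n) else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("polymorphism_summary", class(out))
  out
}

#' Pooled Watterson's theta across loci
#'
#' Pools complete sites across loci: theta_pooled = sum(S_i) /
#' sum(a1(n_i) * L_i), which reduces to S_total / (a1(n) * L_total) when the
#' sample size is shared.  Also returns the length-weighted pooled pi.
#'
#' @param summaries data frame of \code{\link{summarize_population}} rows.
#' @return list with \code{theta_w}, \code{pi}, \code{S}, \code{L}.
#' @export
pooled_diversity <- function(summaries) {
  if (!nrow(summaries)) stop("no summaries to pool")
  denom <- sum(vapply(summaries$n, harmonic_a1, 0) * summaries$L_surveyed)
  list(theta_w = sum(summaries$S) / denom,
       pi = sum(summaries$pi * summaries$L_surveyed) / sum(summaries$L_surveyed),
       S = sum(summaries$S), L = sum(summaries$L_surveyed))
}

#' Polymorphism report table
#'
#' Binds per-population summaries into the standard report layout
#' (population, n, L, S, s, pi, theta_w, D) with pi and theta rounded to 4
#' decimals and D to 3; undefined D is rendered as "-".
#'
#' @param summaries data frame of \code{\link{summarize_population}} rows.
#' @param path optional TSV output path.
#' @return the formatted data frame, invisibly if written.
#' @export
polymorphism_table <- function(summaries, path = NULL) {
  tab <- data.frame(locus = summaries$locus,
                    population = summaries$population,
                    chrom_class = summaries$chrom_class,
                    n = summaries$n,
                    L = summaries$L_surveyed,
                    S = summaries$S,
                    s = summaries$singletons,
                    pi = sprintf("%.4f", summaries$pi),
                    theta_w = sprintf("%.4f", summaries$theta_w),
                    tajima_d = ifelse(is.na(summaries$tajima_d), "-",
                                      sprintf("%.3f", summaries$tajima_d)),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) { .write_tsv(tab, path); return(invisible(tab)) }
  tab
}
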