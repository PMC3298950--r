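#' Classify sites between two populations or species
#'
#' On the joint complete-site set (columns fully resolved in both samples),
#' every segregating or differentiated site is assigned exactly one
#' category: polymorphic in both samples (shared polymorphism), polymorphic
#' in exactly one (exclusive to that one; this includes the case where the
#' other sample is monomorphic for an allele absent from the first), or
#' monomorphic in each for different alleles (fixed difference).  The mean
#' between-sample pairwise divergence dxy shares the same denominator.
#'
#' @param alignment a \code{\link{locus_alignment}} containing both samples.
#' @param pop1,pop2 population labels.
#' @return an object of class \code{pair_spectrum}: a one-row data frame
#'   with pop1, pop2, locus, chrom_class, exclusive1, exclusive2, shared,
#'   fixed, dxy (per site), dxy_count (absolute) and L_surveyed.
#' @export
classify_pair_sites <- function(alignment, pop1, pop2) {
  meta <- alignment$meta
  r1 <- which(meta$population == pop1 & meta$role == "ingroup")
  r2 <- which(meta$population == pop2 & meta$role == "ingroup")
  if (length(r1) < 2) stop("population '", pop1, "' missing or has < 2 haplotypes")
  if (length(r2) < 2) stop("population '", pop2, "' missing or has < 2 haplotypes")
  cs <- complete_sites(alignment, c(r1, r2))
  s1 <- alignment$seqs[r1, cs, drop = FALSE]
  s2 <- alignment$seqs[r2, cs, drop = FALSE]
  n1 <- nrow(s1); n2 <- nrow(s2)

  poly1 <- colSums(s1 != s1[rep(1, n1), , drop = FALSE]) > 0
  poly2 <- colSums(s2 != s2[rep(1, n2), , drop = FALSE]) > 0
  shared <- sum(poly1 & poly2)
  excl1 <- sum(poly1 & !poly2)
  excl2 <- sum(!poly1 & poly2)
  fixed <- sum(!poly1 & !poly2 & s1[1, ] != s2[1, ])

  # dxy: per-site sum over alleles of p1_a * (1 - p2_a)
  dxy_count <- 0
  for (b in c("A", "C", "G", "T")) {
    c1 <- colSums(s1 == b); c2 <- colSums(s2 == b)
    dxy_count <- dxy_count + sum(c1 * (n2 - c2)) / (n1 * n2)
  }
  L <- length(cs)
  out <- data.frame(pop1 = pop1, pop2 = pop2,
                    locus = alignment$locus_name,
                    chrom_class = alignment$chrom_class,
                    exclusive1 = excl1, exclusive2 = excl2,
                    shared = shared, fixed = fixed,
                    dxy_count = dxy_count,
                    dxy = if (L > 0) dxy_count / L else NA_real_,
                    L_surveyed = L, stringsAsFactors = FALSE)
  class(out) <- c("pair_spectrum", class(out))
  out
}

#' Divergent sites between a population and the outgroup
#'
#' K counts the joint complete sites at which the single outgroup haplotype
#' carries an allele absent from the focal population sample (sites where
#' the outgroup allele also segregates in the sample are not counted).
#'
#' @param alignment a \code{\link{locus_alignment}} with exactly one
#'   outgroup haplotype.
#' @param population focal population label.
#' @param outgroup_id optional individual id of the outgroup (needed only
#'   if several outgroup individuals are present, which is an error here).
#' @return a one-row data frame with population, locus, K and L_surveyed.
#' @export
outgroup_divergence <- function(alignment, population, outgroup_id = NULL) {
  meta <- alignment$meta
  og <- which(meta$role == "outgroup")
  if (!is.null(outgroup_id)) og <- og[meta$individual_id[og] == outgroup_id]
  if (length(og) != 1)
    stop("exactly one outgroup haplotype required, found ", length(og))
  rf <- which(meta$population == population & meta$role == "ingroup")
  if (!length(rf)) stop("population '", population, "' absent from alignment")
  cs <- complete_sites(alignment, c(rf, og))
  sf <- alignment$seqs[rf, cs, drop = FALSE]
  so <- alignment$seqs[og, cs]
  # outgroup allele present in the focal sample?
  hit <- colSums(sf == matrix(so, nrow(sf), length(cs), byrow = TRUE)) > 0
  data.frame(population = population, locus = alignment$locus_name,
             K = sum(!hit), L_surveyed = length(cs), stringsAsFactors = FALSE)
}

#' Mean and standard error of shared/fixed counts across loci
#'
#' Summarizes a set of per-locus pair spectra per species pair and
#' chromosome class: mean and standard error of the shared-polymorphism and
#' fixed-difference counts across loci, plus the pooled fixed:shared 2x2
#' contingency test (Fisher's exact, two-sided) contrasting the Z-linked and
#' autosomal compartments of each pair.
#'
#' @param spectra data frame of stacked \code{\link{classify_pair_sites}}
#'   rows (one per locus per pair).
#' @return list with \code{per_class} (pair x chromosome class means and
#'   SEs; SE is NA with a single locus) and \code{fixed_shared_fisher}
#'   (pooled counts and p-value per pair, rows only for pairs observed in
#'   both classes).
#' @export
pair_summary_table <- function(spectra) {
  if (!nrow(spectra)) stop("no spectra supplied")
  pair <- paste(spectra$pop1, spectra$pop2, sep = ":")
  keyv <- paste(pair, spectra$chrom_class)
  agg <- function(x, f) tapply(x, keyv, f)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  keys <- sort(unique(keyv))
  per_class <- data.frame(
    pair = sub(" [AZ]$", "", keys),
    chrom_class = sub("^.* ", "", keys),
    n_loci = as.integer(agg(spectra$shared, length)[keys]),
    shared_mean = as.numeric(agg(spectra$shared, mean)[keys]),
    shared_se = as.numeric(agg(spectra$shared, se)[keys]),
    fixed_mean = as.numeric(agg(spectra$fixed, mean)[keys]),
    fixed_se = as.numeric(agg(spectra$fixed, se)[keys]),
    shared_total = as.integer(agg(spectra$shared, sum)[keys]),
    fixed_total = as.integer(agg(spectra$fixed, sum)[keys]),
    stringsAsFactors = FALSE, row.names = NULL)

  both <- intersect(per_class$pair[per_class$chrom_class == "Z"],
                    per_class$pair[per_class$chrom_class == "A"])
  fish <- do.call(rbind, lapply(both, function(p) {
    z <- per_class[per_class$pair == p & per_class$chrom_class == "Z", ]
    a <- per_class[per_class$pair == p & per_class$chrom_class == "A", ]
    tb <- matrix(c(z$fixed_total, z$shared_total, a$fixed_total, a$shared_total),
                 2, byrow = TRUE)
    data.frame(pair = p, fixed_z = tb[1, 1], shared_z = tb[1, 2],
               fixed_a = tb[2, 1], shared_a = tb[2, 2],
               p = if (all(rowSums(tb) > 0)) stats::fisher.test(tb)$p.value else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_class = per_class, fixed_shared_fisher = fish)
}
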