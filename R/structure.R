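#' Multi-locus pairwise-difference distance matrix
#'
#' Sums, over loci, the number of nucleotide differences between every pair
#' of haplotypes on each locus's joint complete-site set (no substitution
#' model correction, matching the standard haplotype-distance convention of
#' molecular-variance analysis).  Haplotypes are matched across loci by
#' (individual, haplotype index, population); only haplotypes present at
#' every locus are kept.
#'
#' @param alignments list of \code{\link{locus_alignment}} objects.
#' @param include_outgroup keep outgroup haplotypes? default FALSE.
#' @return a symmetric numeric matrix with zero diagonal; attribute
#'   \code{meta} holds the per-haplotype metadata (individual, population,
#'   species, sex).
#' @export
pairwise_distance_matrix <- function(alignments, include_outgroup = FALSE) {
  keys <- lapply(alignments, function(a) {
    m <- a$meta
    keep <- if (include_outgroup) rep(TRUE, nrow(m)) else m$role == "ingroup"
    paste(m$individual_id, m$hap_index, m$population, sep = "|")[keep]
  })
  common <- Reduce(intersect, keys)
  if (!length(common)) stop("no haplotypes shared across loci")
  N <- length(common)
  D <- matrix(0, N, N, dimnames = list(common, common))
  surveyed <- 0L
  for (a in alignments) {
    k <- paste(a$meta$individual_id, a$meta$hap_index, a$meta$population, sep = "|")
    rows <- match(common, k)
    cs <- complete_sites(a, rows)
    surveyed <- surveyed + length(cs)
    if (!length(cs)) next
    s <- a$seqs[rows, cs, drop = FALSE]
    same <- matrix(0, N, N)
    for (b in c("A", "C", "G", "T")) {
      ind <- s == b
      same <- same + tcrossprod(ind * 1)
    }
    D <- D + (length(cs) - same)
  }
  if (surveyed == 0L) stop("no shared complete sites across loci")
  diag(D) <- 0
  a1 <- alignments[[1]]
  k1 <- paste(a1$meta$individual_id, a1$meta$hap_index, a1$meta$population, sep = "|")
  m <- a1$meta[match(common, k1), ]
  attr(D, "meta") <- data.frame(individual_id = m$individual_id,
                                population = m$population,
                                species = m$species, sex = m$sex,
                                stringsAsFactors = FALSE)
  D
}

# two-level molecular-variance decomposition of a (squared-)distance matrix.
# Returns sigma_among, sigma_within and their ratio Phi_ST.
.phi_decomp <- function(D, labels) {
  N <- nrow(D)
  pops <- unique(labels)
  P <- length(pops)
  ss_total <- sum(D) / (2 * N)
  ss_within <- 0
  np <- numeric(P)
  for (i in seq_len(P)) {
    idx <- labels == pops[i]
    np[i] <- sum(idx)
    ss_within <- ss_within + sum(D[idx, idx]) / (2 * np[i])
  }
  ss_among <- ss_total - ss_within
  ms_within <- ss_within / (N - P)
  ms_among <- ss_among / (P - 1)
  n0 <- (N - sum(np^2) / N) / (P - 1)
  sigma_w <- ms_within
  sigma_a <- (ms_among - ms_within) / n0
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       phi_st = sigma_a / (sigma_a + sigma_w),
       ss = c(among = ss_among, within = ss_within, total = ss_total))
}

#' Pairwise Phi_ST with a permutation test
#'
#' Distance-based F_ST (Phi_ST) between two population samples, from the
#' two-level molecular-variance decomposition of the pairwise-difference
#' matrix.  The null distribution is obtained by permuting haplotypes
#' between the populations under the hypothesis of no differentiation; the
#' p-value is the proportion of permuted statistics greater than or equal
#' to the observed one, with the (count + 1)/(n_perm + 1) correction.
#'
#' @param dist distance matrix (e.g. \code{\link{pairwise_distance_matrix}}).
#' @param labels population label per haplotype (rows of \code{dist});
#'   exactly two populations, each with >= 2 haplotypes.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return an object of class \code{fst_result}: list with \code{fst},
#'   \code{p_perm}, \code{n_perm}, \code{sigma}.
#' @export
pairwise_fst <- function(dist, labels, n_perm = 10000L, seed = NULL) {
  labels <- as.character(labels)
  if (length(labels) != nrow(dist)) stop("labels must match the matrix rows")
  if (length(unique(labels)) != 2) stop("exactly two populations required")
  if (any(table(labels) < 2)) stop("each population needs >= 2 haplotypes")
  if (!is.null(seed)) set.seed(seed)
  obs <- .phi_decomp(dist, labels)
  if (!is.finite(obs$phi_st))
    stop("no molecular variance among these haplotypes; Phi_ST undefined")
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(labels)
    if (.phi_decomp(dist, perm)$phi_st >= obs$phi_st) cnt <- cnt + 1L
  }
  structure(list(fst = obs$phi_st,
                 p_perm = (cnt + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm),
                 sigma = c(among = obs$sigma_a, within = obs$sigma_w)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Phi_ST = %.4f (permutation p = %.4g, %d permutations)\n",
              x$fst, x$p_perm, x$n_perm))
  invisible(x)
}

# sum over groups of within-group distance sums / group size
.ss_within <- function(D, groups) {
  u <- unique(groups)
  s <- 0
  for (g in u) {
    idx <- groups == g
    s <- s + sum(D[idx, idx]) / (2 * sum(idx))
  }
  s
}

.amova_components <- function(D, species, population, individual) {
  N <- nrow(D)
  G <- length(unique(species))
  P <- length(unique(population))
  I <- length(unique(individual))
  ss_tot <- sum(D) / (2 * N)
  ss_wsp <- .ss_within(D, species)
  ss_wpop <- .ss_within(D, population)
  ss_wind <- .ss_within(D, individual)
  SS <- c(ss_tot - ss_wsp, ss_wsp - ss_wpop, ss_wpop - ss_wind, ss_wind)
  df <- c(G - 1, P - G, I - P, N - I)

  tfun <- function(child, parent) {
    nc <- tapply(rep(1, N), child, sum)
    pa <- tapply(parent, child, function(x) x[1])
    np <- tapply(rep(1, N), parent, sum)
    sum(tapply(nc^2, pa, sum) / np[names(tapply(nc^2, pa, sum))])
  }
  tot <- rep("all", N)
  t_ind_pop <- tfun(individual, population)
  t_ind_sp <- tfun(individual, species)
  t_ind_tot <- tfun(individual, tot)
  t_pop_sp <- tfun(population, species)
  t_pop_tot <- tfun(population, tot)
  t_sp_tot <- tfun(species, tot)

  # E[SS] coefficient matrix on (sigma_a, sigma_b, sigma_c, sigma_w),
  # solved bottom-up
  sigma_w <- SS[4] / df[4]
  sigma_c <- (SS[3] - df[3] * sigma_w) / (N - t_ind_pop)
  sigma_b <- (SS[2] - df[2] * sigma_w - (t_ind_pop - t_ind_sp) * sigma_c) /
    (N - t_pop_sp)
  sigma_a <- (SS[1] - df[1] * sigma_w - (t_ind_sp - t_ind_tot) * sigma_c -
                (t_pop_sp - t_pop_tot) * sigma_b) / (N - t_sp_tot)
  list(SS = SS, df = df,
       sigma = c(between_species = sigma_a,
                 among_populations_within_species = sigma_b,
                 among_individuals_within_populations = sigma_c,
                 within_individuals = sigma_w))
}

#' Four-level analysis of molecular variance
#'
#' Partitions the molecular variance of a haplotype pairwise-difference
#' matrix into four nested levels: between species, among populations
#' within species, among individuals within populations, and within
#' individuals.  Variance components follow the nested expected-sums-of-
#' squares system for unbalanced designs; negative components are reported
#' as computed (not truncated) and percentages are taken on the signed
#' components, whose sum equals the total variance exactly.
#'
#' Permutation p-values use the standard stratified schemes: whole
#' populations permuted among species (between-species level), individuals
#' permuted among populations within species, haplotypes permuted among
#' individuals within populations, and haplotypes permuted across the whole
#' sample for the within-individual level (lower tail: structure shows as a
#' deficit of within-individual variance).
#'
#' @param dist distance matrix with one row per haplotype.
#' @param hierarchy data frame with columns \code{species},
#'   \code{population}, \code{individual} (one row per haplotype).
#' @param n_perm permutations per level (0 to skip tests).
#' @param seed optional integer seed.
#' @return an object of class \code{amova_result}: a data frame with
#'   source, df, SS, sigma2, percent and p_perm rows plus a Total row.
#' @export
amova <- function(dist, hierarchy, n_perm = 1000L, seed = NULL) {
  need <- c("species", "population", "individual")
  if (!all(need %in% names(hierarchy))) stop("hierarchy needs species/population/individual")
  if (nrow(hierarchy) != nrow(dist)) stop("hierarchy must match the matrix rows")
  sp <- as.character(hierarchy$species)
  po <- paste(sp, hierarchy$population, sep = "/")
  id <- paste(po, hierarchy$individual, sep = "/")
  if (length(unique(sp)) < 2) stop("need >= 2 species")
  if (length(unique(po)) <= length(unique(sp)))
    stop("degenerate hierarchy: populations do not subdivide species")
  if (!is.null(seed)) set.seed(seed)
  obs <- .amova_components(dist, sp, po, id)

  pvals <- rep(NA_real_, 4)
  if (n_perm > 0) {
    cnt <- c(0L, 0L, 0L, 0L)
    pops <- unique(po)
    sp_of_pop <- tapply(sp, po, function(x) x[1])[pops]
    ind_rows <- split(seq_along(id), id)
    pop_of_ind <- tapply(po, id, function(x) x[1])[names(ind_rows)]
    for (r in seq_len(n_perm)) {
      # (a) permute populations among species
      sp_perm_of_pop <- sample(as.character(sp_of_pop))
      sp_a <- sp_perm_of_pop[match(po, pops)]
      ca <- .amova_components(dist, sp_a, po, id)
      if (ca$sigma[1] >= obs$sigma[1]) cnt[1] <- cnt[1] + 1L
      # (b) permute individuals among populations within species
      po_b <- po
      for (s in unique(sp)) {
        inds <- names(ind_rows)[as.character(tapply(sp, id, function(x) x[1])[names(ind_rows)]) == s]
        newpop <- sample(as.character(pop_of_ind[inds]))
        for (j in seq_along(inds)) po_b[ind_rows[[inds[j]]]] <- newpop[j]
      }
      cb <- .amova_components(dist, sp, po_b, id)
      if (cb$sigma[2] >= obs$sigma[2]) cnt[2] <- cnt[2] + 1L
      # (c) permute haplotypes among individuals within populations
      id_c <- id
      for (p in pops) {
        rows <- which(po == p)
        id_c[rows] <- sample(id_c[rows])
      }
      cc <- .amova_components(dist, sp, po, id_c)
      if (cc$sigma[3] >= obs$sigma[3]) cnt[3] <- cnt[3] + 1L
      # (d) permute haplotypes across the whole sample
      ord <- sample(length(id))
      cd <- .amova_components(dist, sp[ord], po[ord], id[ord])
      if (cd$sigma[4] <= obs$sigma[4]) cnt[4] <- cnt[4] + 1L
    }
    pvals <- (cnt + 1) / (n_perm + 1)
  }

  total <- sum(obs$sigma)
  out <- data.frame(
    source = c("Between species", "Among populations within species",
               "Among individuals within populations", "Within individuals",
               "Total"),
    df = c(obs$df, sum(obs$df)),
    SS = c(obs$SS, sum(obs$SS)),
    sigma2 = c(unname(obs$sigma), total),
    percent = c(unname(obs$sigma) / total * 100, 100),
    p_perm = c(pvals, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("amova_result", class(out))
  out
}

#' Lower-triangular F_ST matrix report
#'
#' Computes \code{\link{pairwise_fst}} for every population pair of a
#' distance matrix and formats the results as a lower-triangular matrix
#' (the standard layout of pairwise differentiation tables).
#'
#' @param dist distance matrix with attribute \code{meta} (or supply
#'   \code{labels}).
#' @param labels population per haplotype; default taken from the matrix
#'   metadata.
#' @param n_perm,seed passed to \code{\link{pairwise_fst}}.
#' @return list with \code{fst} and \code{p} matrices (lower triangle
#'   filled) and the long-format data frame \code{pairs}.
#' @export
fst_matrix <- function(dist, labels = NULL, n_perm = 1000L, seed = NULL) {
  if (is.null(labels)) labels <- attr(dist, "meta")$population
  pops <- unique(labels)
  k <- length(pops)
  fst <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pm <- fst
  rows <- list()
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    idx <- labels %in% pops[c(i, j)]
    r <- pairwise_fst(dist[idx, idx], labels[idx], n_perm = n_perm)
    fst[j, i] <- r$fst
    pm[j, i] <- r$p_perm
    rows[[length(rows) + 1]] <- data.frame(pop1 = pops[i], pop2 = pops[j],
                                           fst = r$fst, p_perm = r$p_perm,
                                           stringsAsFactors = FALSE)
  }
  diag(fst) <- 0
  list(fst = fst, p = pm, pairs = do.call(rbind, rows))
}
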