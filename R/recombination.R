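#' Hudson-Kaplan minimum number of recombination events
#'
#' Applies the four-gamete test to every pair of biallelic complete sites:
#' a pair at which all four gametes occur is incompatible with a single
#' genealogy and implies at least one recombination event between the two
#' sites.  R_M is the size of a maximum set of non-overlapping incompatible
#' intervals (greedy scan by right endpoint, which is optimal for interval
#' scheduling).  A greedy site-removal set (repeatedly removing the site
#' involved in the most incompatible pairs) is also computed, for use by
#' \code{\link{filter_recombinant_sites}}.
#'
#' @param alignment a \code{\link{locus_alignment}}.
#' @param populations optional vector of population labels to pool; default
#'   all ingroup haplotypes.
#' @return an object of class \code{rm_result}: list with \code{rm},
#'   \code{incompatible_pairs} (2-column matrix of site indices),
#'   \code{removed_sites}, \code{retained_sites} and \code{scope}.
#' @export
four_gamete_rm <- function(alignment, populations = NULL) {
  meta <- alignment$meta
  rows <- which(meta$role == "ingroup" &
                  (if (is.null(populations)) TRUE else meta$population %in% populations))
  if (length(rows) < 4)
    warning("fewer than 4 haplotypes: the four-gamete test has no power")
  cs <- complete_sites(alignment, rows)
  s <- alignment$seqs[rows, cs, drop = FALSE]
  nall <- apply(s, 2, function(col) length(unique(col)))
  bi <- which(nall == 2)
  scope <- if (is.null(populations)) "all ingroup" else paste(populations, collapse = "+")
  empty <- structure(list(rm = 0L,
                          incompatible_pairs = matrix(integer(), 0, 2),
                          removed_sites = integer(),
                          retained_sites = seq_len(alignment$L),
                          scope = scope),
                     class = "rm_result")
  if (length(bi) < 2) return(empty)

  # 0/1 coding on the minor (non-first) allele
  M <- vapply(bi, function(j) as.integer(s[, j] != s[1, j]), integer(nrow(s)))
  n11 <- crossprod(M)
  n10 <- crossprod(M, 1 - M)
  n01 <- t(n10)
  n00 <- crossprod(1 - M)
  inc <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
  inc[lower.tri(inc, diag = TRUE)] <- FALSE
  if (!any(inc)) return(empty)

  idx <- which(inc, arr.ind = TRUE)
  pairs <- cbind(cs[bi[idx[, 1]]], cs[bi[idx[, 2]]])
  colnames(pairs) <- c("left", "right")

  # Hudson-Kaplan: maximum disjoint incompatible intervals, greedy by right
  # endpoint; intervals (l, r) and (l', r') are disjoint when r <= l'
  ord <- order(pairs[, 2], pairs[, 1])
  rm_count <- 0L
  last_right <- -Inf
  for (i in ord) {
    if (pairs[i, 1] >= last_right) {
      rm_count <- rm_count + 1L
      last_right <- pairs[i, 2]
    }
  }

  # greedy removal set: drop the site in the most incompatible pairs until
  # no incompatibility remains
  removed <- integer()
  live <- pairs
  while (nrow(live)) {
    tab <- sort(table(as.vector(live)), decreasing = TRUE)
    victim <- as.integer(names(tab)[1])
    removed <- c(removed, victim)
    live <- live[live[, 1] != victim & live[, 2] != victim, , drop = FALSE]
  }

  structure(list(rm = rm_count,
                 incompatible_pairs = pairs,
                 removed_sites = sort(removed),
                 retained_sites = setdiff(seq_len(alignment$L), removed),
                 scope = scope),
            class = "rm_result")
}

#' @export
print.rm_result <- function(x, ...) {
  cat(sprintf("four-gamete test (%s): R_M = %d, %d incompatible pair(s), %d site(s) flagged\n",
              x$scope, x$rm, nrow(x$incompatible_pairs), length(x$removed_sites)))
  invisible(x)
}

#' Remove sites with evidence of recombination
#'
#' Drops the greedy minimal removal set computed by
#' \code{\link{four_gamete_rm}} so that the filtered alignment passes the
#' four-gamete test (R_M = 0), as required before fitting a
#' non-recombining coalescent model.  Idempotent: filtering an already
#' clean alignment returns it unchanged.
#'
#' @param alignment the \code{\link{locus_alignment}} the result was
#'   computed on.
#' @param rm_result a \code{\link{four_gamete_rm}} result; recomputed when
#'   omitted.
#' @return the filtered \code{\link{locus_alignment}}.
#' @export
filter_recombinant_sites <- function(alignment, rm_result = NULL) {
  if (is.null(rm_result)) rm_result <- four_gamete_rm(alignment)
  if (!length(rm_result$removed_sites)) return(alignment)
  keep <- setdiff(seq_len(alignment$L), rm_result$removed_sites)
  locus_alignment(alignment$locus_name, alignment$chrom_class,
                  alignment$seqs[, keep, drop = FALSE], alignment$meta)
}

#' Per-locus recombination report
#'
#' @param alignments list of \code{\link{locus_alignment}} objects.
#' @param populations optional scope, as in \code{\link{four_gamete_rm}}.
#' @param path optional TSV output path.
#' @return data frame with locus, scope, rm, n_incompatible_pairs,
#'   n_removed_sites.
#' @export
rm_report <- function(alignments, populations = NULL, path = NULL) {
  rows <- lapply(alignments, function(a) {
    r <- four_gamete_rm(a, populations)
    data.frame(locus = a$locus_name, scope = r$scope, rm = r$rm,
               n_incompatible_pairs = nrow(r$incompatible_pairs),
               n_removed_sites = length(r$removed_sites),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) .write_tsv(out, path)
  out
}
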