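# In-code fixtures and independent brute-force oracles.

# diploid-male metadata for n haplotypes (n even) in one population
flat_meta <- function(n, population = "p1", species = population,
                      role = "ingroup") {
  data.frame(individual_id = sprintf("%s_i%02d", population, (seq_len(n) + 1) %/% 2),
             species = species, population = population,
             sex = "male", role = role,
             hap_index = 2 - seq_len(n) %% 2,
             stringsAsFactors = FALSE)
}

# alignment from a character vector of equal-length sequence strings
aln_from_strings <- function(strings, chrom_class = "A", meta = NULL,
                             locus_name = "locus1") {
  seqs <- do.call(rbind, strsplit(strings, ""))
  if (is.null(meta)) meta <- flat_meta(length(strings))
  locus_alignment(locus_name, chrom_class, seqs, meta)
}

# n identical sequences of length L carrying one biallelic site where
# `minor` haplotypes hold the alternative base (the Tajima worked examples)
single_site_alignment <- function(n, L, minor, meta = NULL) {
  seqs <- matrix("A", n, L)
  seqs[seq_len(minor), 25] <- "G"
  if (is.null(meta)) {
    if (n %% 2 == 0) meta <- flat_meta(n)
    else {  # odd n: make it Z-linked with one hemizygous female
      meta <- flat_meta(n - 1)
      meta <- rbind(meta,
                    data.frame(individual_id = "p1_f01", species = "p1",
                               population = "p1", sex = "female",
                               role = "ingroup", hap_index = 1))
    }
  }
  cls <- if (n %% 2 == 0) "A" else "Z"
  locus_alignment("single_site", cls, seqs, meta)
}

# random small alignment over A/C/G/T with optional missing characters
random_alignment <- function(n = 8, L = 30, miss_rate = 0,
                             chrom_class = "A") {
  seqs <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                        prob = c(.55, .2, .15, .1)), n, L)
  if (miss_rate > 0) {
    idx <- which(stats::runif(n * L) < miss_rate)
    seqs[idx] <- sample(c("N", "-"), length(idx), replace = TRUE)
  }
  locus_alignment("rand", chrom_class, seqs, flat_meta(n))
}

# ---- brute-force oracles (deliberately naive) ----

# mean pairwise differences by explicit double loop over complete columns
brute_k <- function(aln, population) {
  rows <- which(aln$meta$population == population & aln$meta$role == "ingroup")
  cols <- Filter(function(j) all(aln$seqs[rows, j] %in% c("A", "C", "G", "T")),
                 seq_len(aln$L))
  s <- aln$seqs[rows, cols, drop = FALSE]
  n <- nrow(s)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(s[i, ] != s[j, ]); np <- np + 1
  }
  list(k = tot / np, L = length(cols))
}

# per-site pair classification by explicit scan
brute_classify <- function(aln, pop1, pop2) {
  m <- aln$meta
  r1 <- which(m$population == pop1 & m$role == "ingroup")
  r2 <- which(m$population == pop2 & m$role == "ingroup")
  cols <- Filter(function(j) all(aln$seqs[c(r1, r2), j] %in% c("A", "C", "G", "T")),
                 seq_len(aln$L))
  out <- c(exclusive1 = 0, exclusive2 = 0, shared = 0, fixed = 0)
  for (j in cols) {
    a1 <- unique(aln$seqs[r1, j]); a2 <- unique(aln$seqs[r2, j])
    p1 <- length(a1) > 1; p2 <- length(a2) > 1
    if (p1 && p2) out["shared"] <- out["shared"] + 1
    else if (p1) out["exclusive1"] <- out["exclusive1"] + 1
    else if (p2) out["exclusive2"] <- out["exclusive2"] + 1
    else if (a1 != a2) out["fixed"] <- out["fixed"] + 1
  }
  out
}

# distance matrix by triple loop
brute_dist <- function(alns) {
  keys <- lapply(alns, function(a)
    paste(a$meta$individual_id, a$meta$hap_index, a$meta$population, sep = "|"))
  common <- Reduce(intersect, keys)
  D <- matrix(0, length(common), length(common))
  for (a in alns) {
    k <- paste(a$meta$individual_id, a$meta$hap_index, a$meta$population, sep = "|")
    rows <- match(common, k)
    cols <- Filter(function(j) all(a$seqs[rows, j] %in% c("A", "C", "G", "T")),
                   seq_len(a$L))
    for (i in seq_along(common)) for (j in seq_along(common))
      D[i, j] <- D[i, j] + sum(a$seqs[rows[i], cols] != a$seqs[rows[j], cols])
  }
  D
}

# maximum number of pairwise-disjoint intervals by exhaustive search
brute_rm <- function(pairs) {
  np <- nrow(pairs)
  if (np == 0) return(0L)
  if (np > 16) stop("brute_rm fixture too large")
  best <- 0L
  for (mask in seq_len(2^np) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    ok <- TRUE
    if (length(sel) > 1) {
      iv <- pairs[sel, , drop = FALSE]
      ord <- order(iv[, 1])
      iv <- iv[ord, , drop = FALSE]
      for (i in seq_len(nrow(iv) - 1))
        if (iv[i + 1, 1] < iv[i, 2]) { ok <- FALSE; break }
    }
    if (ok) best <- max(best, length(sel))
  }
  best
}

# MRCA time of two tips by walking parent pointers
tip_pair_tmrca <- function(g, i, j) {
  anc <- function(k) {
    path <- k
    while (!is.na(g$parent[k])) { k <- g$parent[k]; path <- c(path, k) }
    path
  }
  common <- intersect(anc(i), anc(j))
  min(g$time[common])
}
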