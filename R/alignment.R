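#' Locus alignment container
#'
#' A \code{locus_alignment} holds one locus's aligned phased haplotypes
#' together with per-haplotype sample metadata and the chromosome class of
#' the locus (autosomal \code{"A"} or Z-linked \code{"Z"}).  Sequences are
#' stored as a character matrix with one row per haplotype and one column
#' per alignment position; the only letters admitted are A, C, G, T, N and
#' the gap character \code{-} (phased haplotype data carry no ambiguity
#' codes, so IUPAC codes other than N are rejected).
#'
#' Validated invariants: all sequences share one length; at least two
#' ingroup haplotypes; on Z-linked loci every ingroup female contributes
#' exactly one haplotype (hemizygosity) and every male exactly two, while on
#' autosomal loci every ingroup individual contributes two; any outgroup
#' individual contributes exactly one haplotype.
#'
#' @param locus_name character scalar.
#' @param chrom_class "A" or "Z".
#' @param seqs character matrix (haplotypes x sites) of single upper-case
#'   characters, rownames giving haplotype ids.
#' @param meta data frame with one row per haplotype and columns
#'   \code{individual_id}, \code{species}, \code{population}, \code{sex}
#'   (male/female/unknown), \code{role} (ingroup/outgroup) and
#'   \code{hap_index}.
#' @return an object of class \code{locus_alignment}.
#' @export
locus_alignment <- function(locus_name, chrom_class, seqs, meta) {
  stopifnot(is.character(locus_name), length(locus_name) == 1)
  if (!chrom_class %in% c("A", "Z"))
    stop("unknown chrom_class '", chrom_class, "' (must be 'A' or 'Z')")
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("'seqs' must be a character matrix of single characters")
  need <- c("individual_id", "species", "population", "sex", "role", "hap_index")
  if (!all(need %in% names(meta)))
    stop("meta is missing columns: ", paste(setdiff(need, names(meta)), collapse = ", "))
  if (nrow(meta) != nrow(seqs))
    stop("meta rows (", nrow(meta), ") do not match haplotype rows (", nrow(seqs), ")")

  bad <- setdiff(unique(as.vector(seqs)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("disallowed characters in alignment (phased haplotypes admit only ",
         "A/C/G/T/N/-): ", paste(bad, collapse = " "))
  if (!all(meta$sex %in% c("male", "female", "unknown")))
    stop("sex must be male, female or unknown")
  if (!all(meta$role %in% c("ingroup", "outgroup")))
    stop("role must be ingroup or outgroup")

  ing <- meta$role == "ingroup"
  if (sum(ing) < 2) stop("need at least 2 ingroup haplotypes")

  # uniqueness of individual ids within population
  key <- paste(meta$population, meta$individual_id)
  # ploidy bookkeeping per individual
  cnt <- table(key[ing])
  sex_of <- tapply(meta$sex[ing], key[ing], function(s) unique(s)[1])
  if (chrom_class == "Z") {
    f2 <- names(cnt)[sex_of[names(cnt)] == "female" & cnt != 1]
    if (length(f2))
      stop("Z-linked locus: female individual(s) with more than one haplotype: ",
           paste(f2, collapse = ", "))
    m1 <- names(cnt)[sex_of[names(cnt)] == "male" & cnt != 2]
    if (length(m1))
      stop("Z-linked locus: male individual(s) without exactly two haplotypes: ",
           paste(m1, collapse = ", "))
  } else {
    d1 <- names(cnt)[cnt != 2]
    if (length(d1))
      stop("autosomal locus: individual(s) without exactly two haplotypes: ",
           paste(d1, collapse = ", "))
  }
  out_cnt <- table(key[!ing])
  if (length(out_cnt) && any(out_cnt != 1))
    stop("outgroup individuals must carry exactly one haplotype per locus")

  if (is.null(rownames(seqs)))
    rownames(seqs) <- paste(meta$individual_id, meta$hap_index, meta$population, sep = "|")
  structure(list(locus_name = locus_name,
                 chrom_class = chrom_class,
                 L = ncol(seqs),
                 seqs = seqs,
                 meta = meta),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus_alignment '%s' (%s-linked): %d haplotypes x %d bp, %d population(s)\n",
              x$locus_name, x$chrom_class, nrow(x$seqs), x$L,
              length(unique(x$meta$population[x$meta$role == "ingroup"]))))
  invisible(x)
}

# split "ind|hap|pop" fasta ids; strict about the three-field dialect
.parse_hap_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("FASTA record ids must follow 'individualID|hapIndex|population': ",
         paste(ids[lengths(parts) != 3], collapse = ", "))
  data.frame(individual_id = vapply(parts, `[`, "", 1),
             hap_index = as.integer(vapply(parts, `[`, "", 2)),
             population = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Read a locus alignment from FASTA plus metadata tables
#'
#' One locus per FASTA file, one record per phased haplotype, record ids in
#' the \code{individualID|hapIndex|population} dialect.  The sample table
#' (TSV with columns \code{individual_id}, \code{species},
#' \code{population}, \code{sex}, \code{role}) supplies per-individual
#' metadata and the locus table (TSV with columns \code{locus},
#' \code{chrom_class}) supplies the chromosome class.  Ids that do not
#' resolve against the sample table are an error, never silently dropped.
#'
#' @param fasta_path path to the FASTA file.
#' @param sample_table path to the sample metadata TSV, or a data frame.
#' @param locus_table path to the locus metadata TSV, or a data frame.
#' @param locus_name name of the locus; default is the FASTA base name.
#' @return a \code{\link{locus_alignment}}.
#' @export
read_locus <- function(fasta_path, sample_table, locus_table, locus_name = NULL) {
  if (is.null(locus_name))
    locus_name <- sub("\\.(fa|fasta|fas)$", "", basename(fasta_path))
  samples <- if (is.character(sample_table)) .read_tsv(sample_table) else sample_table
  loci <- if (is.character(locus_table)) .read_tsv(locus_table) else locus_table

  row <- loci[loci$locus == locus_name, , drop = FALSE]
  if (nrow(row) != 1)
    stop("locus '", locus_name, "' not found (or duplicated) in the locus table")
  chrom_class <- row$chrom_class

  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(unique(Biostrings::width(dna))) != 1)
    stop("length mismatch among FASTA records of locus '", locus_name, "'")
  ids <- .parse_hap_ids(names(dna))
  skey <- paste(samples$population, samples$individual_id)
  ikey <- paste(ids$population, ids$individual_id)
  miss <- !(ikey %in% skey)
  if (any(miss))
    stop("FASTA ids not resolvable in the sample table: ",
         paste(names(dna)[miss], collapse = ", "))
  m <- match(ikey, skey)
  meta <- data.frame(individual_id = ids$individual_id,
                     species = samples$species[m],
                     population = ids$population,
                     sex = samples$sex[m],
                     role = samples$role[m],
                     hap_index = ids$hap_index,
                     stringsAsFactors = FALSE)
  seqs <- do.call(rbind, strsplit(toupper(as.character(dna)), ""))
  rownames(seqs) <- names(dna)
  locus_alignment(locus_name, chrom_class, seqs, meta)
}

#' Write a locus alignment to FASTA
#'
#' Emits one record per haplotype with ids in the same
#' \code{individualID|hapIndex|population} dialect that \code{read_locus}
#' parses, so read -> write -> read round-trips byte-for-byte.
#'
#' @param alignment a \code{\link{locus_alignment}}.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_locus <- function(alignment, path) {
  ids <- paste(alignment$meta$individual_id, alignment$meta$hap_index,
               alignment$meta$population, sep = "|")
  dna <- Biostrings::DNAStringSet(apply(alignment$seqs, 1, paste, collapse = ""))
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write the sample and locus metadata tables
#'
#' @param alignments list of \code{\link{locus_alignment}} objects.
#' @param sample_path,locus_path output TSV paths.
#' @return invisibly, a list with the two data frames.
#' @export
write_metadata_tables <- function(alignments, sample_path, locus_path) {
  metas <- do.call(rbind, lapply(alignments, function(a)
    a$meta[c("individual_id", "species", "population", "sex", "role")]))
  samples <- unique(metas)
  loci <- data.frame(locus = vapply(alignments, `[[`, "", "locus_name"),
                     chrom_class = vapply(alignments, `[[`, "", "chrom_class"),
                     length = vapply(alignments, function(a) a$L, 0L))
  .write_tsv(samples, sample_path)
  .write_tsv(loci, locus_path)
  invisible(list(samples = samples, loci = loci))
}

#' Trim alignments of one locus to the shortest common length
#'
#' Sequences of one locus obtained from different populations may extend to
#' different lengths; all are adjusted to the length of the shortest by
#' removing trailing columns, and the haplotypes are combined into one
#' alignment.
#'
#' @param alignments non-empty list of \code{\link{locus_alignment}} objects
#'   for the same locus.
#' @return a single combined \code{\link{locus_alignment}} whose length
#'   equals the minimum input length.
#' @export
trim_to_common_length <- function(alignments) {
  if (length(alignments) == 0) stop("empty input list")
  nm <- unique(vapply(alignments, `[[`, "", "locus_name"))
  cc <- unique(vapply(alignments, `[[`, "", "chrom_class"))
  if (length(nm) != 1 || length(cc) != 1)
    stop("all inputs must be the same locus")
  Lmin <- min(vapply(alignments, function(a) a$L, 0L))
  seqs <- do.call(rbind, lapply(alignments, function(a) a$seqs[, seq_len(Lmin), drop = FALSE]))
  meta <- do.call(rbind, lapply(alignments, `[[`, "meta"))
  rownames(meta) <- NULL
  locus_alignment(nm, cc, seqs, meta)
}

#' Complete (fully resolved) site indices
#'
#' Returns the indices (1-based, as reported throughout the package) of
#' alignment columns containing only A, C, G or T across a set of
#' haplotypes.  All downstream statistics are computed on these columns
#' only, i.e. missing data are handled by complete-case deletion per site so
#' that S, pi and Watterson's theta refer to one common site set.
#'
#' @param alignment a \code{\link{locus_alignment}}.
#' @param rows optional integer/logical row subset; default is all ingroup
#'   haplotypes.
#' @return integer vector of column indices.
#' @export
complete_sites <- function(alignment, rows = NULL) {
  if (is.null(rows)) rows <- alignment$meta$role == "ingroup"
  s <- alignment$seqs[rows, , drop = FALSE]
  ok <- colSums(s == "A" | s == "C" | s == "G" | s == "T") == nrow(s)
  which(ok)
}
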