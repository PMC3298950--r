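#' Run the full Z-versus-autosome analysis pipeline
#'
#' Orchestrates every analysis stage over a set of locus alignments and
#' writes the standard report bundle: per-population polymorphism table,
#' per-pair site-classification spectra with mean/SE summaries, the Z/A
#' test battery (polymorphic-site Fisher tests, Z:A ratio t-tests, Fisher's
#' combined probability), HKA results per population, the pairwise F_ST
#' matrices and AMOVA tables for the Z-linked and autosomal datasets, and
#' the per-locus recombination report, plus a JSON manifest recording the
#' package version, seed, options and input hashes so a run can be
#' reproduced bit-identically.
#'
#' @param config list with elements: either \code{alignments} (a named list
#'   of \code{\link{locus_alignment}} objects) or \code{input_dir} (a
#'   directory of FASTA + samples.tsv + loci.tsv as written by
#'   \code{\link{write_dataset}}); \code{out_dir}; \code{seed}
#'   (mandatory: every stochastic stage derives from it); \code{n_perm}
#'   (permutations, default 1000); \code{n_sims} (HKA simulations, default
#'   1000); \code{ratio_statistic} ("pi", the default, or "theta_w").
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  if (is.null(config$seed)) stop("config$seed is mandatory")
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_perm <- if (is.null(config$n_perm)) 1000L else config$n_perm
  n_sims <- if (is.null(config$n_sims)) 1000L else config$n_sims
  ratio_stat <- if (is.null(config$ratio_statistic)) "pi" else config$ratio_statistic
  input_hashes <- NULL

  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    message(sprintf("stage %-14s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), ts, units = "secs"))))
    res
  }

  alignments <- stage("load", {
    if (!is.null(config$alignments)) config$alignments
    else {
      fa <- list.files(config$input_dir, "\\.(fa|fasta|fas)$", full.names = TRUE)
      input_hashes <<- as.list(tools::md5sum(fa))
      st <- file.path(config$input_dir, "samples.tsv")
      lt <- file.path(config$input_dir, "loci.tsv")
      stats::setNames(lapply(fa, read_locus, sample_table = st, locus_table = lt),
                      sub("\\.(fa|fasta|fas)$", "", basename(fa)))
    }
  })
  meta <- alignments[[1]]$meta
  pops <- unique(meta$population[meta$role == "ingroup"])

  summaries <- stage("polymorphism", {
    do.call(rbind, lapply(alignments, function(a) {
      ap <- unique(a$meta$population[a$meta$role == "ingroup"])
      do.call(rbind, lapply(ap, function(p) summarize_population(a, p)))
    }))
  })
  polymorphism_table(summaries, file.path(out_dir, "polymorphism.tsv"))

  spectra <- stage("pairs", {
    if (length(pops) < 2) NULL
    else {
      prs <- utils::combn(pops, 2, simplify = FALSE)
      do.call(rbind, lapply(alignments, function(a)
        do.call(rbind, lapply(prs, function(p)
          classify_pair_sites(a, p[1], p[2])))))
    }
  })
  pair_tab <- NULL
  if (!is.null(spectra)) {
    .write_tsv(spectra, file.path(out_dir, "pair_spectra.tsv"))
    pair_tab <- pair_summary_table(spectra)
    .write_tsv(pair_tab$per_class, file.path(out_dir, "pair_means.tsv"))
    if (!is.null(pair_tab$fixed_shared_fisher))
      .write_tsv(pair_tab$fixed_shared_fisher,
                 file.path(out_dir, "fixed_shared_fisher.tsv"))
  }

  za <- stage("za-tests", {
    has_z <- any(summaries$chrom_class == "Z")
    has_a <- any(summaries$chrom_class == "A")
    if (!has_z || !has_a) {
      writeLines("not applicable: need both Z-linked and autosomal loci",
                 file.path(out_dir, "za_tests.txt"))
      NULL
    } else {
      res <- za_test_battery(summaries, statistic = ratio_stat)
      .write_tsv(res$per_population, file.path(out_dir, "za_tests.tsv"))
      jsonlite::write_json(res$combined, file.path(out_dir, "za_combined.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    }
  })

  has_outgroup <- any(meta$role == "outgroup")
  hka <- stage("hka", {
    if (!has_outgroup) NULL
    else {
      res <- lapply(pops, function(p) {
        inp <- hka_inputs_from_alignments(alignments, p)
        hka_pvalue(fit_hka(inp), n_sims = n_sims, seed = config$seed)
      })
      names(res) <- pops
      tab <- do.call(rbind, lapply(pops, function(p)
        data.frame(population = p, T = res[[p]]$T, X2 = res[[p]]$X2_obs,
                   p_sim = res[[p]]$p_sim, n_sims = res[[p]]$n_sims,
                   stringsAsFactors = FALSE)))
      .write_tsv(tab, file.path(out_dir, "hka.tsv"))
      res
    }
  })

  structure_res <- stage("structure", {
    res <- list()
    for (cls in intersect(c("Z", "A"), unique(summaries$chrom_class))) {
      alns <- Filter(function(a) a$chrom_class == cls, alignments)
      D <- pairwise_distance_matrix(alns)
      dm <- attr(D, "meta")
      fm <- fst_matrix(D, dm$population, n_perm = n_perm, seed = config$seed)
      utils::write.table(round(fm$fst, 3),
                         file.path(out_dir, paste0("fst_", cls, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
      am <- if (length(unique(dm$species)) >= 2 &&
                length(unique(dm$population)) > length(unique(dm$species)))
        amova(D, data.frame(species = dm$species, population = dm$population,
                            individual = dm$individual_id),
              n_perm = n_perm, seed = config$seed)
      else NULL
      if (!is.null(am)) .write_tsv(am, file.path(out_dir, paste0("amova_", cls, ".tsv")))
      res[[cls]] <- list(fst = fm, amova = am)
    }
    res
  })

  fst_za <- if (!is.null(za) && all(c("Z", "A") %in% names(structure_res))) {
    z <- structure_res$Z$fst$pairs; a <- structure_res$A$fst$pairs
    key <- paste(z$pop1, z$pop2)
    m <- match(key, paste(a$pop1, a$pop2))
    if (!any(is.na(m)) && any(z$fst - a$fst[m] != 0)) {
      pt <- paired_t(z$fst, a$fst[m])
      jsonlite::write_json(pt, file.path(out_dir, "fst_paired_t.json"),
                           auto_unbox = TRUE, digits = NA)
      pt
    } else NULL
  } else NULL

  rm_tab <- stage("recombination",
                  rm_report(alignments, path = file.path(out_dir, "rm_report.tsv")))

  manifest <- list(
    package = "fasterz",
    version = as.character(utils::packageVersion("fasterz")),
    seed = config$seed, n_perm = n_perm, n_sims = n_sims,
    ratio_statistic = ratio_stat,
    input_hashes = input_hashes,
    n_loci = length(alignments), populations = pops,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(summaries = summaries, spectra = spectra, pair_tab = pair_tab,
                 za = za, hka = hka, structure = structure_res,
                 fst_paired_t = fst_za, rm = rm_tab, manifest = manifest))
}
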