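#' Isolation-with-migration model parameters
#'
#' Parameters of the two-population isolation-with-migration coalescent for
#' one locus.  \code{theta1}, \code{theta2} and \code{thetaA} are per-locus
#' scaled mutation rates (4 Ne mu L for autosomal loci, 3 Ne mu L for
#' Z-linked ones, i.e. 4 h Ne mu L with inheritance scalar h).  Time is
#' measured in coalescent units of 2 Ne1 generations of population 1 (whose
#' relative size is the reference); \code{t_split} is the split time on
#' that scale.  \code{m1} is the backwards-in-time rate per lineage (per
#' 2 Ne1 generations) at which a lineage currently in population 1 traces
#' back to population 2 -- equivalently the forward-time migration of genes
#' from population 2 into population 1 -- and \code{m2} is the reverse.
#' Use \code{\link{scaled_units}} / \code{\link{demographic_units}} to move
#' between this scale and demographic quantities (Ne, years, per-generation
#' migration).
#'
#' @param theta1,theta2,thetaA per-locus scaled mutation rates (>= 0,
#'   theta1 > 0).
#' @param t_split split time in units of 2 Ne1 generations (>= 0).
#' @param m1,m2 scaled migration rates (>= 0).
#' @param h inheritance scalar: 1.0 (autosomal) or 0.75 (Z-linked).
#' @param mu mutation rate, substitutions/site/year.
#' @param generation_time years per generation.
#' @return an object of class \code{im_parameters}.
#' @export
im_parameters <- function(theta1, theta2 = theta1, thetaA = theta1,
                          t_split = 0, m1 = 0, m2 = 0, h = 1,
                          mu = 1.35e-9, generation_time = 1) {
  stopifnot(theta1 > 0, theta2 >= 0, thetaA > 0, t_split >= 0,
            m1 >= 0, m2 >= 0, h %in% c(1, 0.75), mu > 0, generation_time > 0)
  structure(list(theta1 = theta1, theta2 = theta2, thetaA = thetaA,
                 t_split = t_split, m1 = m1, m2 = m2, h = h, mu = mu,
                 generation_time = generation_time),
            class = "im_parameters")
}

#' Simulate a structured-coalescent genealogy under the IM model
#'
#' Standard backwards-in-time structured coalescent: within-deme
#' coalescence at rate k(k-1)/2 per relative deme size, per-lineage
#' migration between the two demes, and at \code{t_split} all lineages
#' merge into the ancestral deme of relative size thetaA/theta1.  An
#' optional outgroup lineage is carried in its own deme and joins the
#' ancestral deme at \code{t_outgroup}.
#'
#' @param n1,n2 tip counts in populations 1 and 2 (n1 + n2 >= 2).
#' @param params an \code{\link{im_parameters}} object.
#' @param outgroup add one outgroup tip? default FALSE.
#' @param t_outgroup join time of the outgroup lineage (2 Ne1 units).
#' @return an object of class \code{im_genealogy}: list with \code{parent}
#'   (1-based, NA at the root), \code{time} (node times, tips at 0),
#'   \code{node_deme}, \code{tip_deme} and \code{n_tips}.
#' @export
simulate_genealogy <- function(n1, n2 = 0, params, outgroup = FALSE,
                               t_outgroup = NULL) {
  stopifnot(inherits(params, "im_parameters"))
  if (n1 + n2 < 2) stop("need at least 2 tips")
  r2 <- params$theta2 / params$theta1
  rA <- params$thetaA / params$theta1
  tip_deme <- c(rep(0L, n1), rep(1L, n2))
  rel <- c(1, max(r2, 1e-12), rA)
  mig <- matrix(0, 4, 4)
  mig[1, 2] <- params$m1
  mig[2, 1] <- params$m2
  mt <- c(params$t_split, params$t_split)
  mf <- c(0L, 1L); mi <- c(2L, 2L)
  if (outgroup) {
    if (is.null(t_outgroup)) stop("outgroup requested without t_outgroup")
    if (t_outgroup < params$t_split)
      stop("the outgroup must join at or after t_split")
    tip_deme <- c(tip_deme, 3L)
    mt <- c(mt, t_outgroup); mf <- c(mf, 3L); mi <- c(mi, 2L)
    rel <- c(rel, 1)
  } else mig <- mig[1:3, 1:3]
  if (params$t_split == 0) {
    # degenerate limit: a single panmictic population at thetaA
    tip_deme[tip_deme %in% c(0L, 1L)] <- 2L
  }
  # a non-finite split never happens: drop it so a zero-rate state is
  # reported as the non-terminating configuration it is
  keep <- is.finite(mt)
  mt <- mt[keep]; mf <- mf[keep]; mi <- mi[keep]
  ord <- order(mt)
  g <- .sim_genealogy_cpp(tip_deme, rel, mig, mt[ord], mf[ord], mi[ord])
  structure(list(parent = g$parent, time = g$time, node_deme = g$node_deme,
                 tip_deme = tip_deme, n_tips = g$n_tips),
            class = "im_genealogy")
}

#' Total branch length and TMRCA of a genealogy
#' @param genealogy an \code{im_genealogy}.
#' @return list with \code{tmrca} and \code{total_length}.
#' @export
genealogy_summary <- function(genealogy) {
  p <- genealogy$parent
  tm <- genealogy$time
  len <- ifelse(is.na(p), 0, tm[p] - tm)
  list(tmrca = max(tm), total_length = sum(len, na.rm = TRUE))
}

.base_set <- c("A", "C", "G", "T")

# metadata for simulator tips: consecutive pairing into diploid individuals
# (Z loci: females contribute one haplotype and are listed first)
.design_tips <- function(populations, chrom_class) {
  rows <- list()
  for (i in seq_len(nrow(populations))) {
    p <- populations[i, ]
    for (j in seq_len(p$n_ind)) {
      ind <- sprintf("%s_i%02d", p$population, j)
      female <- j <= p$n_female
      nh <- if (chrom_class == "Z" && female) 1L else 2L
      for (hp in seq_len(nh))
        rows[[length(rows) + 1]] <- data.frame(
          individual_id = ind, species = p$species, population = p$population,
          sex = if (female) "female" else "male", role = "ingroup",
          hap_index = hp, deme = i - 1L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Places Poisson(theta/2 x total branch length) mutations uniformly on the
#' branches and assigns each a unique alignment column (infinite-sites
#' model: at most two alleles per site, no back mutation).  The ancestral
#' base at every column is drawn uniformly from A/C/G/T and the derived
#' base from the remaining three; tips below a mutation's branch carry the
#' derived base.
#'
#' @param genealogy an \code{\link{im_genealogy}}.
#' @param theta per-locus scaled mutation rate of the reference population.
#' @param L locus length in bp.
#' @param meta optional haplotype metadata (as in
#'   \code{\link{locus_alignment}}); generated automatically when omitted
#'   (tips paired into diploid male individuals per deme).
#' @param locus_name,chrom_class passed to the alignment container.
#' @param on_overflow "error" or "retry" when more mutations than sites are
#'   drawn.
#' @return a \code{\link{locus_alignment}}.
#' @export
drop_mutations <- function(genealogy, theta, L, meta = NULL,
                           locus_name = "locus", chrom_class = "A",
                           on_overflow = c("error", "retry")) {
  on_overflow <- match.arg(on_overflow)
  stopifnot(inherits(genealogy, "im_genealogy"), theta >= 0, L >= 1)
  tries <- 0L
  repeat {
    mut <- .drop_mutations_cpp(genealogy$parent, genealogy$time,
                               genealogy$n_tips, theta)
    S <- ncol(mut$geno)
    if (S <= L) break
    tries <- tries + 1L
    if (on_overflow == "error" || tries > 1000L)
      stop("more mutations (", S, ") than sites (", L, ")")
  }
  n <- genealogy$n_tips
  anc <- sample(.base_set, L, replace = TRUE)
  seqs <- matrix(anc, n, L, byrow = TRUE)
  if (S > 0) {
    pos <- sample.int(L, S)
    for (m in seq_len(S)) {
      derived <- sample(setdiff(.base_set, anc[pos[m]]), 1)
      seqs[mut$geno[, m] == 1, pos[m]] <- derived
    }
  }
  if (is.null(meta)) {
    deme <- genealogy$tip_deme
    ids <- integer(n); hap <- integer(n)
    for (d in unique(deme)) {
      w <- which(deme == d)
      ids[w] <- (seq_along(w) + 1) %/% 2
      hap[w] <- 2 - seq_along(w) %% 2
    }
    meta <- data.frame(individual_id = sprintf("pop%d_i%02d", deme + 1, ids),
                       species = paste0("pop", deme + 1),
                       population = paste0("pop", deme + 1),
                       sex = "male", role = "ingroup", hap_index = hap,
                       stringsAsFactors = FALSE)
  }
  locus_alignment(locus_name, chrom_class, seqs, meta)
}

#' Locus tables for study designs
#'
#' The default locus panel emulates a multilocus intron survey of the four
#' black-and-white \emph{Ficedula} flycatchers: six autosomal loci of
#' 358/290/551/372/983/402 bp and five Z-linked loci of
#' 437/1439/638/555/562 bp.
#'
#' @return data frame with columns locus, chrom_class, length.
#' @export
flycatcher_loci <- function() {
  data.frame(
    locus = c("Acly-16", "Alas1-8", "Fas-y", "Rho-1", "Rpl30-3", "Tgfb2-5",
              "Aldob-6", "Brm-12", "Chdz", "Ghr", "Vldlr"),
    chrom_class = c(rep("A", 6), rep("Z", 5)),
    length = c(358L, 290L, 551L, 372L, 983L, 402L,
               437L, 1439L, 638L, 555L, 562L),
    stringsAsFactors = FALSE)
}

#' Study designs for the dataset simulator
#'
#' A design bundles the sampled populations (with diploid counts and the
#' number of hemizygous females), the locus panel, the per-site autosomal
#' theta, the Z:A effective-size ratio (0.75 under a balanced sex ratio),
#' the Z:A mutation-rate ratio, and the demography: per-population relative
#' sizes, a migration matrix, and a merge schedule of deme coalescences in
#' units of 2 Ne generations (autosomal scale).  Z-linked loci are
#' simulated with the inheritance-scaled theta and with the schedule
#' rescaled to the Z coalescent time unit.
#'
#' \code{single_population_design} gives one population with no history --
#' the neutral-equilibrium setting used for Z:A ratio calibration.
#' \code{two_population_design} gives the isolation-with-migration pair.
#' \code{flycatcher_design} emulates the six-population, four-species
#' sampling layout (nested splits, no migration, one outgroup).
#'
#' @param n_ind diploid individuals per population.
#' @param n_female hemizygous females per population.
#' @param loci locus table, as \code{\link{flycatcher_loci}}.
#' @param theta_site per-site autosomal 4 Ne mu.
#' @param z_ratio Z:A effective-size ratio.
#' @param mu_ratio Z:A mutation-rate ratio (1 = equal rates).
#' @param outgroup_t outgroup join time (2 Ne units), NA for none.
#' @return a list of class \code{im_design}.
#' @export
single_population_design <- function(n_ind = 16L, n_female = 8L,
                                     loci = flycatcher_loci(),
                                     theta_site = 0.004, z_ratio = 0.75,
                                     mu_ratio = 1, outgroup_t = NA) {
  structure(list(
    populations = data.frame(population = "pop1", species = "sp1",
                             n_ind = n_ind, n_female = n_female,
                             rel_size = 1, stringsAsFactors = FALSE),
    loci = loci, theta_site = theta_site, z_ratio = z_ratio,
    mu_ratio = mu_ratio,
    merges = NULL, mig = NULL, outgroup_t = outgroup_t),
    class = "im_design")
}

#' @rdname single_population_design
#' @param t_split split time of the two populations (2 Ne units).
#' @param m1,m2 scaled migration rates (see \code{\link{im_parameters}}).
#' @param rel_size2,rel_sizeA relative sizes of population 2 and the
#'   ancestor.
#' @export
two_population_design <- function(n_ind = 16L, n_female = 8L,
                                  loci = flycatcher_loci(),
                                  theta_site = 0.004, z_ratio = 0.75,
                                  mu_ratio = 1, t_split = 1,
                                  m1 = 0, m2 = 0,
                                  rel_size2 = 1, rel_sizeA = 1,
                                  outgroup_t = NA) {
  mig <- matrix(0, 3, 3)
  mig[1, 2] <- m1; mig[2, 1] <- m2
  structure(list(
    populations = data.frame(population = c("pop1", "pop2"),
                             species = c("sp1", "sp2"),
                             n_ind = n_ind, n_female = n_female,
                             rel_size = c(1, rel_size2),
                             stringsAsFactors = FALSE),
    loci = loci, theta_site = theta_site, z_ratio = z_ratio,
    mu_ratio = mu_ratio,
    ancestors = data.frame(deme = "anc", rel_size = rel_sizeA,
                           stringsAsFactors = FALSE),
    merges = data.frame(time = c(t_split, t_split),
                        from = c("pop1", "pop2"), into = c("anc", "anc"),
                        stringsAsFactors = FALSE),
    mig = mig, outgroup_t = outgroup_t),
    class = "im_design")
}

#' @rdname single_population_design
#' @param pop_split,species_depths split times (2 Ne units) of populations
#'   within species and of the successive species branching events.
#' @export
flycatcher_design <- function(loci = flycatcher_loci(), theta_site = 0.004,
                              z_ratio = 0.75, mu_ratio = 1.45 / 1.35,
                              pop_split = 0.1,
                              species_depths = c(1, 1.5, 2),
                              outgroup_t = 8) {
  pops <- data.frame(
    population = c("A-Mar", "C-It", "C-Hun", "P-Spa", "P-Nor", "S-Bul"),
    species = c("atlas", "collared", "collared", "pied", "pied", "semicollared"),
    n_ind = c(15L, 16L, 16L, 16L, 16L, 15L),
    n_female = c(0L, 0L, 0L, 2L, 0L, 3L),
    rel_size = 1, stringsAsFactors = FALSE)
  merges <- data.frame(
    time = c(pop_split, pop_split,
             species_depths[1], species_depths[1],
             species_depths[2], species_depths[2],
             species_depths[3], species_depths[3]),
    from = c("C-Hun", "P-Nor", "C-It", "P-Spa", "anc_cp", "S-Bul",
             "anc_cps", "A-Mar"),
    into = c("C-It", "P-Spa", "anc_cp", "anc_cp", "anc_cps", "anc_cps",
             "root", "root"),
    stringsAsFactors = FALSE)
  structure(list(
    populations = pops, loci = loci, theta_site = theta_site,
    z_ratio = z_ratio, mu_ratio = mu_ratio,
    ancestors = data.frame(deme = c("anc_cp", "anc_cps", "root"),
                           rel_size = 1, stringsAsFactors = FALSE),
    merges = merges, mig = NULL, outgroup_t = outgroup_t),
    class = "im_design")
}

#' Simulate a full multilocus haplotype dataset
#'
#' Simulates per-locus independent genealogies under the design's
#' demography and drops infinite-sites mutations, yielding phased
#' \code{\link{locus_alignment}} objects that mirror the sampling layout:
#' autosomal loci carry two haplotypes per individual, Z-linked loci one
#' per female and two per male, and (optionally) one outgroup haplotype
#' joins the deepest ancestral deme at \code{outgroup_t}.  Z-linked loci
#' use theta_site x z_ratio x mu_ratio per site and a time scale rescaled
#' by the Z:A size ratio so that a shared demographic history (in
#' generations) is simulated consistently for both chromosome classes.
#'
#' Reproducible: a single seed drives per-locus substreams derived by fixed
#' offsets, so the same seed yields byte-identical alignments.
#'
#' @param design an \code{im_design}.
#' @param seed integer seed.
#' @return an object of class \code{im_dataset}: list with
#'   \code{alignments} (named list), \code{design} and \code{seed}.
#' @export
simulate_dataset <- function(design, seed = NULL) {
  stopifnot(inherits(design, "im_design"))
  if (!is.null(seed)) set.seed(seed)
  nloci <- nrow(design$loci)
  sub_seeds <- sample.int(2147483646L, nloci)
  pops <- design$populations
  npop <- nrow(pops)
  demes <- pops$population
  anc <- if (!is.null(design$merges)) design$ancestors else NULL
  if (!is.null(anc)) demes <- c(demes, anc$deme)
  has_outgroup <- !is.null(design$outgroup_t) && !is.na(design$outgroup_t)
  if (has_outgroup) demes <- c(demes, ".outgroup")
  rel <- c(pops$rel_size, if (!is.null(anc)) anc$rel_size,
           if (has_outgroup) 1)
  nd <- length(demes)
  mig <- matrix(0, nd, nd)
  if (!is.null(design$mig))
    mig[seq_len(nrow(design$mig)), seq_len(ncol(design$mig))] <- design$mig

  merges <- design$merges
  mt <- numeric(); mf <- integer(); mi <- integer()
  if (!is.null(merges)) {
    mt <- merges$time
    mf <- match(merges$from, demes) - 1L
    mi <- match(merges$into, demes) - 1L
  }
  if (has_outgroup) {
    root_deme <- if (!is.null(merges)) merges$into[which.max(merges$time)] else demes[1]
    mt <- c(mt, design$outgroup_t)
    mf <- c(mf, nd - 1L)
    mi <- c(mi, match(root_deme, demes) - 1L)
  }
  ord <- order(mt)

  alignments <- list()
  for (l in seq_len(nloci)) {
    set.seed(sub_seeds[l])
    lc <- design$loci[l, ]
    is_z <- lc$chrom_class == "Z"
    h_eff <- if (is_z) design$z_ratio else 1
    theta_site <- design$theta_site * (if (is_z) design$z_ratio * design$mu_ratio else 1)
    theta_locus <- theta_site * lc$length
    meta <- .design_tips(pops, lc$chrom_class)
    tip_deme <- meta$deme
    if (has_outgroup) {
      meta <- rbind(meta[names(meta) != "deme"],
                    data.frame(individual_id = "outgroup1", species = "outgroup",
                               population = "outgroup", sex = "male",
                               role = "outgroup", hap_index = 1L,
                               stringsAsFactors = FALSE))
      tip_deme <- c(tip_deme, nd - 1L)
    } else meta <- meta[names(meta) != "deme"]
    g <- .sim_genealogy_cpp(as.integer(tip_deme), rel,
                            mig * h_eff, mt[ord] / h_eff, mf[ord], mi[ord])
    gen <- structure(list(parent = g$parent, time = g$time,
                          node_deme = g$node_deme, tip_deme = tip_deme,
                          n_tips = g$n_tips), class = "im_genealogy")
    alignments[[lc$locus]] <- drop_mutations(gen, theta_locus, lc$length,
                                             meta = meta,
                                             locus_name = lc$locus,
                                             chrom_class = lc$chrom_class,
                                             on_overflow = "retry")
  }
  structure(list(alignments = alignments, design = design, seed = seed),
            class = "im_dataset")
}

#' Write a simulated dataset as FASTA + metadata TSVs
#'
#' Emits the same FASTA and TSV dialect that \code{\link{read_locus}}
#' consumes, one FASTA per locus, plus \code{samples.tsv} and
#' \code{loci.tsv}.
#'
#' @param dataset an \code{im_dataset}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in dataset$alignments)
    write_locus(a, file.path(dir, paste0(a$locus_name, ".fasta")))
  write_metadata_tables(dataset$alignments,
                        file.path(dir, "samples.tsv"),
                        file.path(dir, "loci.tsv"))
  invisible(dir)
}

#' Convert scaled coalescent parameters to demographic quantities
#'
#' Ne = theta / (4 h mu L) (so theta/(4 mu L) for autosomal and
#' theta/(3 mu L) for Z-linked loci); times in 2 Ne_class generations map
#' to years through the class coalescent unit theta/(2 mu L) and the
#' generation time; scaled per-lineage migration maps to per-gene
#' per-generation rates.  \code{scaled_units} is the exact inverse.
#'
#' @param theta per-locus scaled mutation rate.
#' @param t time in units of 2 Ne_class generations (optional).
#' @param m migration rate per lineage per 2 Ne_class generations
#'   (optional).
#' @param mu mutation rate, substitutions/site/year.
#' @param L locus length (bp); use the geometric mean length when
#'   converting multilocus estimates.
#' @param h inheritance scalar, 1.0 or 0.75.
#' @param generation_time years per generation.
#' @return list with \code{Ne}, \code{t_years}, \code{m_per_gen}.
#' @export
demographic_units <- function(theta, t = NULL, m = NULL, mu, L, h = 1,
                              generation_time = 1) {
  if (mu <= 0) stop("mutation rate must be positive")
  stopifnot(L > 0, h %in% c(1, 0.75))
  mu_gen <- mu * generation_time            # substitutions/site/generation
  Ne <- theta / (4 * h * mu_gen * L)
  unit_gen <- theta / (2 * mu_gen * L)      # 2 Ne_class generations
  list(Ne = Ne,
       t_years = if (is.null(t)) NULL else t * unit_gen * generation_time,
       m_per_gen = if (is.null(m)) NULL else m / unit_gen)
}

#' @rdname demographic_units
#' @param Ne effective population size.
#' @param t_years divergence time in years (optional).
#' @param m_per_gen migration rate per gene per generation (optional).
#' @export
scaled_units <- function(Ne, t_years = NULL, m_per_gen = NULL, mu, L, h = 1,
                         generation_time = 1) {
  if (mu <= 0) stop("mutation rate must be positive")
  stopifnot(L > 0, h %in% c(1, 0.75), Ne > 0)
  mu_gen <- mu * generation_time
  theta <- 4 * h * Ne * mu_gen * L
  unit_gen <- theta / (2 * mu_gen * L)
  list(theta = theta,
       t = if (is.null(t_years)) NULL else t_years / generation_time / unit_gen,
       m = if (is.null(m_per_gen)) NULL else m_per_gen * unit_gen)
}
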