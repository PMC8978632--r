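# Synthetic-cohort generator.
#
# Generates a fully self-consistent cohort (sequences, features, proteomes,
# annotations, metadata, quality) with planted pH-dependent effects so every
# pipeline stage can be checked against ground truth. The trait model is
# drawn at the configured scale first (draw_cohort_truth); sequence
# realization (generate_cohort) then emits genomes whose measured metrics
# reproduce the drawn traits. `size_scale` scales the genome dimension
# (base pairs and ORF counts, with their noise) linearly so that
# sequence-level stages can be exercised on desk-sized genomes while the
# statistical structure is unchanged; protein lengths are never scaled.

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the analyses target: ~120 species
#' spanning pH 1-8, genome size 4.5 Mb at pH 7 shrinking by 0.22 Mb per pH
#' unit (about 3.4 Mb at pH 2), ORF count 4,100 at pH 7 shrinking by 180 per
#' unit, mean protein length 320 aa shrinking by 4 aa per unit, an 8%
#' paralog rate, COG-category and subcellular log-odds trends matching the
#' reported enrichment directions, and a screen of 100 planted Pfams of
#' which 60 shrink at low pH, 10 grow and 30 are null. Genome-size noise
#' grows with pH (heteroscedasticity) as in the observed scatter.
#'
#' @param n_species Number of species clusters.
#' @param genomes_per_species Integer vector sampled uniformly per species.
#' @param ph_range Uniform range of species pH optima.
#' @param genome_size_at_ph7,genome_size_slope Mb and Mb per pH unit.
#' @param orf_at_ph7,orf_slope ORFs and ORFs per pH unit.
#' @param protein_len_at_ph7,protein_len_slope Residues and residues per pH.
#' @param genome_size_sd,genome_size_hetero Base noise SD (Mb) and its
#'   linear growth per pH unit above the range minimum.
#' @param orf_sd,protein_len_sd Trait noise SDs.
#' @param ig_base Nominal intergenic percentage used for bookkeeping.
#' @param gc_mean,gc_sd,temp_mean,temp_sd Species G+C (%) and optimal
#'   temperature (deg C) draws, independent of pH by construction.
#' @param quality_fail_rate Fraction of genomes planted to fail the 80/5
#'   quality gate.
#' @param cog_coverage_at_ph7,coverage_logodds_slope Annotation-coverage
#'   model: P(protein has COG) = logistic(logit(base) + slope * (pH - 7)).
#' @param category_enrichment Named log-odds-per-pH slopes for COG category
#'   weights (negative = enriched at low pH).
#' @param location_enrichment Named log-odds-per-pH slopes for subcellular
#'   classes.
#' @param paralog_rate Target fraction of proteins in paralog families.
#' @param duplicate_divergence Amino-acid substitution rate applied to
#'   planted duplicate copies.
#' @param n_pfam_shrink,n_pfam_grow,n_pfam_null Planted Pfam screen
#'   composition; @param pfam_len_slope aa per pH unit for the non-null
#'   plants; @param pfam_len_sd per-species noise;
#'   @param pfam_presence Per-species presence probability of each plant.
#' @param size_scale Linear scale of the genome dimension (bp, ORF counts
#'   and their noise SDs).
#' @param within_species_divergence Nucleotide substitution rate between
#'   genomes of one species (keeps within-species ANI >= 99%).
#' @param contigs_per_genome Integer vector sampled per genome.
#' @param seed Integer seed; a fixed seed makes output byte-identical.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_species = 120L,
                          genomes_per_species = 1:3,
                          ph_range = c(1, 8),
                          genome_size_at_ph7 = 4.5,
                          genome_size_slope = 0.22,
                          orf_at_ph7 = 4100,
                          orf_slope = 180,
                          protein_len_at_ph7 = 320,
                          protein_len_slope = 4,
                          genome_size_sd = 0.45,
                          genome_size_hetero = 0.10,
                          orf_sd = 330,
                          protein_len_sd = 6,
                          ig_base = 12,
                          gc_mean = 55, gc_sd = 8,
                          temp_mean = 35, temp_sd = 12,
                          quality_fail_rate = 0.12,
                          cog_coverage_at_ph7 = 0.80,
                          pfam_coverage_at_ph7 = 0.85,
                          coverage_logodds_slope = 0.08,
                          category_enrichment = c(
                            L = -0.10, F = -0.07, C = -0.07, H = -0.06,
                            D = -0.05, J = -0.05, O = -0.04,
                            S = 0.12, T = 0.10),
                          location_enrichment = c(
                            inner_membrane = -0.08, periplasmic = 0.10,
                            outer_membrane = 0.10, cell_wall = 0.10,
                            exported = 0.10),
                          paralog_rate = 0.08,
                          duplicate_divergence = 0.05,
                          n_pfam_shrink = 60L, n_pfam_grow = 10L,
                          n_pfam_null = 30L,
                          pfam_len_slope = 3,
                          pfam_len_sd = 4,
                          pfam_presence = 0.96,
                          size_scale = 1,
                          within_species_divergence = 0.003,
                          contigs_per_genome = 1:3,
                          seed = 42L) {
  stopifnot(n_species > 0, all(genomes_per_species >= 1),
            ph_range[1] > 0, ph_range[2] < 14, ph_range[1] < ph_range[2],
            size_scale > 0, paralog_rate >= 0, paralog_rate < 1)
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' Desk-scale configuration preset
#'
#' The default trait model linearly scaled 1:100 in the genome dimension
#' (about 45 kb genomes with about 40 ORFs) over 12 species, with a reduced
#' planted Pfam screen; suitable for exercising sequence-level stages
#' (I/O, ANI, alignment, profiles) end to end in seconds.
#'
#' @param ... Overrides passed to [cohort_config].
#' @export
desk_config <- function(...) {
  args <- list(n_species = 12L, size_scale = 0.01,
               genome_size_sd = 0.25, orf_sd = 150,
               n_pfam_shrink = 10L, n_pfam_grow = 2L, n_pfam_null = 6L,
               quality_fail_rate = 0.15)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

#' Null configuration (all planted slopes zero)
#'
#' @param config A [cohort_config]; every planted trend (trait slopes,
#'   category/location/coverage log-odds, Pfam size slopes) is set to zero.
#'   Used for type-I-error and FDR-control simulations.
#' @export
null_config <- function(config = cohort_config()) {
  config$genome_size_slope <- 0
  config$orf_slope <- 0
  config$protein_len_slope <- 0
  config$coverage_logodds_slope <- 0
  config$category_enrichment[] <- 0
  config$location_enrichment[] <- 0
  config$pfam_len_slope <- 0
  config$n_pfam_shrink <- 0L
  config$n_pfam_grow <- 0L
  config$n_pfam_null <- config$n_pfam_null +
    cohort_config()$n_pfam_shrink + cohort_config()$n_pfam_grow
  config
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Draw the cohort ground truth
#'
#' Realizes the statistical layer of the generator: species pH optima and
#' traits (with planted slopes and noise), per-genome quality values and
#' trait jitter, the within-species ANI table, and the planted Pfam screen
#' composition. This is the ground truth against which pipeline output is
#' compared, and is sufficient for all trait-level statistics without
#' sequence realization.
#'
#' @param config A [cohort_config].
#' @return List of class `cohort_truth` with elements `config`, `species`,
#'   `genomes`, `ani`, `pfams`.
#' @export
draw_cohort_truth <- function(config) {
  set.seed(config$seed)
  ns <- config$n_species
  sc <- config$size_scale
  # stratified draw: one species per pH stratum (shuffled), so the cohort
  # covers its configured range even at small n
  ph <- config$ph_range[1] + (sample(ns) - stats::runif(ns)) / ns *
    diff(config$ph_range)
  size_sd <- (config$genome_size_sd +
                config$genome_size_hetero * (ph - config$ph_range[1])) * sc
  species <- data.frame(
    species_id = sprintf("S%03d", seq_len(ns)),
    ph_opt = ph,
    temp_opt = rtrunc_norm(ns, config$temp_mean, config$temp_sd, 5, 85),
    gc_percent = rtrunc_norm(ns, config$gc_mean, config$gc_sd, 25, 75),
    genome_size_mb = pmax(
      (config$genome_size_at_ph7 + config$genome_size_slope * (ph - 7)) * sc +
        stats::rnorm(ns, 0, size_sd), 0.3 * sc),
    orf_count = pmax(round(
      (config$orf_at_ph7 + config$orf_slope * (ph - 7)) * sc +
        stats::rnorm(ns, 0, config$orf_sd * sc)), 5),
    mean_protein_len = pmax(
      config$protein_len_at_ph7 + config$protein_len_slope * (ph - 7) +
        stats::rnorm(ns, 0, config$protein_len_sd), 80),
    stringsAsFactors = FALSE)
  n_g <- sample(config$genomes_per_species, ns, replace = TRUE)
  genomes <- do.call(rbind, lapply(seq_len(ns), function(i) {
    gids <- sprintf("%sG%d", species$species_id[i], seq_len(n_g[i]))
    fail <- stats::runif(n_g[i]) < config$quality_fail_rate
    comp <- ifelse(fail & stats::runif(n_g[i]) < 0.5,
                   stats::runif(n_g[i], 40, 80),
                   stats::runif(n_g[i], 85, 100))
    cont <- ifelse(fail & comp > 80,
                   stats::runif(n_g[i], 5, 15),
                   stats::runif(n_g[i], 0, 4))
    data.frame(genome_id = gids, species_id = species$species_id[i],
               completeness = comp, contamination = cont,
               passes_quality = comp > 80 & cont < 5,
               stringsAsFactors = FALSE)
  }))
  ani <- do.call(rbind, lapply(split(genomes$genome_id, genomes$species_id),
                               function(g) {
    if (length(g) < 2L) return(NULL)
    cmb <- utils::combn(g, 2L)
    data.frame(genome_a = cmb[1L, ], genome_b = cmb[2L, ],
               ani_percent = stats::runif(ncol(cmb), 99.3, 99.9),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ani))
    ani <- data.frame(genome_a = character(), genome_b = character(),
                      ani_percent = numeric(), stringsAsFactors = FALSE)
  rownames(ani) <- NULL
  npf <- config$n_pfam_shrink + config$n_pfam_grow + config$n_pfam_null
  pfams <- if (npf > 0) data.frame(
    pfam_id = sprintf("PF%05d", seq_len(npf)),
    base_len = round(stats::runif(npf, 150, 500)),
    len_slope = rep(c(config$pfam_len_slope, -config$pfam_len_slope, 0),
                    c(config$n_pfam_shrink, config$n_pfam_grow,
                      config$n_pfam_null)),
    is_null = rep(c(FALSE, FALSE, TRUE),
                  c(config$n_pfam_shrink, config$n_pfam_grow,
                    config$n_pfam_null)),
    # two plants carry a minority second-domain architecture; one is
    # duplicated per genome (exercises the single-copy/architecture filter)
    minor_arch_frac = 0, extra_copy = FALSE,
    stringsAsFactors = FALSE)
  else data.frame(pfam_id = character(), base_len = numeric(),
                  len_slope = numeric(), is_null = logical(),
                  minor_arch_frac = numeric(), extra_copy = logical(),
                  stringsAsFactors = FALSE)
  if (npf >= 3L) {
    pfams$minor_arch_frac[c(1L, 2L)] <- 0.6  # dominant arch only 40%
    pfams$extra_copy[3L] <- TRUE
  }
  structure(list(config = config, species = species, genomes = genomes,
                 ani = ani, pfams = pfams),
            class = "cohort_truth")
}

#' Per-genome trait table from the ground truth
#'
#' Genome-level realization of the species traits (small within-species
#' jitter) together with metadata and quality columns, in the same layout as
#' [genome_traits] so the quality -> cluster -> aggregate -> trend chain can
#' run directly on it.
#'
#' @param truth A `cohort_truth`.
#' @param jitter Relative within-species trait jitter SD (default 0.002).
#' @export
truth_trait_table <- function(truth, jitter = 0.002) {
  g <- truth$genomes
  s <- truth$species[match(g$species_id, truth$species$species_id), ]
  n <- nrow(g)
  data.frame(
    genome_id = g$genome_id,
    species_label = g$species_id,
    genome_size_mb = s$genome_size_mb * (1 + stats::rnorm(n, 0, jitter)),
    orf_count = round(s$orf_count * (1 + stats::rnorm(n, 0, jitter))),
    ig_percent = truth$config$ig_base + stats::rnorm(n, 0, 0.5),
    mean_protein_len = s$mean_protein_len * (1 + stats::rnorm(n, 0, jitter)),
    gc_percent = s$gc_percent,
    ph_opt = s$ph_opt,
    temp_opt = s$temp_opt,
    completeness = g$completeness,
    contamination = g$contamination,
    stringsAsFactors = FALSE)
}

#' Quality gate for a trait table
#'
#' Same strict rule as [quality_filter], applied to a per-genome trait
#' data.frame.
#'
#' @param traits data.frame with `completeness` and `contamination`.
#' @param min_completeness,max_contamination Percent cutoffs.
#' @export
quality_filter_table <- function(traits, min_completeness = 80,
                                 max_contamination = 5) {
  traits[traits$completeness > min_completeness &
           traits$contamination < max_contamination, , drop = FALSE]
}

#' Planted Pfam screen table from the ground truth
#'
#' Trait-level realization of the planted Pfam model: for each (plant,
#' species) pair present (per-species presence probability), the species
#' mean carrier length is `base + slope * (pH - 7) + noise`. Output matches
#' [pfam_species_table] so [screen_pfam_trends] runs on it directly.
#'
#' @param truth A `cohort_truth`.
#' @export
draw_pfam_screen_table <- function(truth) {
  cfg <- truth$config
  sp <- truth$species
  rows <- lapply(seq_len(nrow(truth$pfams)), function(i) {
    pf <- truth$pfams[i, ]
    present <- stats::runif(nrow(sp)) < cfg$pfam_presence
    if (!any(present)) return(NULL)
    s <- sp[present, , drop = FALSE]
    len <- pmax(round(pf$base_len + pf$len_slope * (s$ph_opt - 7) +
                        stats::rnorm(nrow(s), 0, cfg$pfam_len_sd)), 30)
    data.frame(pfam_id = pf$pfam_id, cluster_id = s$species_id,
               n_carriers = 1L, n_genomes = 1L, mean_len = len,
               architectures = I(replicate(nrow(s), {
                 t <- table(pf$pfam_id); t
               }, simplify = FALSE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
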