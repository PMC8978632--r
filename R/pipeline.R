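# End-to-end orchestration: filter -> cluster -> metrics -> families ->
# profiles -> trends -> Pfam screen -> report. Every number written to the
# report directory is reproducible by calling the underlying module function
# on the logged inputs.

#' Pipeline configuration
#'
#' Thresholds default to the analysis conventions used throughout: quality
#' gate 80/5 (97/2 for the intergenic analysis), 95% ANI species boundary,
#' 50/50/1e-5 homology cutoffs, q = 0.05 FDR, 2 PCA components. Group bins:
#' acidophile pH < 5 (extreme < 3, moderate 3-5), non-acidophile 5-8.
#'
#' @param ... Overrides of the defaults.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_completeness = 80, max_contamination = 5,
              strict_completeness = 97, strict_contamination = 2,
              ani_threshold = 95, ani_k = 21L,
              min_coverage = 50, min_identity = 50, max_evalue = 1e-5,
              fdr_q = 0.05, pfam_min_species_frac = 0.90,
              pfam_min_ph_span = 6,
              acidophile_ph = 5, extreme_ph = 3)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline
#'
#' @param records List of [genome_record] objects (e.g. from [read_cohort]).
#' @param out_dir Report directory (created).
#' @param config List from [pipeline_config].
#' @param ani_matrix Optional precomputed ANI pairs (data.frame or TSV path)
#'   bypassing the k-mer estimator.
#' @return Invisibly, a list with every intermediate table: `traits`,
#'   `membership`, `clusters`, `trends`, `pca`, `profiles`,
#'   `cluster_profiles`, `screen`, `screen_single_copy`, `census`, `log`.
#' @export
run_pipeline <- function(records, out_dir, config = pipeline_config(),
                         ani_matrix = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("streamlinr %s", as.character(
    utils::packageVersion("streamlinr"))),
    sprintf("genomes in: %d", length(records)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  kept <- stage("quality_filter", quality_filter(
    records, config$min_completeness, config$max_contamination))
  log_lines <- c(log_lines, sprintf("pass quality %g/%g: %d",
                                    config$min_completeness,
                                    config$max_contamination, length(kept)))
  ani <- stage("ani", ani_pairs(kept, k = config$ani_k,
                                supplied = ani_matrix))
  membership <- stage("cluster_species",
                      cluster_species(kept, ani, config$ani_threshold))
  traits <- stage("size_metrics", genome_traits(kept))
  clusters <- stage("aggregate", aggregate_clusters(traits, membership))
  log_lines <- c(log_lines, sprintf("species clusters: %d", nrow(clusters)))
  trends <- stage("trends", trait_trends(
    clusters, c("genome_size_mb", "orf_count", "mean_protein_len")))
  # the intergenic analysis re-filters at the stricter gate
  strict <- quality_filter(records, config$strict_completeness,
                           config$strict_contamination)
  strict <- strict[vapply(strict, `[[`, "", "genome_id") %in%
                     membership$genome_id]
  if (length(strict) >= 3L) {
    m2 <- membership[membership$genome_id %in%
                       vapply(strict, `[[`, "", "genome_id"), , drop = FALSE]
    cl2 <- aggregate_clusters(genome_traits(strict), m2)
    if (nrow(cl2) >= 3L && stats::sd(cl2$ph_opt) > 0 &&
        stats::sd(cl2$ig_percent) > 0) {
      ig_tr <- trait_trends(cl2, "ig_percent")
      trends <- rbind(trends, ig_tr)
      log_lines <- c(log_lines,
                     sprintf("strict %g/%g gate for intergenic: %d genomes, %d clusters",
                             config$strict_completeness,
                             config$strict_contamination,
                             length(strict), nrow(cl2)))
    }
  }
  pca <- if (nrow(clusters) >= 4L)
    stage("pca", pca_biplot(clusters[, c("ph_opt", "temp_opt", "gc_percent",
                                         "genome_size_mb")]))
  else NULL
  families_list <- stage("families", lapply(kept, function(r)
    proteome_families(r, config$min_coverage, config$min_identity,
                      config$max_evalue)))
  profiles <- stage("profiles", cohort_profiles(kept, families_list))
  flat <- flatten_profiles(profiles)
  cluster_profiles <- aggregate_clusters(flat, membership)
  screen_tbl <- stage("pfam_table", pfam_species_table(kept, membership))
  cluster_ph <- stats::setNames(clusters$ph_opt, clusters$cluster_id)
  screen <- stage("pfam_screen", screen_pfam_trends(
    screen_tbl, cluster_ph, config$fdr_q, single_copy = FALSE,
    config$pfam_min_species_frac, config$pfam_min_ph_span))
  screen_sc <- stage("pfam_screen_single_copy", screen_pfam_trends(
    screen_tbl, cluster_ph, config$fdr_q, single_copy = TRUE,
    config$pfam_min_species_frac, config$pfam_min_ph_span))
  census <- trend_census(screen)
  log_lines <- c(log_lines,
                 sprintf("pfams screened: %d (single-copy variant: %d)",
                         nrow(screen), nrow(screen_sc)),
                 sprintf("census: %d positive / %d negative",
                         census$n_positive, census$n_negative))
  write_trait_table(traits, file.path(out_dir, "genome_traits.tsv"))
  write_trait_table(clusters, file.path(out_dir, "cluster_traits.tsv"))
  write_trait_table(trends, file.path(out_dir, "trait_trends.tsv"))
  write_trait_table(flat, file.path(out_dir, "genome_profiles.tsv"))
  write_trait_table(cluster_profiles,
                    file.path(out_dir, "cluster_profiles.tsv"))
  write_trait_table(screen, file.path(out_dir, "pfam_screen.tsv"))
  write_trait_table(screen_sc,
                    file.path(out_dir, "pfam_screen_single_copy.tsv"))
  fam_tab <- do.call(rbind, lapply(seq_along(kept), function(i)
    cbind(genome_id = kept[[i]]$genome_id, families_list[[i]])))
  utils::write.table(fam_tab, file.path(out_dir, "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pca)) {
    write_trait_table(as.data.frame(pca$loadings),
                      file.path(out_dir, "pca_loadings.tsv"))
    write_trait_table(as.data.frame(pca$scores),
                      file.path(out_dir, "pca_scores.tsv"))
  }
  census_df <- data.frame(n_positive = census$n_positive,
                          n_negative = census$n_negative,
                          ratio = census$ratio,
                          binomial_p = census$binomial_p)
  write_trait_table(census_df, file.path(out_dir, "census.tsv"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(traits = traits, membership = membership,
                 clusters = clusters, trends = trends, pca = pca,
                 families = families_list, profiles = profiles,
                 cluster_profiles = cluster_profiles, screen = screen,
                 screen_single_copy = screen_sc, census = census,
                 log = log_lines))
}

#' Render figures from a report directory
#'
#' One scatter per trait trend with the fitted line and annotated r / p, a
#' PCA biplot, and the screen's correlation histogram. Requires ggplot2;
#' missing tables are skipped with a warning.
#'
#' @param report_dir Directory written by [run_pipeline].
#' @param format Device suffix (default "pdf").
#' @return Character vector of written plot paths.
#' @export
make_figures <- function(report_dir, format = "pdf") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for figure rendering")
  out <- character()
  gg <- ggplot2::ggplot
  need <- function(f) {
    p <- file.path(report_dir, f)
    if (!file.exists(p)) {
      warning("missing table, skipping: ", f)
      return(NULL)
    }
    read_trait_table(p)
  }
  clusters <- need("cluster_traits.tsv")
  trends <- need("trait_trends.tsv")
  if (!is.null(clusters) && !is.null(trends)) {
    for (i in seq_len(nrow(trends))) {
      tn <- trends$trait_name[i]
      if (!tn %in% names(clusters)) next
      lab <- sprintf("r = %.2f, p = %.2g", trends$pearson_r[i],
                     trends$p_value[i])
      g <- gg(clusters, ggplot2::aes(.data[["ph_opt"]], .data[[tn]])) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
        ggplot2::labs(x = "optimal growth pH", y = tn, subtitle = lab)
      f <- file.path(report_dir, paste0("trend_", tn, ".", format))
      ggplot2::ggsave(f, g, width = 5, height = 4)
      out <- c(out, f)
    }
  }
  loadings <- need("pca_loadings.tsv")
  scores <- need("pca_scores.tsv")
  if (!is.null(loadings) && !is.null(scores)) {
    loadings$var <- c("ph_opt", "temp_opt", "gc_percent",
                      "genome_size_mb")[seq_len(nrow(loadings))]
    sc <- max(abs(scores$PC1), abs(scores$PC2))
    g <- gg(scores, ggplot2::aes(.data[["PC1"]], .data[["PC2"]])) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_segment(data = loadings,
                            ggplot2::aes(x = 0, y = 0,
                                         xend = .data[["PC1"]] * sc,
                                         yend = .data[["PC2"]] * sc),
                            arrow = grid::arrow(length = grid::unit(3, "mm")),
                            colour = "red") +
      ggplot2::geom_text(data = loadings,
                         ggplot2::aes(x = .data[["PC1"]] * sc,
                                      y = .data[["PC2"]] * sc,
                                      label = .data[["var"]]),
                         vjust = -0.5, colour = "red") +
      ggplot2::labs(title = "PCA biplot of cluster traits")
    f <- file.path(report_dir, paste0("pca_biplot.", format))
    ggplot2::ggsave(f, g, width = 5, height = 5)
    out <- c(out, f)
  }
  screen <- need("pfam_screen.tsv")
  if (!is.null(screen) && nrow(screen)) {
    g <- gg(screen, ggplot2::aes(.data[["pearson_r"]],
                                 fill = .data[["sign"]])) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::labs(x = "Pearson r (protein size vs pH)",
                    title = "Conserved-Pfam size-trend screen")
    f <- file.path(report_dir, paste0("pfam_screen.", format))
    ggplot2::ggsave(f, g, width = 5, height = 4)
    out <- c(out, f)
  }
  out
}
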