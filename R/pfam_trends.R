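# Conserved-Pfam protein-size trend screen.
#
# Pfams present in over 90% of species and spanning at least 6 pH units are
# screened for a correlation between carrier protein size (species averages)
# and optimal growth pH; Benjamini-Hochberg control is applied once per
# screen at q = 0.05 and the significant positive/negative counts feed an
# exact sign binomial test. A positive correlation means proteins are
# shorter at low pH. A stricter variant keeps only Pfams in single copy
# (mean carriers per genome < 1.1) with one dominant domain architecture.

#' Per-species Pfam carrier table
#'
#' Derives, from annotated proteomes and the cluster membership, one row per
#' (pfam, species cluster): number of carrier proteins, carrier count per
#' genome, mean carrier protein length, and the architecture tally. A
#' protein is a carrier when the Pfam occurs anywhere in its architecture; a
#' protein with several copies of the same Pfam counts once.
#'
#' @param records List of [genome_record] objects.
#' @param membership data.frame `genome_id`, `cluster_id`.
#' @return data.frame `pfam_id`, `cluster_id`, `n_carriers`, `n_genomes`,
#'   `mean_len`, `architectures` (list column of named carrier counts).
#' @export
pfam_species_table <- function(records, membership) {
  rows <- list()
  for (r in records) {
    cid <- membership$cluster_id[membership$genome_id == r$genome_id]
    if (!length(cid)) next
    p <- r$proteins
    for (i in seq_len(nrow(p))) {
      arch <- p$pfam_ids[[i]]
      if (is.null(arch) || !nrow(arch)) next
      arch_str <- paste(arch$pfam_id, collapse = "+")
      for (pf in unique(arch$pfam_id)) {
        rows[[length(rows) + 1L]] <- data.frame(
          pfam_id = pf, cluster_id = cid, genome_id = r$genome_id,
          length = p$length[i], architecture = arch_str,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(pfam_id = character(), cluster_id = character(),
                      n_carriers = integer(), n_genomes = integer(),
                      mean_len = numeric(), stringsAsFactors = FALSE))
  long <- do.call(rbind, rows)
  keys <- paste(long$pfam_id, long$cluster_id, sep = "\r")
  agg <- lapply(split(long, keys), function(sub) {
    data.frame(pfam_id = sub$pfam_id[1L], cluster_id = sub$cluster_id[1L],
               n_carriers = nrow(sub),
               n_genomes = length(unique(sub$genome_id)),
               mean_len = mean(sub$length),
               architectures = I(list(table(sub$architecture))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Select conserved Pfams
#'
#' A Pfam is retained iff it is present in strictly more than
#' `min_species_frac` of the species clusters and the pH optima of its
#' carrier species span at least `min_ph_span` units.
#'
#' @param pfam_table Table from [pfam_species_table].
#' @param cluster_ph Named numeric vector: cluster_id -> pH optimum.
#' @param min_species_frac Fraction of species (default 0.90, strict ">").
#' @param min_ph_span pH span floor (default 6, inclusive ">=").
#' @return Character vector of retained pfam ids.
#' @export
select_conserved <- function(pfam_table, cluster_ph,
                             min_species_frac = 0.90, min_ph_span = 6) {
  n_species <- length(cluster_ph)
  keep <- vapply(split(pfam_table, pfam_table$pfam_id), function(sub) {
    frac <- length(unique(sub$cluster_id)) / n_species
    span <- diff(range(cluster_ph[sub$cluster_id]))
    frac > min_species_frac && span >= min_ph_span
  }, TRUE)
  sort(names(keep)[keep])
}

#' Restrict to single-copy, single-architecture Pfams
#'
#' Keeps a Pfam iff its mean number of carrier proteins per carrier genome
#' is below `max_copies` and its most common domain architecture accounts
#' for strictly more than `dominance_frac` of all carrier proteins.
#'
#' @param pfam_ids Candidate ids (already conserved-selected).
#' @param pfam_table Table from [pfam_species_table].
#' @param max_copies Copies-per-genome ceiling (default 1.1, strict "<").
#' @param dominance_frac Architecture dominance floor (default 0.5,
#'   strict ">").
#' @return Character vector of retained pfam ids.
#' @export
select_single_copy_single_arch <- function(pfam_ids, pfam_table,
                                           max_copies = 1.1,
                                           dominance_frac = 0.5) {
  keep <- vapply(pfam_ids, function(pf) {
    sub <- pfam_table[pfam_table$pfam_id == pf, , drop = FALSE]
    copies <- sum(sub$n_carriers) / sum(sub$n_genomes)
    arch <- Reduce(function(a, b) {
      all_n <- union(names(a), names(b))
      out <- stats::setNames(numeric(length(all_n)), all_n)
      out[names(a)] <- out[names(a)] + as.numeric(a)
      out[names(b)] <- out[names(b)] + as.numeric(b)
      out
    }, lapply(sub$architectures, function(t) {
      stats::setNames(as.numeric(t), names(t))
    }))
    copies < max_copies && max(arch) / sum(arch) > dominance_frac
  }, TRUE)
  pfam_ids[keep]
}

#' Size-vs-pH trend of one Pfam
#'
#' Pearson correlation of per-species mean carrier protein length against
#' species pH optimum; excluded (returns `NULL`) with fewer than three
#' carrier species or constant lengths.
#'
#' @param pfam_id Pfam id.
#' @param pfam_table Table from [pfam_species_table].
#' @param cluster_ph Named numeric vector: cluster_id -> pH optimum.
#' @return One-row data.frame (`pfam_id`, `n_species`, `ph_span`,
#'   `mean_copies`, `pearson_r`, `p_value`) or `NULL` when excluded.
#' @export
per_pfam_trend <- function(pfam_id, pfam_table, cluster_ph) {
  sub <- pfam_table[pfam_table$pfam_id == pfam_id, , drop = FALSE]
  if (length(unique(sub$cluster_id)) < 3L) return(NULL)
  ph <- cluster_ph[sub$cluster_id]
  if (stats::sd(sub$mean_len) == 0 || stats::sd(ph) == 0) return(NULL)
  tr <- pearson_trend(ph, sub$mean_len, pfam_id)
  data.frame(pfam_id = pfam_id, n_species = nrow(sub),
             ph_span = diff(range(ph)),
             mean_copies = sum(sub$n_carriers) / sum(sub$n_genomes),
             pearson_r = tr$pearson_r, p_value = tr$p_value,
             stringsAsFactors = FALSE)
}

#' Run the conserved-Pfam size-trend screen
#'
#' Selects conserved Pfams (optionally restricted to single-copy,
#' single-architecture), computes per-Pfam trends, applies BH control once
#' over the screened set, and assigns signs: `positive` (shorter proteins at
#' low pH) or `negative` iff q <= `q`, else `nonsignificant`.
#'
#' @param pfam_table Table from [pfam_species_table].
#' @param cluster_ph Named numeric vector: cluster_id -> pH optimum.
#' @param q FDR level (default 0.05).
#' @param single_copy Apply the single-copy/dominant-architecture
#'   restriction (default FALSE).
#' @param min_species_frac,min_ph_span Passed to [select_conserved].
#' @return data.frame with one row per screened Pfam incl. `q_value`, `sign`.
#' @export
screen_pfam_trends <- function(pfam_table, cluster_ph, q = 0.05,
                               single_copy = FALSE,
                               min_species_frac = 0.90, min_ph_span = 6) {
  ids <- select_conserved(pfam_table, cluster_ph, min_species_frac,
                          min_ph_span)
  if (single_copy)
    ids <- select_single_copy_single_arch(ids, pfam_table)
  trends <- do.call(rbind, lapply(ids, per_pfam_trend,
                                  pfam_table = pfam_table,
                                  cluster_ph = cluster_ph))
  if (is.null(trends) || !nrow(trends))
    return(data.frame(pfam_id = character(), n_species = integer(),
                      ph_span = numeric(), mean_copies = numeric(),
                      pearson_r = numeric(), p_value = numeric(),
                      q_value = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  fdr <- bh_fdr(trends$p_value, q)
  trends$q_value <- fdr$q_value
  trends$sign <- ifelse(!fdr$significant, "nonsignificant",
                        ifelse(trends$pearson_r > 0, "positive", "negative"))
  trends
}

#' Census of significant size trends
#'
#' Counts significant positive (protein shorter at low pH) and negative
#' trends, their ratio, and the exact two-sided sign binomial test on the
#' counts under a null probability of 0.5. With no significant trends the
#' ratio is undefined and the test is skipped (both `NA`).
#'
#' @param trends Screen output from [screen_pfam_trends], or a data.frame
#'   with a `sign` column.
#' @return List: `n_positive`, `n_negative`, `ratio`, `binomial_p`.
#' @export
trend_census <- function(trends) {
  n_pos <- sum(trends$sign == "positive")
  n_neg <- sum(trends$sign == "negative")
  if (n_pos + n_neg == 0L)
    return(list(n_positive = 0L, n_negative = 0L, ratio = NA_real_,
                binomial_p = NA_real_))
  list(n_positive = n_pos, n_negative = n_neg,
       ratio = if (n_neg > 0) n_pos / n_neg else Inf,
       binomial_p = binomial_two_sided(n_pos, n_pos + n_neg, 0.5))
}
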