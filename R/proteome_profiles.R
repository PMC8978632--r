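# Per-genome frequency profiles of protein families: subcellular classes,
# signal peptides, COG/Pfam annotation coverage and COG-category
# representativity. All percentages are over the total number of families of
# the proteome; families inherit per-protein labels by majority vote.

#' Majority location and signal flag of one family
#'
#' The family location is the majority location among members (ties,
#' including all-unknown, resolve to `unknown`); the family carries a signal
#' peptide iff a strict majority of members do.
#'
#' @param locations Character vector of member location labels.
#' @param signals Logical vector of member signal-peptide flags.
#' @return List with `location` and `has_signal_peptide`.
#' @export
family_location <- function(locations, signals) {
  known <- locations[locations != "unknown"]
  loc <- "unknown"
  if (length(known)) {
    tab <- sort(table(known), decreasing = TRUE)
    if (length(tab) == 1L || tab[1L] > tab[2L]) loc <- names(tab)[1L]
  }
  list(location = loc,
       has_signal_peptide = sum(signals) > length(signals) / 2)
}

family_cog_category <- function(categories) {
  cats <- categories[!is.na(categories)]
  if (!length(cats)) return(NA_character_)
  # majority; ties resolve to the alphabetically smallest letter because
  # table() orders its names
  tab <- table(cats)
  names(tab)[which.max(tab)]
}

#' Proteome profile of one genome
#'
#' Family-level percentages over the total number of families: subcellular
#' classes (cytoplasmic, inner membrane, the pooled periplasmic / outer
#' membrane / cell wall / exported class), signal-peptide presence, COG and
#' Pfam annotation coverage (a family has an assignment iff any member does),
#' per-COG-category representativity (family category = majority category
#' among annotated members, ties to the alphabetically smallest; unannotated
#' families count in the denominator only), and paralog percentages overall
#' and per category.
#'
#' @param proteins Proteins data.frame of one genome (columns `protein_id`,
#'   `cog_id`, `cog_category`, `pfam_ids`, `location`, `has_signal_peptide`).
#' @param families Family table from [build_families].
#' @return One-row data.frame; the category maps are list columns
#'   (`pct_families_by_cog_category`, `paralog_pct_by_cog_category`).
#' @export
proteome_profile <- function(proteins, families) {
  stopifnot(setequal(proteins$protein_id, families$protein_id))
  fam_ids <- unique(families$family_id)
  n_fam <- length(fam_ids)
  idx <- split(match(families$protein_id, proteins$protein_id),
               families$family_id)[fam_ids]
  has_pfam_protein <- vapply(proteins$pfam_ids,
                             function(p) !is.null(p) && nrow(p) > 0, TRUE)
  locs <- vapply(idx, function(i)
    family_location(proteins$location[i],
                    proteins$has_signal_peptide[i])$location, "")
  sigs <- vapply(idx, function(i)
    family_location(proteins$location[i],
                    proteins$has_signal_peptide[i])$has_signal_peptide, TRUE)
  cogs <- vapply(idx, function(i) any(!is.na(proteins$cog_id[i])), TRUE)
  pfams <- vapply(idx, function(i) any(has_pfam_protein[i]), TRUE)
  cats <- vapply(idx, function(i)
    family_cog_category(proteins$cog_category[i]), "")
  outer_pool <- c("periplasmic", "outer_membrane", "cell_wall", "exported")
  cat_tab <- table(cats[!is.na(cats)])
  cat_pct <- as.list(100 * as.numeric(cat_tab) / n_fam)
  names(cat_pct) <- names(cat_tab)
  paralog_by_cat <- lapply(
    stats::setNames(nm = sort(unique(
      proteins$cog_category[!is.na(proteins$cog_category)]))),
    function(cc) paralog_fraction(families, proteins, cc))
  out <- data.frame(
    n_families = n_fam,
    pct_families_cytoplasmic = 100 * mean(locs == "cytoplasmic"),
    pct_families_inner_membrane = 100 * mean(locs == "inner_membrane"),
    pct_families_peri_out_wall_exported = 100 * mean(locs %in% outer_pool),
    pct_families_signal_peptide = 100 * mean(sigs),
    pct_families_with_cog = 100 * mean(cogs),
    pct_families_with_pfam = 100 * mean(pfams),
    paralog_pct_overall = paralog_fraction(families, proteins),
    stringsAsFactors = FALSE)
  out$pct_families_by_cog_category <- list(cat_pct)
  out$paralog_pct_by_cog_category <- list(paralog_by_cat)
  out
}

#' Profiles for a cohort
#'
#' Runs family construction and profiling per genome; cluster-level profiles
#' are the arithmetic means of member-genome profiles.
#'
#' @param records List of [genome_record] objects.
#' @param families_list Optional precomputed list of family tables, parallel
#'   to `records`; computed with [proteome_families] when absent.
#' @return data.frame keyed by `genome_id`.
#' @export
cohort_profiles <- function(records, families_list = NULL) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    fam <- if (is.null(families_list)) proteome_families(r)
           else families_list[[i]]
    cbind(data.frame(genome_id = r$genome_id,
                     ph_opt = if (!is.null(r$metadata)) r$metadata$ph_opt
                              else NA_real_,
                     stringsAsFactors = FALSE),
          proteome_profile(r$proteins, fam))
  })
  do.call(rbind, rows)
}

#' Explode category list columns of a profile table
#'
#' Turns `pct_families_by_cog_category` and `paralog_pct_by_cog_category`
#' into flat numeric columns (`cat_pct_X`, `paralog_pct_X`), with `NA` where
#' a genome has no family / protein of the category.
#'
#' @param profiles data.frame from [cohort_profiles].
#' @export
flatten_profiles <- function(profiles) {
  flat <- profiles[, !(names(profiles) %in%
                         c("pct_families_by_cog_category",
                           "paralog_pct_by_cog_category")), drop = FALSE]
  expand <- function(col, prefix, fill = NA_real_) {
    letters_all <- sort(unique(unlist(lapply(col, names))))
    m <- vapply(letters_all, function(L) {
      vapply(col, function(x) {
        v <- x[[L]]
        if (is.null(v)) fill else v
      }, numeric(1))
    }, numeric(nrow(profiles)))
    m <- matrix(m, nrow = nrow(profiles),
                dimnames = list(NULL, paste0(prefix, letters_all)))
    as.data.frame(m)
  }
  cbind(flat,
        expand(profiles$pct_families_by_cog_category, "cat_pct_", 0),
        expand(profiles$paralog_pct_by_cog_category, "paralog_pct_"))
}
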