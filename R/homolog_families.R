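# Within-proteome homolog families by the reciprocal-best-hit rule.
#
# All-vs-all local protein alignment (Smith-Waterman, BLOSUM62, gap open 11 /
# extend 1) stands in for an external BLASTP run; externally computed hits in
# 12-column tabular format can be ingested instead. Two proteins join the
# same family when their pair passes the 50% coverage / 50% identity /
# 1e-5 e-value cutoffs AND at least one of them is the best-scoring kept hit
# of the other; families are the connected components of those edges.

# Karlin-Altschul parameters for gapped BLOSUM62 (open 11 / extend 1).
KA_LAMBDA <- 0.267
KA_K <- 0.041

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

karlin_altschul_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

#' Align one protein pair locally
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps (a gap of
#' length L costs `gap_open + L * gap_extend`). Identity is percent identical
#' positions over aligned columns; coverage is the aligned span on the query
#' divided by query length.
#'
#' @param query,subject Amino-acid strings.
#' @param db_length Summed database length used for the e-value (defaults to
#'   the subject length).
#' @param gap_open,gap_extend Gap penalties (defaults 11, 1).
#' @return List with `score`, `identity`, `coverage`, `evalue`.
#' @export
align_pair <- function(query, subject, db_length = nchar(subject),
                       gap_open = 11, gap_extend = 1) {
  if (grepl("[^ARNDCQEGHILKMFPSTWYV]", toupper(query)) ||
      grepl("[^ARNDCQEGHILKMFPSTWYV]", toupper(subject)))
    stop("sequence contains non-amino-acid characters")
  pa <- Biostrings::pairwiseAlignment(
    query, subject, type = "local",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  span <- Biostrings::end(Biostrings::pattern(pa)) -
    Biostrings::start(Biostrings::pattern(pa)) + 1L
  list(score = sc,
       identity = Biostrings::pid(pa, type = "PID1"),
       coverage = 100 * span / nchar(query),
       evalue = karlin_altschul_evalue(sc, nchar(query), db_length))
}

blosum62_cache <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

# Candidate pre-screen: unrelated random proteins share essentially no exact
# amino-acid 4-mers, while any pair clearing the 50% identity cutoff shares
# many; pairs sharing fewer than `min_shared` are skipped before alignment.
protein_kmers <- function(seq, k = 4L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' All-vs-all within-proteome similarity search
#'
#' Aligns every ordered protein pair of one proteome (self-hits excluded) and
#' reports hits passing the e-value reporting floor. A shared-4-mer
#' pre-screen (on by default) skips pairs that cannot approach the identity
#' cutoff; exact alignment is performed on the survivors.
#'
#' @param proteome Named character vector of amino-acid sequences
#'   (names = protein ids) or a proteins data.frame with `protein_id` and
#'   `sequence`.
#' @param report_floor E-value reporting floor (default 10).
#' @param prescreen Use the shared-k-mer candidate filter (default TRUE).
#' @param min_shared Minimum shared 4-mers for a candidate pair (default 3).
#' @param gap_open,gap_extend Gap penalties.
#' @return data.frame of hits: `query_id`, `subject_id`, `score`, `identity`,
#'   `coverage`, `evalue` (both orientations of each retained pair).
#' @export
all_vs_all_search <- function(proteome, report_floor = 10, prescreen = TRUE,
                              min_shared = 3L, gap_open = 11,
                              gap_extend = 1) {
  if (is.data.frame(proteome)) {
    seqs <- proteome$sequence
    names(seqs) <- proteome$protein_id
    proteome <- seqs
  }
  if (!length(proteome)) stop("empty proteome")
  proteome <- toupper(proteome)
  if (any(grepl("[^ARNDCQEGHILKMFPSTWYV]", proteome)))
    stop("sequence contains non-amino-acid characters: ",
         names(proteome)[grepl("[^ARNDCQEGHILKMFPSTWYV]", proteome)][1L])
  n <- length(proteome)
  db_len <- sum(nchar(proteome))
  empty <- data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), identity = numeric(),
                      coverage = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  cmb <- utils::combn(n, 2L)
  if (prescreen) {
    km <- lapply(proteome, protein_kmers)
    keep <- vapply(seq_len(ncol(cmb)), function(i) {
      length(intersect(km[[cmb[1L, i]]], km[[cmb[2L, i]]])) >= min_shared
    }, TRUE)
    cmb <- cmb[, keep, drop = FALSE]
  }
  if (!ncol(cmb)) return(empty)
  ids <- names(proteome)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1L, i]; b <- cmb[2L, i]
    pa <- Biostrings::pairwiseAlignment(
      proteome[[a]], proteome[[b]], type = "local",
      substitutionMatrix = blosum62_matrix(),
      gapOpening = gap_open, gapExtension = gap_extend)
    sc <- Biostrings::score(pa)
    idn <- Biostrings::pid(pa, type = "PID1")
    span_q <- Biostrings::end(Biostrings::pattern(pa)) -
      Biostrings::start(Biostrings::pattern(pa)) + 1L
    span_s <- Biostrings::end(Biostrings::subject(pa)) -
      Biostrings::start(Biostrings::subject(pa)) + 1L
    # both orientations of the pair: coverage is query-side, so it differs
    data.frame(
      query_id = c(ids[a], ids[b]), subject_id = c(ids[b], ids[a]),
      score = sc, identity = idn,
      coverage = c(100 * span_q / nchar(proteome[[a]]),
                   100 * span_s / nchar(proteome[[b]])),
      evalue = c(karlin_altschul_evalue(sc, nchar(proteome[[a]]), db_len),
                 karlin_altschul_evalue(sc, nchar(proteome[[b]]), db_len)),
      stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= report_floor, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read externally computed search hits
#'
#' Ingests 12-column tabular search output (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) in place of the
#' built-in aligner; coverage is reconstructed query-side from the aligned
#' span and `query_lengths`.
#'
#' @param path Tabular file path.
#' @param query_lengths Named integer vector of query protein lengths.
#' @return Hits data.frame as from [all_vs_all_search].
#' @export
read_tabular_hits <- function(path, query_lengths) {
  cols <- c("query_id", "subject_id", "identity", "aln_length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "score")
  df <- utils::read.delim(path, header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE)
  df <- df[df$query_id != df$subject_id, , drop = FALSE]
  df$coverage <- 100 * (df$qend - df$qstart + 1) /
    query_lengths[df$query_id]
  df[, c("query_id", "subject_id", "score", "identity", "coverage",
         "evalue")]
}

#' Apply homology cutoffs to search hits
#'
#' A hit is kept iff `coverage >= min_coverage`, `identity >= min_identity`
#' and `evalue <= max_evalue` (all inclusive).
#'
#' @param hits Hits data.frame.
#' @param min_coverage,min_identity Percent cutoffs (defaults 50, 50).
#' @param max_evalue E-value cutoff (default 1e-5).
#' @export
apply_cutoffs <- function(hits, min_coverage = 50, min_identity = 50,
                          max_evalue = 1e-5) {
  hits[hits$coverage >= min_coverage & hits$identity >= min_identity &
         hits$evalue <= max_evalue, , drop = FALSE]
}

# Best kept hit per query: highest score, then lowest e-value, then smallest
# subject id.
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits[0, , drop = FALSE])
  o <- order(hits$query_id, -hits$score, hits$evalue, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Build homolog families from filtered hits
#'
#' An undirected edge joins proteins a and b iff the pair passed the cutoffs
#' and b is a's best-scoring kept hit or a is b's. Families are the connected
#' components; proteins without edges are singleton families. Family ids are
#' the lexicographically smallest member protein id, so families partition
#' the proteome deterministically.
#'
#' @param protein_ids All protein ids of the proteome.
#' @param filtered_hits Hits surviving [apply_cutoffs].
#' @return data.frame `protein_id`, `family_id`, `family_size`,
#'   `is_paralog_family` (TRUE iff size >= 2).
#' @export
build_families <- function(protein_ids, filtered_hits) {
  bh <- best_hits(filtered_hits)
  edges <- unique(data.frame(
    a = pmin(bh$query_id, bh$subject_id),
    b = pmax(bh$query_id, bh$subject_id), stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = protein_ids))
  comp <- igraph::components(g)$membership
  fam <- vapply(split(names(comp), comp), min, "")[as.character(comp)]
  out <- data.frame(protein_id = names(comp), family_id = unname(fam),
                    stringsAsFactors = FALSE)
  sizes <- table(out$family_id)
  out$family_size <- as.integer(sizes[out$family_id])
  out$is_paralog_family <- out$family_size >= 2L
  # partition invariant: family sizes (one per family) sum to proteome size
  stopifnot(sum(sizes) == length(protein_ids),
            nrow(out) == length(protein_ids))
  out[match(protein_ids, out$protein_id), , drop = FALSE]
}

#' Family table for one genome record
#'
#' Convenience wrapper: search, cutoffs, family construction.
#'
#' @param record A [genome_record].
#' @param ... Passed to [all_vs_all_search] and [apply_cutoffs].
#' @export
proteome_families <- function(record, min_coverage = 50, min_identity = 50,
                              max_evalue = 1e-5, ...) {
  hits <- all_vs_all_search(record$proteins, ...)
  kept <- apply_cutoffs(hits, min_coverage, min_identity, max_evalue)
  build_families(record$proteins$protein_id, kept)
}

#' Percentage of proteins in paralog families
#'
#' The percent of proteins (of one COG category, or of the whole proteome)
#' that belong to families of size two or more. A category with no proteins
#' yields `NA` (undefined, not zero).
#'
#' @param families Family table from [build_families].
#' @param proteins Proteins data.frame with `protein_id` and `cog_category`.
#' @param category Optional single-letter COG category.
#' @export
paralog_fraction <- function(families, proteins, category = NULL) {
  stopifnot(setequal(families$protein_id, proteins$protein_id))
  in_paralog <- families$is_paralog_family[
    match(proteins$protein_id, families$protein_id)]
  if (!is.null(category)) {
    sel <- !is.na(proteins$cog_category) & proteins$cog_category == category
    if (!any(sel)) return(NA_real_)
    in_paralog <- in_paralog[sel]
  }
  100 * mean(in_paralog)
}
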