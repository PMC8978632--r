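# Quality gating, ANI estimation and species clustering.
#
# Genomes pass the quality gate only with completeness strictly above and
# contamination strictly below the cutoffs (80/5 by default; the intergenic
# analysis re-filters at 97/2). Species clusters are single-linkage connected
# components of the >= 95% ANI graph, and every cluster contributes one
# analysis point: the arithmetic mean of its members' traits.

#' Filter genomes by assembly quality
#'
#' A genome is retained iff `completeness > min_completeness` and
#' `contamination < max_contamination` (both strict).
#'
#' @param records List of [genome_record] objects, each with a quality slot.
#' @param min_completeness,max_contamination Percent cutoffs (defaults 80, 5).
#' @return The retained subset of `records`.
#' @export
quality_filter <- function(records, min_completeness = 80,
                           max_contamination = 5) {
  keep <- vapply(records, function(r) {
    if (is.null(r$quality)) stop("genome ", r$genome_id, " lacks quality data")
    r$quality$completeness > min_completeness &&
      r$quality$contamination < max_contamination
  }, TRUE)
  records[keep]
}

#' Growth-range midpoint
#'
#' When a strain's optimal growth pH is not reported, it is taken as the
#' midpoint of the reported growth range.
#'
#' @param ph_min,ph_max Range endpoints, `ph_min <= ph_max`.
#' @return `(ph_min + ph_max) / 2`.
#' @export
midpoint_ph <- function(ph_min, ph_max) {
  if (any(ph_min > ph_max)) stop("ph_min exceeds ph_max")
  (ph_min + ph_max) / 2
}

# Canonical k-mer set of a nucleotide sequence (lexicographic minimum of each
# k-mer and its reverse complement), as a character vector of unique k-mers.
canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character())
  fwd <- substring(seq, 1:(n - k + 1L), k:n)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rck <- rev(substring(rc, 1:(n - k + 1L), k:n))
  unique(pmin(fwd, rck))
}

genome_kmer_set <- function(record, k) {
  seqs <- if (inherits(record, "genome_record")) record$contigs else record
  unique(unlist(lapply(seqs, canonical_kmers, k = k), use.names = FALSE))
}

#' Estimate average nucleotide identity from k-mer sets
#'
#' A Mash-style estimator: the Jaccard index `j` of the two genomes'
#' canonical k-mer sets (full sets, no sketching) is converted to an identity
#' estimate by `ANI = 100 * (1 + log(2 j / (1 + j)) / k)`. Identical genomes
#' give 100; disjoint k-mer sets give `NA` ("undetected"). A precomputed ANI
#' matrix can be supplied to the clustering step instead to bypass the
#' estimator entirely.
#'
#' @param genome_a,genome_b [genome_record] objects or character vectors of
#'   contig sequences.
#' @param k K-mer size (default 21; values below 11 are refused as the
#'   estimator is unreliable there).
#' @return ANI estimate in percent, or `NA_real_` when undetected.
#' @export
estimate_ani <- function(genome_a, genome_b, k = 21L) {
  if (k < 11L) stop("k-mer size below 11 is unreliable for ANI estimation")
  ka <- genome_kmer_set(genome_a, k)
  kb <- genome_kmer_set(genome_b, k)
  if (!length(ka) || !length(kb)) stop("empty genome")
  inter <- length(intersect(ka, kb))
  uni <- length(ka) + length(kb) - inter
  j <- inter / uni
  if (j == 0) return(NA_real_)
  max(0, min(100, 100 * (1 + log(2 * j / (1 + j)) / k)))
}

#' Pairwise ANI for a cohort
#'
#' @param records List of [genome_record] objects.
#' @param k K-mer size passed to [estimate_ani].
#' @param supplied Optional precomputed ANI as a data.frame with columns
#'   `genome_a`, `genome_b`, `ani_percent` (pairs absent from the table are
#'   treated as undetected), or a path to such a TSV.
#' @return data.frame `genome_a`, `genome_b`, `ani_percent` with one row per
#'   unordered detected pair.
#' @export
ani_pairs <- function(records, k = 21L, supplied = NULL) {
  ids <- vapply(records, `[[`, "", "genome_id")
  if (!is.null(supplied)) {
    if (is.character(supplied))
      supplied <- utils::read.delim(supplied, stringsAsFactors = FALSE)
    sup <- supplied[supplied$genome_a %in% ids & supplied$genome_b %in% ids, ,
                    drop = FALSE]
    return(sup[!is.na(sup$ani_percent), c("genome_a", "genome_b",
                                          "ani_percent")])
  }
  if (length(records) < 2L)
    return(data.frame(genome_a = character(), genome_b = character(),
                      ani_percent = numeric(), stringsAsFactors = FALSE))
  sets <- lapply(records, genome_kmer_set, k = k)
  cmb <- utils::combn(length(records), 2L)
  ani <- apply(cmb, 2L, function(ij) {
    ka <- sets[[ij[1L]]]; kb <- sets[[ij[2L]]]
    inter <- length(intersect(ka, kb))
    j <- inter / (length(ka) + length(kb) - inter)
    if (j == 0) NA_real_
    else max(0, min(100, 100 * (1 + log(2 * j / (1 + j)) / k)))
  })
  out <- data.frame(genome_a = ids[cmb[1L, ]], genome_b = ids[cmb[2L, ]],
                    ani_percent = ani, stringsAsFactors = FALSE)
  out[!is.na(out$ani_percent), , drop = FALSE]
}

#' Group genomes into species clusters
#'
#' Single-linkage clustering: genomes are vertices, pairs with
#' `ANI >= ani_threshold` are edges, clusters are the connected components.
#' The cluster id is the lexicographically smallest member genome id, which
#' makes the clustering deterministic and invariant to input order.
#'
#' @param records List of [genome_record] objects (or a character vector of
#'   genome ids).
#' @param ani data.frame of detected pairs as returned by [ani_pairs].
#' @param ani_threshold Percent identity defining the species boundary
#'   (default 95, inclusive).
#' @return data.frame `genome_id`, `cluster_id`.
#' @export
cluster_species <- function(records, ani, ani_threshold = 95) {
  ids <- if (is.character(records)) records
         else vapply(records, `[[`, "", "genome_id")
  edges <- ani[!is.na(ani$ani_percent) &
                 ani$ani_percent >= ani_threshold &
                 ani$genome_a %in% ids & ani$genome_b %in% ids, ,
               drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("genome_a", "genome_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  cluster_id <- vapply(split(names(comp), comp), min, "")[as.character(comp)]
  out <- data.frame(genome_id = names(comp), cluster_id = unname(cluster_id),
                    stringsAsFactors = FALSE)
  out[match(ids, out$genome_id), , drop = FALSE]
}

#' Aggregate genome traits to species-cluster means
#'
#' Each cluster becomes a single analysis point: the arithmetic mean of every
#' numeric trait over the member genomes with that trait defined. The group
#' label is acidophile iff the mean pH optimum is below 5.
#'
#' @param traits data.frame of per-genome traits including `genome_id` and
#'   `ph_opt`.
#' @param membership data.frame `genome_id`, `cluster_id` from
#'   [cluster_species].
#' @return data.frame with one row per cluster: `cluster_id`, `n_genomes`,
#'   the trait means, and `group`.
#' @export
aggregate_clusters <- function(traits, membership) {
  stopifnot(nrow(membership) > 0)
  merged <- merge(traits, membership, by = "genome_id")
  num_cols <- setdiff(names(merged)[vapply(merged, is.numeric, TRUE)],
                      "cluster_id")
  split_rows <- split(seq_len(nrow(merged)), merged$cluster_id)
  rows <- lapply(names(split_rows), function(cid) {
    sub <- merged[split_rows[[cid]], , drop = FALSE]
    means <- vapply(num_cols, function(cn) mean(sub[[cn]], na.rm = TRUE),
                    numeric(1))
    cbind(data.frame(cluster_id = cid, n_genomes = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, rows)
  if ("ph_opt" %in% names(out))
    out$group <- ifelse(out$ph_opt < 5, "acidophile", "non_acidophile")
  out[order(out$cluster_id), , drop = FALSE]
}
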