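# Independent oracles used across the suite. Each re-derives the expected
# quantity by a route separate from the package implementation: full dynamic
# programming for local alignment, exhaustive outcome enumeration for the
# binomial test, hand step-up for BH, and depth-first search over explicit
# edge lists for family construction.

# Affine-gap Smith-Waterman by full dynamic programming (a gap of length L
# costs open + L * ext), returning only the optimal local score.
oracle_sw_score <- function(a, b, S, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1L]]
  b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(-Inf, n + 1L, m + 1L)
  Y <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext)
      Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext)
      M[i, j] <- max(0,
                     max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L]) + S[a[i - 1L], b[j - 1L]],
                     X[i, j], Y[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Exact two-sided binomial p-value by enumeration of all 2^n outcome
# sequences (small-probability-sum convention with the standard relative
# tolerance for floating ties).
oracle_binom_enum <- function(k, n, p0) {
  seqs <- expand.grid(rep(list(0:1), n))
  s <- rowSums(seqs)
  prob <- p0^s * (1 - p0)^(n - s)
  pk <- choose(n, k) * p0^k * (1 - p0)^(n - k)
  outcome_prob <- choose(n, s) * p0^s * (1 - p0)^(n - s)
  sum(prob[outcome_prob <= pk * (1 + 1e-7)])
}

# Benjamini-Hochberg adjusted values by the definitional step-up:
# q_(i) = min_{j >= i} ( m * p_(j) / j ), mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Connected components over an explicit undirected edge list by depth-first
# search, plus an independent derivation of the reciprocal-best-hit edge set
# from a hits table.
oracle_components <- function(ids, edges_a, edges_b) {
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  cid <- 0L
  for (root in ids) {
    if (!is.na(comp[root])) next
    cid <- cid + 1L
    stack <- root
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- c(edges_b[edges_a == v], edges_a[edges_b == v])
      stack <- c(stack, nb[is.na(comp[nb])])
    }
  }
  split(ids, comp[ids])
}

oracle_rbh_edges <- function(ids, hits, min_cov = 50, min_id = 50,
                             max_e = 1e-5) {
  kept <- hits[hits$coverage >= min_cov & hits$identity >= min_id &
                 hits$evalue <= max_e, , drop = FALSE]
  best_of <- function(q) {
    sub <- kept[kept$query_id == q, , drop = FALSE]
    if (!nrow(sub)) return(NA_character_)
    sub <- sub[order(-sub$score, sub$evalue, sub$subject_id), , drop = FALSE]
    sub$subject_id[1L]
  }
  best <- vapply(ids, best_of, "")
  ea <- character(); eb <- character()
  if (nrow(kept)) {
    for (r in seq_len(nrow(kept))) {
      a <- kept$query_id[r]; b <- kept$subject_id[r]
      if (identical(best[[a]], b) || identical(best[[b]], a)) {
        ea <- c(ea, min(a, b)); eb <- c(eb, max(a, b))
      }
    }
  }
  unique(data.frame(a = ea, b = eb, stringsAsFactors = FALSE))
}

# Random hits table over n proteins for the family-construction equivalence
# checks: symmetric scores, asymmetric coverage, occasional sub-cutoff rows.
random_hits_table <- function(ids) {
  n <- length(ids)
  cmb <- utils::combn(n, 2L)
  pick <- stats::runif(ncol(cmb)) < 0.3
  cmb <- cmb[, pick, drop = FALSE]
  if (!ncol(cmb))
    return(data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), identity = numeric(),
                      coverage = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  k <- ncol(cmb)
  score <- round(stats::runif(k, 20, 400))
  identity <- stats::runif(k, 30, 100)
  evalue <- 10^stats::runif(k, -40, -3)
  cov_ab <- stats::runif(k, 30, 100)
  cov_ba <- stats::runif(k, 30, 100)
  data.frame(
    query_id = c(ids[cmb[1L, ]], ids[cmb[2L, ]]),
    subject_id = c(ids[cmb[2L, ]], ids[cmb[1L, ]]),
    score = c(score, score), identity = c(identity, identity),
    coverage = c(cov_ab, cov_ba), evalue = c(evalue, evalue),
    stringsAsFactors = FALSE)
}

random_peptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

blosum62_for_tests <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# A small hand-built two-contig genome with three CDS features, written to
# disk for reader tests; returns the file paths and the expected objects.
write_toy_genome <- function(dir, omit_annotation_for = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- c(c1 = paste(rep("ACGT", 250), collapse = ""),  # 1000 bp
               c2 = paste(rep("GGCC", 125), collapse = ""))  # 500 bp
  feats <- data.frame(
    protein_id = c("p1", "p2", "p3"),
    contig_id = c("c1", "c1", "c2"),
    start = c(10L, 400L, 50L), end = c(309L, 699L, 349L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  prot_seqs <- stats::setNames(
    vapply(c(99L, 99L, 99L), random_peptide, ""),
    c("p1", "p2", "p3"))
  write_fasta_named(contigs, file.path(dir, "g.fna"))
  write_gff_cds(feats, file.path(dir, "g.gff"))
  write_fasta_named(prot_seqs, file.path(dir, "g.faa"))
  meta <- data.frame(genome_id = "g", species_label = "toy",
                     ph_opt = 3.2, ph_min = NA, ph_max = NA,
                     temp_opt = 30, gc_percent = 60)
  qual <- data.frame(genome_id = "g", completeness = 99, contamination = 0.5)
  anno <- data.frame(
    protein_id = c("p1", "p2", "p3"), genome_id = "g",
    cog_id = c("COG0001", "COG0002", ""),
    cog_category = c("L", "T", ""),
    pfam_ids = c("PF00001|1|1e-20", "PF00002|5|1e-10;PF00003|60|1e-08", ""),
    location = c("cytoplasmic", "inner_membrane", "exported"),
    has_signal_peptide = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  anno <- anno[!(anno$protein_id %in% omit_annotation_for), , drop = FALSE]
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(qual, file.path(dir, "qual.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(anno, file.path(dir, "anno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(dir = dir, contigs = contigs, feats = feats, prot_seqs = prot_seqs)
}
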