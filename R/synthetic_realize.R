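# Sequence realization of the synthetic cohort: emits FASTA/GFF3/protein
# FASTA per genome plus metadata, quality, annotation and ANI tables that
# read back through read_cohort() and reproduce the drawn traits.

AA_UNIF <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V")

CAT_BASE <- c(C = 0.07, D = 0.03, E = 0.08, F = 0.03, G = 0.06, H = 0.04,
              I = 0.03, J = 0.06, K = 0.07, L = 0.06, M = 0.05, N = 0.02,
              O = 0.04, P = 0.05, Q = 0.02, S = 0.15, T = 0.05, U = 0.03,
              V = 0.03)

LOC_BASE <- c(cytoplasmic = 0.45, inner_membrane = 0.18, periplasmic = 0.03,
              outer_membrane = 0.02, cell_wall = 0.01, exported = 0.04,
              unknown = 0.27)

OUTER_POOL <- c("periplasmic", "outer_membrane", "cell_wall", "exported")

random_protein <- function(len) {
  paste(sample(AA_UNIF, len, replace = TRUE), collapse = "")
}

mutate_string <- function(s, rate, alphabet) {
  n <- nchar(s)
  m <- stats::rbinom(1L, n, rate)
  if (m == 0L) return(s)
  pos <- sample.int(n, m)
  chars <- strsplit(s, "")[[1L]]
  chars[pos] <- vapply(chars[pos], function(c0)
    sample(setdiff(alphabet, c0), 1L), "")
  paste(chars, collapse = "")
}

random_genome_seq <- function(bp, gc) {
  p <- c(A = (100 - gc) / 200, C = gc / 200, G = gc / 200,
         T = (100 - gc) / 200)
  paste(sample(names(p), bp, replace = TRUE, prob = p), collapse = "")
}

weighted_category <- function(ph, slopes) {
  w <- CAT_BASE
  sl <- slopes[names(w)]
  sl[is.na(sl)] <- 0
  w <- w * exp(sl * (ph - 7))
  sample(names(w), 1L, prob = w)
}

weighted_location <- function(ph, slopes) {
  w <- LOC_BASE
  sl <- slopes[names(w)]
  sl[is.na(sl)] <- 0
  w <- w * exp(sl * (ph - 7))
  sample(names(w), 1L, prob = w)
}

# Build the species-level proteome with planted Pfam carriers, paralog
# duplicates and annotations. Returns a proteins data.frame plus the
# duplication map.
build_species_proteome <- function(sp, truth) {
  cfg <- truth$config
  ph <- sp$ph_opt
  n_orf <- sp$orf_count
  pf <- truth$pfams
  carriers <- list()
  if (nrow(pf)) {
    for (i in seq_len(nrow(pf))) {
      if (stats::runif(1) >= cfg$pfam_presence) next
      ncopy <- if (pf$extra_copy[i]) 2L else 1L
      for (cp in seq_len(ncopy)) {
        len <- max(50L, round(pf$base_len[i] +
                                pf$len_slope[i] * (ph - 7) +
                                stats::rnorm(1, 0, cfg$pfam_len_sd)))
        minor <- stats::runif(1) < pf$minor_arch_frac[i]
        arch <- if (minor)
          data.frame(pfam_id = c(pf$pfam_id[i], "PF99999"),
                     start = c(1L, max(2L, len - 40L)),
                     evalue = c(1e-30, 1e-12), stringsAsFactors = FALSE)
        else data.frame(pfam_id = pf$pfam_id[i], start = 1L,
                        evalue = 1e-30, stringsAsFactors = FALSE)
        carriers[[length(carriers) + 1L]] <- list(len = len, arch = arch)
      }
    }
  }
  n_car <- length(carriers)
  n_dup <- max(0L, round(cfg$paralog_rate * n_orf / 2))
  n_fill <- n_orf - n_car - n_dup
  if (n_fill < 1L)
    stop("infeasible geometry: planted proteins exceed ORF budget for ",
         sp$species_id)
  car_sum <- if (n_car) sum(vapply(carriers, `[[`, 0, "len")) else 0
  m_fill <- max(60, (n_orf * sp$mean_protein_len - car_sum) /
                  (n_fill + n_dup))
  fill_len <- pmin(pmax(round(stats::rnorm(n_fill, m_fill, 60)), 50L), 2500L)
  # paralog sources drawn among fillers; the copy diverges at the AA level
  dup_src <- if (n_dup) sample.int(n_fill, n_dup, replace = FALSE) else
    integer()
  lens <- c(vapply(carriers, `[[`, 0, "len"), fill_len, fill_len[dup_src])
  n_tot <- length(lens)
  ids <- sprintf("P%04d", seq_len(n_tot))
  seqs <- character(n_tot)
  for (i in seq_len(n_car + n_fill)) seqs[i] <- random_protein(lens[i])
  if (n_dup) {
    for (d in seq_len(n_dup)) {
      src <- n_car + dup_src[d]
      seqs[n_car + n_fill + d] <-
        mutate_string(seqs[src], cfg$duplicate_divergence, AA_UNIF)
    }
  }
  p_cog <- stats::plogis(stats::qlogis(cfg$cog_coverage_at_ph7) +
                           cfg$coverage_logodds_slope * (ph - 7))
  p_pfam_fill <- stats::plogis(stats::qlogis(cfg$pfam_coverage_at_ph7) +
                                 cfg$coverage_logodds_slope * (ph - 7))
  has_cog <- stats::runif(n_tot) < p_cog
  cat_lab <- ifelse(has_cog, vapply(seq_len(n_tot), function(i)
    weighted_category(ph, cfg$category_enrichment), ""), NA_character_)
  cog_id <- ifelse(has_cog,
                   sprintf("COG%04d", sample.int(4632L, n_tot,
                                                 replace = TRUE)),
                   NA_character_)
  loc <- vapply(seq_len(n_tot), function(i)
    weighted_location(ph, cfg$location_enrichment), "")
  sig <- ifelse(loc %in% OUTER_POOL, stats::runif(n_tot) < 0.8,
                stats::runif(n_tot) < 0.03)
  pfam_arch <- vector("list", n_tot)
  for (i in seq_len(n_car)) pfam_arch[[i]] <- carriers[[i]]$arch
  for (i in seq_len(n_fill)) {
    if (stats::runif(1) < p_pfam_fill) {
      pfam_arch[[n_car + i]] <- data.frame(
        pfam_id = sprintf("PFF%04d", sample.int(400L, 1L)),
        start = 1L, evalue = 10^stats::runif(1, -30, -6),
        stringsAsFactors = FALSE)
    }
  }
  if (n_dup) {
    for (d in seq_len(n_dup)) {
      src <- n_car + dup_src[d]; dst <- n_car + n_fill + d
      pfam_arch[dst] <- pfam_arch[src]  # single bracket: keeps NULLs
      cat_lab[dst] <- cat_lab[src]; cog_id[dst] <- cog_id[src]
      has_cog[dst] <- has_cog[src]; loc[dst] <- loc[src]; sig[dst] <- sig[src]
    }
  }
  proteins <- data.frame(protein_id = ids, sequence = seqs,
                         length = nchar(seqs),
                         cog_id = cog_id, cog_category = cat_lab,
                         location = loc, has_signal_peptide = sig,
                         stringsAsFactors = FALSE)
  proteins$pfam_ids <- lapply(pfam_arch, function(a)
    if (is.null(a)) parse_pfam_field("") else a)
  dup_map <- if (n_dup)
    data.frame(source = ids[n_car + dup_src],
               copy = ids[n_car + n_fill + seq_len(n_dup)],
               stringsAsFactors = FALSE)
  else data.frame(source = character(), copy = character(),
                  stringsAsFactors = FALSE)
  list(proteins = proteins, dup_map = dup_map)
}

# Lay the proteome out on a genome of the drawn size: random gene order and
# strands, intergenic budget spread over the gaps, contig breaks at gap
# boundaries. Longest non-carrier proteins are shed if the coding budget
# exceeds 97% of the genome.
layout_species_genome <- function(sp, proteins, truth) {
  cfg <- truth$config
  bp <- round(sp$genome_size_mb * 1e6)
  repeat {
    coding <- sum(3 * (proteins$length + 1))
    if (coding <= 0.97 * bp) break
    if (nrow(proteins) <= 2L)
      stop("infeasible geometry: ORFs exceed genome size for ",
           sp$species_id)
    drop <- which.max(proteins$length)
    proteins <- proteins[-drop, , drop = FALSE]
  }
  n <- nrow(proteins)
  ord <- sample.int(n)
  proteins <- proteins[ord, , drop = FALSE]
  gene_bp <- 3 * (proteins$length + 1)
  ig <- bp - sum(gene_bp)
  gaps <- as.vector(stats::rmultinom(1L, ig, rep(1, n + 1L)))
  # global 1-based gene start positions: gap_1 gene_1 gap_2 gene_2 ... gap_n+1
  starts <- numeric(n)
  pos <- 0
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos + 1
    pos <- pos + gene_bp[i]
  }
  nc <- sample(cfg$contigs_per_genome, 1L)
  nc <- min(nc, n)
  breaks <- if (nc > 1L) sort(sample(2:n, nc - 1L)) else integer()
  contig_of_gene <- findInterval(seq_len(n), c(1L, breaks))
  contig_start <- vapply(seq_len(nc), function(ci) {
    first <- which(contig_of_gene == ci)[1L]
    starts[first] - gaps[first]
  }, numeric(1))
  contig_end <- c(contig_start[-1L], bp + 1) - 1
  contig_ids <- sprintf("C%02d", seq_len(nc))
  features <- data.frame(
    protein_id = proteins$protein_id,
    contig_id = contig_ids[contig_of_gene],
    start = as.integer(starts - contig_start[contig_of_gene] + 1),
    end = as.integer(starts + gene_bp - 1 - contig_start[contig_of_gene] + 1),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  contig_len <- as.integer(contig_end - contig_start + 1)
  seq_full <- random_genome_seq(bp, sp$gc_percent)
  contigs <- stats::setNames(
    substring(seq_full, contig_start, contig_start + contig_len - 1),
    contig_ids)
  list(contigs = contigs, features = features, proteins = proteins)
}

#' Generate a synthetic cohort on disk
#'
#' Draws the ground truth ([draw_cohort_truth]) and realizes it as one FASTA
#' + GFF3 + protein FASTA triple per genome plus metadata, quality,
#' per-protein annotation and within-species ANI tables under `dir`.
#' Genomes of one species share the species layout and proteome and differ
#' by nucleotide substitutions at `within_species_divergence` (so
#' within-species ANI stays above the species threshold by construction);
#' about one genome in ten has its pH optimum written as a growth range
#' rather than an optimum, exercising the midpoint rule at read time. With
#' a fixed seed the output is byte-identical across runs.
#'
#' @param config A [cohort_config]; sequence realization at the default
#'   full study-scale geometry is expensive, so [desk_config] is the intended
#'   preset here.
#' @param dir Output directory (created).
#' @return List with `truth`, `dir` and a `manifest` of file paths suitable
#'   for [read_cohort].
#' @export
generate_cohort <- function(config = desk_config(), dir = tempfile()) {
  truth <- draw_cohort_truth(config)
  dir.create(file.path(dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  sp_build <- lapply(seq_len(nrow(truth$species)), function(i) {
    sp <- truth$species[i, ]
    pro <- build_species_proteome(sp, truth)
    lay <- layout_species_genome(sp, pro$proteins, truth)
    c(lay, list(dup_map = pro$dup_map, species = sp))
  })
  manifest <- list(genome_fastas = character(), gffs = character(),
                   protein_fastas = character())
  meta_rows <- list(); qual_rows <- list(); anno_rows <- list()
  dup_rows <- list()
  for (b in sp_build) {
    sp <- b$species
    g <- truth$genomes[truth$genomes$species_id == sp$species_id, ,
                       drop = FALSE]
    for (j in seq_len(nrow(g))) {
      gid <- g$genome_id[j]
      contigs <- vapply(b$contigs, function(s)
        mutate_string(s, truth$config$within_species_divergence,
                      c("A", "C", "G", "T")), "")
      names(contigs) <- paste0(gid, "_", names(b$contigs))
      feats <- b$features
      feats$contig_id <- paste0(gid, "_", feats$contig_id)
      feats$protein_id <- paste0(gid, "_", feats$protein_id)
      prots <- b$proteins
      prots$protein_id <- paste0(gid, "_", prots$protein_id)
      fna <- file.path(dir, "genomes", paste0(gid, ".fna"))
      gff <- file.path(dir, "genomes", paste0(gid, ".gff"))
      faa <- file.path(dir, "genomes", paste0(gid, ".faa"))
      write_fasta_named(contigs, fna)
      write_gff_cds(feats, gff)
      write_fasta_named(stats::setNames(prots$sequence, prots$protein_id),
                        faa)
      manifest$genome_fastas[gid] <- fna
      manifest$gffs[gid] <- gff
      manifest$protein_fastas[gid] <- faa
      as_range <- (j == 1L) && (stats::runif(1) < 0.1)
      meta_rows[[gid]] <- data.frame(
        genome_id = gid, species_label = sp$species_id,
        ph_opt = if (as_range) NA_real_ else sp$ph_opt,
        ph_min = if (as_range) sp$ph_opt - 0.5 else NA_real_,
        ph_max = if (as_range) sp$ph_opt + 0.5 else NA_real_,
        temp_opt = sp$temp_opt, gc_percent = sp$gc_percent,
        stringsAsFactors = FALSE)
      qual_rows[[gid]] <- data.frame(
        genome_id = gid, completeness = g$completeness[j],
        contamination = g$contamination[j], stringsAsFactors = FALSE)
      has_anno <- !is.na(prots$cog_id) |
        vapply(prots$pfam_ids, nrow, 0L) > 0L |
        prots$location != "unknown" | prots$has_signal_peptide
      if (any(has_anno)) {
        sub <- prots[has_anno, , drop = FALSE]
        anno_rows[[gid]] <- data.frame(
          protein_id = sub$protein_id, genome_id = gid,
          cog_id = ifelse(is.na(sub$cog_id), "", sub$cog_id),
          cog_category = ifelse(is.na(sub$cog_category), "",
                                sub$cog_category),
          pfam_ids = vapply(sub$pfam_ids, format_pfam_field, ""),
          location = sub$location,
          has_signal_peptide = sub$has_signal_peptide,
          stringsAsFactors = FALSE)
      }
      if (nrow(b$dup_map))
        dup_rows[[gid]] <- data.frame(
          genome_id = gid,
          source = paste0(gid, "_", b$dup_map$source),
          copy = paste0(gid, "_", b$dup_map$copy),
          stringsAsFactors = FALSE)
    }
  }
  manifest$metadata_tsv <- file.path(dir, "metadata.tsv")
  manifest$quality_tsv <- file.path(dir, "quality.tsv")
  manifest$annotation_tsv <- file.path(dir, "annotations.tsv")
  manifest$ani_tsv <- file.path(dir, "ani.tsv")
  utils::write.table(do.call(rbind, meta_rows), manifest$metadata_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, qual_rows), manifest$quality_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, anno_rows), manifest$annotation_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$ani, manifest$ani_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth$dup_map <- do.call(rbind, dup_rows)
  list(truth = truth, dir = dir, manifest = manifest)
}
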