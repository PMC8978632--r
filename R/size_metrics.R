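# Per-genome quantities that decompose genome size change along the pH
# gradient: genome size (Mb), ORF count, intergenic-space percentage, mean
# protein length and G+C content.

#' Genome size in megabase pairs
#' @param record A [genome_record].
#' @return Sum of contig lengths divided by 1e6.
#' @export
genome_size_mb <- function(record) {
  if (!length(record$contigs)) stop("genome has no contigs")
  sum(nchar(record$contigs)) / 1e6
}

#' Number of annotated protein-coding genes (ORFs)
#' @param record A [genome_record].
#' @export
orf_count <- function(record) {
  nrow(record$features)
}

#' Intergenic-space percentage
#'
#' `100 * (genome bp - sum of ORF nucleotide lengths) / genome bp`, the
#' complement of coding density. The sum is taken over feature extents as
#' annotated, so overlapping ORFs are double-counted and the value can go
#' negative (a warning is emitted). The merged-interval coding density is
#' available via [coding_density_merged] as a diagnostic.
#'
#' @param record A [genome_record].
#' @return Percent of the genome not covered by (possibly overlapping) ORFs.
#' @export
intergenic_percent <- function(record) {
  gbp <- sum(nchar(record$contigs))
  if (gbp == 0) stop("zero-length genome")
  coding <- sum(record$features$end - record$features$start + 1)
  ig <- 100 * (gbp - coding) / gbp
  if (ig < 0)
    warning("negative intergenic percentage (overlapping ORFs double-counted)")
  ig
}

#' Merged-interval coding density (diagnostic)
#'
#' Percent of genome positions covered by at least one ORF, with overlapping
#' features merged per contig before summing.
#'
#' @param record A [genome_record].
#' @export
coding_density_merged <- function(record) {
  gbp <- sum(nchar(record$contigs))
  if (gbp == 0) stop("zero-length genome")
  f <- record$features
  if (!nrow(f)) return(0)
  covered <- sum(vapply(split(f, f$contig_id), function(sub) {
    o <- order(sub$start)
    s <- sub$start[o]; e <- sub$end[o]
    tot <- 0L; cur_s <- s[1L]; cur_e <- e[1L]
    for (i in seq_along(s)[-1L]) {
      if (s[i] <= cur_e + 1L) cur_e <- max(cur_e, e[i])
      else { tot <- tot + cur_e - cur_s + 1L; cur_s <- s[i]; cur_e <- e[i] }
    }
    tot + cur_e - cur_s + 1L
  }, numeric(1)))
  100 * covered / gbp
}

#' Mean predicted protein length
#' @param record A [genome_record].
#' @return Arithmetic mean length in residues.
#' @export
mean_protein_length <- function(record) {
  if (!nrow(record$proteins)) stop("empty proteome")
  mean(record$proteins$length)
}

#' G+C content of the genome
#'
#' `100 * (G + C) / (A + C + G + T)`; IUPAC ambiguity codes are excluded from
#' both numerator and denominator.
#'
#' @param record A [genome_record] or character vector of sequences.
#' @export
gc_percent <- function(record) {
  seqs <- if (inherits(record, "genome_record")) record$contigs else record
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(toupper(seqs)))[, c("A", "C", "G", "T"),
                                             drop = FALSE])
  100 * (counts[["G"]] + counts[["C"]]) / sum(counts)
}

#' Trait table for a cohort
#'
#' One row per genome with the size-decomposition metrics and the growth
#' metadata and quality values needed downstream.
#'
#' @param records List of [genome_record] objects.
#' @param measured_gc Use the sequence-measured G+C (default) rather than the
#'   metadata value.
#' @return data.frame keyed by `genome_id`.
#' @export
genome_traits <- function(records, measured_gc = TRUE) {
  rows <- lapply(records, function(r) {
    data.frame(
      genome_id = r$genome_id,
      species_label = if (!is.null(r$metadata)) r$metadata$species_label
                      else NA_character_,
      genome_size_mb = genome_size_mb(r),
      orf_count = orf_count(r),
      ig_percent = intergenic_percent(r),
      mean_protein_len = if (nrow(r$proteins)) mean_protein_length(r)
                         else NA_real_,
      gc_percent = if (measured_gc) gc_percent(r)
                   else r$metadata$gc_percent,
      ph_opt = if (!is.null(r$metadata)) r$metadata$ph_opt else NA_real_,
      temp_opt = if (!is.null(r$metadata)) r$metadata$temp_opt else NA_real_,
      completeness = if (!is.null(r$quality)) r$quality$completeness
                     else NA_real_,
      contamination = if (!is.null(r$quality)) r$quality$contamination
                      else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
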