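# Tab-separated tables use UTF-8 and '.' as the decimal mark throughout.
# GFF3 coordinates are 1-based inclusive; only CDS rows are consumed and the
# protein identifier is taken from the ID attribute (prokka-style output).

VALID_LOCATIONS <- c("cytoplasmic", "inner_membrane", "periplasmic",
                     "outer_membrane", "cell_wall", "exported", "unknown")

#' Construct a genome record
#'
#' The central per-genome container: contig sequences, CDS features, the
#' predicted proteome with its annotations, growth metadata and assembly
#' quality. Invariants are checked at construction: every feature must lie on
#' a known contig within its bounds, every feature must have exactly one
#' protein with a matching identifier, and contig sequences may contain only
#' IUPAC nucleotide codes.
#'
#' @param genome_id Genome identifier.
#' @param contigs Named character vector of nucleotide sequences.
#' @param features data.frame with columns `protein_id`, `contig_id`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates).
#' @param proteins data.frame with columns `protein_id`, `sequence`,
#'   `length`, `cog_id`, `cog_category`, `pfam_ids` (list column of
#'   data.frames with `pfam_id`, `start`, `evalue`), `location`,
#'   `has_signal_peptide`.
#' @param metadata Named list with `species_label`, `ph_opt`, `temp_opt`,
#'   `gc_percent`; the `group` label (acidophile iff `ph_opt < 5`) is derived.
#' @param quality Named list with `completeness` and `contamination` (%).
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, features, proteins,
                          metadata = NULL, quality = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must be uniquely named")
  bad_nt <- grepl("[^ACGTUMRWSYKVHDBN]", toupper(contigs))
  if (any(bad_nt))
    stop("contig ", names(contigs)[which(bad_nt)[1L]],
         " contains non-IUPAC nucleotide codes")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  if (nrow(features)) {
    missing_contig <- setdiff(features$contig_id, names(contigs))
    if (length(missing_contig))
      stop("feature contig not in assembly: ", missing_contig[1L])
    if (any(features$end < features$start))
      stop("feature with end < start: ",
           features$protein_id[which(features$end < features$start)[1L]])
    clen <- nchar(contigs)[features$contig_id]
    if (any(features$end > clen))
      stop("feature extends beyond contig end: ",
           features$protein_id[which(features$end > clen)[1L]])
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'")
    orphan <- setdiff(features$protein_id, proteins$protein_id)
    if (length(orphan))
      stop("protein in features absent from proteome: ", orphan[1L])
    if (anyDuplicated(features$protein_id))
      stop("duplicated feature protein_id")
  }
  if (nrow(proteins)) {
    if (!all(nchar(proteins$sequence) == proteins$length))
      stop("protein length field disagrees with sequence")
    if (any(proteins$length <= 0)) stop("zero-length protein")
    if (!all(proteins$location %in% VALID_LOCATIONS))
      stop("invalid subcellular location label")
    no_cog <- is.na(proteins$cog_id) & !is.na(proteins$cog_category)
    if (any(no_cog)) stop("cog_category present without cog_id")
  }
  if (!is.null(metadata)) {
    if (!is.na(metadata$ph_opt) &&
        (metadata$ph_opt <= 0 || metadata$ph_opt > 14))
      stop("ph_opt outside (0, 14]")
    metadata$group <-
      if (is.na(metadata$ph_opt)) NA_character_
      else if (metadata$ph_opt < 5) "acidophile" else "non_acidophile"
  }
  if (!is.null(quality)) {
    if (quality$completeness < 0 || quality$completeness > 100 ||
        quality$contamination < 0)
      stop("quality values out of range")
  }
  structure(list(genome_id = genome_id, contigs = contigs,
                 features = features, proteins = proteins,
                 metadata = metadata, quality = quality),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, ": ",
      length(x$contigs), " contig(s), ",
      nrow(x$features), " CDS, ",
      nrow(x$proteins), " proteins", sep = "")
  if (!is.null(x$metadata))
    cat(", pH opt ", x$metadata$ph_opt, sep = "")
  cat("\n")
  invisible(x)
}

empty_proteins_df <- function() {
  data.frame(protein_id = character(), sequence = character(),
             length = integer(), cog_id = character(),
             cog_category = character(),
             location = character(), has_signal_peptide = logical(),
             stringsAsFactors = FALSE)
}

#' Read CDS features from a GFF3 file
#'
#' Only `CDS` rows are consumed; the protein identifier is taken from the
#' `ID` attribute. Coordinates are 1-based inclusive.
#'
#' @param path GFF3 file path.
#' @return data.frame with `protein_id`, `contig_id`, `start`, `end`, `strand`.
#' @export
read_gff_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(protein_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 9L
  parts <- parts[ok]
  type <- vapply(parts, `[[`, "", 3L)
  parts <- parts[type == "CDS"]
  if (!length(parts))
    return(data.frame(protein_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  attr9 <- vapply(parts, `[[`, "", 9L)
  id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", attr9)
  data.frame(protein_id = id,
             contig_id = vapply(parts, `[[`, "", 1L),
             start = as.integer(vapply(parts, `[[`, "", 4L)),
             end = as.integer(vapply(parts, `[[`, "", 5L)),
             strand = vapply(parts, `[[`, "", 7L),
             stringsAsFactors = FALSE)
}

write_gff_cds <- function(features, path, source = "streamlinr") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    writeLines(paste(features$contig_id, source, "CDS", features$start,
                     features$end, ".", features$strand, "0",
                     paste0("ID=", features$protein_id), sep = "\t"), con)
  }
  invisible(path)
}

read_fasta_named <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- as.character(set)
  # keep only the first word of the header, as annotation pipelines do
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

write_fasta_named <- function(seqs, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Annotation TSV: one row per annotated protein. pfam_ids encodes the domain
# architecture as ';'-separated entries "PFxxxxx|start|evalue", ordered along
# the sequence when parsed.
parse_pfam_field <- function(field) {
  if (is.na(field) || !nzchar(field))
    return(data.frame(pfam_id = character(), start = integer(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  entries <- strsplit(field, ";", fixed = TRUE)[[1L]]
  parts <- strsplit(entries, "|", fixed = TRUE)
  df <- data.frame(pfam_id = vapply(parts, `[[`, "", 1L),
                   start = as.integer(vapply(parts, `[[`, "", 2L)),
                   evalue = as.numeric(vapply(parts, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  df[order(df$start), , drop = FALSE]
}

format_pfam_field <- function(df) {
  if (is.null(df) || !nrow(df)) return("")
  df <- df[order(df$start), , drop = FALSE]
  paste(sprintf("%s|%d|%g", df$pfam_id, df$start, df$evalue), collapse = ";")
}

#' Read a cohort of genomes into genome records
#'
#' Assembles one [genome_record] per genome from a FASTA + GFF3 + protein
#' FASTA triple and the shared metadata, quality and per-protein annotation
#' tables. Proteins lacking an annotation row default to location `unknown`,
#' no COG/Pfam assignment and no signal peptide.
#'
#' @param genome_fastas,gffs,protein_fastas Named character vectors of file
#'   paths, names = genome ids (one triple per genome).
#' @param metadata_tsv TSV with columns `genome_id`, `species_label`,
#'   `ph_opt`, `ph_min`, `ph_max`, `temp_opt`, `gc_percent`. When `ph_opt` is
#'   missing but a growth range is given, the optimum is taken as the
#'   midpoint of the range (see [midpoint_ph]).
#' @param quality_tsv TSV with `genome_id`, `completeness`, `contamination`.
#' @param annotation_tsv TSV with `protein_id`, `genome_id`, `cog_id`,
#'   `cog_category`, `pfam_ids`, `location`, `has_signal_peptide`.
#' @return List of [genome_record] objects, one per genome.
#' @export
read_cohort <- function(genome_fastas, gffs, protein_fastas,
                        metadata_tsv, quality_tsv, annotation_tsv = NULL) {
  ids <- names(genome_fastas)
  stopifnot(!is.null(ids), identical(sort(ids), sort(names(gffs))),
            identical(sort(ids), sort(names(protein_fastas))))
  meta <- utils::read.delim(metadata_tsv, stringsAsFactors = FALSE)
  qual <- utils::read.delim(quality_tsv, stringsAsFactors = FALSE)
  anno <- if (!is.null(annotation_tsv))
    utils::read.delim(annotation_tsv, stringsAsFactors = FALSE,
                      colClasses = c(pfam_ids = "character")) else NULL
  lapply(ids, function(gid) {
    m <- meta[meta$genome_id == gid, , drop = FALSE]
    if (!nrow(m)) stop("missing metadata row for genome ", gid)
    q <- qual[qual$genome_id == gid, , drop = FALSE]
    if (!nrow(q)) stop("missing quality row for genome ", gid)
    ph <- m$ph_opt[1L]
    if (is.na(ph) && !is.null(m$ph_min) && !is.na(m$ph_min))
      ph <- midpoint_ph(m$ph_min[1L], m$ph_max[1L])
    contigs <- read_fasta_named(genome_fastas[[gid]], "DNA")
    feats <- read_gff_cds(gffs[[gid]])
    prots <- read_fasta_named(protein_fastas[[gid]], "AA")
    missing_prot <- setdiff(feats$protein_id, names(prots))
    if (length(missing_prot))
      stop("protein ", missing_prot[1L],
           " in GFF absent from protein FASTA for genome ", gid)
    pdf <- data.frame(protein_id = names(prots),
                      sequence = unname(prots),
                      length = nchar(prots),
                      cog_id = NA_character_, cog_category = NA_character_,
                      location = "unknown", has_signal_peptide = FALSE,
                      stringsAsFactors = FALSE)
    pdf$pfam_ids <- replicate(nrow(pdf), parse_pfam_field(""),
                              simplify = FALSE)
    if (!is.null(anno)) {
      a <- anno[anno$genome_id == gid, , drop = FALSE]
      idx <- match(pdf$protein_id, a$protein_id)
      hit <- !is.na(idx)
      pdf$cog_id[hit] <- ifelse(nzchar(a$cog_id[idx[hit]]) &
                                  !is.na(a$cog_id[idx[hit]]),
                                a$cog_id[idx[hit]], NA_character_)
      pdf$cog_category[hit] <- ifelse(!is.na(pdf$cog_id[hit]) &
                                        nzchar(a$cog_category[idx[hit]]) &
                                        !is.na(a$cog_category[idx[hit]]),
                                      a$cog_category[idx[hit]], NA_character_)
      pdf$location[hit] <- a$location[idx[hit]]
      pdf$has_signal_peptide[hit] <- as.logical(a$has_signal_peptide[idx[hit]])
      pdf$pfam_ids[hit] <- lapply(a$pfam_ids[idx[hit]], parse_pfam_field)
    }
    genome_record(
      genome_id = gid, contigs = contigs, features = feats, proteins = pdf,
      metadata = list(species_label = m$species_label[1L], ph_opt = ph,
                      temp_opt = m$temp_opt[1L],
                      gc_percent = m$gc_percent[1L]),
      quality = list(completeness = q$completeness[1L],
                     contamination = q$contamination[1L]))
  })
}

#' Write and read trait tables
#'
#' One row per genome or species cluster; values round-trip losslessly
#' through [read_trait_table] (full double precision is written).
#'
#' @param traits data.frame of computed traits.
#' @param path Output TSV path.
#' @export
write_trait_table <- function(traits, path) {
  df <- as.data.frame(traits)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
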