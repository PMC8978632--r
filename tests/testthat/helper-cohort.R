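# One desk-scale realized cohort shared across test files (generated once
# per test session; the generator itself is exercised separately).
.cohort_cache <- new.env(parent = emptyenv())

cached_desk_cohort <- function() {
  if (is.null(.cohort_cache$gen)) {
    gen <- generate_cohort(desk_config(seed = 7L),
                           dir = file.path(tempdir(), "desk_cohort"))
    m <- gen$manifest
    gen$records <- read_cohort(m$genome_fastas, m$gffs, m$protein_fastas,
                               m$metadata_tsv, m$quality_tsv,
                               m$annotation_tsv)
    .cohort_cache$gen <- gen
  }
  .cohort_cache$gen
}
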