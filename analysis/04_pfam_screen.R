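#!/usr/bin/env Rscript
# Stage 4: the conserved-Pfam protein-size screen on the study-scale
# cohort: selection (> 90% of species, >= 6 pH units span), per-Pfam
# Pearson trends over species-average carrier lengths, one BH family at
# q = 0.05, sign census and the exact sign binomial test.

suppressPackageStartupMessages(library(streamlinr))

tbl <- read_trait_table("results/cohort_traits/pfam_species_lengths.tsv")
tt <- read_trait_table("results/cohort_traits/genome_traits.tsv")
# one row per species in the trait cohort: species label = cluster id here
sp <- tt[!duplicated(tt$species_label), ]
ph <- stats::setNames(sp$ph_opt, sp$species_label)

# architectures column round-trips as text; rebuild the minimal structure
tbl$architectures <- lapply(tbl$pfam_id, function(p) {
  t <- table(p); t
})
scr <- screen_pfam_trends(tbl, ph)
cen <- trend_census(scr)
cat(sprintf("screened %d conserved Pfams: %d shrink at low pH, %d grow\n",
            nrow(scr), cen$n_positive, cen$n_negative))
cat(sprintf("ratio %.2f, sign binomial p = %.2g\n",
            cen$ratio, cen$binomial_p))

planted <- read_trait_table("results/cohort_traits/planted_pfams.tsv")
agree <- merge(scr, planted, by = "pfam_id")
cat(sprintf("sign agreement with planted slopes: %.1f%%\n",
            100 * mean((agree$sign == "positive") ==
                         (agree$len_slope > 0) &
                         (agree$sign == "negative") ==
                         (agree$len_slope < 0))))

write_trait_table(scr[, setdiff(names(scr), "architectures")],
                  "results/pfam_screen.tsv")
write_trait_table(data.frame(n_positive = cen$n_positive,
                             n_negative = cen$n_negative,
                             ratio = cen$ratio,
                             binomial_p = cen$binomial_p),
                  "results/pfam_census.tsv")
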