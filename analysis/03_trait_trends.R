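#!/usr/bin/env Rscript
# Stage 3: trait-vs-pH statistics on the study-scale trait cohort: quality
# gate, 95%-ANI species clusters, per-cluster means, Pearson and FGLS
# trends for genome size / ORF count / mean protein length, the stricter
# 97/2 re-gate for the intergenic analysis, and the 2-component PCA of
# pH, temperature, G+C and genome size.

suppressPackageStartupMessages(library(streamlinr))

tt <- read_trait_table("results/cohort_traits/genome_traits.tsv")
ani <- read_trait_table("results/cohort_traits/ani_pairs.tsv")

kept <- quality_filter_table(tt)
memb <- cluster_species(kept$genome_id, ani)
cl <- aggregate_clusters(kept, memb)
cat(sprintf("%d genomes pass 80/5; %d species clusters\n",
            nrow(kept), nrow(cl)))

trends <- trait_trends(cl, c("genome_size_mb", "orf_count",
                             "mean_protein_len"))
# intergenic space under the stricter 97/2 gate
strict <- quality_filter_table(tt, 97, 2)
ms <- cluster_species(strict$genome_id, ani)
cls <- aggregate_clusters(strict, ms)
cat(sprintf("stricter 97/2 gate: %d genomes, %d clusters\n",
            nrow(strict), nrow(cls)))
trends <- rbind(trends, trait_trends(cls, "ig_percent"))
print(trends[, c("trait_name", "n", "slope", "pearson_r", "p_value",
                 "gls_p_value")])
write_trait_table(trends, "results/trait_trends.tsv")
write_trait_table(cl, "results/cluster_traits.tsv")

# confounder correlations: temperature and G+C against size and pH
conf <- rbind(
  pearson_trend(cl$temp_opt, cl$genome_size_mb, "size_vs_temperature"),
  pearson_trend(cl$gc_percent, cl$genome_size_mb, "size_vs_gc"),
  pearson_trend(cl$ph_opt, cl$temp_opt, "temperature_vs_ph"),
  pearson_trend(cl$ph_opt, cl$gc_percent, "gc_vs_ph"))
print(conf[, c("trait_name", "n", "pearson_r", "p_value")])
write_trait_table(conf, "results/confounder_trends.tsv")

pca <- pca_biplot(cl[, c("ph_opt", "temp_opt", "gc_percent",
                         "genome_size_mb")])
print(pca)
write_trait_table(as.data.frame(pca$loadings), "results/pca_loadings.tsv")
write_trait_table(data.frame(
  component = c("PC1", "PC2"),
  explained = pca$explained_variance_fraction), "results/pca_explained.tsv")
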