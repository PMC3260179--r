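#!/usr/bin/env Rscript
# Principal component analysis of the four-group reference cohort's
# scaled allele-dosage matrix.

library(aimpanel)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

map <- unique(read.delim("results/data/reference_true_Q.tsv")[, c("population", "group")])
tab <- read_structure("results/data/reference_cohort.str", label_map = map,
                      loci = read.delim("results/data/panel_metadata.tsv"))
tab4 <- tab[tab$ind$group != "OCE", ]

pc <- genotype_pca(tab4, n_components = 5)
cat(sprintf("PC1-3 explain %.1f%% of the variance (PC1 %.1f, PC2 %.1f, PC3 %.1f)\n",
            sum(pc$percent_var_all[1:3]), pc$percent_var_all[1],
            pc$percent_var_all[2], pc$percent_var_all[3]))

write.table(data.frame(component = seq_along(pc$percent_var_all),
                       percent_var = round(pc$percent_var_all, 3)),
            "results/tables/pca_variance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
sc <- data.frame(sample_id = rownames(pc$scores), group = tab4$ind$group,
                 round(pc$scores, 4))
write.table(sc, "results/tables/pca_scores.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

df <- data.frame(PC1 = pc$scores[, 1], PC2 = pc$scores[, 2],
                 PC3 = pc$scores[, 3], group = tab4$ind$group)
g <- ggplot2::ggplot(df, ggplot2::aes(PC1, PC2, color = group)) +
  ggplot2::geom_point(size = 1) +
  ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pc$percent_var_all[1]),
                y = sprintf("PC2 (%.1f%%)", pc$percent_var_all[2])) +
  ggplot2::theme_minimal()
ggplot2::ggsave("results/figures/pca_pc1_pc2.png", g, width = 6, height = 5,
                dpi = 150)
cat("Scatter: results/figures/pca_pc1_pc2.png\n")
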