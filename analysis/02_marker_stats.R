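#!/usr/bin/env Rscript
# Marker-level characterization of the reference cohort: allele
# frequencies, delta informativeness ranking, pairwise F_ST, and the
# Hardy-Weinberg / linkage-disequilibrium null scans.

library(aimpanel)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

map <- read.delim("results/data/reference_true_Q.tsv")[, c("population", "group")]
tab <- read_structure("results/data/reference_cohort.str",
                      label_map = unique(map),
                      loci = read.delim("results/data/panel_metadata.tsv"))
tab4 <- tab[tab$ind$group != "OCE", ]

fr <- allele_freqs(tab4)
frd <- as.data.frame(fr)
frd$freq <- round(frd$freq, 4)
write.table(frd, "results/tables/allele_frequencies.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

rk <- rank_markers(fr)
write.table(cbind(rk[1], round(rk[-1], 4)), "results/tables/delta_ranking.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Loci with max pairwise delta >= 0.4: %d of 46\n",
            sum(rk$max_delta >= 0.4)))
cat(sprintf("Loci with max pairwise delta >= 0.3: %d of 46\n",
            sum(rk$max_delta >= 0.3)))

fst <- fst_matrix(tab4)
write.table(round(fst, 4), "results/tables/fst_pairwise.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat("Multi-locus pairwise F_ST:\n"); print(round(fst, 3))

hw <- hwe_scan(tab4, alpha = 0.05, n_perm = 1e4, seed = 7)
write.table(hw, "results/tables/hwe_scan.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("HWE scan: %d of %d tests significant after Bonferroni\n",
            sum(hw$significant), sum(!is.na(hw$p))))

ld <- ld_scan(tab4, n_perm = 1e4, max_exceed = 50, seed = 8)
write.table(ld, "results/tables/ld_scan.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("LD scan: %d of %d within-group pairs significant after Bonferroni\n",
            sum(ld$significant), nrow(ld)))
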