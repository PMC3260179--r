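#!/usr/bin/env Rscript
# Naive-Bayes population assignment with leave-one-out cross-validation,
# for the four-group and five-group reference cohorts.

library(aimpanel)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

map <- unique(read.delim("results/data/reference_true_Q.tsv")[, c("population", "group")])
tab <- read_structure("results/data/reference_cohort.str", label_map = map,
                      loci = read.delim("results/data/panel_metadata.tsv"))
tab4 <- tab[tab$ind$group != "OCE", ]

for (case in list(list(t = tab4, tag = "4group"), list(t = tab, tag = "5group"))) {
  cv <- nb_loocv(case$t, pseudocount = 1)
  cat(sprintf("%s LOOCV: %d of %d misclassified (%.2f%%)\n",
              case$tag, cv$n_errors, sum(cv$n), 100 * cv$error_rate))
  print(cv$confusion)
  write.table(cv$confusion,
              sprintf("results/tables/loocv_confusion_%s.tsv", case$tag),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(cv$assignments,
              sprintf("results/tables/loocv_assignments_%s.tsv", case$tag),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
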