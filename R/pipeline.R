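#' Match clusters to groups and extract self-membership
#'
#' Greedily assigns each cluster to the group with the highest mean
#' membership (largest means first), giving the diagonal of the
#' group-mean membership table — each group's average membership in "its
#' own" cluster.
#'
#' @param group_means groups x clusters matrix (e.g.
#'   `ensemble$group_means`).
#' @return list with `assignment` (named cluster index per group) and
#'   `self` (named self-membership vector).
#' @export
self_membership <- function(group_means) {
  gm <- as.matrix(group_means)
  G <- nrow(gm); K <- ncol(gm)
  .aim_assert(K >= G, "fewer clusters than groups")
  assignment <- setNames(rep(NA_integer_, G), rownames(gm))
  work <- gm
  for (step in seq_len(G)) {
    i <- which(work == max(work), arr.ind = TRUE)[1, ]
    assignment[rownames(work)[i[1]]] <- match(colnames(work)[i[2]], colnames(gm))
    work <- work[-i[1], -i[2], drop = FALSE]
  }
  self <- setNames(gm[cbind(seq_len(G), assignment[rownames(gm)])], rownames(gm))
  list(assignment = assignment, self = self)
}

#' Log probability of data across a range of K
#'
#' Runs `n_runs` chains at each K and reports the per-K mean lnPD, the
#' table usually plotted to choose the number of clusters.
#'
#' @param tab a [genotype_table()].
#' @param k_range integer vector of K values.
#' @param config base [admix_config()] (its `K` is overridden).
#' @return data frame with `K`, `lnPD_mean`, `lnPD_sd`, and one row per K.
#' @export
lnPD_by_K <- function(tab, k_range, config = admix_config(K = 1)) {
  rows <- lapply(k_range, function(k) {
    cfg <- config; cfg$K <- as.integer(k)
    lnpd <- vapply(seq_len(cfg$n_runs), function(r)
      run_admixture(tab, cfg, seed = cfg$seed + 100L * k + r)$lnPD,
      numeric(1))
    data.frame(K = k, lnPD_mean = mean(lnpd),
               lnPD_sd = if (length(lnpd) > 1) sd(lnpd) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Full reference-cohort analysis
#'
#' The complete characterization workflow for a labeled reference cohort:
#' allele frequencies, delta ranking, pairwise F_ST, Hardy-Weinberg and
#' linkage-disequilibrium scans, an aligned admixture ensemble at
#' `K = `number of groups (optionally a lnPD-by-K scan), PCA, and
#' leave-one-out classification.
#'
#' @param tab a [genotype_table()] with group labels.
#' @param config an [admix_config()]; `K` defaults to the number of
#'   groups.
#' @param k_range optional K values for a lnPD scan (`NULL` skips it).
#' @param ld_nperm,ld_max_exceed LD-scan permutation settings (`ld_nperm
#'   = 0` skips the scan).
#' @param hwe_nperm Monte-Carlo draws for multiallelic HWE tests.
#' @param outdir optional directory; when given, every table is written
#'   as TSV (3-decimal membership values).
#' @param seed master seed.
#' @return an `analysis_report` list with elements `freqs`, `delta`,
#'   `fst`, `hwe`, `ld`, `lnpd` (or NULL), `admixture` (ensemble),
#'   `group_means`, `self_membership`, `pca`, `loocv`, `provenance`.
#' @export
run_reference_analysis <- function(tab, config = NULL, k_range = NULL,
                                   ld_nperm = 1e4, ld_max_exceed = 50,
                                   hwe_nperm = 1e4, outdir = NULL,
                                   seed = 1L) {
  groups <- sort(unique(tab$ind$group))
  .aim_assert(!anyNA(groups), "reference analysis requires group labels")
  if (is.null(config)) config <- admix_config(K = length(groups), seed = seed)

  freqs <- allele_freqs(tab, by = "group")
  dtab <- rank_markers(freqs)
  fst <- fst_matrix(tab)
  hwe <- hwe_scan(tab, n_perm = hwe_nperm, seed = seed)
  ld <- if (ld_nperm > 0)
    ld_scan(tab, n_perm = ld_nperm, max_exceed = ld_max_exceed, seed = seed)
  else NULL
  lnpd <- if (!is.null(k_range)) lnPD_by_K(tab, k_range, config) else NULL
  ens <- admixture_ensemble(tab, config)
  sm <- self_membership(ens$group_means)
  pca <- genotype_pca(tab)
  cv <- nb_loocv(tab)

  report <- structure(list(
    freqs = freqs, delta = dtab, fst = fst, hwe = hwe, ld = ld,
    lnpd = lnpd, admixture = ens, group_means = ens$group_means,
    self_membership = sm, pca = pca, loocv = cv,
    provenance = .provenance(config, seed)), class = "analysis_report")
  if (!is.null(outdir)) write_report(report, tab, outdir)
  report
}

.provenance <- function(config, seed) {
  list(config = unclass(config), seed = seed,
       package_version = as.character(utils::packageVersion("aimpanel")),
       r_version = R.version.string,
       rng_kind = RNGkind()[1],
       timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
}

#' Supervised analysis of test samples against a reference
#'
#' Estimates ancestry membership of unlabeled test individuals using the
#' reference cohort as flagged training data ([supervised_estimate()]),
#' with an optional rerun excluding reference groups (e.g. a three-group
#' analysis of a tri-hybrid admixed population).
#'
#' @param ref,test [genotype_table()]s over the same panel.
#' @param config an [admix_config()] (K forced to the group count).
#' @param exclude_groups optional groups to drop in a second run.
#' @return list with `full` (supervised result) and `reduced` (result
#'   without the excluded groups, or NULL).
#' @export
run_test_samples <- function(ref, test, config = NULL, exclude_groups = NULL) {
  full <- supervised_estimate(ref, test, config)
  reduced <- if (!is.null(exclude_groups))
    supervised_estimate(ref, test, config, exclude_groups = exclude_groups)
  else NULL
  list(full = full, reduced = reduced)
}

#' Write the tables of an analysis report as TSV files
#'
#' Membership and frequency values are printed at 3 decimals.
#'
#' @param report an `analysis_report` from [run_reference_analysis()].
#' @param tab the analyzed [genotype_table()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, tab, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name, row = FALSE)
    write.table(x, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = row, col.names = if (row) NA else TRUE)
  fr <- as.data.frame(report$freqs)
  fr$freq <- round(fr$freq, 3)
  w(fr, "allele_frequencies.tsv")
  dt <- report$delta
  dt[-1] <- round(dt[-1], 3)
  w(dt, "delta_ranking.tsv")
  w(round(report$fst, 4), "fst_pairwise.tsv", row = TRUE)
  w(report$hwe, "hwe_scan.tsv")
  if (!is.null(report$ld)) w(report$ld, "ld_scan.tsv")
  if (!is.null(report$lnpd)) w(report$lnpd, "lnPD_by_K.tsv")
  export_q_matrix(report$admixture$Q, tab$ind,
                  file.path(outdir, "q_matrix.tsv"))
  w(round(report$group_means, 3), "group_mean_membership.tsv", row = TRUE)
  w(data.frame(component = seq_along(report$pca$percent_var_all),
               percent_var = round(report$pca$percent_var_all, 2)),
    "pca_variance.tsv")
  sc <- data.frame(sample_id = rownames(report$pca$scores),
                   group = tab$ind$group,
                   round(report$pca$scores[, seq_len(min(3, ncol(report$pca$scores))),
                                           drop = FALSE], 4))
  w(sc, "pca_scores.tsv")
  w(report$loocv$assignments, "loocv_assignments.tsv")
  w(as.data.frame(report$loocv$confusion), "loocv_confusion.tsv")
  writeLines(c(
    paste0("package_version\t", report$provenance$package_version),
    paste0("r_version\t", report$provenance$r_version),
    paste0("rng_kind\t", report$provenance$rng_kind),
    paste0("seed\t", report$provenance$seed),
    paste0("timestamp\t", report$provenance$timestamp),
    paste0("config\t", paste(names(report$provenance$config),
                             vapply(report$provenance$config, function(v)
                               paste(format(v), collapse = ","), character(1)),
                             sep = "=", collapse = "; "))),
    file.path(outdir, "provenance.tsv"))
  invisible(outdir)
}

#' Export a membership matrix as TSV
#'
#' @param Q individuals x clusters membership matrix.
#' @param ind individual metadata (`sample_id`, `population`, `group`).
#' @param path output file.
#' @return the exported data frame, invisibly.
#' @export
export_q_matrix <- function(Q, ind, path) {
  out <- data.frame(sample_id = ind$sample_id, population = ind$population,
                    group = ind$group, Q, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Stacked-bar plot of a membership matrix
#'
#' Each individual is one vertical segment divided into K colors by
#' membership. Individuals are sorted by group, then population, then
#' sample id (or by a user-supplied key); colors map deterministically to
#' cluster index.
#'
#' @param Q individuals x clusters membership matrix.
#' @param ind individual metadata with `sample_id`, `population`, `group`.
#' @param order_by optional precomputed ordering (integer vector).
#' @return a ggplot object.
#' @export
plot_q_barplot <- function(Q, ind, order_by = NULL) {
  if (is.null(order_by))
    order_by <- order(ind$group, ind$population, ind$sample_id)
  K <- ncol(Q)
  df <- data.frame(
    idx = rep(seq_along(order_by), K),
    group = rep(ind$group[order_by], K),
    cluster = factor(rep(colnames(Q) %||% paste0("cluster", 1:K),
                         each = length(order_by)),
                     levels = colnames(Q) %||% paste0("cluster", 1:K)),
    membership = c(Q[order_by, ]))
  ggplot2::ggplot(df, ggplot2::aes(x = idx, y = membership, fill = cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~group, scales = "free_x", space = "free_x") +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
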