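#' Permutation test of linkage disequilibrium between two loci
#'
#' Likelihood-ratio test of gametic association within one group:
#' haplotype frequencies are estimated by EM under linkage and compared
#' with the product of single-locus frequencies; the null distribution is
#' obtained by permuting one locus's genotypes across individuals (which
#' preserves both single-locus margins). The p-value is the add-one
#' permutation estimate `(1 + #{LR_perm >= LR_obs}) / (B + 1)`.
#'
#' `max_exceed` enables sequential early stopping for scans: once that
#' many permuted statistics have reached the observed one, the p-value
#' estimate is already far from any Bonferroni threshold and further
#' permutations are skipped.
#'
#' @param tab a [genotype_table()].
#' @param locusA,locusB marker ids or column indices.
#' @param group restrict to one group label (recommended: pooling groups
#'   creates spurious LD from population structure). `NULL` uses all
#'   individuals.
#' @param n_perm number of permutations (default 1e5 for a single pair).
#' @param seed integer seed.
#' @param max_exceed early-stopping threshold (default `Inf`: none).
#' @param by label column used for `group`.
#' @return list with `lr` (observed statistic), `p`, `n_perm_done`,
#'   `exceed`, `haplotype_freqs` (EM fit, loci alleles x alleles) and
#'   `n_used` (individuals observed at both loci).
#' @export
ld_test <- function(tab, locusA, locusB, group = NULL, n_perm = 1e5,
                    seed = 1L, max_exceed = Inf,
                    by = c("group", "population")) {
  by <- match.arg(by)
  rows <- seq_len(nrow(tab$a1))
  if (!is.null(group)) rows <- which(tab$ind[[by]] == group)
  lA <- if (is.character(locusA)) match(locusA, tab$loci$marker_id) else locusA
  lB <- if (is.character(locusB)) match(locusB, tab$loci$marker_id) else locusB
  ok <- rows[!is.na(tab$a1[rows, lA]) & !is.na(tab$a1[rows, lB])]
  .aim_assert(length(ok) >= 5, "fewer than 5 individuals observed at both loci")
  kA <- max(tab$alleles[[lA]]); kB <- max(tab$alleles[[lB]])
  mono <- function(l) length(unique(c(tab$a1[ok, l], tab$a2[ok, l]))) < 2
  if (mono(lA) || mono(lB)) {
    warning("monomorphic locus: LD test has no power, p = 1")
    return(list(lr = 0, p = 1, n_perm_done = 0L, exceed = 0L,
                haplotype_freqs = NULL, n_used = length(ok)))
  }
  res <- .ld_perm_cpp(tab$a1[ok, lA], tab$a2[ok, lA],
                      tab$a1[ok, lB], tab$a2[ok, lB],
                      kA, kB, as.integer(n_perm),
                      if (is.finite(max_exceed)) as.integer(max_exceed) else
                        as.integer(n_perm + 1L),
                      as.integer(seed))
  res$haplotype_freqs <- matrix(res$haplotype_freqs, kA, kB, byrow = TRUE,
                                dimnames = list(1:kA, 1:kB))
  res$n_used <- length(ok)
  res
}

#' Linkage-disequilibrium scan over all locus pairs within groups
#'
#' Runs [ld_test()] for every unordered locus pair within each group
#' separately and applies a Bonferroni correction across all tests. Early
#' stopping (`max_exceed`) keeps the scan fast: clearly null pairs stop
#' after a few hundred permutations while the estimate near the
#' significance threshold stays exact.
#'
#' @param tab a [genotype_table()] with labels.
#' @param by `"group"` or `"population"`.
#' @param n_perm permutations per pair (default 1e4 for the scan).
#' @param alpha family-wise level.
#' @param max_exceed early-stopping exceedance count (default 50).
#' @param seed integer seed.
#' @return data frame with `group`, `markerA`, `markerB`, `lr`, `p`,
#'   `n_perm_done`, `p_bonferroni`, `significant`.
#' @export
ld_scan <- function(tab, by = c("group", "population"), n_perm = 1e4,
                    alpha = 0.05, max_exceed = 50, seed = 1L) {
  by <- match.arg(by)
  groups <- sort(unique(tab$ind[[by]]))
  L <- ncol(tab$a1)
  prs <- combn(L, 2)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g, markerA = tab$loci$marker_id[prs[1, ]],
               markerB = tab$loci$marker_id[prs[2, ]],
               lr = NA_real_, p = NA_real_, n_perm_done = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  for (r in seq_len(nrow(out))) {
    res <- suppressWarnings(
      ld_test(tab, out$markerA[r], out$markerB[r], group = out$group[r],
              n_perm = n_perm, seed = seed + r, max_exceed = max_exceed,
              by = by))
    out$lr[r] <- res$lr; out$p[r] <- res$p
    out$n_perm_done[r] <- res$n_perm_done
  }
  n_tests <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(1, out$p * n_tests)
  out$significant <- !is.na(out$p) & out$p < alpha / n_tests
  out
}
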