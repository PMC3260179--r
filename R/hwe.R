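#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test of HWE from the genotype counts of one locus in
#' one group. Biallelic loci are tested by full enumeration: conditional
#' on the observed allele counts, every heterozygote count with the same
#' parity is enumerated and the p-value sums the probabilities of all
#' tables no more probable than the observed one (inclusive ordering).
#' Loci with three or more alleles use a seeded Monte-Carlo exact test
#' (random re-pairing of the observed allele copies, Guo-Thompson style)
#' with the same ordering rule and the add-one estimator
#' `p = (1 + #more extreme) / (B + 1)`.
#'
#' @param counts genotype counts: either a symmetric matrix / lower
#'   triangle indexed by allele, or a named vector like
#'   `c("1/1" = 3, "1/2" = 5, "2/2" = 2)`.
#' @param n_perm Monte-Carlo draws for loci with more than two alleles.
#' @param seed integer seed for the Monte-Carlo branch.
#' @return p-value in `(0, 1]`, or `NA` (with a warning) when no
#'   genotypes were observed.
#' @export
hwe_exact <- function(counts, n_perm = 1e5, seed = 1L) {
  m <- .as_geno_matrix(counts)
  n <- sum(m[lower.tri(m, diag = TRUE)])
  if (n == 0) {
    warning("no observed genotypes; HWE test undefined")
    return(NA_real_)
  }
  allele_counts <- rowSums(m) + colSums(m)  # copies of each allele
  active <- which(allele_counts > 0)
  if (length(active) <= 1) return(1)     # monomorphic: single possible table
  if (length(active) == 2) {
    het_obs <- m[max(active), min(active)] + m[min(active), max(active)]
    .hwe_exact_biallelic(allele_counts[active[1]], allele_counts[active[2]],
                         het_obs)
  } else {
    .hwe_mc(m[active, active, drop = FALSE], n_perm = n_perm, seed = seed)
  }
}

.as_geno_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
    # fold to lower triangle
    low <- lower.tri(m)
    m[low] <- m[low] + t(m)[low]
    m[upper.tri(m)] <- 0
    return(m)
  }
  .aim_assert(!is.null(names(counts)), "vector counts must be named like \"1/2\"")
  ali <- strsplit(names(counts), "/")
  codes <- sort(unique(as.integer(unlist(ali))))
  m <- matrix(0, length(codes), length(codes), dimnames = list(codes, codes))
  for (i in seq_along(counts)) {
    a <- sort(match(as.integer(ali[[i]]), codes))
    m[a[2], a[1]] <- m[a[2], a[1]] + counts[[i]]
  }
  m
}

# Full-enumeration biallelic exact test conditional on allele counts
# (Wigginton-style, computed via log factorials).
.hwe_exact_biallelic <- function(nA, nB, het_obs) {
  n <- (nA + nB) / 2
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hets == het_obs)
  .aim_assert(length(obs) == 1, "heterozygote count inconsistent with allele counts")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# log conditional probability of a genotype table given its allele counts
.log_table_prob <- function(m) {
  g <- m[lower.tri(m, diag = TRUE)]
  n <- sum(g)
  h <- sum(m[lower.tri(m)])
  ac <- rowSums(m) + colSums(m)
  lfactorial(n) - sum(lfactorial(g)) + h * log(2) +
    sum(lfactorial(ac)) - lfactorial(2 * n)
}

.hwe_mc <- function(m, n_perm, seed) {
  k <- nrow(m)
  ac <- rowSums(m) + colSums(m)
  obs_lp <- .log_table_prob(m)
  copies <- rep(seq_len(k), ac)
  n <- sum(ac) / 2
  exceed <- 0L
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(copies)
      a <- pmin(perm[seq_len(n)], perm[n + seq_len(n)])
      bb <- pmax(perm[seq_len(n)], perm[n + seq_len(n)])
      mm <- matrix(tabulate((a - 1L) * k + bb, k * k), k, k)
      if (.log_table_prob(mm) <= obs_lp + 1e-12) exceed <- exceed + 1L
    }
  })
  (1 + exceed) / (n_perm + 1)
}

# evaluate `expr` under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Hardy-Weinberg scan over all groups and loci
#'
#' Runs [hwe_exact()] for every (group, locus) combination and applies a
#' Bonferroni correction across the scan.
#'
#' @param tab a [genotype_table()] with labels.
#' @param by `"group"` or `"population"`.
#' @param alpha family-wise significance level (default 0.05).
#' @param n_perm,seed passed to [hwe_exact()] for multiallelic loci.
#' @return data frame with `group`, `marker_id`, `p`, `p_bonferroni`,
#'   `significant` (at the Bonferroni-adjusted threshold).
#' @export
hwe_scan <- function(tab, by = c("group", "population"), alpha = 0.05,
                     n_perm = 1e4, seed = 1L) {
  by <- match.arg(by)
  labels <- tab$ind[[by]]
  groups <- sort(unique(labels))
  out <- expand.grid(group = groups, marker_id = tab$loci$marker_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$p <- NA_real_
  for (r in seq_len(nrow(out))) {
    rows <- which(labels == out$group[r])
    l <- match(out$marker_id[r], tab$loci$marker_id)
    m <- .geno_count_matrix(tab$a1[rows, l], tab$a2[rows, l])
    out$p[r] <- if (sum(m) == 0) NA_real_ else
      suppressWarnings(hwe_exact(m, n_perm = n_perm, seed = seed + r))
  }
  n_tests <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(1, out$p * n_tests)
  out$significant <- !is.na(out$p) & out$p < alpha / n_tests
  out
}

.geno_count_matrix <- function(x1, x2, k = 3L) {
  ok <- !is.na(x1)
  a <- pmin(x1[ok], x2[ok]); b <- pmax(x1[ok], x2[ok])
  m <- matrix(0, k, k, dimnames = list(1:k, 1:k))
  tab <- table(factor(b, levels = 1:k), factor(a, levels = 1:k))
  m[] <- tab
  m
}
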