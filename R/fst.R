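#' Pairwise Weir-Cockerham F_ST between two groups
#'
#' Two-population Weir-Cockerham theta from genotype counts. For each
#' locus and allele the among-population (a), among-individual (b) and
#' within-individual (c) variance components are computed; multiallelic
#' loci sum components over alleles, per-locus theta is `a / (a + b + c)`
#' and the multi-locus estimate is the ratio of component sums over loci.
#' Loci monomorphic across both groups contribute zero components and are
#' excluded from the per-locus ratio (theta `NA`), not turned into `NaN`.
#'
#' @param tab a [genotype_table()] with group labels.
#' @param groupA,groupB group labels present in `tab`.
#' @param by `"group"` or `"population"` stratification.
#' @return list with `per_locus` (data frame: `marker_id`, `a`, `abc`,
#'   `theta`) and `theta` (multi-locus ratio-of-sums estimate).
#' @export
pairwise_fst <- function(tab, groupA, groupB, by = c("group", "population")) {
  by <- match.arg(by)
  labels <- tab$ind[[by]]
  rowsA <- which(labels == groupA); rowsB <- which(labels == groupB)
  .aim_assert(length(rowsA) >= 2 && length(rowsB) >= 2,
              "both groups need at least 2 individuals")
  L <- ncol(tab$a1)
  a_sum <- abc_sum <- numeric(L)
  for (l in seq_len(L)) {
    comp <- .wc_components(tab$a1[rowsA, l], tab$a2[rowsA, l],
                           tab$a1[rowsB, l], tab$a2[rowsB, l],
                           tab$alleles[[l]])
    a_sum[l] <- comp[1]; abc_sum[l] <- comp[2]
  }
  theta_locus <- ifelse(abc_sum == 0, NA_real_, a_sum / abc_sum)
  list(per_locus = data.frame(marker_id = tab$loci$marker_id,
                              a = a_sum, abc = abc_sum, theta = theta_locus,
                              stringsAsFactors = FALSE),
       theta = if (sum(abc_sum) == 0) NA_real_ else sum(a_sum) / sum(abc_sum))
}

# Weir & Cockerham (1984) variance components for r = 2 populations at one
# locus; returns c(sum_a, sum_a+b+c) over alleles.
.wc_components <- function(xa1, xa2, xb1, xb2, alleles) {
  okA <- !is.na(xa1); okB <- !is.na(xb1)
  n1 <- sum(okA); n2 <- sum(okB)
  if (n1 == 0 || n2 == 0) return(c(0, 0))
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  a_tot <- abc_tot <- 0
  for (j in alleles) {
    p1 <- (sum(xa1[okA] == j) + sum(xa2[okA] == j)) / (2 * n1)
    p2 <- (sum(xb1[okB] == j) + sum(xb2[okB] == j)) / (2 * n2)
    h1 <- sum(okA & xor(xa1 == j, xa2 == j), na.rm = TRUE) / n1
    h2 <- sum(okB & xor(xb1 == j, xb2 == j), na.rm = TRUE) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar == 0 || pbar == 1) next  # monomorphic for this allele
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a
    abc_tot <- abc_tot + a + b + cc
  }
  c(a_tot, abc_tot)
}

#' Multi-locus F_ST for every pair of groups
#'
#' @param tab a [genotype_table()] with group labels.
#' @param by `"group"` or `"population"`.
#' @return symmetric matrix of multi-locus theta (0 on the diagonal).
#' @export
fst_matrix <- function(tab, by = c("group", "population")) {
  by <- match.arg(by)
  groups <- sort(unique(tab$ind[[by]]))
  m <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
  if (length(groups) < 2) return(m)
  pairs <- combn(groups, 2)
  for (p in seq_len(ncol(pairs))) {
    th <- pairwise_fst(tab, pairs[1, p], pairs[2, p], by = by)$theta
    m[pairs[1, p], pairs[2, p]] <- m[pairs[2, p], pairs[1, p]] <- th
  }
  m
}
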