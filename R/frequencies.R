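#' Per-group allele frequencies
#'
#' Sample allele frequencies per group (or per population) and locus:
#' observed allele copies divided by `2 * n` observed copies. Missing
#' genotypes contribute nothing.
#'
#' @param tab a [genotype_table()].
#' @param by `"group"` (default) or `"population"`: which label defines
#'   the strata.
#' @return a `freq_table`: list with `freq` (groups x loci x allele-code
#'   array; frequencies over declared codes, 0 elsewhere), `copies`
#'   (groups x loci matrix of observed allele-copy counts `2n`), `groups`,
#'   `loci` (marker ids) and `alleles` (declared codes per locus).
#' @export
allele_freqs <- function(tab, by = c("group", "population")) {
  by <- match.arg(by)
  labels <- tab$ind[[by]]
  .aim_assert(!anyNA(labels), "missing %s labels; apply a label map first", by)
  groups <- sort(unique(labels))
  counts <- allele_counts(tab, labels, groups)
  freq_table(counts$counts, counts$copies, groups, tab)
}

# raw copy counts: G x L x 3 array + G x L copies matrix
allele_counts <- function(tab, labels, groups) {
  n <- nrow(tab$a1); L <- ncol(tab$a1)
  counts <- array(0, c(length(groups), L, 3L),
                  dimnames = list(groups, tab$loci$marker_id, 1:3))
  for (g in seq_along(groups)) {
    rows <- which(labels == groups[g])
    .aim_assert(length(rows) > 0, "empty group: %s", groups[g])
    for (j in 1:3) {
      counts[g, , j] <- colSums(tab$a1[rows, , drop = FALSE] == j, na.rm = TRUE) +
        colSums(tab$a2[rows, , drop = FALSE] == j, na.rm = TRUE)
    }
  }
  list(counts = counts, copies = apply(counts, c(1, 2), sum))
}

freq_table <- function(counts, copies, groups, tab) {
  freq <- counts / c(ifelse(copies == 0, 1, copies))
  structure(list(freq = freq, counts = counts, copies = copies,
                 groups = groups, loci = tab$loci$marker_id,
                 alleles = tab$alleles),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d groups x %d loci\n",
              length(x$groups), length(x$loci)))
  cat("groups:", paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a frequency table to a long-format data frame
#'
#' @param x a `freq_table`.
#' @param ... unused.
#' @return data frame with `group`, `marker_id`, `allele`, `freq`, `copies`.
#' @export
as.data.frame.freq_table <- function(x, ...) {
  out <- expand.grid(group = x$groups, marker_id = x$loci, allele = 1:3,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$freq <- c(x$freq)
  out$copies <- x$copies[cbind(match(out$group, x$groups),
                               match(out$marker_id, x$loci))]
  declared <- mapply(function(m, a) a %in% x$alleles[[match(m, x$loci)]],
                     out$marker_id, out$allele)
  out[declared, ]
}

#' Allele-frequency differential (delta)
#'
#' Half-L1 (total-variation) distance between two allele-frequency
#' vectors. For biallelic loci this reduces to the absolute difference of
#' one allele's frequencies, the classical ancestry-informativeness delta.
#'
#' @param pA,pB numeric frequency vectors over the same allele set, each
#'   summing to 1.
#' @return delta in `[0, 1]`.
#' @export
delta <- function(pA, pB) {
  .aim_assert(length(pA) == length(pB), "frequency vectors differ in length")
  .aim_assert(abs(sum(pA) - 1) < 1e-6 && abs(sum(pB) - 1) < 1e-6,
              "frequency vectors must each sum to 1")
  sum(abs(pA - pB)) / 2
}

#' Rank markers by maximum pairwise frequency differential
#'
#' Computes delta for every unordered pair of groups at every locus and
#' ranks loci by the maximum over pairs, the criterion used to select
#' ancestry-informative markers.
#'
#' @param freqs a `freq_table` from [allele_freqs()].
#' @param groups groups to compare (default: all in `freqs`; at least 2).
#' @return data frame sorted by decreasing `max_delta` (ties broken by
#'   `marker_id`), with one `delta` column per group pair
#'   (`"A.B"`) plus `max_delta`.
#' @export
rank_markers <- function(freqs, groups = freqs$groups) {
  .aim_assert(length(groups) >= 2, "need at least 2 groups")
  .aim_assert(all(groups %in% freqs$groups), "unknown group in `groups`")
  pairs <- combn(sort(groups), 2)
  out <- data.frame(marker_id = freqs$loci, stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    gA <- match(pairs[1, p], freqs$groups); gB <- match(pairs[2, p], freqs$groups)
    fa <- matrix(freqs$freq[gA, , ], ncol = 3)
    fb <- matrix(freqs$freq[gB, , ], ncol = 3)
    out[[paste(pairs[1, p], pairs[2, p], sep = ".")]] <- rowSums(abs(fa - fb)) / 2
  }
  dcols <- setdiff(names(out), "marker_id")
  out$max_delta <- do.call(pmax, out[dcols])
  out[order(-out$max_delta, out$marker_id), , drop = FALSE]
}
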