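#' Encode genotypes as an allele-dosage matrix
#'
#' One column per (locus, non-reference allele) pair — a single column for
#' a biallelic locus, two for a triallelic one — holding the number of
#' copies (0/1/2) of that allele. The first declared allele of each locus
#' is the implicit reference, so an individual's dosages at one locus sum
#' with the reference count to 2. Missing calls are imputed with the
#' column mean; constant columns are dropped (recorded in the `dropped`
#' attribute).
#'
#' @param tab a [genotype_table()].
#' @param impute impute missing cells with the column mean (default TRUE;
#'   otherwise they stay `NA`).
#' @return numeric matrix (individuals x dosage columns) with columns
#'   named `"<marker>.<allele>"`.
#' @export
encode_dosage <- function(tab, impute = TRUE) {
  cols <- list(); cn <- character()
  for (l in seq_len(ncol(tab$a1))) {
    ref <- tab$alleles[[l]][1]
    for (al in setdiff(tab$alleles[[l]], ref)) {
      d <- (tab$a1[, l] == al) + (tab$a2[, l] == al)
      cols[[length(cols) + 1L]] <- d
      cn <- c(cn, paste0(tab$loci$marker_id[l], ".", al))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- cn
  rownames(m) <- tab$ind$sample_id
  if (impute) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- mu[idx[, 2]]
  }
  keep <- apply(m, 2, function(x) sd(x, na.rm = TRUE) > 0)
  dropped <- colnames(m)[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " constant dosage column(s)")
  structure(m[, keep, drop = FALSE], dropped = dropped)
}

#' Principal component analysis of a genotype matrix
#'
#' Centers (and by default scales to unit variance) the dosage columns,
#' takes the singular-value decomposition, and reports per-component
#' percent variance. Component signs are fixed so that each component's
#' largest-magnitude loading is positive, making scores reproducible
#' across platforms.
#'
#' @param x a [genotype_table()] or a dosage matrix from
#'   [encode_dosage()].
#' @param n_components number of components to keep (default: all).
#' @param scale. scale columns to unit variance (default TRUE).
#' @return list with `scores` (individuals x components), `percent_var`
#'   (per kept component), `percent_var_all` (all components, summing to
#'   100), `rotation` and `sdev`.
#' @export
genotype_pca <- function(x, n_components = NULL, scale. = TRUE) {
  m <- if (inherits(x, "genotype_table")) encode_dosage(x) else x
  .aim_assert(nrow(m) >= 2, "need at least 2 individuals")
  .aim_assert(ncol(m) >= 1, "no non-constant dosage columns")
  fit <- prcomp(m, center = TRUE, scale. = scale.)
  pv <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components %||% ncol(fit$x), ncol(fit$x))
  scores <- fit$x[, seq_len(k), drop = FALSE]
  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # deterministic sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  list(scores = scores, percent_var = pv[seq_len(k)], percent_var_all = pv,
       rotation = rot, sdev = fit$sdev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
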