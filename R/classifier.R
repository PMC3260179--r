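#' Train a naive-Bayes population classifier
#'
#' Per-group, per-locus allele frequencies with additive smoothing:
#' `p = (count + c) / (2n + c * n_alleles)`. The pseudocount keeps every
#' declared allele's probability strictly positive so that alleles unseen
#' in training (e.g. group-private rare length variants) never produce
#' `-Inf` log-likelihoods. Genotype likelihoods assume Hardy-Weinberg
#' proportions within each group and independent loci.
#'
#' @param tab a [genotype_table()] with labels.
#' @param by `"group"` (default) or `"population"`.
#' @param pseudocount additive smoothing constant `c >= 0` (default 1);
#'   `c = 0` gives maximum-likelihood frequencies.
#' @return an object of class `nb_model`.
#' @export
nb_train <- function(tab, by = c("group", "population"), pseudocount = 1) {
  by <- match.arg(by)
  labels <- tab$ind[[by]]
  .aim_assert(!anyNA(labels), "missing %s labels", by)
  .aim_assert(pseudocount >= 0, "pseudocount must be nonnegative")
  groups <- sort(unique(labels))
  cc <- allele_counts(tab, labels, groups)
  .aim_assert(all(rowSums(cc$copies) > 0),
              "a group has zero observed allele copies at every locus")
  structure(list(groups = groups, counts = cc$counts, copies = cc$copies,
                 alleles = tab$alleles, loci = tab$loci$marker_id,
                 pseudocount = pseudocount),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("nb_model: %d groups x %d loci, pseudocount %g\n",
              length(x$groups), length(x$loci), x$pseudocount))
  invisible(x)
}

# smoothed frequency array G x L x 3 (0 for undeclared alleles)
.nb_freqs <- function(model) {
  G <- length(model$groups); L <- length(model$loci)
  n_all <- vapply(model$alleles, length, integer(1))
  declared <- array(0, c(G, L, 3))
  for (l in seq_len(L)) declared[, l, model$alleles[[l]]] <- 1
  cpc <- model$pseudocount
  denom <- model$copies + cpc * rep(n_all, each = G)
  f <- (model$counts + cpc * declared) / c(denom)
  f * declared
}

#' Per-group log-likelihood of a single genotype profile
#'
#' Sum over non-missing loci of the Hardy-Weinberg genotype
#' log-likelihood: `log(p_a^2)` for a homozygote, `log(2 p_a p_b)` for a
#' heterozygote, under each group's smoothed frequencies.
#'
#' @param model an [nb_train()] model.
#' @param a1,a2 integer allele vectors of one individual over the model's
#'   loci (`NA` = missing, skipped).
#' @return named numeric vector of log-likelihoods, one per group.
#' @export
profile_loglik <- function(model, a1, a2) {
  .aim_assert(length(a1) == length(model$loci) && length(a2) == length(a1),
              "profile length must match the model's panel")
  f <- .nb_freqs(model)
  .profile_loglik_freq(f, model$groups, a1, a2)
}

.profile_loglik_freq <- function(f, groups, a1, a2) {
  ok <- which(!is.na(a1))
  ll <- setNames(numeric(length(groups)), groups)
  if (!length(ok)) return(ll + NA_real_)
  G <- length(groups); L <- dim(f)[2]
  i1 <- cbind(rep(seq_len(G), length(ok)), rep(ok, each = G),
              rep(a1[ok], each = G))
  i2 <- i1; i2[, 3] <- rep(a2[ok], each = G)
  p1 <- matrix(f[i1], G); p2 <- matrix(f[i2], G)
  het <- rep(a1[ok] != a2[ok], each = G)
  terms <- log(p1) + log(p2) + log(2) * matrix(het, G)
  setNames(rowSums(terms), groups)
}

#' Classify one genotype profile
#'
#' Assigns the profile to the group with the highest Hardy-Weinberg
#' naive-Bayes likelihood and reports the likelihood ratio of the best
#' against the second-best group. Ties are broken lexicographically by
#' group name and flagged.
#'
#' @inheritParams profile_loglik
#' @return list with `best`, `second`, `loglik` (per-group vector), `lr`
#'   (`>= 1`), `log10_lr`, `tie` (logical), `n_loci_used`.
#' @export
nb_classify <- function(model, a1, a2) {
  ll <- profile_loglik(model, a1, a2)
  n_used <- sum(!is.na(a1))
  if (n_used == 0) {
    warning("profile has no observed loci; assignment undefined")
    return(list(best = NA_character_, second = NA_character_, loglik = ll,
                lr = NA_real_, log10_lr = NA_real_, tie = NA, n_loci_used = 0L))
  }
  ord <- order(-ll, names(ll))  # ties: lexicographic winner
  best <- names(ll)[ord[1]]; second <- names(ll)[ord[2]]
  d <- ll[[ord[1]]] - ll[[ord[2]]]
  list(best = best, second = second, loglik = ll,
       lr = exp(d), log10_lr = d / log(10),
       tie = abs(d) < 1e-9, n_loci_used = as.integer(n_used))
}

#' Leave-one-out cross-validation of the naive-Bayes classifier
#'
#' Each individual is removed from the training counts (decrement
#' update; identical to full retraining), classified, and tallied against
#' its true label.
#'
#' @inheritParams nb_train
#' @param method `"decrement"` (fast count update, default) or
#'   `"retrain"` (rebuild the model per individual; for verification).
#' @return list with `confusion` (true x predicted matrix), `errors`
#'   (per-group misclassification counts), `n` (per-group sizes),
#'   `n_errors`, `error_rate`, and `assignments` (per-individual data
#'   frame with `sample_id`, `true`, `predicted`, `log10_lr`, `tie`).
#' @export
nb_loocv <- function(tab, by = c("group", "population"), pseudocount = 1,
                     method = c("decrement", "retrain")) {
  by <- match.arg(by); method <- match.arg(method)
  labels <- tab$ind[[by]]
  groups <- sort(unique(labels))
  .aim_assert(all(table(labels) >= 2), "every group needs >= 2 individuals")
  model <- nb_train(tab, by = by, pseudocount = pseudocount)
  n <- nrow(tab$a1)
  pred <- character(n); l10 <- numeric(n); tie <- logical(n)
  for (i in seq_len(n)) {
    g <- match(labels[i], groups)
    if (method == "decrement") {
      m <- model
      for (slot in c("a1", "a2")) {
        al <- tab[[slot]][i, ]
        okl <- which(!is.na(al))
        idx <- cbind(g, okl, al[okl])
        m$counts[idx] <- m$counts[idx] - 1
        m$copies[cbind(g, okl)] <- m$copies[cbind(g, okl)] - 1
      }
    } else {
      m <- nb_train(tab[-i, ], by = by, pseudocount = pseudocount)
    }
    res <- nb_classify(m, tab$a1[i, ], tab$a2[i, ])
    pred[i] <- res$best; l10[i] <- res$log10_lr; tie[i] <- res$tie
  }
  confusion <- table(true = factor(labels, groups), predicted = factor(pred, groups))
  errors <- rowSums(confusion) - diag(confusion)
  list(confusion = unclass(confusion), errors = errors,
       n = rowSums(confusion), n_errors = sum(errors),
       error_rate = sum(errors) / n,
       assignments = data.frame(sample_id = tab$ind$sample_id, true = labels,
                                predicted = pred, log10_lr = l10, tie = tie,
                                stringsAsFactors = FALSE))
}
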