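#' Synthetic panel allele frequencies with a target delta profile
#'
#' Draws per-group allele frequencies for a panel of biallelic loci such
#' that the realized maximum pairwise frequency differential of each locus
#' equals the requested target. For locus `i` a rotating pair of groups is
#' set `delta_profile[i]` apart (the low frequency drawn uniformly within
#' the feasible band) and the remaining groups are drawn uniformly between
#' the two, so no other pair exceeds the target. Deterministic under
#' `seed`; R's Mersenne-Twister generator is used throughout the package.
#'
#' @param K number of ancestral groups (>= 2).
#' @param n_loci number of loci.
#' @param delta_profile numeric vector (recycled to `n_loci`) of target
#'   per-locus maximum deltas in `(0, 1]`.
#' @param seed integer seed.
#' @param groups group names (default `G1..GK`).
#' @param marker_ids locus names (default `L001..`).
#' @return matrix (groups x loci) of allele-1 frequencies, with the
#'   realized target as attribute `target_delta`.
#' @export
make_panel_frequencies <- function(K, n_loci, delta_profile, seed = 1L,
                                   groups = paste0("G", seq_len(K)),
                                   marker_ids = sprintf("L%03d", seq_len(n_loci))) {
  .aim_assert(K >= 2, "need K >= 2 groups")
  .aim_assert(all(delta_profile > 0 & delta_profile <= 1),
              "delta targets must lie in (0, 1]")
  d <- rep_len(delta_profile, n_loci)
  pairs <- combn(K, 2)
  p <- matrix(NA_real_, K, n_loci, dimnames = list(groups, marker_ids))
  .with_seed(seed, {
    for (l in seq_len(n_loci)) {
      pr <- pairs[, (l - 1L) %% ncol(pairs) + 1L]
      lo_max <- 1 - d[l]
      margin <- min(0.02, lo_max / 2)
      lo <- runif(1, margin, lo_max - margin)
      p[pr[1], l] <- lo
      p[pr[2], l] <- lo + d[l]
      others <- setdiff(seq_len(K), pr)
      p[others, l] <- runif(length(others), lo, lo + d[l])
    }
  })
  attr(p, "target_delta") <- d
  p
}

#' Simulate a genotype cohort under the admixture model
#'
#' Generates diploid genotypes exactly under the generative assumptions of
#' the admixture model: each individual has an ancestry vector `q` over
#' the K ancestral groups; each of the two allele copies at each locus
#' independently draws an ancestral origin `z ~ Categorical(q)` and then
#' an allele from that group's frequencies, i.e. Hardy-Weinberg
#' equilibrium within groups and independent loci. Whole genotypes are
#' masked missing with probability `missing_rate`.
#'
#' @param freqs allele-1 frequency matrix (groups x loci) as returned by
#'   [make_panel_frequencies()], or a 3-d array (groups x loci x 3 allele
#'   codes) for panels with triallelic loci.
#' @param cohort list of block specifications; each block is a list with
#'   `n` (individuals) plus exactly one of `group` (unadmixed origin,
#'   named as in `freqs`), `q` (fixed admixture vector of length K), or
#'   `alpha` (Dirichlet parameter vector of length K for per-individual
#'   admixture draws), and optionally `population` (label, defaults to
#'   the group name or `popN`) and `popflag` (0/1, default 0).
#' @param missing_rate whole-genotype missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @param loci optional locus metadata (see [genotype_table()]).
#' @param id_prefix prefix for generated sample ids (default `"sim"`).
#' @return a `sim_cohort`: list with `table` (a [genotype_table()]; the
#'   `group` column holds the block's group when unadmixed, else the
#'   population label), `true_Q` (individuals x K) and `freqs` (the 3-d
#'   frequency array actually used).
#' @export
simulate_cohort <- function(freqs, cohort, missing_rate = 0, seed = 1L,
                            loci = NULL, id_prefix = "sim") {
  .aim_assert(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must be in [0, 1)")
  farr <- .freq_array(freqs)
  K <- dim(farr)[1]; L <- dim(farr)[2]
  groups <- dimnames(farr)[[1]]
  marker_ids <- dimnames(farr)[[2]]

  blocks <- lapply(seq_along(cohort), function(b) {
    spec <- cohort[[b]]
    .aim_assert(!is.null(spec$n) && spec$n >= 0, "block %d: n missing", b)
    kind <- intersect(names(spec), c("group", "q", "alpha"))
    .aim_assert(length(kind) == 1,
                "block %d: give exactly one of group/q/alpha", b)
    if (kind == "group")
      .aim_assert(spec$group %in% groups, "unknown group '%s' in cohort spec",
                  as.character(spec$group))
    spec$kind <- kind
    spec$population <- spec$population %||%
      if (kind == "group") spec$group else paste0("pop", b)
    spec$popflag <- spec$popflag %||% 0L
    spec
  })
  n <- sum(vapply(blocks, function(b) b$n, numeric(1)))

  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  trueQ <- matrix(0, n, K, dimnames = list(NULL, groups))
  pop <- character(n); grp <- rep(NA_character_, n); flag <- integer(n)

  .with_seed(seed, {
    row <- 0L
    for (b in blocks) {
      for (i in seq_len(b$n)) {
        row <- row + 1L
        q <- switch(b$kind,
          group = as.numeric(groups == b$group),
          q = { .aim_assert(length(b$q) == K && abs(sum(b$q) - 1) < 1e-6,
                            "q must be a length-K simplex vector"); b$q },
          alpha = {
            g <- rgamma(K, shape = b$alpha)
            # tiny alpha underflows to all-zero draws: the Dirichlet limit
            # is a point mass on a vertex chosen with probability alpha_k
            if (sum(g) <= 0) as.numeric(seq_len(K) ==
                                          sample.int(K, 1, prob = b$alpha))
            else g / sum(g)
          })
        trueQ[row, ] <- q
        z1 <- sample.int(K, L, replace = TRUE, prob = q)
        z2 <- sample.int(K, L, replace = TRUE, prob = q)
        a1[row, ] <- .draw_alleles(farr, z1)
        a2[row, ] <- .draw_alleles(farr, z2)
        pop[row] <- b$population
        if (b$kind == "group") grp[row] <- b$group
        else grp[row] <- b$population
        flag[row] <- b$popflag
      }
    }
    if (missing_rate > 0 && n > 0) {
      mask <- matrix(runif(n * L) < missing_rate, n, L)
      a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
    }
  })

  if (is.null(loci)) {
    alleles <- apply(farr, 2, function(m) {
      paste(which(colSums(matrix(m, ncol = 3)) > 0), collapse = ",")
    })
    loci <- data.frame(marker_id = marker_ids, alleles = alleles,
                       stringsAsFactors = FALSE)
  }
  ind <- data.frame(sample_id = sprintf("%s%04d", id_prefix, seq_len(n)),
                    population = pop, group = grp, popflag = flag,
                    stringsAsFactors = FALSE)
  structure(list(table = genotype_table(a1, a2, ind, loci),
                 true_Q = trueQ, freqs = farr),
            class = "sim_cohort")
}

# normalize frequency input to a groups x loci x 3 array
.freq_array <- function(freqs) {
  if (length(dim(freqs)) == 3) {
    .aim_assert(all(abs(apply(freqs, c(1, 2), sum) - 1) < 1e-9),
                "frequency vectors must sum to 1")
    return(freqs)
  }
  .aim_assert(is.matrix(freqs), "freqs must be a matrix or 3-d array")
  .aim_assert(all(freqs >= 0 & freqs <= 1), "frequencies must lie in [0,1]")
  K <- nrow(freqs); L <- ncol(freqs)
  arr <- array(0, c(K, L, 3),
               dimnames = list(rownames(freqs), colnames(freqs), 1:3))
  arr[, , 1] <- freqs; arr[, , 2] <- 1 - freqs
  arr
}

.draw_alleles <- function(farr, z) {
  L <- dim(farr)[2]
  u <- runif(L)
  p1 <- farr[cbind(z, seq_len(L), 1L)]
  p2 <- farr[cbind(z, seq_len(L), 2L)]
  ifelse(u < p1, 1L, ifelse(u < p1 + p2, 2L, 3L))
}

#' Add a group-private third allele to a frequency array
#'
#' Splits frequency `freq` off one allele's background in one group,
#' emulating rare length variants private to a continental group.
#'
#' @param farr groups x loci x 3 frequency array (see [simulate_cohort()]).
#' @param marker marker id (column name of `farr`).
#' @param group group carrying the variant.
#' @param freq frequency of allele 3 in that group.
#' @param from_allele background allele (1 or 2) the variant arose on.
#' @return the modified array.
#' @export
add_third_allele <- function(farr, marker, group, freq, from_allele = 1L) {
  l <- match(marker, dimnames(farr)[[2]])
  g <- match(group, dimnames(farr)[[1]])
  .aim_assert(!is.na(l) && !is.na(g), "unknown marker or group")
  .aim_assert(farr[g, l, from_allele] > freq,
              "background allele frequency too small to split off %g", freq)
  farr[g, l, from_allele] <- farr[g, l, from_allele] - freq
  farr[g, l, 3] <- farr[g, l, 3] + freq
  farr
}

#' Reference-like synthetic cohort over the 46-marker panel
#'
#' A packaged five-group (AFR, EUR, EAS, NAM, OCE), 46-locus synthetic
#' cohort used as the package's default test surface. Its generator
#' emulates the statistical structure of the HGDP-CEPH reference database
#' of the AIM-INDEL panel: a four-group delta profile with 39 loci at
#' maximum delta >= 0.4 and 44 at >= 0.3; Oceanian frequencies mostly
#' intermediate between EUR and EAS with a subset of divergent loci; two
#' group-private third alleles (an AFR-private variant on the short-allele
#' background of MID-360 and an EUR-private variant on the long-allele
#' background of MID-2264); unadmixed individuals in Hardy-Weinberg
#' proportions; and a small whole-genotype missing rate. All frequencies
#' are synthetic draws, not transcriptions of the published tables.
#'
#' @param seed integer seed (fixed default makes this a stable fixture).
#' @param n_per_group named or unnamed vector of group sizes, recycled to
#'   5 (default 60 per group).
#' @param missing_rate whole-genotype missing probability (default 0.002).
#' @return a `sim_cohort` (see [simulate_cohort()]).
#' @export
reference_fixture <- function(seed = 46L, n_per_group = 60,
                              missing_rate = 0.002) {
  groups <- c("AFR", "EUR", "EAS", "NAM", "OCE")
  n_per_group <- rep_len(n_per_group, 5)
  panel <- aim_panel()
  # four-group delta profile mirroring the panel's published informativeness
  profile <- c(seq(0.50, 0.85, length.out = 39),  # high-delta AIMs
               seq(0.31, 0.35, length.out = 5),   # mid informativeness
               0.22, 0.26)                        # the least informative pair
  .with_seed(seed, profile <- sample(profile))    # spread over the panel
  p4 <- make_panel_frequencies(4, 46, profile, seed = seed + 1L,
                               groups = groups[1:4],
                               marker_ids = panel$marker_id)
  # OCE: intermediate between EUR and EAS, with every 5th locus divergent
  p <- rbind(p4, OCE = NA_real_)
  .with_seed(seed + 2L, {
    lo <- pmin(p4["EUR", ], p4["EAS", ]); hi <- pmax(p4["EUR", ], p4["EAS", ])
    p["OCE", ] <- runif(46, lo, hi)
    div <- seq(1, 46, by = 5)
    shift <- 0.35 * sample(c(-1, 1), length(div), replace = TRUE)
    p["OCE", div] <- pmin(0.98, pmax(0.02, p["OCE", div] + shift))
  })
  farr <- .freq_array(p)
  farr <- add_third_allele(farr, "MID-360", "AFR", 0.08, from_allele = 1L)
  farr <- add_third_allele(farr, "MID-2264", "EUR", 0.06, from_allele = 2L)
  loci <- panel
  loci$alleles <- vapply(seq_len(46), function(l) {
    paste(which(colSums(matrix(farr[, l, ], ncol = 3)) > 0), collapse = ",")
  }, character(1))
  cohort <- lapply(seq_along(groups), function(g)
    list(group = groups[g], n = n_per_group[g], popflag = 1L))
  simulate_cohort(farr, cohort, missing_rate = missing_rate,
                  seed = seed + 3L, loci = loci)
}
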