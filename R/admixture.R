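#' Configuration for the admixture-model Gibbs sampler
#'
#' Defaults mirror the documented defaults of the classical clustering
#' program for this model: Dirichlet frequency prior `lambda = 1`, uniform
#' prior on the admixture concentration `alpha` over `(0, alpha_max)` with
#' a Metropolis normal proposal of sd 0.025, and for the correlated
#' frequency model a Gamma prior on the per-cluster drift parameter `F_k`
#' with mean 0.01 and sd 0.05. Chain lengths default to the package's
#' reduced test scale; pass `burnin`/`reps` explicitly for full-scale
#' runs.
#'
#' @param K number of clusters (>= 1).
#' @param burnin discarded sweeps (default 2000).
#' @param reps retained sweeps (default 5000).
#' @param freq_model `"correlated"` (default) or `"independent"` cluster
#'   allele-frequency prior.
#' @param lambda Dirichlet prior parameter for allele frequencies.
#' @param alpha_init,alpha_max,alpha_prop_sd admixture parameter: initial
#'   value, uniform prior upper bound, Metropolis proposal sd.
#' @param f_prior_mean,f_prior_sd Gamma prior moments for `F_k`
#'   (correlated model).
#' @param infer_alpha update `alpha` by Metropolis (default); `FALSE`
#'   holds it fixed at `alpha_init`, making unflagged individuals
#'   conditionally independent given the cluster frequencies.
#' @param use_popinfo supervised mode: individuals with `popflag = 1` have
#'   `q` fixed to the indicator of their labeled cluster.
#' @param pfrompopflagonly only flagged individuals' allele copies update
#'   the cluster frequencies (supervised training).
#' @param n_runs independent runs for [admixture_ensemble()] (default 3).
#' @param seed master seed; run `r` uses `seed + r`.
#' @return an `admix_config` list.
#' @export
admix_config <- function(K, burnin = 2000, reps = 5000,
                         freq_model = c("correlated", "independent"),
                         lambda = 1, alpha_init = 1, alpha_max = 10,
                         alpha_prop_sd = 0.025,
                         f_prior_mean = 0.01, f_prior_sd = 0.05,
                         infer_alpha = TRUE,
                         use_popinfo = FALSE, pfrompopflagonly = FALSE,
                         n_runs = 3, seed = 1L) {
  freq_model <- match.arg(freq_model)
  .aim_assert(K >= 1, "K must be >= 1")
  .aim_assert(burnin >= 1 && reps >= 1, "burnin and reps must be >= 1")
  .aim_assert(alpha_init > 0 && alpha_init < alpha_max,
              "need 0 < alpha_init < alpha_max")
  structure(list(K = as.integer(K), burnin = as.integer(burnin),
                 reps = as.integer(reps), freq_model = freq_model,
                 lambda = lambda, alpha_init = alpha_init,
                 alpha_max = alpha_max, alpha_prop_sd = alpha_prop_sd,
                 f_prior_mean = f_prior_mean, f_prior_sd = f_prior_sd,
                 infer_alpha = isTRUE(infer_alpha),
                 use_popinfo = isTRUE(use_popinfo),
                 pfrompopflagonly = isTRUE(pfrompopflagonly),
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "admix_config")
}

#' Run one MCMC chain of the admixture model
#'
#' Gibbs sampler for the admixture model: each allele copy of individual
#' `i` at locus `l` carries a latent cluster of origin `z`; individuals
#' have Dirichlet(`alpha`) admixture vectors `q_i`; clusters have allele
#' frequencies `P_k`. Sweeps alternate (i) `z | q, P` (multinomial,
#' `Pr(z = k)` proportional to `q_ik P_kla`), (ii) `q_i | z ~
#' Dirichlet(alpha + n_i.)` for unflagged individuals, (iii) `P_kl | z ~
#' Dirichlet(prior + m_kl.)` — prior `lambda` in the independent model,
#' `p_A (1 - F_k) / F_k` in the correlated model, whose `F_k` and
#' ancestral frequencies `p_A` get Metropolis updates — and (iv) a
#' Metropolis update of `alpha`. Missing genotypes contribute nothing to
#' any count. The log-likelihood trace records `ln Pr(X | P, q)` summed
#' over observed copies each sweep.
#'
#' @param tab a [genotype_table()].
#' @param config an [admix_config()].
#' @param seed integer seed for this chain (default `config$seed`).
#' @return an `admixture_run`: list with `Q` (posterior-mean membership,
#'   rows summing to 1), `P_mean`, `alpha_trace`, `loglik_trace`
#'   (post-burnin), `lnPD` (see [estimate_lnPD()]), acceptance rates,
#'   `cluster_labels` (supervised mode), `ind` and `config`.
#' @export
run_admixture <- function(tab, config, seed = config$seed) {
  K <- config$K
  n <- nrow(tab$a1); L <- ncol(tab$a1)
  A1 <- tab$a1; A2 <- tab$a2
  obs1 <- !is.na(A1)
  A1z <- A1; A1z[!obs1] <- 0L
  A2z <- A2; A2z[!obs1] <- 0L
  n_obs_copies <- 2L * sum(obs1)
  .aim_assert(n_obs_copies > 0, "table has no observed genotypes")

  # declared-allele mask L x 3 (and its K x L x 3 expansion)
  D <- matrix(0, L, 3)
  for (l in seq_len(L)) D[l, tab$alleles[[l]]] <- 1
  Darr <- aperm(array(D, c(L, 3, K)), c(3, 1, 2))

  cluster_labels <- paste0("cluster", seq_len(K))
  flagged <- rep(FALSE, n)
  if (config$use_popinfo) {
    flagged <- tab$ind$popflag == 1L
    .aim_assert(any(flagged), "use_popinfo requires popflag = 1 individuals")
    labels <- sort(unique(tab$ind$group[flagged]))
    .aim_assert(!anyNA(labels), "flagged individuals need group labels")
    .aim_assert(K <= length(labels),
                "K (%d) exceeds the number of labeled clusters (%d)",
                K, length(labels))
    .aim_assert(K == length(labels),
                "K must equal the number of labeled clusters in supervised mode")
    cluster_labels <- labels
    flag_cluster <- match(tab$ind$group, labels)
  }
  upd_rows <- if (config$pfrompopflagonly) which(flagged) else seq_len(n)
  .aim_assert(length(upd_rows) > 0, "no individuals contribute to frequency updates")

  gamma_prior <- c(shape = (config$f_prior_mean / config$f_prior_sd)^2,
                   rate = config$f_prior_mean / config$f_prior_sd^2)

  res <- .with_seed(seed, {
    # --- init ---
    alpha <- config$alpha_init
    q <- matrix(1 / K, n, K)
    if (config$use_popinfo) {
      q[flagged, ] <- 0
      q[cbind(which(flagged), flag_cluster[flagged])] <- 1
    }
    # random frequency init breaks label symmetry
    P <- array(0, c(K, L, 3))
    for (k in seq_len(K)) {
      g <- matrix(rgamma(L * 3, shape = config$lambda), L, 3) * D
      P[k, , ] <- g / rowSums(g)
    }
    correlated <- config$freq_model == "correlated" && K > 1
    if (correlated) {
      tot <- matrix(0, L, 3)
      for (j in 1:3) tot[, j] <- colSums(A1z == j) + colSums(A2z == j)
      tot <- (tot + 0.5 * D)
      pA <- tot / rowSums(tot)
      Fk <- rep(config$f_prior_mean, K)
    }

    Qsum <- matrix(0, n, K); Psum <- array(0, c(K, L, 3))
    loglik_trace <- numeric(config$reps)
    alpha_trace <- numeric(config$burnin + config$reps)
    acc_alpha <- 0L; try_alpha <- 0L
    acc_F <- 0L; try_F <- 0L

    upd_mask <- seq_len(n) %in% upd_rows
    total_sweeps <- config$burnin + config$reps
    for (sweep in seq_len(total_sweeps)) {
      # (i) z | q, P for both copies, with count summaries and
      # ln Pr(X | P, q) over observed copies (compiled inner loop)
      zres <- .admix_zstep_cpp(q, c(P), A1z, A2z, upd_mask, K, L)
      ll <- zres$loglik
      if (!is.finite(ll))
        stop("non-finite likelihood at sweep ", sweep, "; state: alpha=",
             alpha, call. = FALSE)

      # (ii) q | z
      if (K > 1) {
        G <- matrix(rgamma(n * K, shape = alpha + zres$Nik), n, K)
        G <- pmax(G, 1e-300)
        q <- G / rowSums(G)
        if (config$use_popinfo) {
          q[flagged, ] <- 0
          q[cbind(which(flagged), flag_cluster[flagged])] <- 1
        }
      }

      # (iii) P | z (+ F, pA in the correlated model)
      m <- array(zres$m, c(K, L, 3))
      if (correlated) {
        prior <- aperm(array(pA, c(L, 3, K)), c(3, 1, 2)) * Darr *
          array((1 - Fk) / Fk, c(K, L, 3))
      } else {
        prior <- config$lambda * Darr
      }
      sh <- prior + m
      G <- array(rgamma(length(sh), shape = sh), dim(sh))
      G <- G * Darr
      sums <- G[, , 1] + G[, , 2] + G[, , 3]
      P <- G / c(pmax(sums, 1e-300))

      if (correlated) {
        # Metropolis on each F_k given P and pA
        for (k in seq_len(K)) {
          try_F <- try_F + 1L
          f_new <- Fk[k] * exp(rnorm(1, 0, 0.2))
          if (f_new > 1e-6 && f_new < 0.999) {
            lp <- function(f) {
              cpar <- (1 - f) / f
              sh_k <- cpar * pA * D
              Pk <- matrix(P[k, , ], L, 3)
              terms <- D * ((sh_k - 1) * log(pmax(Pk, 1e-300)) -
                              lgamma(pmax(sh_k, 1e-300)))
              sum(lgamma(cpar * rowSums(pA * D))) + sum(terms) +
                (gamma_prior["shape"] - 1) * log(f) - gamma_prior["rate"] * f
            }
            lr <- lp(f_new) - lp(Fk[k]) + log(f_new) - log(Fk[k])
            if (is.finite(lr) && log(runif(1)) < lr) {
              Fk[k] <- f_new; acc_F <- acc_F + 1L
            }
          }
        }
        # Metropolis on pA, locus-wise Dirichlet random-walk proposals
        s_prop <- 200
        prop_sh <- s_prop * pA * D + 0.5 * D
        g <- matrix(rgamma(L * 3, shape = prop_sh), L, 3) * D
        pA_new <- g / pmax(rowSums(g), 1e-300)
        lp_pA <- function(pa) {
          out <- numeric(L)
          for (k in seq_len(K)) {
            cpar <- (1 - Fk[k]) / Fk[k]
            sh_k <- cpar * pa * D
            Pk <- matrix(P[k, , ], L, 3)
            terms <- D * ((sh_k - 1) * log(pmax(Pk, 1e-300)) -
                            lgamma(pmax(sh_k, 1e-300)))
            out <- out + lgamma(cpar * rowSums(pa * D)) + rowSums(terms)
          }
          out
        }
        ldir <- function(x, sh) {  # per-locus Dirichlet log-density
          lgamma(rowSums(sh * D)) +
            rowSums(D * ((sh - 1) * log(pmax(x, 1e-300)) -
                           lgamma(pmax(sh, 1e-300))))
        }
        prop_sh_rev <- s_prop * pA_new * D + 0.5 * D
        lr <- lp_pA(pA_new) - lp_pA(pA) +
          ldir(pA, prop_sh_rev) - ldir(pA_new, prop_sh)
        accept <- is.finite(lr) & (log(runif(L)) < lr)
        pA[accept, ] <- pA_new[accept, ]
      }

      # (iv) alpha | q (unflagged individuals)
      if (K > 1 && config$infer_alpha && any(!flagged)) {
        try_alpha <- try_alpha + 1L
        a_new <- alpha + rnorm(1, 0, config$alpha_prop_sd)
        if (a_new > 0 && a_new < config$alpha_max) {
          qu <- q[!flagged, , drop = FALSE]
          slq <- sum(log(pmax(qu, 1e-300)))
          nq <- nrow(qu)
          ldens <- function(a) nq * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * slq
          if (log(runif(1)) < ldens(a_new) - ldens(alpha)) {
            alpha <- a_new; acc_alpha <- acc_alpha + 1L
          }
        }
      }
      alpha_trace[sweep] <- alpha

      if (sweep > config$burnin) {
        Qsum <- Qsum + q
        Psum <- Psum + P
        loglik_trace[sweep - config$burnin] <- ll
      }
    }

    Q <- Qsum / config$reps
    dimnames(Q) <- list(tab$ind$sample_id, cluster_labels)
    list(Q = Q, P_mean = Psum / config$reps,
         alpha_trace = alpha_trace, loglik_trace = loglik_trace,
         lnPD = estimate_lnPD(loglik_trace),
         accept_alpha = if (try_alpha) acc_alpha / try_alpha else NA_real_,
         accept_F = if (try_F) acc_F / try_F else NA_real_,
         cluster_labels = cluster_labels,
         ind = tab$ind, config = config, seed = seed)
  })
  class(res) <- "admixture_run"
  res
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf("admixture_run: K=%d, %d individuals, lnPD=%.1f\n",
              x$config$K, nrow(x$Q), x$lnPD))
  invisible(x)
}

#' Model-choice diagnostic from a log-likelihood trace
#'
#' The estimated log probability of the data given K:
#' `mean(trace) - var(trace) / 2` (sample variance, `n - 1` denominator),
#' the standard diagnostic plotted against K to choose the number of
#' clusters.
#'
#' @param loglik_trace numeric trace of post-burnin log-likelihood values.
#' @return scalar estimate.
#' @export
estimate_lnPD <- function(loglik_trace) {
  .aim_assert(length(loglik_trace) >= 1, "empty trace")
  if (length(loglik_trace) == 1) return(loglik_trace)
  mean(loglik_trace) - var(loglik_trace) / 2
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Align cluster labels across independent runs and average
#'
#' Cluster labels are arbitrary in unsupervised runs; each run's columns
#' are permuted to minimize the summed squared difference to the first
#' run (exhaustive search over permutations, K <= 8), then membership
#' matrices are averaged element-wise.
#'
#' @param runs list of `admixture_run` objects sharing K and individual
#'   ordering.
#' @param by label column (`"group"` or `"population"`) for the per-group
#'   mean memberships.
#' @return an `admixture_ensemble`: list with `Q` (aligned average),
#'   `group_means` (groups x K mean membership), `perms`, `lnPD`
#'   (per run), `runs`.
#' @export
align_runs <- function(runs, by = c("group", "population")) {
  by <- match.arg(by)
  K <- unique(vapply(runs, function(r) ncol(r$Q), integer(1)))
  .aim_assert(length(K) == 1, "runs disagree on K")
  .aim_assert(K <= 8, "exhaustive alignment supports K <= 8")
  ref <- runs[[1]]$Q
  perms <- .permutations(K)
  used <- vector("list", length(runs))
  used[[1]] <- seq_len(K)
  Qsum <- ref
  for (r in seq_along(runs)[-1]) {
    .aim_assert(nrow(runs[[r]]$Q) == nrow(ref), "runs disagree on individuals")
    cost <- vapply(perms, function(p) sum((runs[[r]]$Q[, p] - ref)^2),
                   numeric(1))
    best <- perms[[which.min(cost)]]
    used[[r]] <- best
    Qsum <- Qsum + runs[[r]]$Q[, best]
  }
  Q <- Qsum / length(runs)
  colnames(Q) <- colnames(ref)
  labels <- runs[[1]]$ind[[by]]
  gm <- NULL
  if (!anyNA(labels)) {
    gm <- rowsum(Q, labels) / as.vector(table(labels)[sort(unique(labels))])
  }
  structure(list(Q = Q, group_means = gm, perms = used,
                 lnPD = vapply(runs, function(r) r$lnPD, numeric(1)),
                 runs = runs, ind = runs[[1]]$ind),
            class = "admixture_ensemble")
}

#' @export
print.admixture_ensemble <- function(x, ...) {
  cat(sprintf("admixture_ensemble: %d run(s), K=%d, mean lnPD=%.1f\n",
              length(x$runs), ncol(x$Q), mean(x$lnPD)))
  if (!is.null(x$group_means)) {
    cat("per-group mean membership:\n")
    print(round(x$group_means, 3))
  }
  invisible(x)
}

#' Run an ensemble of aligned admixture chains
#'
#' Runs `config$n_runs` independent chains (run `r` seeded `seed + r`)
#' and aligns them with [align_runs()].
#'
#' @inheritParams run_admixture
#' @param by label column for group means.
#' @return an `admixture_ensemble`.
#' @export
admixture_ensemble <- function(tab, config, by = c("group", "population")) {
  runs <- lapply(seq_len(config$n_runs), function(r)
    run_admixture(tab, config, seed = config$seed + r))
  align_runs(runs, by = by)
}

#' Supervised ancestry estimation for test individuals
#'
#' Combines flagged reference individuals with unflagged test individuals
#' and runs the sampler in supervised mode (`use_popinfo`): reference
#' individuals' `q` stay fixed at their labeled cluster and, with
#' `pfrompopflagonly` (the default here), only reference allele copies
#' update cluster frequencies. Clusters are thereby anchored to the
#' reference group labels, so no cross-run label alignment is needed.
#'
#' @param ref a [genotype_table()] of reference individuals with group
#'   labels (popflag is forced to 1).
#' @param test a [genotype_table()] over the same panel (popflag forced
#'   to 0).
#' @param config an [admix_config()]; `K` defaults to the number of
#'   reference groups, `use_popinfo`/`pfrompopflagonly` are forced on.
#' @param exclude_groups reference groups to drop before the run (e.g. a
#'   three-group analysis of a tri-hybrid admixed population).
#' @return list with `Q` (test individuals x clusters, cluster columns
#'   named by reference group), `population_means` (test populations x
#'   clusters), `ensemble`.
#' @export
supervised_estimate <- function(ref, test, config = NULL,
                                exclude_groups = NULL) {
  if (!is.null(exclude_groups))
    ref <- ref[!(ref$ind$group %in% exclude_groups), ]
  groups <- sort(unique(ref$ind$group))
  .aim_assert(!anyNA(groups) && length(groups) >= 1,
              "reference individuals need group labels")
  if (is.null(config)) config <- admix_config(K = length(groups))
  config$K <- length(groups)
  config$use_popinfo <- TRUE
  config$pfrompopflagonly <- TRUE
  ref$ind$popflag <- 1L
  test$ind$popflag <- 0L
  test$ind$group <- NA_character_
  comb <- bind_tables(ref, test)
  ens <- admixture_ensemble(comb, config, by = "population")
  test_rows <- which(comb$ind$popflag == 0L)
  Q <- ens$Q[test_rows, , drop = FALSE]
  pops <- comb$ind$population[test_rows]
  pm <- rowsum(Q, pops) / as.vector(table(pops)[sort(unique(pops))])
  list(Q = Q, population_means = pm, ensemble = ens)
}
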