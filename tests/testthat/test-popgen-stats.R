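# --- allele frequencies -----------------------------------------------------

test_that("allele frequencies are observed copy proportions", {
  tab1 <- genotype_table(matrix(1L), matrix(1L),
                         data.frame(sample_id = "s", population = "p", group = "A"),
                         data.frame(marker_id = "m"))
  expect_equal(allele_freqs(tab1)$freq[1, 1, 1], 1.0)

  tab2 <- genotype_table(matrix(c(1L, 1L)), matrix(c(2L, 1L)),
                         data.frame(sample_id = c("s1", "s2"),
                                    population = "p", group = "A"),
                         data.frame(marker_id = "m"))
  expect_equal(allele_freqs(tab2)$freq[1, 1, 1], 0.75)

  # large-cohort consistency against the generating frequency
  sim <- simulate_cohort(matrix(0.3, 1, 1, dimnames = list("A", "m")),
                         list(list(group = "A", n = 5000)), seed = 42)
  expect_lt(abs(allele_freqs(sim$table)$freq[1, 1, 1] - 0.3), 0.02)
})

test_that("empty groups are rejected by name", {
  tab <- small_cohort()$table
  tab$ind$group[tab$ind$group == "NAM"] <- NA
  expect_error(allele_freqs(tab), "label")
})

# --- delta ------------------------------------------------------------------

test_that("delta is the half-L1 frequency differential", {
  expect_equal(delta(c(0.4, 0.6), c(0.4, 0.6)), 0)
  expect_equal(delta(c(1, 0), c(0, 1)), 1)
  expect_equal(delta(c(0.9, 0.1), c(0.1, 0.9)), 0.8)
  # triallelic: half total variation
  expect_equal(delta(c(0.5, 0.3, 0.2), c(0.1, 0.3, 0.6)), 0.4)
  expect_error(delta(c(1, 0), c(0.2, 0.3, 0.5)), "length")
  # symmetry over random simplex pairs
  set.seed(9)
  for (i in 1:20) {
    a <- rgamma(3, 1); a <- a / sum(a)
    b <- rgamma(3, 1); b <- b / sum(b)
    expect_equal(delta(a, b), delta(b, a))
    expect_gte(delta(a, b), 0); expect_lte(delta(a, b), 1)
  }
})

test_that("rank_markers sorts by max pairwise delta with stable ties", {
  fr <- allele_freqs(small_cohort()$table)
  rk <- rank_markers(fr)
  expect_setequal(rk$marker_id, fr$loci)            # permutation of input loci
  expect_true(all(diff(rk$max_delta) <= 1e-12))     # non-increasing
  pair_cols <- setdiff(names(rk), c("marker_id", "max_delta"))
  expect_true(all(rk$max_delta >= as.matrix(rk[pair_cols]) - 1e-12))

  # identical groups give all-zero deltas
  tab <- small_cohort()$table
  tab$ind$group <- rep(c("X", "Y"), length.out = nrow(tab$a1))
  tab$a1[tab$ind$group == "Y", ] <- tab$a1[tab$ind$group == "X", ]
  tab$a2[tab$ind$group == "Y", ] <- tab$a2[tab$ind$group == "X", ]
  rk0 <- rank_markers(allele_freqs(tab))
  expect_equal(rk0$max_delta, rep(0, 20))
})

# --- F_ST -------------------------------------------------------------------

# independent scalar Weir-Cockerham oracle for one biallelic locus, two groups
wc_oracle <- function(gA, gB) {
  n1 <- length(gA); n2 <- length(gB)
  p1 <- mean(gA) / 2; p2 <- mean(gB) / 2
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  total_a <- 0; total_abc <- 0
  for (p_i in list(c(p1, p2, pbar), c(1 - p1, 1 - p2, 1 - pbar))) {
    pb <- p_i[3]
    ss <- (n1 * (p_i[1] - pb)^2 + n2 * (p_i[2] - pb)^2) / nbar
    a <- (nbar / nc) * (ss - (pb * (1 - pb) - ss / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pb * (1 - pb) - ss / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    total_a <- total_a + a; total_abc <- total_abc + a + b + cc
  }
  total_a / total_abc
}

test_that("pairwise F_ST matches a hand-computed variance-component oracle", {
  # toy counts: group A = {1/1, 1/2, 1/2}, group B = {2/2, 1/2}
  a1 <- matrix(c(1L, 1L, 1L, 2L, 1L)); a2 <- matrix(c(1L, 2L, 2L, 2L, 2L))
  tab <- genotype_table(a1, a2,
                        data.frame(sample_id = paste0("s", 1:5),
                                   population = "p",
                                   group = c("A", "A", "A", "B", "B")),
                        data.frame(marker_id = "m"))
  gA <- c(0L, 1L, 1L)  # copies of allele 2 per A individual
  gB <- c(2L, 1L)
  expect_equal(pairwise_fst(tab, "A", "B")$theta, wc_oracle(gA, gB),
               tolerance = 1e-12)
})

test_that("F_ST is 1 for fixed differences and ~0 under the null", {
  p <- matrix(c(0, 1), 2, 1, dimnames = list(c("A", "B"), "m"))
  sim <- simulate_cohort(p, list(list(group = "A", n = 20),
                                 list(group = "B", n = 20)), seed = 5)
  expect_equal(pairwise_fst(sim$table, "A", "B")$theta, 1)

  # identical generating frequencies: multi-locus theta near zero
  pnull <- matrix(rep(runif(46, 0.2, 0.8), each = 2), 2, 46,
                  dimnames = list(c("A", "B"), sprintf("L%02d", 1:46)))
  simn <- simulate_cohort(pnull, list(list(group = "A", n = 100),
                                      list(group = "B", n = 100)), seed = 6)
  expect_lt(abs(pairwise_fst(simn$table, "A", "B")$theta), 0.02)
})

test_that("F_ST is invariant to group order and allele relabeling", {
  tab <- small_cohort()$table
  f1 <- pairwise_fst(tab, "AFR", "EUR")
  f2 <- pairwise_fst(tab, "EUR", "AFR")
  expect_equal(f1$theta, f2$theta)
  expect_equal(f1$per_locus$theta, f2$per_locus$theta)
  # swap allele codes 1 and 2 everywhere
  swap <- function(m) { s <- m; s[m == 1L] <- 2L; s[m == 2L] <- 1L; s }
  tab2 <- genotype_table(swap(tab$a1), swap(tab$a2), tab$ind, tab$loci)
  expect_equal(pairwise_fst(tab2, "AFR", "EUR")$theta, f1$theta)
})

test_that("monomorphic loci are excluded from the ratio, not NaN", {
  a1 <- matrix(1L, 4, 1); a2 <- matrix(1L, 4, 1)
  tab <- genotype_table(a1, a2,
                        data.frame(sample_id = paste0("s", 1:4), population = "p",
                                   group = c("A", "A", "B", "B")),
                        data.frame(marker_id = "m", alleles = "1,2"))
  res <- pairwise_fst(tab, "A", "B")
  expect_true(is.na(res$per_locus$theta))
  expect_equal(res$per_locus$abc, 0)
})

# --- HWE exact test ---------------------------------------------------------

# independent enumeration oracle for the biallelic conditional exact test
hwe_oracle <- function(n11, n12, n22) {
  nA <- 2 * n11 + n12; nB <- 2 * n22 + n12; n <- n11 + n12 + n22
  hs <- seq(if (nA %% 2) 1 else 0, min(nA, nB), by = 2)
  pr <- vapply(hs, function(h) {
    choose(n, (nA - h) / 2) * choose(n - (nA - h) / 2, h) * 2^h /
      choose(2 * n, nA)
  }, numeric(1))
  pobs <- pr[hs == n12]
  sum(pr[pr <= pobs * (1 + 1e-9)])
}

test_that("biallelic exact test equals the enumeration oracle", {
  expect_equal(hwe_exact(c("1/1" = 0, "1/2" = 1, "2/2" = 0)), 1.0)
  expect_equal(hwe_exact(c("1/1" = 3, "1/2" = 5, "2/2" = 2)),
               hwe_oracle(3, 5, 2), tolerance = 1e-12)
  # full sweep over all genotype count triples with n <= 20
  for (n in 2:20) {
    for (n11 in 0:n) for (n12 in 0:(n - n11)) {
      n22 <- n - n11 - n12
      m <- c("1/1" = n11, "1/2" = n12, "2/2" = n22)
      got <- hwe_exact(m)
      want <- if (2 * n11 + n12 == 0 || 2 * n22 + n12 == 0) 1.0
      else hwe_oracle(n11, n12, n22)
      if (abs(got - want) > 1e-9)
        fail(sprintf("mismatch at (%d,%d,%d): %g vs %g", n11, n12, n22, got, want))
    }
  }
  succeed()
})

test_that("triallelic Monte-Carlo test agrees with exhaustive enumeration", {
  # tiny triallelic table: enumerate all pairings of the allele copies
  m <- matrix(0, 3, 3); m[1, 1] <- 2; m[2, 1] <- 1; m[3, 2] <- 1; m[3, 3] <- 1
  # oracle: exact tail probability by enumerating heterozygote structures
  ac <- rowSums(m) + colSums(m)
  tables <- list(); probs <- c()
  # enumerate all genotype tables with allele counts ac = (5, 2, 3), n = 5
  cnt <- function(tab) {
    g <- tab[lower.tri(tab, diag = TRUE)]
    factorial(5) / prod(factorial(g)) * 2^sum(tab[lower.tri(tab)]) *
      prod(factorial(ac)) / factorial(10)
  }
  obs_p <- cnt(m)
  total <- 0; tail_p <- 0
  for (g11 in 0:2) for (g21 in 0:2) for (g31 in 0:3) for (g22 in 0:1)
    for (g32 in 0:2) for (g33 in 0:1) {
      tab <- matrix(0, 3, 3)
      tab[1, 1] <- g11; tab[2, 1] <- g21; tab[3, 1] <- g31
      tab[2, 2] <- g22; tab[3, 2] <- g32; tab[3, 3] <- g33
      if (sum(tab) != 5) next
      if (!all(rowSums(tab) + colSums(tab) == ac)) next
      p <- cnt(tab)
      total <- total + p
      if (p <= obs_p * (1 + 1e-9)) tail_p <- tail_p + p
    }
  expect_equal(total, 1, tolerance = 1e-9)  # enumeration is complete
  mc <- hwe_exact(m, n_perm = 2e4, seed = 3)
  expect_equal(mc, tail_p, tolerance = 0.015)
})

test_that("all-missing input is flagged undefined, not 1", {
  expect_warning(p <- hwe_exact(matrix(0, 2, 2)), "undefined")
  expect_true(is.na(p))
})

test_that("exact test holds its size on Hardy-Weinberg data", {
  # rejection rate at alpha = 0.05 for HW-simulated counts (n = 100)
  set.seed(101)
  rej <- 0L; B <- 500L
  for (b in seq_len(B)) {
    p <- runif(1, 0.2, 0.8)
    g <- rbinom(100, 1, p) + rbinom(100, 1, p)  # allele-2 dosage under HWE
    pv <- hwe_exact(c("1/1" = sum(g == 0), "1/2" = sum(g == 1),
                      "2/2" = sum(g == 2)))
    if (pv < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / B, 0.02)
  expect_lte(rej / B, 0.09)
})

# --- linkage disequilibrium -------------------------------------------------

# independent two-locus EM in plain R (oracle for the LR statistic)
ld_oracle_lr <- function(a1, a2, b1, b2) {
  n <- length(a1)
  pa <- tabulate(c(a1, a2), 2) / (2 * n)
  pb <- tabulate(c(b1, b2), 2) / (2 * n)
  h <- outer(pa, pb)
  glik <- function(h) {
    sum(vapply(seq_len(n), function(i) {
      x <- sort(c(a1[i], a2[i])); y <- sort(c(b1[i], b2[i]))
      if (x[1] != x[2] && y[1] != y[2])
        log(2 * h[x[1], y[1]] * h[x[2], y[2]] + 2 * h[x[1], y[2]] * h[x[2], y[1]])
      else if (x[1] != x[2]) log(2 * h[x[1], y[1]] * h[x[2], y[1]])
      else if (y[1] != y[2]) log(2 * h[x[1], y[1]] * h[x[1], y[2]])
      else log(h[x[1], y[1]]^2)
    }, numeric(1)))
  }
  ll0 <- glik(h)
  for (it in 1:500) {
    cnt <- matrix(0, 2, 2)
    for (i in seq_len(n)) {
      x <- sort(c(a1[i], a2[i])); y <- sort(c(b1[i], b2[i]))
      if (x[1] != x[2] && y[1] != y[2]) {
        w1 <- h[x[1], y[1]] * h[x[2], y[2]]; w2 <- h[x[1], y[2]] * h[x[2], y[1]]
        cnt[x[1], y[1]] <- cnt[x[1], y[1]] + w1 / (w1 + w2)
        cnt[x[2], y[2]] <- cnt[x[2], y[2]] + w1 / (w1 + w2)
        cnt[x[1], y[2]] <- cnt[x[1], y[2]] + w2 / (w1 + w2)
        cnt[x[2], y[1]] <- cnt[x[2], y[1]] + w2 / (w1 + w2)
      } else {
        cnt[x[1], y[1]] <- cnt[x[1], y[1]] + 1
        cnt[x[2], y[2]] <- cnt[x[2], y[2]] + 1
      }
    }
    hn <- cnt / (2 * n)
    expect_true(all(hn >= 0))                  # EM stays on the simplex
    expect_equal(sum(hn), 1, tolerance = 1e-9)
    if (max(abs(hn - h)) < 1e-12) { h <- hn; break }
    h <- hn
  }
  2 * (glik(h) - ll0)
}

test_that("LD likelihood-ratio statistic matches an independent EM oracle", {
  set.seed(21)
  sim <- simulate_cohort(matrix(0.5, 1, 10, dimnames = list("A", sprintf("L%02d", 1:10))),
                         list(list(group = "A", n = 40)), seed = 22)
  tab <- sim$table
  res <- ld_test(tab, 1, 2, n_perm = 10, seed = 1)
  lr_ref <- ld_oracle_lr(tab$a1[, 1], tab$a2[, 1], tab$a1[, 2], tab$a2[, 2])
  expect_equal(res$lr, lr_ref, tolerance = 1e-6)
  expect_equal(sum(res$haplotype_freqs), 1, tolerance = 1e-9)
  expect_true(all(res$haplotype_freqs >= 0))
})

test_that("a duplicated locus attains the minimal permutation p-value", {
  sim <- simulate_cohort(matrix(0.5, 1, 2, dimnames = list("A", c("mA", "mB"))),
                         list(list(group = "A", n = 50)), seed = 30)
  tab <- sim$table
  tab$a1[, 2] <- tab$a1[, 1]; tab$a2[, 2] <- tab$a2[, 1]  # perfect correlation
  res <- ld_test(tab, 1, 2, n_perm = 499, seed = 2)
  expect_equal(res$p, 1 / 500)
})

test_that("monomorphic loci give p = 1 with a warning", {
  a1 <- cbind(rep(1L, 10), rep(1L, 10)); a2 <- cbind(rep(1L, 10), c(rep(1L, 5), rep(2L, 5)))
  tab <- genotype_table(a1, a2,
                        data.frame(sample_id = paste0("s", 1:10), population = "p"),
                        data.frame(marker_id = c("mA", "mB")))
  expect_warning(res <- ld_test(tab, 1, 2, n_perm = 100), "monomorphic")
  expect_equal(res$p, 1)
})

test_that("the permutation test holds its size for independent loci", {
  p <- matrix(runif(2, 0.3, 0.7), 1, 2, dimnames = list("A", c("mA", "mB")))
  rej <- 0L; B <- 200L
  for (b in seq_len(B)) {
    sim <- simulate_cohort(p, list(list(group = "A", n = 200)), seed = 1000 + b)
    res <- ld_test(sim$table, 1, 2, n_perm = 1000, seed = 2000 + b)
    if (res$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / B, 0.02)
  expect_lte(rej / B, 0.09)
})

test_that("scans flag nothing on the Hardy-Weinberg reference fixture", {
  tab <- drop_group(ref_cohort()$table, "OCE")
  hw <- hwe_scan(tab, n_perm = 2000, seed = 5)
  expect_equal(sum(hw$significant), 0)
  expect_false(anyNA(hw$p))
})
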