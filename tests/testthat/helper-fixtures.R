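# Shared fixtures, built once per test run and cached.
.fx_cache <- new.env(parent = emptyenv())

# small 4-group cohort over a moderately informative 20-locus panel
small_cohort <- function() {
  if (is.null(.fx_cache$small)) {
    p <- make_panel_frequencies(4, 20, 0.5, seed = 11,
                                groups = c("AFR", "EUR", "EAS", "NAM"))
    .fx_cache$small <- simulate_cohort(
      p, lapply(c("AFR", "EUR", "EAS", "NAM"),
                function(g) list(group = g, n = 25)),
      missing_rate = 0.01, seed = 12)
  }
  .fx_cache$small
}

# packaged reference-like cohort at its default size (60 per group)
ref_cohort <- function() {
  if (is.null(.fx_cache$ref)) .fx_cache$ref <- reference_fixture()
  .fx_cache$ref
}

# reference-like cohort at the emulated study group sizes
ref_cohort_study <- function() {
  if (is.null(.fx_cache$ref_study))
    .fx_cache$ref_study <- reference_fixture(
      n_per_group = c(105, 158, 229, 64, 28))
  .fx_cache$ref_study
}

drop_group <- function(tab, g) tab[!(tab$ind$group %in% g), ]

# tiny hand-rolled genotype table
toy_table <- function() {
  genotype_table(
    a1 = rbind(c(1L, 1L), c(1L, NA)),
    a2 = rbind(c(2L, 1L), c(2L, NA)),
    ind = data.frame(sample_id = c("s1", "s2"), population = c("p1", "p2"),
                     stringsAsFactors = FALSE),
    loci = data.frame(marker_id = c("mA", "mB"), stringsAsFactors = FALSE))
}
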