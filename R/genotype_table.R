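#' Construct a genotype table
#'
#' The central container of the package: a cohort of diploid individuals
#' typed at a panel of biallelic (occasionally triallelic) INDEL loci.
#' Alleles are small integer codes (1 = short, 2 = long, 3 = rare length
#' variant); a missing genotype has both allele slots `NA`. Missingness is
#' whole-genotype: a call with exactly one missing allele slot is promoted
#' to fully missing with a warning.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   slots of each call; `NA` marks a missing call. Slot order is not
#'   meaningful (genotypes are unordered pairs).
#' @param ind data frame with one row per individual: `sample_id`
#'   (unique character), `population` (character), optional `group`
#'   (continental group label, `NA` allowed), optional `popflag` (0/1
#'   training designation, default 0).
#' @param loci data frame with one row per locus: `marker_id` (unique
#'   character) and optional `alleles` (comma-separated declared allele
#'   codes, e.g. `"1,2"` or `"1,2,3"`). When `alleles` is absent, declared
#'   codes are inferred from the observed data (minimum `1,2`). Additional
#'   metadata columns (rs id, chromosome, position) are carried along.
#' @return An object of class `genotype_table`.
#' @seealso [read_structure()], [simulate_cohort()]
#' @export
genotype_table <- function(a1, a2, ind, loci) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  .aim_assert(all(dim(a1) == dim(a2)), "allele matrices must have equal dimensions")
  .aim_assert(nrow(a1) == nrow(ind), "ind must have one row per individual")
  .aim_assert(ncol(a1) == nrow(loci), "loci must have one row per locus")
  .aim_assert(!anyDuplicated(ind$sample_id), "sample_id values must be unique")
  .aim_assert(!anyDuplicated(loci$marker_id), "marker_id values must be unique")
  .aim_assert(!is.null(ind$population), "ind must carry a population column")

  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(ind$group)) ind$group <- NA_character_
  if (is.null(ind$popflag)) ind$popflag <- 0L
  ind$popflag <- as.integer(ind$popflag)

  # promote half-missing calls to fully missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-missing genotype(s) promoted to fully missing")
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
  }

  alleles <- .declared_alleles(loci, a1, a2)
  for (l in seq_len(ncol(a1))) {
    obs <- c(a1[, l], a2[, l])
    bad <- which(!is.na(obs) & !(obs %in% alleles[[l]]))
    if (length(bad)) {
      i <- (bad[1] - 1L) %% nrow(a1) + 1L
      stop(sprintf("undeclared allele code %d at marker %s for sample %s",
                   obs[bad[1]], loci$marker_id[l], ind$sample_id[i]), call. = FALSE)
    }
  }

  dimnames(a1) <- dimnames(a2) <- list(ind$sample_id, loci$marker_id)
  structure(list(a1 = a1, a2 = a2, ind = ind, loci = loci, alleles = alleles),
            class = "genotype_table")
}

.declared_alleles <- function(loci, a1, a2) {
  lapply(seq_len(nrow(loci)), function(l) {
    if (!is.null(loci$alleles) && !is.na(loci$alleles[l]) && nzchar(loci$alleles[l])) {
      codes <- sort(as.integer(strsplit(loci$alleles[l], ",")[[1]]))
    } else {
      codes <- sort(unique(c(a1[, l], a2[, l])))
      codes <- union(c(1L, 2L), codes[!is.na(codes)])
      codes <- sort(as.integer(codes))
    }
    .aim_assert(length(codes) >= 2, "locus %s declares fewer than 2 alleles",
                loci$marker_id[l])
    codes
  })
}

#' @export
print.genotype_table <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("genotype_table: %d individuals, %d populations, %d loci (%.2f%% missing calls)\n",
              s$n_individuals, s$n_populations, s$n_loci,
              100 * s$missing_call_fraction))
  grp <- x$ind$group
  if (!all(is.na(grp))) {
    tb <- table(grp, useNA = "no")
    cat("groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a genotype table
#'
#' @param object a [genotype_table()].
#' @param ... unused.
#' @return list with `n_individuals`, `n_populations`, `n_loci` and
#'   `missing_call_fraction` (missing calls over individuals x loci).
#' @export
summary.genotype_table <- function(object, ...) {
  n <- nrow(object$a1); L <- ncol(object$a1)
  list(n_individuals = n,
       n_populations = length(unique(object$ind$population)),
       n_loci = L,
       missing_call_fraction = if (n * L) sum(is.na(object$a1)) / (n * L) else 0)
}

#' Number of individuals / loci in a genotype table
#' @param tab a [genotype_table()].
#' @return integer count.
#' @export
n_ind <- function(tab) nrow(tab$a1)

#' @rdname n_ind
#' @export
n_loci <- function(tab) ncol(tab$a1)

#' Subset a genotype table by individuals and/or loci
#'
#' @param x a [genotype_table()].
#' @param i individual index (logical/integer/sample_id character).
#' @param j locus index (logical/integer/marker_id character).
#' @param ... unused.
#' @return a [genotype_table()].
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_len(ncol(x$a1))
  if (is.character(i)) i <- match(i, x$ind$sample_id)
  if (is.character(j)) j <- match(j, x$loci$marker_id)
  genotype_table(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                 x$ind[i, , drop = FALSE], x$loci[j, , drop = FALSE])
}

#' Stack two genotype tables over the same locus panel
#'
#' Used to combine reference (training) and test cohorts before a
#' supervised admixture run. Panels must list the same markers in the same
#' order; declared alleles are merged.
#'
#' @param x,y [genotype_table()] objects over identical panels.
#' @return a [genotype_table()] with the individuals of `x` then `y`.
#' @export
bind_tables <- function(x, y) {
  .aim_assert(identical(x$loci$marker_id, y$loci$marker_id),
              "tables must share an identical marker panel")
  ind <- rbind(x$ind, y$ind)
  if (anyDuplicated(ind$sample_id)) {
    warning("duplicate sample ids across tables; suffixing to make unique")
    ind$sample_id <- make.unique(ind$sample_id, sep = "_")
  }
  loci <- x$loci
  loci$alleles <- vapply(seq_along(x$alleles), function(l) {
    paste(sort(union(x$alleles[[l]], y$alleles[[l]])), collapse = ",")
  }, character(1))
  genotype_table(rbind(x$a1, y$a1), rbind(x$a2, y$a2), ind, loci)
}

#' Assign continental group labels from a population label map
#'
#' @param tab a [genotype_table()].
#' @param label_map named character vector mapping population codes to
#'   group labels, or a two-column data frame `(population, group)`.
#' @return the table with `ind$group` filled in.
#' @export
apply_label_map <- function(tab, label_map) {
  if (is.data.frame(label_map))
    label_map <- setNames(as.character(label_map[[2]]), as.character(label_map[[1]]))
  tab$ind$group <- unname(label_map[as.character(tab$ind$population)])
  tab
}

#' The 46-marker AIM-INDEL panel metadata
#'
#' Marker identifiers, dbSNP rs numbers, chromosome and position (dbSNP
#' build 132, 1-based) and declared allele codes for the 46-plex
#' ancestry-informative INDEL panel. Two markers (MID-360, MID-2264) carry
#' a rare third length allele on a group-private background.
#'
#' @return data frame with columns `marker_id`, `rs_id`, `chromosome`,
#'   `position_bp`, `alleles`, `note`.
#' @export
aim_panel <- function() {
  path <- system.file("extdata", "aim_indel_panel.tsv", package = "aimpanel")
  read.delim(path, stringsAsFactors = FALSE)
}
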