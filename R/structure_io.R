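#' Read a STRUCTURE-format genotype file
#'
#' Parses the whitespace-delimited text format used by the STRUCTURE
#' program: a header line of marker names followed by individual rows. In
#' the one-row dialect each individual occupies a single line with two
#' adjacent columns per locus; in the two-row dialect each individual
#' occupies two lines with one column per locus. The first column is the
#' sample id, the second the population code; an optional third metadata
#' column is the 0/1 population flag (training designation). `-9` encodes a
#' missing allele.
#'
#' Dialect and presence of the popflag column are auto-detected from the
#' column count (`2L + meta` columns means one-row, `L + meta` two-row).
#' With a single-locus file the two layouts have equal widths and the
#' dialect must be given explicitly.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"one-row"` or `"two-row"`.
#' @param popflag `NA` to auto-detect the flag column, or `TRUE`/`FALSE`
#'   to force it.
#' @param label_map optional population-to-group map, as in
#'   [apply_label_map()].
#' @param loci optional locus metadata data frame (see [genotype_table()]);
#'   row order must match the header. When supplied, allele codes are
#'   validated against the declared `alleles`.
#' @return a [genotype_table()].
#' @export
read_structure <- function(path, dialect = c("auto", "one-row", "two-row"),
                           popflag = NA, label_map = NULL, loci = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  .aim_assert(length(lines) >= 1, "empty file: %s", path)
  markers <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  L <- length(markers)
  body <- lines[-1]

  tokens <- lapply(body, function(x) strsplit(trimws(x), "[ \t]+")[[1]])
  widths <- lengths(tokens)
  if (length(body)) {
    w <- widths[1]
    bad <- which(widths != w)
    if (length(bad))
      stop(sprintf("ragged row at line %d: %d columns, expected %d",
                   bad[1] + 1L, widths[bad[1]], w), call. = FALSE)
  } else w <- NA_integer_

  if (dialect == "auto") {
    if (!length(body)) { dialect <- "one-row" }
    else if (L == 1 && (w - 2L) %in% c(1L, 2L, 3L))
      stop("dialect is ambiguous for a single-locus file; pass dialect explicitly",
           call. = FALSE)
    else if (w %in% (2L * L + 2:3)) dialect <- "one-row"
    else if (w %in% (L + 2:3)) dialect <- "two-row"
    else stop(sprintf("cannot detect dialect: %d columns for %d markers", w, L),
              call. = FALSE)
  }
  n_allele_cols <- if (dialect == "one-row") 2L * L else L
  if (length(body)) {
    n_meta <- w - n_allele_cols
    if (!is.na(popflag)) {
      .aim_assert(n_meta == 2L + as.integer(popflag),
                  "column count inconsistent with popflag=%s", popflag)
    }
    .aim_assert(n_meta %in% 2:3,
                "expected 2 or 3 metadata columns, found %d", n_meta)
    has_flag <- n_meta == 3L
  } else has_flag <- isTRUE(popflag)

  if (dialect == "one-row") {
    mat <- do.call(rbind, tokens)
    if (is.null(mat)) mat <- matrix(character(), 0, 2L + has_flag + 2L * L)
    geno <- mat[, (2L + has_flag + 1L):ncol(mat), drop = FALSE]
    if (ncol(geno) %% 2L != 0L)
      stop("odd number of allele columns in one-row dialect", call. = FALSE)
    a1 <- geno[, seq(1, ncol(geno), by = 2), drop = FALSE]
    a2 <- geno[, seq(2, ncol(geno), by = 2), drop = FALSE]
    ids <- mat[, 1]; pops <- mat[, 2]
    flags <- if (has_flag) mat[, 3] else rep("0", nrow(mat))
  } else {
    .aim_assert(length(body) %% 2L == 0L,
                "two-row dialect requires an even number of data lines")
    mat <- do.call(rbind, tokens)
    if (is.null(mat)) mat <- matrix(character(), 0, 2L + has_flag + L)
    odd <- seq(1, nrow(mat), by = 2); even <- odd + 1L
    .aim_assert(all(mat[odd, 1] == mat[even, 1]),
                "two-row dialect: paired lines disagree on sample id")
    geno_cols <- (2L + has_flag + 1L):ncol(mat)
    a1 <- mat[odd, geno_cols, drop = FALSE]
    a2 <- mat[even, geno_cols, drop = FALSE]
    ids <- mat[odd, 1]; pops <- mat[odd, 2]
    flags <- if (has_flag) mat[odd, 3] else rep("0", length(odd))
  }

  to_int <- function(m) {
    v <- suppressWarnings(as.integer(m))
    .aim_assert(!anyNA(v), "non-numeric allele code in genotype columns")
    v[v == MISSING_CODE] <- NA_integer_
    matrix(v, nrow = nrow(m))
  }
  a1 <- to_int(a1); a2 <- to_int(a2)

  ind <- data.frame(sample_id = ids, population = pops,
                    group = NA_character_, popflag = as.integer(flags),
                    stringsAsFactors = FALSE)
  if (is.null(loci)) loci <- data.frame(marker_id = markers, stringsAsFactors = FALSE)
  else .aim_assert(identical(loci$marker_id, markers) || nrow(loci) == L,
                   "loci metadata does not match header")
  tab <- genotype_table(a1, a2, ind, loci)
  if (!is.null(label_map)) tab <- apply_label_map(tab, label_map)
  tab
}

#' Write a genotype table in STRUCTURE format
#'
#' Emits a file that [read_structure()] parses back to an equal table
#' (missing calls round-trip as `-9`). The population-flag column is
#' always written; group labels are not part of the format and travel via
#' a label map instead.
#'
#' @param tab a [genotype_table()].
#' @param path output file path.
#' @param dialect `"one-row"` (default) or `"two-row"`.
#' @export
write_structure <- function(tab, path, dialect = c("one-row", "two-row")) {
  dialect <- match.arg(dialect)
  a1 <- tab$a1; a2 <- tab$a2
  a1[is.na(a1)] <- MISSING_CODE; a2[is.na(a2)] <- MISSING_CODE
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(tab$loci$marker_id, collapse = " "), con)
  n <- nrow(a1); L <- ncol(a1)
  if (!n) return(invisible(NULL))
  meta <- paste(tab$ind$sample_id, tab$ind$population, tab$ind$popflag)
  if (dialect == "one-row") {
    inter <- matrix(NA_integer_, n, 2L * L)
    inter[, seq(1, 2 * L, by = 2)] <- a1
    inter[, seq(2, 2 * L, by = 2)] <- a2
    writeLines(paste(meta, apply(inter, 1, paste, collapse = " ")), con)
  } else {
    out <- character(2L * n)
    out[seq(1, 2 * n, by = 2)] <- paste(meta, apply(a1, 1, paste, collapse = " "))
    out[seq(2, 2 * n, by = 2)] <- paste(meta, apply(a2, 1, paste, collapse = " "))
    writeLines(out, con)
  }
  invisible(NULL)
}
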