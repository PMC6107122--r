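#' Construct a diploid multi-allelic genotype matrix
#'
#' The central container of the package: unordered diploid allele pairs
#' (integer fragment sizes in base pairs) for a set of samples at a set of
#' microsatellite loci, with an optional population label per sample.
#' Missing data are encoded as a fully missing call (both alleles \code{NA});
#' half-calls (exactly one allele missing) are normalized to fully missing
#' with a warning, because every downstream statistic is defined on complete
#' diploid calls.
#'
#' @param a1,a2 integer matrices (samples x loci) holding the two alleles of
#'   each call. Row names are sample identifiers, column names locus names.
#'   The pair is unordered; it is stored canonically with \code{a1 <= a2}.
#' @param pop optional character vector of population labels, one per sample;
#'   \code{NA} marks a sample of unknown origin (a forensic query).
#' @return An object of class \code{geno_matrix}: a list with elements
#'   \code{a1}, \code{a2}, \code{pop}, \code{pop_known}.
#' @export
geno_matrix <- function(a1, a2, pop = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(identical(dim(a1), dim(a2)))
  if (is.null(rownames(a1)) && nrow(a1))
    rownames(a1) <- paste0("S", seq_len(nrow(a1)))
  if (is.null(colnames(a1)) && ncol(a1))
    colnames(a1) <- paste0("L", seq_len(ncol(a1)))
  dimnames(a2) <- dimnames(a1)
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-call(s) normalized to missing")
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  if (is.null(pop)) pop <- rep(NA_character_, nrow(a1))
  pop <- as.character(pop)
  stopifnot(length(pop) == nrow(a1))
  structure(list(a1 = a1, a2 = a2, pop = pop, pop_known = !is.na(pop)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$a1), "samples x", ncol(x$a1), "loci;",
      sum(x$pop_known), "with known population;",
      sum(is.na(x$a1)), "missing calls\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$a1)

#' Sample identifiers of a genotype matrix
#' @param g a \code{geno_matrix}
#' @export
sample_ids <- function(g) rownames(g$a1)

#' Locus names of a genotype matrix
#' @param g a \code{geno_matrix}
#' @export
locus_names <- function(g) colnames(g$a1)

#' Subset a genotype matrix by samples and/or loci
#' @param x a \code{geno_matrix}
#' @param i,j sample and locus indices (any form \code{[} accepts)
#' @param ... ignored
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_len(ncol(x$a1))
  ii <- seq_len(nrow(x$a1)); names(ii) <- rownames(x$a1)
  geno_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
              pop = x$pop[ii[i]])
}

#' Bind two genotype matrices over the same loci
#' @param x,y \code{geno_matrix} objects sharing an identical locus set
#' @export
rbind_geno <- function(x, y) {
  stopifnot(identical(colnames(x$a1), colnames(y$a1)))
  geno_matrix(rbind(x$a1, y$a1), rbind(x$a2, y$a2), pop = c(x$pop, y$pop))
}

#' Per-population allele frequency and count tables
#'
#' Tallies gene copies per (population, locus, allele); missing calls are
#' excluded from both numerator and denominator. A (population, locus) cell
#' with zero observed gene copies is marked unavailable (\code{NA}
#' frequencies) rather than zero, and downstream assignment code must treat
#' it as such.
#'
#' @param g a \code{geno_matrix}
#' @param by_pop if \code{TRUE} (default) tally per population label (samples
#'   with unknown population are skipped); if \code{FALSE} pool everything
#'   into a single population \code{"all"}.
#' @return An object of class \code{allele_freq_table}: list with \code{pops},
#'   \code{loci}, per-locus frequency matrices \code{freq[[locus]]}
#'   (populations x sorted allele labels), matching integer count matrices
#'   \code{counts[[locus]]}, and \code{n} (populations x loci gene copies).
#' @export
allele_frequencies <- function(g, by_pop = TRUE) {
  if (by_pop) {
    keep <- g$pop_known
    pops <- sort(unique(g$pop[keep]))
    popv <- g$pop[keep]
    a1 <- g$a1[keep, , drop = FALSE]; a2 <- g$a2[keep, , drop = FALSE]
  } else {
    pops <- "all"
    popv <- rep("all", nrow(g$a1))
    a1 <- g$a1; a2 <- g$a2
  }
  loci <- colnames(a1)
  freq <- counts <- vector("list", length(loci)); names(freq) <- names(counts) <- loci
  n <- matrix(0L, length(pops), length(loci), dimnames = list(pops, loci))
  for (l in seq_along(loci)) {
    alle <- sort(unique(c(a1[, l], a2[, l])))
    alle <- alle[!is.na(alle)]
    cnt <- matrix(0L, length(pops), length(alle),
                  dimnames = list(pops, as.character(alle)))
    for (p in seq_along(pops)) {
      sel <- popv == pops[p]
      copies <- c(a1[sel, l], a2[sel, l])
      copies <- copies[!is.na(copies)]
      if (length(copies)) {
        tab <- table(factor(as.character(copies), levels = as.character(alle)))
        cnt[p, ] <- as.integer(tab)
      }
      n[p, l] <- length(copies)
    }
    fr <- cnt / n[, l]
    fr[n[, l] == 0, ] <- NA_real_
    freq[[l]] <- fr
    counts[[l]] <- cnt
  }
  structure(list(pops = pops, loci = loci, freq = freq, counts = counts, n = n),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("allele_freq_table:", length(x$pops), "population(s),",
      length(x$loci), "loci\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## File formats. GenePop fixed-width codes, STRUCTURE whitespace matrices and
## a simple "a/b"-cell CSV all map onto geno_matrix losslessly.

#' Read a genotype file
#'
#' @param path file path
#' @param format one of \code{"genepop"}, \code{"structure"}, \code{"csv"}
#' @return a \code{geno_matrix}
#' @details GenePop: 2- and 3-digit allele codes are auto-detected from the
#'   code width; \code{0000}/\code{000000} is missing; populations are named
#'   \code{pop1, pop2, ...} in file order. STRUCTURE: first line holds locus
#'   names; data rows are \code{id [pop] alleles} with \code{-9} missing, in
#'   either the one-row-per-individual (2 columns per locus) or
#'   two-rows-per-individual (1 column per locus) dialect, detected from the
#'   column count. CSV: samples x loci with \code{"a/b"} cells, empty cell
#'   missing, optional \code{pop} column.
#' @export
read_genotypes <- function(path, format = c("genepop", "structure", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         genepop = read_genepop(path),
         structure = read_structure(path),
         csv = read_geno_csv(path))
}

#' Write a genotype file
#'
#' The inverse of \code{\link{read_genotypes}}: for every supported format,
#' reading a written file reproduces the calls, sample identifiers and
#' missingness exactly.
#'
#' @param g a \code{geno_matrix}
#' @param path output path
#' @param format one of \code{"genepop"}, \code{"structure"}, \code{"csv"}
#' @export
write_genotypes <- function(g, path, format = c("genepop", "structure", "csv")) {
  format <- match.arg(format)
  switch(format,
         genepop = write_genepop(g, path),
         structure = write_structure(g, path),
         csv = write_geno_csv(g, path))
  invisible(path)
}

read_genepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed GenePop file: fewer than 2 lines")
  lines <- lines[!grepl("^\\s*$", lines)]
  body <- lines[-1]                       # first line is a title comment
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("malformed GenePop file: no 'Pop' separator")
  loc_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); a1 <- a2 <- NULL; pop <- character()
  cur_pop <- 0L
  for (i in seq_along(body)) {
    if (i %in% pop_idx) { cur_pop <- cur_pop + 1L; next }
    if (i <= pop_idx[1]) next
    ln <- body[i]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("malformed GenePop line ", i + 1, ": ", ln)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("GenePop line ", i + 1, ": expected ", length(loci),
           " loci, found ", length(codes))
    zero <- grepl("^0+$", codes)      # all-zero missing code, any width
    w <- unique(nchar(codes[!zero]))
    if (length(w) > 1 || (length(w) == 1 && !(w %in% c(4L, 6L))))
      stop("GenePop line ", i + 1, ": inconsistent allele code width")
    if (!length(w)) w <- 4L
    half <- w / 2
    x1 <- suppressWarnings(as.integer(substr(codes, 1, half)))
    x2 <- suppressWarnings(as.integer(substr(codes, half + 1, w)))
    x1[zero] <- NA_integer_; x2[zero] <- NA_integer_
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id); pop <- c(pop, paste0("pop", cur_pop))
    a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
  }
  if (is.null(a1)) {
    a1 <- a2 <- matrix(NA_integer_, 0, length(loci))
  }
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- loci
  geno_matrix(a1, a2, pop = if (length(pop)) pop else NULL)
}

write_genepop <- function(g, path) {
  digits <- 3L     # reader auto-detects 2- vs 3-digit; writer emits 3-digit
  if (any(!is.na(g$a2)) && max(g$a2, na.rm = TRUE) > 999)
    stop("allele labels exceed the 3-digit GenePop code width")
  if (any(!is.na(g$a1)) && min(g$a1, na.rm = TRUE) < 1)
    stop("allele labels must be positive for GenePop codes")
  fmt <- function(x) ifelse(is.na(x), strrep("0", digits),
                            formatC(x, width = digits, flag = "0"))
  lines <- c("forensat genotypes", colnames(g$a1))
  popv <- ifelse(g$pop_known, g$pop, "unknown")
  if (!length(popv)) lines <- c(lines, "Pop")   # header-only file
  for (p in unique(popv)) {
    lines <- c(lines, "Pop")
    for (i in which(popv == p)) {
      codes <- paste0(fmt(g$a1[i, ]), fmt(g$a2[i, ]))
      lines <- c(lines, paste0(rownames(g$a1)[i], " , ",
                               paste(codes, collapse = " ")))
    }
  }
  writeLines(lines, path)
}

read_structure <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2) stop("malformed STRUCTURE file")
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- length(loci)
  rows <- lapply(lines[-1], function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1) stop("ragged STRUCTURE rows")
  has_pop <- ncols %in% c(L + 2L, 2L * L + 2L)
  two_row <- ncols %in% c(L + 1L, L + 2L)
  if (!ncols %in% c(L + 1L, L + 2L, 2L * L + 1L, 2L * L + 2L))
    stop("STRUCTURE row has ", ncols, " columns; cannot match ", L, " loci")
  off <- 1L + has_pop
  ids <- vapply(rows, `[`, "", 1L)
  popv <- if (has_pop) vapply(rows, `[`, "", 2L) else NULL
  to_int <- function(v) {
    x <- suppressWarnings(as.integer(v))
    x[v == "-9"] <- NA_integer_
    if (anyNA(x[v != "-9"])) stop("non-numeric allele in STRUCTURE file")
    x
  }
  if (two_row) {
    if (length(rows) %% 2 != 0) stop("two-row STRUCTURE file with odd row count")
    first <- seq(1, length(rows), by = 2)
    if (!all(ids[first] == ids[first + 1]))
      stop("two-row STRUCTURE file: row pairs have mismatched ids")
    a1 <- t(vapply(rows[first], function(r) to_int(r[(off + 1):(off + L)]),
                   integer(L)))
    a2 <- t(vapply(rows[first + 1], function(r) to_int(r[(off + 1):(off + L)]),
                   integer(L)))
    ids <- ids[first]
    if (!is.null(popv)) popv <- popv[first]
  } else {
    mat <- t(vapply(rows, function(r) to_int(r[(off + 1):(off + 2 * L)]),
                    integer(2 * L)))
    a1 <- mat[, seq(1, 2 * L, by = 2), drop = FALSE]
    a2 <- mat[, seq(2, 2 * L, by = 2), drop = FALSE]
  }
  if (L == 1 && !is.matrix(a1)) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- loci
  if (!is.null(popv)) popv[popv %in% c("0", "-9", "NA")] <- NA_character_
  geno_matrix(a1, a2, pop = popv)
}

write_structure <- function(g, path) {
  na9 <- function(x) ifelse(is.na(x), "-9", as.character(x))
  popv <- ifelse(g$pop_known, g$pop, "0")
  lines <- paste(colnames(g$a1), collapse = " ")
  inter <- matrix("", nrow(g$a1), 2 * ncol(g$a1))
  inter[, seq(1, ncol(inter), by = 2)] <- na9(g$a1)
  inter[, seq(2, ncol(inter), by = 2)] <- na9(g$a2)
  for (i in seq_len(nrow(g$a1))) {
    lines <- c(lines, paste(c(rownames(g$a1)[i], popv[i], inter[i, ]),
                            collapse = " "))
  }
  writeLines(lines, path)
}

read_geno_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!ncol(df)) stop("empty CSV")
  id_col <- 1L
  pop <- NULL
  loci_cols <- setdiff(seq_along(df), id_col)
  if ("pop" %in% names(df)) {
    pop <- df[["pop"]]
    pop[pop == ""] <- NA_character_
    loci_cols <- setdiff(loci_cols, which(names(df) == "pop"))
  }
  n <- nrow(df); L <- length(loci_cols)
  a1 <- a2 <- matrix(NA_integer_, n, L,
                     dimnames = list(df[[id_col]], names(df)[loci_cols]))
  for (j in seq_along(loci_cols)) {
    cell <- trimws(df[[loci_cols[j]]])
    ok <- nzchar(cell)
    parts <- strsplit(cell[ok], "/", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("malformed CSV genotype cell at column ",
                       names(df)[loci_cols[j]])
    a1[ok, j] <- as.integer(vapply(parts, `[`, "", 1L))
    a2[ok, j] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  geno_matrix(a1, a2, pop = pop)
}

write_geno_csv <- function(g, path) {
  cell <- matrix("", nrow(g$a1), ncol(g$a1))
  ok <- !is.na(g$a1)
  cell[ok] <- paste0(g$a1[ok], "/", g$a2[ok])
  df <- data.frame(sample = rownames(g$a1), pop = g$pop, check.names = FALSE,
                   stringsAsFactors = FALSE)
  cell_df <- as.data.frame(cell, stringsAsFactors = FALSE)
  names(cell_df) <- colnames(g$a1)
  utils::write.csv(cbind(df, cell_df), path, row.names = FALSE, na = "")
}
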