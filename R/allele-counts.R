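#' Allele count matrices
#'
#' Per-SNP derived and total haplotype counts for n+1 populations (one of
#' which will be designated the outgroup at covariance time). Missing
#' entries are explicit `NA`s.
#'
#' @param x integer matrix (SNPs x populations) of derived-allele counts.
#' @param m integer matrix of total haplotype counts, same shape.
#' @param populations column labels.
#' @return An `allele_counts` object with fields `x`, `m`, `p = x/m`,
#'   `populations` and `n_snps`.
#' @export
allele_counts <- function(x, m, populations = colnames(x)) {
  x <- as.matrix(x); m <- as.matrix(m)
  stopifnot(all(dim(x) == dim(m)), !is.null(populations),
            length(populations) == ncol(x))
  if (ncol(x) < 3L)
    stop("need at least 2 non-outgroup populations plus an outgroup")
  miss <- is.na(x) | is.na(m)
  x[miss] <- NA; m[miss] <- NA
  bad <- which(!miss & (x < 0 | m < 1 | x > m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid counts at SNP %d, population %s",
                 bad[1, 1], populations[bad[1, 2]]))
  colnames(x) <- colnames(m) <- populations
  structure(list(x = x, m = m, p = x / m, populations = populations,
                 n_snps = nrow(x)),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele counts: %d SNPs x %d populations (%s); %.1f%% missing\n",
              x$n_snps, length(x$populations),
              paste(x$populations, collapse = ", "),
              100 * mean(is.na(x$x))))
  invisible(x)
}

#' Read an allele-count file
#'
#' The format is TreeMix-style: the first line holds whitespace-separated
#' population labels; each following line holds, for one biallelic SNP and
#' each population, a field `a1,a2` with the two allele counts (the total
#' haplotype count is a1+a2) or `NA` for a missing entry.
#'
#' @param path file path.
#' @return An [allele_counts()] object; population order follows the
#'   header.
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("count file has no SNP lines: ", path)
  pops <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  np <- length(pops)
  N <- length(lines) - 1L
  x <- matrix(NA_real_, N, np)
  m <- matrix(NA_real_, N, np)
  for (j in seq_len(N)) {
    fields <- strsplit(trimws(lines[j + 1L]), "\\s+")[[1L]]
    if (length(fields) != np)
      stop(sprintf("line %d: expected %d fields, found %d",
                   j + 1L, np, length(fields)))
    for (i in seq_len(np)) {
      f <- fields[i]
      if (identical(f, "NA")) next
      parts <- suppressWarnings(as.numeric(strsplit(f, ",", fixed = TRUE)[[1L]]))
      if (length(parts) != 2L || anyNA(parts) || any(parts < 0))
        stop(sprintf("line %d: malformed count field '%s'", j + 1L, f))
      x[j, i] <- parts[1L]
      m[j, i] <- parts[1L] + parts[2L]
    }
  }
  allele_counts(x, m, pops)
}

#' Write an allele-count file
#'
#' Inverse of [read_counts()]; writes the derived count as `a1` and the
#' remainder `m - a1` as `a2`.
#'
#' @param counts an [allele_counts()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "allele_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(counts$populations, collapse = " "), con)
  x <- counts$x; m <- counts$m
  body <- vapply(seq_len(nrow(x)), function(j) {
    f <- ifelse(is.na(x[j, ]), "NA",
                paste0(x[j, ], ",", m[j, ] - x[j, ]))
    paste(f, collapse = " ")
  }, "")
  writeLines(body, con)
  invisible(path)
}
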