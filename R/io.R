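#' Read and write population frequency tables
#'
#' The frequency-table dialect: UTF-8 TSV, header row `population` followed
#' by SNP ids, then one row per population with decimal frequencies in
#' [0, 1]. Values are written with 15 significant digits, so tables
#' round-trip losslessly well past 12 significant digits. Parse errors name
#' the offending line.
#'
#' @param path file path.
#' @param freqs a [freq_matrix()].
#' @return `read_freq_table` returns a [freq_matrix()];
#'   `write_freq_table` returns `path` invisibly.
#' @export
read_freq_table <- function(path) {
  if (!file.exists(path)) fp_stop_parse("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) fp_stop_parse("%s: empty file", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "population") {
    fp_stop_parse("%s line 1: header must be 'population' followed by SNP ids", path)
  }
  if (length(lines) < 2L) fp_stop_parse("%s: no data rows", path)
  snp_ids <- header[-1L]
  S <- length(snp_ids)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  labels <- character(length(rows))
  values <- matrix(NA_real_, length(rows), S)
  for (i in seq_along(rows)) {
    ln <- i + 1L
    r <- rows[[i]]
    if (length(r) != S + 1L) {
      fp_stop_parse("%s line %d: expected %d fields, found %d", path, ln,
                    S + 1L, length(r))
    }
    labels[i] <- r[1L]
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (any(is.na(v))) {
      fp_stop_parse("%s line %d: non-numeric frequency '%s'", path, ln,
                    r[-1L][which(is.na(v))[1L]])
    }
    if (any(v < 0) || any(v > 1)) {
      fp_stop_parse("%s line %d: frequency %g outside [0, 1]", path, ln,
                    v[which(v < 0 | v > 1)[1L]])
    }
    values[i, ] <- v
  }
  if (anyDuplicated(labels)) {
    fp_stop_parse("%s: duplicate population label '%s'", path,
                  labels[anyDuplicated(labels)])
  }
  freq_matrix(values, pop_labels = labels, snp_ids = snp_ids)
}

#' @rdname read_freq_table
#' @export
write_freq_table <- function(freqs, path) {
  stopifnot(is_freq_matrix(freqs))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("population", colnames(freqs)), collapse = "\t"), con)
  for (i in seq_len(nrow(freqs))) {
    writeLines(paste(c(rownames(freqs)[i], sprintf("%.15g", freqs[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read and write pairwise F2 matrices
#'
#' Square labelled TSV: header `population` plus population labels, one row
#' per population. On read, the matrix is required to be symmetric within
#' `tol` (relative to its largest entry) and is then exactly symmetrized, a
#' guard against round-tripping asymmetries; its diagonal must be zero.
#'
#' @param path file path.
#' @param m an [f2_matrix()].
#' @param source how to flag the matrix on read (default `"external"`,
#'   which permits small negative entries from estimation noise).
#' @param tol symmetry/diagonal tolerance for [f2_matrix()].
#' @return `read_f2_matrix` returns an [f2_matrix()]; `write_f2_matrix`
#'   returns `path` invisibly.
#' @export
read_f2_matrix <- function(path, source = "external", tol = 1e-8) {
  if (!file.exists(path)) fp_stop_parse("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) fp_stop_parse("%s: no data rows", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "population") {
    fp_stop_parse("%s line 1: header must start with 'population'", path)
  }
  labels <- header[-1L]
  n <- length(labels)
  if (length(lines) - 1L != n) {
    fp_stop_parse("%s: F2 matrix must be square (%d columns, %d rows)", path,
                  n, length(lines) - 1L)
  }
  values <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    r <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    if (length(r) != n + 1L) {
      fp_stop_parse("%s line %d: expected %d fields, found %d", path, i + 1L,
                    n + 1L, length(r))
    }
    if (r[1L] != labels[i]) {
      fp_stop_parse("%s line %d: row label '%s' does not match column label '%s'",
                    path, i + 1L, r[1L], labels[i])
    }
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (any(is.na(v))) fp_stop_parse("%s line %d: non-numeric entry", path, i + 1L)
    values[i, ] <- v
  }
  f2_matrix(values, source = source, tol = tol)
}

#' @rdname read_f2_matrix
#' @export
write_f2_matrix <- function(m, path) {
  stopifnot(inherits(m, "f2_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("population", rownames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], sprintf("%.15g", m[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write PC coordinates / an F-statistic spectrum as TSV
#'
#' `write_pc_coords` emits `#`-prefixed comment lines carrying the
#' eigenvalues and the clamp count, then a TSV of population coordinates.
#' `write_spectrum` emits one `(pc, contribution)` row per PC, with the
#' statistic and its total in comments; the column sum equals the total.
#'
#' @param d a `pc_decomp`.
#' @param s an `fstat_spectrum`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pc_coords <- function(d, path) {
  stopifnot(inherits(d, "pc_decomp"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# eigenvalues\t%s",
                     paste(sprintf("%.15g", d$eigenvalues), collapse = "\t")),
             con)
  writeLines(sprintf("# n_clamped\t%d", d$n_clamped), con)
  writeLines(paste(c("population", colnames(d$coords)), collapse = "\t"), con)
  for (i in seq_len(nrow(d$coords))) {
    writeLines(paste(c(d$pop_labels[i], sprintf("%.15g", d$coords[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pc_coords
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "fstat_spectrum"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# statistic\t%s(%s)", s$kind,
                     paste(s$pops, collapse = ",")), con)
  writeLines(sprintf("# total\t%.15g", s$total), con)
  writeLines("pc\tcontribution", con)
  for (k in seq_along(s$contributions)) {
    writeLines(sprintf("%d\t%.15g", k, s$contributions[k]), con)
  }
  invisible(path)
}

#' Aggregate an EIGENSTRAT triple to population allele frequencies
#'
#' Reads a geno/ind/snp file triple (genotypes coded 0/1/2 copies of the
#' reference allele, 9 = missing; one geno line per SNP, one character per
#' individual) and averages genotypes within the populations named in the
#' ind file: frequency = mean(genotype) / 2 over non-missing individuals.
#' SNPs for which any population has no non-missing individual are dropped
#' when `drop_incomplete = TRUE` (the default), so the result satisfies the
#' no-missing-data contract of [freq_matrix()]; with
#' `drop_incomplete = FALSE` such SNPs raise an error instead.
#'
#' @param geno,ind,snp file paths of the EIGENSTRAT triple.
#' @param drop_incomplete drop SNPs missing in any population (default
#'   `TRUE`).
#' @return a [freq_matrix()] (populations x retained SNPs).
#' @export
freqs_from_eigenstrat <- function(geno, ind, snp, drop_incomplete = TRUE) {
  for (f in c(geno, ind, snp)) {
    if (!file.exists(f)) fp_stop_parse("file not found: %s", f)
  }
  ind_lines <- readLines(ind, warn = FALSE)
  ind_lines <- ind_lines[nzchar(trimws(ind_lines))]
  ind_fields <- strsplit(trimws(ind_lines), "[ \t]+")
  if (any(lengths(ind_fields) < 3L)) {
    fp_stop_parse("%s: each line needs individual, sex, population", ind)
  }
  pops <- vapply(ind_fields, `[`, character(1L), 3L)
  n_ind <- length(pops)
  snp_lines <- readLines(snp, warn = FALSE)
  snp_lines <- snp_lines[nzchar(trimws(snp_lines))]
  snp_ids <- vapply(strsplit(trimws(snp_lines), "[ \t]+"), `[`,
                    character(1L), 1L)
  geno_lines <- readLines(geno, warn = FALSE)
  geno_lines <- geno_lines[nzchar(geno_lines)]
  if (length(geno_lines) != length(snp_ids)) {
    fp_stop_parse("geno has %d lines but snp lists %d SNPs",
                  length(geno_lines), length(snp_ids))
  }
  bad_len <- which(nchar(geno_lines) != n_ind)
  if (length(bad_len) > 0L) {
    fp_stop_parse("%s line %d: %d genotype characters for %d individuals",
                  geno, bad_len[1L], nchar(geno_lines[bad_len[1L]]), n_ind)
  }
  G <- matrix(NA_integer_, length(snp_ids), n_ind)
  for (i in seq_along(geno_lines)) {
    ch <- strsplit(geno_lines[i], "", fixed = TRUE)[[1L]]
    bad <- !ch %in% c("0", "1", "2", "9")
    if (any(bad)) {
      fp_stop_parse("%s line %d: unknown genotype character '%s'", geno, i,
                    ch[bad][1L])
    }
    g <- as.integer(ch)
    g[g == 9L] <- NA_integer_
    G[i, ] <- g
  }
  pop_levels <- unique(pops)
  freq <- matrix(NA_real_, length(pop_levels), length(snp_ids),
                 dimnames = list(pop_levels, snp_ids))
  for (p in pop_levels) {
    cols <- pops == p
    sub <- G[, cols, drop = FALSE]
    freq[p, ] <- rowMeans(sub, na.rm = TRUE) / 2
  }
  incomplete <- apply(freq, 2L, function(x) any(is.nan(x) | is.na(x)))
  if (any(incomplete)) {
    if (!drop_incomplete) {
      fp_stop_parse("SNP '%s' has no non-missing individuals in some population",
                    snp_ids[which(incomplete)[1L]])
    }
    freq <- freq[, !incomplete, drop = FALSE]
  }
  if (ncol(freq) == 0L) fp_stop_parse("no SNPs left after dropping incomplete ones")
  freq_matrix(freq)
}
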