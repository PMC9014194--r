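#' Population allele-frequency matrix
#'
#' The central container: an \eqn{n \times S} matrix of allele frequencies,
#' one row per population, one column per biallelic SNP. Each population is a
#' point in the S-dimensional allele frequency space; all F-statistics are
#' Euclidean quantities (squared distances, dot products) in that space.
#'
#' Missing data is not allowed at this layer: frequency tables are expected
#' to be complete (SNPs with missing populations are dropped upstream, e.g.
#' by [freqs_from_eigenstrat()]).
#'
#' @param values numeric matrix (or object coercible to one), `n x S`, all
#'   entries finite and in `[0, 1]`.
#' @param pop_labels character vector of `n` unique population labels;
#'   defaults to `rownames(values)`.
#' @param snp_ids character vector of `S` unique SNP identifiers; defaults to
#'   `colnames(values)` or `snp1..snpS`.
#' @return an object of class `freq_matrix`: the numeric matrix with
#'   populations as rownames and SNP ids as colnames.
#' @examples
#' fm <- freq_matrix(rbind(a = c(1, 0), b = c(0, 1)))
#' f2(fm, "a", "b")
#' @export
freq_matrix <- function(values, pop_labels = NULL, snp_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) fp_stop_parse("frequency values must be numeric")
  n <- nrow(values)
  S <- ncol(values)
  if (n < 1L || S < 1L) {
    fp_stop_parse("frequency matrix must have at least 1 population and 1 SNP")
  }
  if (is.null(pop_labels)) pop_labels <- rownames(values)
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- colnames(values)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(S))
  pop_labels <- as.character(pop_labels)
  snp_ids <- as.character(snp_ids)
  if (length(pop_labels) != n) fp_stop_parse("pop_labels length != number of rows")
  if (length(snp_ids) != S) fp_stop_parse("snp_ids length != number of columns")
  if (anyDuplicated(pop_labels)) {
    fp_stop_parse("duplicate population label '%s'",
                  pop_labels[anyDuplicated(pop_labels)])
  }
  if (anyDuplicated(snp_ids)) fp_stop_parse("duplicate SNP ids")
  if (any(!is.finite(values))) fp_stop_parse("frequency values must be finite (no missing data)")
  if (any(values < 0) || any(values > 1)) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1L, ]
    fp_stop_parse("frequency out of [0,1] for population '%s', SNP '%s'",
                  pop_labels[bad[1L]], snp_ids[bad[2L]])
  }
  dimnames(values) <- list(pop_labels, snp_ids)
  class(values) <- c("freq_matrix", "matrix", "array")
  values
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("<freq_matrix> %d populations x %d SNPs\n", nrow(x), ncol(x)))
  cat("populations:", paste(utils::head(rownames(x), 8L), collapse = ", "),
      if (nrow(x) > 8L) "..." else "", "\n")
  invisible(x)
}

is_freq_matrix <- function(x) inherits(x, "freq_matrix")

n_pops <- function(freqs) nrow(freqs)
n_snps <- function(freqs) ncol(freqs)

# Resolve one population label to a row index, with a classed error.
pop_index <- function(freqs, label, where = "frequency matrix") {
  i <- match(label, rownames(freqs))
  if (is.na(i)) fp_stop_label(label, where)
  i
}

# Subsetting keeps the class whenever the result is still a matrix
# (frequency invariants are closed under subsetting); with drop = TRUE a
# single row/column falls back to a plain numeric vector.
#' @export
`[.freq_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- c("freq_matrix", "matrix", "array")
  out
}
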