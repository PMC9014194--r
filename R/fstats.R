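#' F-statistics from allele frequencies
#'
#' The three Patterson F-statistics, computed as plug-in averages over SNPs:
#' \deqn{F_2(a,b)   = \frac{1}{S}\sum_l (x_{al}-x_{bl})^2}
#' \deqn{F_3(t;a,b) = \frac{1}{S}\sum_l (x_{tl}-x_{al})(x_{tl}-x_{bl})}
#' \deqn{F_4(a,b;c,d) = \frac{1}{S}\sum_l (x_{al}-x_{bl})(x_{cl}-x_{dl})}
#' Geometrically, with populations as points in allele-frequency space, F2 is
#' a squared Euclidean distance (scaled by 1/S) and F3/F4 are dot products of
#' difference vectors. No sample-size bias correction is applied: these are
#' the population-frequency statistics; bias-corrected estimates from tools
#' such as admixtools can be supplied instead as an external F2 matrix.
#'
#' Monomorphic or population-invariant SNPs contribute 0 and are retained,
#' so the 1/S normalisation is identical for every statistic.
#'
#' @param freqs a [freq_matrix()].
#' @param a,b,c,d,target population labels.
#' @return a single numeric value.
#' @seealso [pairwise_f2()], [f3_from_f2()], [f4_from_f2()]
#' @examples
#' fm <- freq_matrix(rbind(t = c(0.5, 0.5), a = c(1, 0), b = c(0, 1)))
#' f2(fm, "a", "b")      # 1
#' f3(fm, "t", "a", "b") # -0.25: t is the midpoint of a and b
#' @export
f2 <- function(freqs, a, b) {
  i <- pop_index(freqs, a)
  j <- pop_index(freqs, b)
  d <- freqs[i, ] - freqs[j, ]
  sum(d * d) / ncol(freqs)
}

#' @rdname f2
#' @export
f3 <- function(freqs, target, a, b) {
  t_ <- pop_index(freqs, target)
  i <- pop_index(freqs, a)
  j <- pop_index(freqs, b)
  sum((freqs[t_, ] - freqs[i, ]) * (freqs[t_, ] - freqs[j, ])) / ncol(freqs)
}

#' @rdname f2
#' @export
f4 <- function(freqs, a, b, c, d) {
  i <- pop_index(freqs, a)
  j <- pop_index(freqs, b)
  k <- pop_index(freqs, c)
  l <- pop_index(freqs, d)
  sum((freqs[i, ] - freqs[j, ]) * (freqs[k, ] - freqs[l, ])) / ncol(freqs)
}

#' Pairwise F2 matrix
#'
#' Computes the symmetric \eqn{n \times n} matrix of all pairwise F2
#' statistics. This matrix is the sufficient statistic for the population
#' PCA: double-centring it recovers the Gram matrix of the PC coordinates
#' (see [pca_from_f2()]).
#'
#' @param freqs a [freq_matrix()].
#' @return an `f2_matrix`: symmetric numeric matrix with zero diagonal,
#'   labelled by population, with attribute `source = "computed"`.
#' @examples
#' fm <- freq_matrix(rbind(a = c(0, 0), b = c(0.5, 0.5), c = c(1, 1)))
#' pairwise_f2(fm)
#' @export
pairwise_f2 <- function(freqs) {
  stopifnot(is_freq_matrix(freqs))
  X <- unclass(freqs)
  S <- ncol(X)
  G <- tcrossprod(X) / S
  sq <- diag(G)
  m <- outer(sq, sq, `+`) - 2 * G
  m <- (m + t(m)) / 2          # exact symmetry against round-off
  m[m < 0] <- 0                # squared norms; clip tiny negative round-off
  diag(m) <- 0
  f2_matrix(m, source = "computed")
}

#' Construct / validate an F2 matrix
#'
#' An `f2_matrix` is a labelled symmetric matrix of pairwise F2 values with a
#' zero diagonal. `source = "computed"` marks plug-in matrices from
#' [pairwise_f2()] (all entries are then required to be non-negative, being
#' squared Euclidean distances); `source = "external"` marks matrices
#' estimated elsewhere (e.g. bias-corrected estimates), where small negative
#' entries from estimation noise are permitted.
#'
#' @param values square numeric matrix with population labels as dimnames.
#' @param source `"computed"`, `"external"`, or `"expected"` (analytic
#'   expectations from [expected_f2()]).
#' @param tol symmetry tolerance, relative to the largest absolute entry.
#' @return an object of class `f2_matrix`.
#' @export
f2_matrix <- function(values, source = c("computed", "external", "expected"),
                      tol = 1e-12) {
  source <- match.arg(source)
  values <- as.matrix(values)
  n <- nrow(values)
  if (n != ncol(values)) fp_stop_parse("F2 matrix must be square")
  if (is.null(rownames(values))) rownames(values) <- paste0("pop", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!identical(rownames(values), colnames(values))) {
    fp_stop_parse("F2 matrix row/column labels disagree")
  }
  scale <- max(abs(values), 1e-300)
  if (max(abs(values - t(values))) > tol * scale) {
    fp_stop_parse("F2 matrix is not symmetric within tolerance %g", tol)
  }
  if (max(abs(diag(values))) > tol * scale) {
    fp_stop_parse("F2 matrix diagonal is not zero")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (source %in% c("computed", "expected") && any(values < 0)) {
    fp_stop_parse("computed F2 matrix has negative entries")
  }
  structure(values, source = source, class = c("f2_matrix", "matrix", "array"))
}

#' @export
print.f2_matrix <- function(x, ...) {
  cat(sprintf("<f2_matrix> %d populations (source: %s)\n", nrow(x),
              attr(x, "source")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

f2_lookup <- function(m, a, b) {
  i <- match(a, rownames(m)); if (is.na(i)) fp_stop_label(a, "F2 matrix")
  j <- match(b, rownames(m)); if (is.na(j)) fp_stop_label(b, "F2 matrix")
  m[i, j]
}

#' F3 and F4 from a pairwise F2 matrix
#'
#' The exact algebraic identities expressing F3 and F4 as linear
#' combinations of F2 statistics:
#' \deqn{2 F_3(t;a,b) = F_2(t,a) + F_2(t,b) - F_2(a,b)}
#' \deqn{2 F_4(a,b;c,d) = F_2(a,d) + F_2(b,c) - F_2(a,c) - F_2(b,d)}
#' These make a pairwise F2 matrix (computed or externally estimated)
#' sufficient for every F-statistic among its populations.
#'
#' @param m an [f2_matrix()].
#' @param a,b,c,d,target population labels present in `m`.
#' @return a single numeric value.
#' @export
f3_from_f2 <- function(m, target, a, b) {
  (f2_lookup(m, target, a) + f2_lookup(m, target, b) - f2_lookup(m, a, b)) / 2
}

#' @rdname f3_from_f2
#' @export
f4_from_f2 <- function(m, a, b, c, d) {
  (f2_lookup(m, a, d) + f2_lookup(m, b, c) -
     f2_lookup(m, a, c) - f2_lookup(m, b, d)) / 2
}

#' Compute one F-statistic by name
#'
#' Dispatch helper used by the CLI: computes F2, F3 or F4 for an ordered
#' tuple of population labels (2, 3 or 4 of them; order matters).
#'
#' @param freqs a [freq_matrix()].
#' @param kind `"f2"`, `"f3"` or `"f4"`.
#' @param pops character vector of population labels, length matching `kind`.
#' @return a single numeric value.
#' @export
fstat <- function(freqs, kind = c("f2", "f3", "f4"), pops) {
  kind <- match.arg(kind)
  need <- c(f2 = 2L, f3 = 3L, f4 = 4L)[[kind]]
  if (length(pops) != need) {
    fp_stop_parse("%s requires %d population labels, got %d",
                  kind, need, length(pops))
  }
  switch(kind,
    f2 = f2(freqs, pops[1L], pops[2L]),
    f3 = f3(freqs, pops[1L], pops[2L], pops[3L]),
    f4 = f4(freqs, pops[1L], pops[2L], pops[3L], pops[4L])
  )
}
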