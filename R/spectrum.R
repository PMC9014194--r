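#' Decompose an F-statistic into per-PC contributions
#'
#' Because the dot product is rotation-invariant, any F-statistic computed on
#' allele frequencies equals the same expression computed on the full PC
#' coordinates, and therefore splits into a sum of per-PC terms:
#' \deqn{F_2: c_k = (p_{ak}-p_{bk})^2, \quad
#'       F_3: c_k = (p_{tk}-p_{ak})(p_{tk}-p_{bk}), \quad
#'       F_4: c_k = (p_{ak}-p_{bk})(p_{ck}-p_{dk}).}
#' Coordinates are already in F2 units (the 1/S convention is folded into the
#' decomposition), so the contributions sum to the statistic computed on the
#' frequencies. F2 contributions are squares and hence all non-negative; F3
#' and F4 contributions can have either sign.
#'
#' @param d a `pc_decomp` from [pca_from_data()] or [pca_from_f2()].
#' @param kind `"f2"`, `"f3"` or `"f4"`.
#' @param pops ordered population labels (2, 3 or 4 to match `kind`).
#' @return an `fstat_spectrum`: list with `kind`, `pops`, `contributions`
#'   (length `K_max`) and `total`.
#' @export
fstat_spectrum <- function(d, kind = c("f2", "f3", "f4"), pops) {
  kind <- match.arg(kind)
  need <- c(f2 = 2L, f3 = 3L, f4 = 4L)[[kind]]
  if (length(pops) != need) {
    fp_stop_parse("%s spectrum requires %d labels, got %d", kind, need,
                  length(pops))
  }
  P <- lapply(pops, function(p) coord_row(d, p))
  contrib <- switch(kind,
    f2 = (P[[1L]] - P[[2L]])^2,
    f3 = (P[[1L]] - P[[2L]]) * (P[[1L]] - P[[3L]]),
    f4 = (P[[1L]] - P[[2L]]) * (P[[3L]] - P[[4L]])
  )
  contrib <- as.numeric(contrib)
  structure(list(kind = kind, pops = pops, contributions = contrib,
                 total = sum(contrib)),
            class = "fstat_spectrum")
}

#' @export
print.fstat_spectrum <- function(x, ...) {
  cat(sprintf("<fstat_spectrum> %s(%s) = %.6g\n", x$kind,
              paste(x$pops, collapse = ", "), x$total))
  k <- seq_len(min(10L, length(x$contributions)))
  cat("PC contributions:", paste(signif(x$contributions[k], 3L),
                                 collapse = ", "),
      if (length(x$contributions) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Truncate an F-statistic to the first K PCs
#'
#' Splits an F-statistic into the part carried by PCs `1..K` (`approx`) and
#' the remainder carried by PCs `K+1..K_max` (`error`):
#' \deqn{F = \hat F^{(K)} + \epsilon^{(K)}.}
#' For F2 the remainder is a sum of squares, so `error >= 0` and `approx` is
#' non-decreasing in `K`: distances on a PCA plot always underestimate the
#' full F2 distance.
#'
#' @inheritParams fstat_spectrum
#' @param K number of leading PCs, `0 <= K <= K_max`.
#' @return a `truncated_fstat`: list with `kind`, `pops`, `K`, `approx`,
#'   `error` and `total`.
#' @export
fstat_truncated <- function(d, kind = c("f2", "f3", "f4"), pops, K) {
  sp <- fstat_spectrum(d, kind, pops)
  K_max <- length(sp$contributions)
  if (!is.numeric(K) || length(K) != 1L || K != round(K) || K < 0 ||
      K > K_max) {
    fp_stop_parse("K must be an integer in [0, %d]", K_max)
  }
  K <- as.integer(K)
  approx <- if (K > 0L) sum(sp$contributions[seq_len(K)]) else 0
  err <- if (K < K_max) sum(sp$contributions[(K + 1L):K_max]) else 0
  structure(list(kind = sp$kind, pops = sp$pops, K = K, approx = approx,
                 error = err, total = sp$total),
            class = "truncated_fstat")
}

#' @export
print.truncated_fstat <- function(x, ...) {
  cat(sprintf("<truncated_fstat> %s(%s): K = %d\n", x$kind,
              paste(x$pops, collapse = ", "), x$K))
  cat(sprintf("  approx %.6g + error %.6g = %.6g\n", x$approx, x$error,
              x$total))
  invisible(x)
}

#' Frobenius norm of the rank-K truncation error of an F2 matrix
#'
#' The sum over all population pairs of squared per-pair truncation errors
#' equals the squared Frobenius norm of the difference between the F2 matrix
#' and its K-PC reconstruction. Classical MDS minimizes exactly this
#' quantity, so the K-PC reconstruction is the optimal rank-constrained
#' approximation of the F2 matrix.
#'
#' @param m an [f2_matrix()].
#' @param K number of leading PCs.
#' @param d optionally, a precomputed `pc_decomp` of `m` (saves the
#'   eigendecomposition when calling repeatedly).
#' @return the Frobenius norm (a single non-negative number); 0 at
#'   `K = K_max` for Euclidean (computed) F2 matrices.
#' @export
f2_frobenius_error <- function(m, K, d = NULL) {
  if (is.null(d)) d <- pca_from_f2(m)
  if (!is.numeric(K) || length(K) != 1L || K != round(K) || K < 0 ||
      K > d$K_max) {
    fp_stop_parse("K must be an integer in [0, %d]", d$K_max)
  }
  hat <- f2_hat_matrix(d, as.integer(K))
  sqrt(sum((unclass(m) - hat)^2))
}

# Rank-K F2 reconstruction from leading PC coordinates: squared pairwise
# distances in the first K coordinate columns.
f2_hat_matrix <- function(d, K) {
  if (K == 0L) {
    return(matrix(0, d$n, d$n))
  }
  Pk <- d$coords[, seq_len(K), drop = FALSE]
  G <- tcrossprod(Pk)
  sq <- diag(G)
  hat <- outer(sq, sq, `+`) - 2 * G
  hat <- (hat + t(hat)) / 2
  diag(hat) <- 0
  hat
}
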