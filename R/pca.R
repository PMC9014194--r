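#' Mean-centre an allele-frequency matrix
#'
#' Subtracts from every column (SNP) its unweighted mean over populations, so
#' the column sums of the result are zero. Population-level PCA operates on
#' this centred matrix.
#'
#' @param freqs a [freq_matrix()].
#' @return a list with `centred` (n x S numeric matrix) and `snp_means`
#'   (length-S numeric vector).
#' @export
center_freqs <- function(freqs) {
  stopifnot(is_freq_matrix(freqs))
  X <- unclass(freqs)
  mu <- colMeans(X)
  list(centred = sweep(X, 2L, mu, `-`), snp_means = mu)
}

# Internal constructor for PC decompositions. coords is n x K_max with
# column norms^2 equal to eigenvalues; loadings (K_max x S) and snp_means are
# NULL when the decomposition came from an F2 matrix alone.
new_pc_decomp <- function(coords, eigenvalues, loadings, snp_means,
                          pop_labels, n_clamped, n_snps, route) {
  K_max <- length(eigenvalues)
  dimnames(coords) <- list(pop_labels, paste0("PC", seq_len(K_max)))
  structure(list(
    coords = coords,
    eigenvalues = eigenvalues,
    loadings = loadings,
    snp_means = snp_means,
    pop_labels = pop_labels,
    n = length(pop_labels),
    K_max = K_max,
    n_clamped = n_clamped,
    n_snps = n_snps,
    route = route
  ), class = "pc_decomp")
}

#' @export
print.pc_decomp <- function(x, ...) {
  cat(sprintf("<pc_decomp> %d populations, K_max = %d (route: %s)\n",
              x$n, x$K_max, x$route))
  ev <- x$eigenvalues
  cat("eigenvalues:", paste(signif(utils::head(ev, 6L), 4L), collapse = ", "),
      if (length(ev) > 6L) "..." else "", "\n")
  if (x$n_clamped > 0L) cat("negative eigenvalues clamped:", x$n_clamped, "\n")
  if (!is.null(x$loadings)) cat("loadings: yes (", nrow(x$loadings), "x",
                                ncol(x$loadings), ")\n")
  invisible(x)
}

# Deterministic sign convention: each PC is flipped so that its
# largest-magnitude coordinate is positive; ties resolved by the lowest
# population index (which.max takes the first maximum). Loadings rows are
# flipped in step so coords %*% loadings is unchanged.
apply_sign_convention <- function(coords, loadings = NULL) {
  for (k in seq_len(ncol(coords))) {
    v <- coords[, k]
    if (all(v == 0)) next
    if (v[which.max(abs(v))] < 0) {
      coords[, k] <- -v
      if (!is.null(loadings)) loadings[k, ] <- -loadings[k, ]
    }
  }
  list(coords = coords, loadings = loadings)
}

# Round-off/negativity handling for an eigenvalue vector: values within
# tau = rel_tol * largest eigenvalue of zero are snapped to exactly 0
# (round-off); strictly more negative values are genuine non-Euclidean
# structure -- clamped to 0 and counted.
clamp_eigenvalues <- function(lam, rel_tol = 1e-9) {
  scale <- max(lam, abs(lam), 0)
  tau <- rel_tol * scale
  lam[abs(lam) < tau | lam == 0] <- 0
  n_clamped <- sum(lam < 0)
  lam[lam < 0] <- 0
  list(values = lam, n_clamped = n_clamped)
}

#' Population PCA from allele frequencies (SVD route)
#'
#' Centres the frequency matrix, scales it by \eqn{1/\sqrt{S}} and takes its
#' singular value decomposition. The scaling folds the 1/S convention of the
#' F-statistics into the decomposition, so PC coordinates are in F2 units:
#' for every pair, \eqn{F_2(i,j) = \sum_k (p_{ik} - p_{jk})^2} exactly over
#' the full spectrum, and [pca_from_data()] and [pca_from_f2()] are directly
#' comparable.
#'
#' Coordinates are `U %*% diag(d)` of the SVD; eigenvalues are the squared
#' singular values; at most `n - 1` are nonzero because centring removes one
#' dimension. Column signs follow a fixed convention (largest-magnitude
#' coordinate positive) so results are reproducible across linear-algebra
#' backends. No per-SNP variance scaling is applied by default; `scale_snps`
#' divides each centred column by its standard deviation, but this breaks
#' the exact F2 correspondence and is off by default.
#'
#' @param freqs a [freq_matrix()] with at least 2 populations.
#' @param want_loadings keep the SNP loadings matrix `L` (K_max x S) and SNP
#'   means, enabling reconstruction and [project_sample()]. Default `TRUE`.
#' @param scale_snps divide centred columns by their SD (not the default;
#'   see above).
#' @return a `pc_decomp` object.
#' @examples
#' fm <- freq_matrix(rbind(a = c(0, 0), b = c(0.5, 0.5), c = c(1, 1)))
#' d <- pca_from_data(fm)
#' d$eigenvalues   # 0.5, 0: the three populations are collinear
#' @export
pca_from_data <- function(freqs, want_loadings = TRUE, scale_snps = FALSE) {
  stopifnot(is_freq_matrix(freqs))
  n <- nrow(freqs)
  if (n < 2L) fp_stop_degenerate("PCA requires at least 2 populations")
  S <- ncol(freqs)
  cen <- center_freqs(freqs)
  Ys <- cen$centred / sqrt(S)
  if (scale_snps) {
    sds <- sqrt(colSums(cen$centred^2) / n)
    sds[sds == 0] <- 1
    Ys <- sweep(Ys, 2L, sds, `/`)
  }
  K_max <- min(n - 1L, S)  # rank bound: centring removes one dimension
  sv <- svd(Ys, nu = K_max, nv = if (want_loadings) K_max else 0L)
  lam <- sv$d[seq_len(K_max)]^2
  cl <- clamp_eigenvalues(lam)
  lam <- cl$values
  coords <- sv$u %*% diag(sv$d[seq_len(K_max)], K_max, K_max)
  coords[, lam == 0] <- 0
  loadings <- if (want_loadings) t(sv$v) else NULL
  sgn <- apply_sign_convention(coords, loadings)
  new_pc_decomp(sgn$coords, lam, sgn$loadings,
                if (want_loadings) cen$snp_means else NULL,
                rownames(freqs), cl$n_clamped, S, "data")
}

#' Population PCA from a pairwise F2 matrix (MDS route)
#'
#' Classical multidimensional scaling: double-centres the F2 matrix,
#' \deqn{B = -\tfrac{1}{2} C F_2 C, \quad C = I - \tfrac{1}{n}\mathbf{1},}
#' and eigendecomposes `B`. Because F2 distances are squared Euclidean, `B`
#' is the Gram matrix of the centred configuration and the eigendecomposition
#' recovers the same PC coordinates as [pca_from_data()] (up to sign, and up
#' to rotation within blocks of equal eigenvalues).
#'
#' F2 matrices estimated from data can fail to be exactly Euclidean, giving
#' `B` small negative eigenvalues; these are set to zero and counted in
#' `n_clamped`. Loadings are not recoverable from F2 alone, so the result
#' cannot be used to project new samples.
#'
#' @param m an [f2_matrix()] (symmetrized on construction).
#' @return a `pc_decomp` object with `loadings = NULL`.
#' @export
pca_from_f2 <- function(m) {
  if (!inherits(m, "f2_matrix")) m <- f2_matrix(m, source = "external")
  n <- nrow(m)
  if (n < 2L) fp_stop_degenerate("PCA requires at least 2 populations")
  Mi <- unclass(m)
  B <- -0.5 * Mi
  B <- sweep(B, 1L, rowMeans(B), `-`)
  B <- sweep(B, 2L, colMeans(B), `-`)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  cl <- clamp_eigenvalues(eg$values)
  lam <- cl$values
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]
  vec <- eg$vectors[, ord, drop = FALSE]
  K_max <- n - 1L
  lam <- lam[seq_len(K_max)]
  coords <- vec[, seq_len(K_max), drop = FALSE] %*%
    diag(sqrt(lam), K_max, K_max)
  sgn <- apply_sign_convention(coords)
  new_pc_decomp(sgn$coords, lam, NULL, NULL, rownames(m), cl$n_clamped,
                NA_integer_, "f2")
}

# Coordinate row for one population label.
coord_row <- function(d, label) {
  i <- match(label, d$pop_labels)
  if (is.na(i)) fp_stop_label(label, "PC decomposition")
  d$coords[i, ]
}

#' Reconstruct the centred frequency matrix from a decomposition
#'
#' Inverts the 1/sqrt(S) metric scaling: returns `coords %*% loadings *
#' sqrt(S)`, which equals the centred frequency matrix up to numerical
#' precision when all PCs are kept.
#'
#' @param d a `pc_decomp` with loadings.
#' @return an n x S numeric matrix.
#' @export
reconstruct_centred <- function(d) {
  if (is.null(d$loadings)) {
    fp_stop_capability("decomposition has no loadings; rebuild with pca_from_data(want_loadings = TRUE)")
  }
  (d$coords %*% d$loadings) * sqrt(d$n_snps)
}
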