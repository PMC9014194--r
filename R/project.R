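#' Project a new sample onto an existing PCA
#'
#' A new frequency vector is centred with the reference SNP means, scaled by
#' \eqn{1/\sqrt{S}} into F2 units, and post-multiplied by the transposed
#' loadings to obtain its PC coordinates. The part of the sample outside the
#' span of the reference loadings is the projection error, reported as an F2
#' (squared distance between the sample and its reconstruction); it is
#' orthogonal to the projection, which is what makes the three-part F2
#' decomposition of [f2_with_projected()] exact.
#'
#' With missing loci (mask entries `FALSE`), the coordinates are the ordinary
#' least-squares fit of the observed centred values on the observed loading
#' columns. This reduces to the plain projection when the loadings restricted
#' to the observed loci are near-orthonormal, and recovers the exact
#' coordinates of any sample lying in the reference span (in particular, a
#' population used to build the PCA) as long as enough loci are observed.
#'
#' @param d a `pc_decomp` from [pca_from_data()] with loadings.
#' @param new_freqs numeric vector of S allele frequencies.
#' @param mask optional logical vector of length S; `TRUE` = observed.
#' @return a `projected_sample`: list with `coords` (length `K_max`),
#'   `projection_error_f2` and `observed_mask`.
#' @export
project_sample <- function(d, new_freqs, mask = NULL) {
  if (is.null(d$loadings) || is.null(d$snp_means)) {
    fp_stop_capability("projection requires loadings and SNP means; use pca_from_data(want_loadings = TRUE)")
  }
  S <- d$n_snps
  new_freqs <- as.numeric(new_freqs)
  if (length(new_freqs) != S) {
    fp_stop_parse("new sample has %d loci; decomposition was built on %d",
                  length(new_freqs), S)
  }
  if (is.null(mask)) mask <- rep(TRUE, S)
  mask <- as.logical(mask)
  if (length(mask) != S) fp_stop_parse("mask length must equal SNP count")
  if (!any(mask)) fp_stop_degenerate("all loci are missing; nothing to project")
  y <- (new_freqs - d$snp_means) / sqrt(S)
  complete <- all(mask)
  if (complete) {
    coords <- as.numeric(y %*% t(d$loadings))
    resid <- y - as.numeric(coords %*% d$loadings)
    err <- sum(resid^2)
  } else {
    A <- t(d$loadings[, mask, drop = FALSE])  # obs x K_max
    fit <- qr(A)
    coords <- as.numeric(qr.coef(fit, y[mask]))
    coords[is.na(coords)] <- 0  # rank-deficient observed subset
    resid <- y[mask] - as.numeric(A %*% coords)
    err <- sum(resid^2)
  }
  names(coords) <- paste0("PC", seq_along(coords))
  structure(list(coords = coords, projection_error_f2 = err,
                 observed_mask = mask),
            class = "projected_sample")
}

#' @export
print.projected_sample <- function(x, ...) {
  cat(sprintf("<projected_sample> %d/%d loci observed, projection error (F2) = %.6g\n",
              sum(x$observed_mask), length(x$observed_mask),
              x$projection_error_f2))
  k <- seq_len(min(6L, length(x$coords)))
  cat("coords:", paste(signif(x$coords[k], 4L), collapse = ", "),
      if (length(x$coords) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Three-part F2 decomposition against a projected sample
#'
#' For a reference population `i` and a projected new sample, the F2 between
#' the population's frequencies and the raw sample splits exactly into
#' \deqn{F_2 = \hat F_2^{(K)}(P_i, P_{proj}) + \epsilon^{(K)}(P_i, P_{proj})
#'       + F_2(P_{proj} L, Y_{new}),}
#' i.e. the K-PC truncated part, the truncation remainder over the higher
#' PCs, and the projection error — the projection and its error being
#' orthogonal. Both truncation and projection lose information, so the
#' truncated term alone approximates the true F2 well only when both other
#' terms are small.
#'
#' @param d a `pc_decomp` with loadings.
#' @param pop a population label in `d`.
#' @param sample a `projected_sample` from a complete-data projection.
#' @param K number of leading PCs for the truncated part.
#' @return a `projected_f2`: list with `truncated`, `truncation_remainder`,
#'   `projection_error` and their sum `total`.
#' @export
f2_with_projected <- function(d, pop, sample, K) {
  if (!inherits(sample, "projected_sample")) {
    fp_stop_parse("`sample` must come from project_sample()")
  }
  if (!all(sample$observed_mask)) {
    fp_stop_capability("three-part F2 decomposition requires a complete-data projection")
  }
  p_i <- coord_row(d, pop)
  K_max <- d$K_max
  if (!is.numeric(K) || length(K) != 1L || K != round(K) || K < 0 ||
      K > K_max) {
    fp_stop_parse("K must be an integer in [0, %d]", K_max)
  }
  K <- as.integer(K)
  contrib <- (p_i - sample$coords)^2
  truncated <- if (K > 0L) sum(contrib[seq_len(K)]) else 0
  remainder <- if (K < K_max) sum(contrib[(K + 1L):K_max]) else 0
  structure(list(
    pop = pop, K = K,
    truncated = truncated,
    truncation_remainder = remainder,
    projection_error = sample$projection_error_f2,
    total = truncated + remainder + sample$projection_error_f2
  ), class = "projected_f2")
}

#' @export
print.projected_f2 <- function(x, ...) {
  cat(sprintf("<projected_f2> F2(%s, sample), K = %d\n", x$pop, x$K))
  cat(sprintf("  truncated %.6g + remainder %.6g + projection error %.6g = %.6g\n",
              x$truncated, x$truncation_remainder, x$projection_error,
              x$total))
  invisible(x)
}
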