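#' The admixture-F3 circle on a PCA plot
#'
#' By the Pythagorean theorem, F3(t; a, b) is negative exactly when the
#' target lies inside the n-ball whose diameter is the segment from a to b,
#' zero on its surface, and positive outside. On a low-dimensional PCA plot
#' two circles matter: the circle through the projected sources (radius =
#' half their distance in the plotted subspace) and the projection of the
#' full n-ball (radius = half the full-space F2 distance). The projected
#' ball is at least as large; a target outside *it* in any subspace is
#' guaranteed to have positive F3, whereas the subspace circle alone gives
#' no guarantee.
#'
#' @param d a `pc_decomp`.
#' @param a,b source population labels.
#' @param subspace integer vector of PC indices (e.g. `c(1, 2)` for a
#'   biplot).
#' @return a `circle_region`: list with `source_a`, `source_b`, `subspace`,
#'   `center` (midpoint of the sources in the subspace), `radius` (half the
#'   source distance in the subspace), `full_diameter_f2` (full-space F2
#'   between the sources) and `radius_full_ball`
#'   (`sqrt(full_diameter_f2)/2`, the projected n-ball radius).
#' @export
admixture_circle <- function(d, a, b, subspace = c(1L, 2L)) {
  subspace <- check_subspace(d, subspace)
  pa <- coord_row(d, a)
  pb <- coord_row(d, b)
  diff_full <- pa - pb
  full_f2 <- sum(diff_full^2)
  center <- (pa[subspace] + pb[subspace]) / 2
  radius <- sqrt(sum(diff_full[subspace]^2)) / 2
  structure(list(source_a = a, source_b = b, subspace = subspace,
                 center = center, radius = radius,
                 full_diameter_f2 = full_f2,
                 radius_full_ball = sqrt(full_f2) / 2),
            class = "circle_region")
}

check_subspace <- function(d, subspace) {
  subspace <- as.integer(subspace)
  if (length(subspace) < 1L) fp_stop_parse("subspace must contain at least one PC index")
  if (any(subspace < 1L) || any(subspace > d$K_max) || anyDuplicated(subspace)) {
    fp_stop_parse("subspace indices must be distinct and in 1..%d", d$K_max)
  }
  subspace
}

#' @export
print.circle_region <- function(x, ...) {
  cat(sprintf("<circle_region> sources %s, %s in PCs (%s)\n", x$source_a,
              x$source_b, paste(x$subspace, collapse = ",")))
  cat(sprintf("  center (%s), subspace radius %.6g, projected-ball radius %.6g\n",
              paste(signif(x$center, 4L), collapse = ", "), x$radius,
              x$radius_full_ball))
  invisible(x)
}

#' Classify a target population against the admixture ball
#'
#' Computes F3(target; a, b) on the frequencies and reports the target's
#' position relative to the n-ball with diameter a--b: `inside_ball`
#' (F3 < 0, admixture signal), `on_sphere` (F3 = 0 within 1e-12, right
#' angle at the target) or `outside_ball` (F3 > 0). It also tests whether
#' the target falls strictly outside the projection of the full n-ball in
#' the requested PC subspace; when it does, F3 is guaranteed positive no
#' matter what the higher PCs contain. Boundary points count as not-outside,
#' which keeps that guarantee conservative.
#'
#' @param freqs a [freq_matrix()] containing `a`, `b` and (if a label)
#'   `target`.
#' @param d a `pc_decomp` built from `freqs` (or from its F2 matrix).
#' @param target a population label in `freqs`/`d`, or a numeric vector of S
#'   frequencies (projected onto `d`, which then needs loadings).
#' @param a,b source population labels.
#' @param subspace PC indices for the projected-circle test.
#' @return an `f3_class`: list with `target`, `f3_value`, `position`,
#'   `outside_projected_circle` and the `circle_region` used.
#' @export
classify_f3 <- function(freqs, d, target, a, b, subspace = c(1L, 2L)) {
  circ <- admixture_circle(d, a, b, subspace)
  if (is.character(target) && length(target) == 1L) {
    f3v <- f3(freqs, target, a, b)
    t_coords <- coord_row(d, target)
    t_label <- target
  } else {
    proj <- project_sample(d, target)
    pa <- coord_row(d, a)
    pb <- coord_row(d, b)
    # F3 in full frequency space: PC part + orthogonal residual contributes
    # only to the squared terms, i.e. to both factors equally.
    f3v <- sum((proj$coords - pa) * (proj$coords - pb)) +
      proj$projection_error_f2
    t_coords <- proj$coords
    t_label <- "<vector>"
  }
  position <- if (abs(f3v) < 1e-12) {
    "on_sphere"
  } else if (f3v < 0) {
    "inside_ball"
  } else {
    "outside_ball"
  }
  dist_sub <- sqrt(sum((t_coords[circ$subspace] - circ$center)^2))
  outside <- dist_sub > circ$radius_full_ball
  structure(list(target = t_label, f3_value = f3v, position = position,
                 outside_projected_circle = outside, circle = circ),
            class = "f3_class")
}

#' @export
print.f3_class <- function(x, ...) {
  cat(sprintf("<f3_class> F3(%s; %s, %s) = %.6g: %s\n", x$target,
              x$circle$source_a, x$circle$source_b, x$f3_value, x$position))
  cat(sprintf("  outside projected circle in PCs (%s): %s\n",
              paste(x$circle$subspace, collapse = ","),
              x$outside_projected_circle))
  invisible(x)
}

#' Rank a panel by outgroup-F3 (shared-drift projection)
#'
#' The outgroup-F3 statistic F3(O; U, X_i) ranks panel populations X_i by
#' shared drift with an unknown sample U, using an outgroup O as anchor.
#' Geometrically it is the projection of X_i - O onto the axis from O to U:
#' only the F3 term depends on X_i, so ordering by F3 equals ordering by
#' signed projected length along that axis.
#'
#' @param freqs a [freq_matrix()].
#' @param outgroup,unknown population labels; they must differ in frequency
#'   (F2 > 0) or the projection axis is undefined.
#' @param panel character vector of panel population labels.
#' @return a data.frame with columns `population`, `f3` and
#'   `projected_length` (= `f3 / sqrt(F2(O, U))`), sorted by decreasing
#'   `f3`.
#' @export
outgroup_f3_rank <- function(freqs, outgroup, unknown, panel) {
  if (length(panel) < 1L) fp_stop_parse("panel must contain at least one population")
  axis_f2 <- f2(freqs, outgroup, unknown)
  if (axis_f2 <= 0) {
    fp_stop_degenerate("outgroup and unknown have identical frequencies; projection axis is undefined")
  }
  f3s <- vapply(panel, function(p) f3(freqs, outgroup, unknown, p),
                numeric(1L))
  out <- data.frame(population = as.character(panel), f3 = f3s,
                    projected_length = f3s / sqrt(axis_f2),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$f3, decreasing = TRUE), , drop = FALSE]
}

#' F4 as an angle / correlation between difference vectors
#'
#' F4(a, b; c, d) is the dot product of the difference vectors a - b and
#' c - d; normalizing by their lengths gives the correlation
#' \deqn{\cos\varphi = \frac{F_4(a,b;c,d)}{\sqrt{F_2(a,b)\,F_2(c,d)}},}
#' where phi is the angle between the two vectors. Independent drift gives
#' cos(phi) = 0 (90 degrees); shared drift pushes |cos(phi)| towards 1.
#' Passing a `pc_decomp` and finite `K` evaluates all three ingredients on
#' the first K PCs only, for comparing a plot-level angle with the
#' full-data one.
#'
#' @param x a [freq_matrix()] or a `pc_decomp`.
#' @param a,b,c,d population labels; the vectors are a - b and c - d.
#' @param K `"full"` (default) or the number of leading PCs (requires a
#'   `pc_decomp`).
#' @return an `f4_angle`: list with `cos_phi`, `phi_degrees`, `f4_value` and
#'   `K_used`.
#' @export
f4_angle <- function(x, a, b, c, d, K = "full") {
  if (inherits(x, "pc_decomp")) {
    K_used <- if (identical(K, "full")) x$K_max else {
      if (!is.numeric(K) || K < 1L || K > x$K_max) {
        fp_stop_parse("K must be 'full' or an integer in 1..%d", x$K_max)
      }
      as.integer(K)
    }
    idx <- seq_len(K_used)
    v1 <- (coord_row(x, a) - coord_row(x, b))[idx]
    v2 <- (coord_row(x, c) - coord_row(x, d))[idx]
    f4v <- sum(v1 * v2)
    n1 <- sum(v1^2)
    n2 <- sum(v2^2)
  } else {
    if (!identical(K, "full")) {
      fp_stop_parse("truncated angles need a pc_decomp; frequencies are full-space only")
    }
    K_used <- "full"
    f4v <- f4(x, a, b, c, d)
    n1 <- f2(x, a, b)
    n2 <- f2(x, c, d)
  }
  if (n1 <= 0 || n2 <= 0) {
    fp_stop_degenerate("zero-length difference vector; angle undefined")
  }
  cos_phi <- f4v / sqrt(n1 * n2)
  if (abs(cos_phi) > 1 + 1e-12) {
    fp_stop_degenerate("cosine outside [-1, 1] beyond round-off")
  }
  structure(list(cos_phi = cos_phi,
                 phi_degrees = acos(min(1, max(-1, cos_phi))) * 180 / pi,
                 f4_value = f4v, K_used = K_used),
            class = "f4_angle")
}

#' @export
print.f4_angle <- function(x, ...) {
  cat(sprintf("<f4_angle> F4 = %.6g, cos(phi) = %.4f, phi = %.2f deg (K = %s)\n",
              x$f4_value, x$cos_phi, x$phi_degrees, as.character(x$K_used)))
  invisible(x)
}

#' F4-ratio admixture proportion
#'
#' Estimates an admixture proportion as the ratio of two F4-statistics,
#' \deqn{\alpha = \frac{F_4(R_1, R_2; X_X, X_1)}{F_4(R_1, R_2; X_2, X_1)},}
#' i.e. the ratio of the projections of X_X - X_1 and X_2 - X_1 onto the
#' reference axis R_1 - R_2. For a drift-free linear mixture
#' X_X = (1 - w) X_1 + w X_2 the ratio equals w exactly, by linearity of the
#' dot product; `alpha` is therefore the ancestry fraction attributed to the
#' X2 side (0 when X_X = X_1, 1 when X_X = X_2), and `1 - alpha` the X1
#' side. Drift on X_X after admixture leaves the estimate unbiased as long
#' as that drift is independent of the reference axis.
#'
#' @param freqs a [freq_matrix()].
#' @param R1,R2 reference populations defining the projection axis.
#' @param XX the admixed target.
#' @param X1,X2 the proxy source populations.
#' @return an `f4_ratio`: list with `alpha`, `numerator_f4`,
#'   `denominator_f4`, `references`, `endpoints` and `target`.
#' @export
f4_ratio <- function(freqs, R1, R2, XX, X1, X2) {
  num <- f4(freqs, R1, R2, XX, X1)
  den <- f4(freqs, R1, R2, X2, X1)
  scale <- max(f2(freqs, R1, R2), f2(freqs, X1, X2), 1e-300)
  if (abs(den) < 1e-12 * scale) {
    fp_stop_degenerate("references are uninformative: F4(R1,R2;X2,X1) is below the degeneracy threshold")
  }
  structure(list(alpha = num / den, numerator_f4 = num,
                 denominator_f4 = den, references = c(R1, R2),
                 endpoints = c(X1, X2), target = XX),
            class = "f4_ratio")
}

#' @export
print.f4_ratio <- function(x, ...) {
  cat(sprintf("<f4_ratio> target %s on axis %s-%s\n", x$target,
              x$references[1L], x$references[2L]))
  cat(sprintf("  alpha = %.4f (fraction from %s side); 1 - alpha = %.4f (from %s side)\n",
              x$alpha, x$endpoints[2L], 1 - x$alpha, x$endpoints[1L]))
  invisible(x)
}

#' Rotate PC coordinates onto a reference axis
#'
#' Re-expresses every population as (i) its signed position along the unit
#' axis from R1 to R2 and (ii) its coordinates in a PCA of the residual
#' space orthogonal to that axis. Axis-position differences between
#' populations are proportional to F4(R1, R2; ., .), so ratios of axis
#' distances reproduce F4-ratio admixture estimates; the residual PCs
#' expose departures from collinearity that would invalidate a
#' two-source admixture reading.
#'
#' @param d a `pc_decomp`.
#' @param R1,R2 reference population labels with F2(R1, R2) > 0.
#' @return a `residual_rotation`: list with `axis_pos` (named vector, signed
#'   positions with R1 at 0), `residual_pcs` (matrix, populations x residual
#'   PCs), `axis_length` (`sqrt(F2(R1, R2))`), `references`.
#' @export
residual_rotation <- function(d, R1, R2) {
  p1 <- coord_row(d, R1)
  p2 <- coord_row(d, R2)
  axis <- p2 - p1
  len <- sqrt(sum(axis^2))
  if (len <= 0) fp_stop_degenerate("references coincide; rotation axis undefined")
  u <- axis / len
  P <- sweep(d$coords, 2L, p1, `-`)
  pos <- as.numeric(P %*% u)
  names(pos) <- d$pop_labels
  resid <- P - outer(pos, u)
  pc <- stats::prcomp(resid, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(ncol(pc$x), max(1L, d$K_max - 1L)))
  residual_pcs <- pc$x[, keep, drop = FALSE]
  rownames(residual_pcs) <- d$pop_labels
  structure(list(axis_pos = pos, residual_pcs = residual_pcs,
                 axis_length = len, references = c(R1, R2)),
            class = "residual_rotation")
}

#' @export
print.residual_rotation <- function(x, ...) {
  cat(sprintf("<residual_rotation> axis %s -> %s, length %.6g\n",
              x$references[1L], x$references[2L], x$axis_length))
  print(utils::head(data.frame(axis_pos = x$axis_pos,
                               residual_pc1 = x$residual_pcs[, 1L]), 8L))
  invisible(x)
}

#' Test orthogonality of two difference vectors
#'
#' Convenience wrapper for the admixture-graph residual check: disjoint
#' branches of a tree drift independently, so the difference vectors a - a2
#' and b - b2 should be orthogonal and F4(a, a2; b, b2) about zero. Returns
#' the F4 value, the corresponding cos(phi), and whether |cos(phi)| is below
#' the caller's tolerance.
#'
#' @param freqs a [freq_matrix()].
#' @param a,a2,b,b2 population labels; vectors are a - a2 and b - b2.
#' @param tol tolerance on |cos(phi)| for declaring orthogonality.
#' @return a list with `f4_value`, `cos_phi`, `orthogonal`.
#' @export
orthogonality_test <- function(freqs, a, a2, b, b2, tol = 0.1) {
  if (identical(a, a2) || identical(b, b2)) {
    # identical labels give a zero vector: F4 is exactly 0 by construction
    return(list(f4_value = 0, cos_phi = NA_real_, orthogonal = TRUE))
  }
  ang <- f4_angle(freqs, a, a2, b, b2)
  list(f4_value = ang$f4_value, cos_phi = ang$cos_phi,
       orthogonal = abs(ang$cos_phi) < tol)
}
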