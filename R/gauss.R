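#' Signed solid angle of an ordered pair of edges
#'
#' Computes the signed spherical area Omega contributed by the edge pair
#' `(p1, p2)` and `(p3, p4)` to the discrete Gauss linking integral, using the
#' four normalized cross products of the tetrahedron's connecting segments
#' (the standard segment-pair quadrilateral construction): Omega is the sum of
#' four arcsines of consecutive dot products, signed by
#' `sign((r34 x r12) . r13)`. `Omega / (4 pi)` is the pair's contribution to
#' the writhe double sum.
#'
#' Degenerate-geometry contract: arcsine arguments are clamped to `[-1, 1]`;
#' the result is exactly 0 whenever the two edges share an endpoint or any
#' normalization denominator falls below `1e-12` (adjacent or coplanar
#' configurations carry no spherical area).
#'
#' @param p1,p2 endpoints of the first edge (numeric length-3).
#' @param p3,p4 endpoints of the second edge.
#' @return the signed solid angle Omega (steradians).
#' @export
omega <- function(p1, p2, p3, p4) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  p3 <- as.numeric(p3); p4 <- as.numeric(p4)
  if (sum((p2 - p1)^2) < 1e-24 || sum((p4 - p3)^2) < 1e-24) {
    stop("degenerate (zero-length) edge")
  }
  omega_block(matrix(p1, ncol = 3L), matrix(p2, ncol = 3L),
              matrix(p3, ncol = 3L), matrix(p4, ncol = 3L))[1L]
}

# Vectorized Omega over rows of P1..P4 (each m x 3). Returns length-m vector.
omega_block <- function(P1, P2, P3, P4) {
  r12 <- P2 - P1
  r34 <- P4 - P3
  r13 <- P3 - P1
  r14 <- P4 - P1
  r23 <- P3 - P2
  r24 <- P4 - P2

  cross3 <- function(a, b) {
    cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
          a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
          a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  }
  unit <- function(v, ok) {
    nrm <- sqrt(rowSums(v^2))
    bad <- nrm < 1e-12
    nrm[bad] <- 1
    list(v = v / nrm, ok = ok & !bad)
  }

  ok <- rep(TRUE, nrow(P1))
  n1 <- unit(cross3(r13, r14), ok); ok <- n1$ok
  n2 <- unit(cross3(r14, r24), ok); ok <- n2$ok
  n3 <- unit(cross3(r24, r23), ok); ok <- n3$ok
  n4 <- unit(cross3(r23, r13), ok); ok <- n4$ok

  clamp <- function(x) pmin(1, pmax(-1, x))
  area <- asin(clamp(rowSums(n1$v * n2$v))) +
    asin(clamp(rowSums(n2$v * n3$v))) +
    asin(clamp(rowSums(n3$v * n4$v))) +
    asin(clamp(rowSums(n4$v * n1$v)))
  sgn <- sign(rowSums(cross3(r34, r12) * r13))

  # shared endpoints contribute exactly 0
  shared <- rowSums((P1 - P3)^2) < 1e-24 | rowSums((P1 - P4)^2) < 1e-24 |
    rowSums((P2 - P3)^2) < 1e-24 | rowSums((P2 - P4)^2) < 1e-24

  out <- area * sgn
  out[!ok | shared] <- 0
  out
}

# Full antisymmetric-free Omega matrix over edge pairs of a curve.
# Edge k joins points k and k+1; returns symmetric (n-1) x (n-1) matrix with
# zero diagonal and zero adjacent-pair entries.
omega_matrix <- function(curve) {
  pts <- curve_points(curve)
  m <- nrow(pts) - 1L
  if (m < 2L) return(matrix(0, m, m))
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  # drop adjacent pairs (share a point): |l - m| == 1
  keep <- idx[, 2L] - idx[, 1L] > 1L
  idx <- idx[keep, , drop = FALSE]
  M <- matrix(0, m, m)
  if (nrow(idx) == 0L) return(M)
  # chunked so temporaries stay bounded for long curves
  chunk <- 200000L
  for (from in seq.int(1L, nrow(idx), by = chunk)) {
    to <- min(from + chunk - 1L, nrow(idx))
    l <- idx[from:to, 1L]; mm <- idx[from:to, 2L]
    om <- omega_block(pts[l, , drop = FALSE], pts[l + 1L, , drop = FALSE],
                      pts[mm, , drop = FALSE], pts[mm + 1L, , drop = FALSE])
    M[idx[from:to, , drop = FALSE]] <- om
    M[idx[from:to, c(2L, 1L), drop = FALSE]] <- om
  }
  M
}

#' Writhe of a discrete curve
#'
#' The discrete Gauss-integral writhe: twice the sum of `Omega / (4 pi)` over
#' all ordered non-adjacent edge pairs. Equals the average over all projection
#' directions of the signed crossing number, is invariant under rigid motion
#' and uniform scaling, and is exactly negated by mirror reflection.
#'
#' @param curve a [discrete_curve] or [smoothed_curve] with at least 5 points.
#' @return the writhe (dimensionless real).
#' @export
#' @examples
#' writhe(make_helix(7.58, 5.98, 50, 14))
writhe <- function(curve) {
  pts <- curve_points(curve)
  if (nrow(pts) < 5L) {
    stop("at least 5 points are required for a meaningful writhe calculation")
  }
  sum(omega_matrix(curve)) / (4 * pi)
}

#' Average crossing number of a discrete curve
#'
#' The unsigned analogue of [writhe()]: twice the sum of `|Omega| / (4 pi)`
#' over all non-adjacent edge pairs, i.e. the average over all projection
#' directions of the unsigned crossing count. Always `>= |writhe|`.
#'
#' @inheritParams writhe
#' @return the average crossing number (non-negative real).
#' @export
acn <- function(curve) {
  pts <- curve_points(curve)
  if (nrow(pts) < 5L) {
    stop("at least 5 points are required for a meaningful acn calculation")
  }
  sum(abs(omega_matrix(curve))) / (4 * pi)
}

#' All-subsection writhe and acn fingerprint
#'
#' For a curve of `j` points, computes the writhe and average crossing number
#' of every contiguous subsection `C_i^n` with `1 <= i <= j - 5` and
#' `i + 5 <= n <= j` (1-based inclusive point indices; at least 6 points per
#' subsection). The pairwise Omega matrix is computed once and subsection
#' values are recovered by 2-D prefix sums, so the whole fingerprint costs
#' the same order as a single whole-curve writhe.
#'
#' @param curve a [discrete_curve] or [smoothed_curve] with at least 6 points.
#' @return an object of class `writhe_fingerprint`: list with `n_points`,
#'   matrices `wr` and `acn` (entry `[i, n]`, `NA` where undefined), and
#'   `label`. Use [fp_wr()] / [fp_acn()] for checked access and
#'   [as.data.frame()] for the long table.
#' @export
fingerprint <- function(curve) {
  pts <- curve_points(curve)
  j <- nrow(pts)
  if (j < 6L) stop("at least 6 points are required for a fingerprint")
  M <- omega_matrix(curve)
  A <- abs(M)
  # 2-D prefix sums P[a, b] = sum(M[1:a, 1:b])
  P <- apply(apply(M, 2L, cumsum), 1L, cumsum)  # transposed, symmetric so ok
  Pa <- apply(apply(A, 2L, cumsum), 1L, cumsum)
  block <- function(P, e1, e2) {
    # sum of M over [e1..e2] x [e1..e2]
    tot <- P[e2, e2]
    if (e1 > 1L) tot <- tot - 2 * P[e1 - 1L, e2] + P[e1 - 1L, e1 - 1L]
    tot
  }
  wr <- matrix(NA_real_, j, j)
  ac <- matrix(NA_real_, j, j)
  for (i in seq_len(j - 5L)) {
    for (n in seq.int(i + 5L, j)) {
      wr[i, n] <- block(P, i, n - 1L) / (4 * pi)
      ac[i, n] <- block(Pa, i, n - 1L) / (4 * pi)
    }
  }
  structure(list(n_points = j, wr = wr, acn = ac, label = curve$label),
            class = "writhe_fingerprint")
}

#' @export
print.writhe_fingerprint <- function(x, ...) {
  cat(sprintf("<writhe_fingerprint> %d points | Wr(C) = %.4f, acn(C) = %.4f\n",
              x$n_points, fp_wr(x, 1L, x$n_points),
              fp_acn(x, 1L, x$n_points)))
  invisible(x)
}

#' Fingerprint accessors
#'
#' Checked access to subsection writhe / acn values of a
#' [fingerprint()] object, in the 1-based inclusive `(i, n)` point-index
#' convention with `n - i >= 5`.
#'
#' @param fp a `writhe_fingerprint`.
#' @param i,n first and last point index of the subsection.
#' @return the stored value.
#' @export
fp_wr <- function(fp, i, n) {
  fp_check_idx(fp, i, n)
  fp$wr[i, n]
}

#' @rdname fp_wr
#' @export
fp_acn <- function(fp, i, n) {
  fp_check_idx(fp, i, n)
  fp$acn[i, n]
}

fp_check_idx <- function(fp, i, n) {
  if (i < 1L || n > fp$n_points || n - i < 5L) {
    stop(sprintf("subsection (%d, %d) is not stored: need 1 <= i, n <= %d, n - i >= 5",
                 i, n, fp$n_points))
  }
  invisible(TRUE)
}

#' Cumulative writhe profile of a fingerprint
#'
#' The sequence `Wr(C_1^n)` for `n = 5..j` is the standard diagnostic for
#' helical super-structure: uniform coiling shows up as a linear rise.
#' (The n = 5 entry is not stored in the fingerprint; the profile starts at
#' n = 6 and is padded with the n = 6 value at n = 5 for plotting symmetry.)
#'
#' @param fp a `writhe_fingerprint`.
#' @return data frame with columns `n` and `wr`.
#' @export
fp_profile <- function(fp) {
  n <- seq.int(6L, fp$n_points)
  data.frame(n = n, wr = fp$wr[1L, n])
}

#' @export
as.data.frame.writhe_fingerprint <- function(x, ...) {
  idx <- which(!is.na(x$wr), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(i = idx[, 1L], n = idx[, 2L],
             wr = x$wr[idx], acn = x$acn[idx])
}

#' Write a fingerprint to CSV
#'
#' Long format with columns `i`, `n`, `wr`, `acn`.
#'
#' @param fp a `writhe_fingerprint`.
#' @param path output path.
#' @export
write_fingerprint_csv <- function(fp, path) {
  utils::write.csv(as.data.frame(fp), path, row.names = FALSE)
  invisible(path)
}

#' Monte-Carlo projection estimate of writhe and acn
#'
#' Independent oracle for the Gauss-integral routines: for each of
#' `n_directions` directions sampled uniformly on the sphere, the curve is
#' projected onto the orthogonal plane and signed / unsigned crossings of
#' non-adjacent edges are counted; the means over directions estimate the
#' writhe and the average crossing number respectively.
#'
#' @param curve a curve with at least 5 points.
#' @param n_directions number of random directions (>= 100).
#' @param seed integer seed.
#' @return list with `wr`, `acn`, `wr_se`, `acn_se` (standard errors of the
#'   direction means) and `n_directions`.
#' @export
mc_projection_estimate <- function(curve, n_directions = 1000L, seed = 1L) {
  pts <- curve_points(curve)
  n <- nrow(pts)
  if (n < 5L) stop("at least 5 points required")
  if (n_directions < 100L) stop("`n_directions` must be >= 100")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  m <- n - 1L
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] > 1L, , drop = FALSE]
  e1 <- idx[, 1L]; e2 <- idx[, 2L]

  wr_s <- numeric(n_directions)
  acn_s <- numeric(n_directions)
  for (d in seq_len(n_directions)) {
    v <- stats::rnorm(3L)
    v <- v / sqrt(sum(v^2))
    ref <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u1 <- ref - sum(ref * v) * v
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(v[2L] * u1[3L] - v[3L] * u1[2L],
            v[3L] * u1[1L] - v[1L] * u1[3L],
            v[1L] * u1[2L] - v[2L] * u1[1L])
    x <- pts %*% u1
    y <- pts %*% u2
    h <- pts %*% v
    cs <- crossing_signs_2d(x, y, h, e1, e2)
    wr_s[d] <- sum(cs)
    acn_s[d] <- sum(abs(cs))
  }
  list(wr = mean(wr_s), acn = mean(acn_s),
       wr_se = stats::sd(wr_s) / sqrt(n_directions),
       acn_se = stats::sd(acn_s) / sqrt(n_directions),
       n_directions = as.integer(n_directions))
}

# Signed crossings of projected edge pairs. x, y: projected point coords;
# h: height along the viewing direction; e1, e2: edge index vectors.
# Returns one value per pair: 0 (no crossing) or +/-1.
crossing_signs_2d <- function(x, y, h, e1, e2) {
  ax <- x[e1]; ay <- y[e1]
  bx <- x[e1 + 1L]; by <- y[e1 + 1L]
  cx <- x[e2]; cy <- y[e2]
  dx <- x[e2 + 1L]; dy <- y[e2 + 1L]

  r1x <- bx - ax; r1y <- by - ay
  r2x <- dx - cx; r2y <- dy - cy
  den <- r1x * r2y - r1y * r2x
  nz <- abs(den) > 1e-14
  t <- s <- rep(NA_real_, length(ax))
  t[nz] <- ((cx - ax) * r2y - (cy - ay) * r2x)[nz] / den[nz]
  s[nz] <- ((cx - ax) * r1y - (cy - ay) * r1x)[nz] / den[nz]
  hit <- nz & t > 0 & t < 1 & s > 0 & s < 1
  hit[is.na(hit)] <- FALSE

  out <- numeric(length(ax))
  if (!any(hit)) return(out)
  # heights of the two strands at the crossing
  h1 <- h[e1][hit] + t[hit] * (h[e1 + 1L][hit] - h[e1][hit])
  h2 <- h[e2][hit] + s[hit] * (h[e2 + 1L][hit] - h[e2][hit])
  det_sign <- sign(den[hit])
  # crossing sign: +1 if (tangent of over strand, tangent of under strand)
  # is positively oriented in the projection plane
  out[hit] <- ifelse(h1 > h2, det_sign, -det_sign)
  out
}

#' Crossing sign sequence from a fixed projection
#'
#' Lists the signs of all crossings seen when the curve is projected along
#' `direction`, ordered by position along the curve (first edge, then second
#' edge of each crossing pair). Used to verify that smoothing preserves the
#' entanglement pattern of a curve.
#'
#' @param curve a curve.
#' @param direction length-3 viewing direction (need not be normalized).
#' @return integer vector of +/-1 signs (possibly empty).
#' @export
crossing_sign_sequence <- function(curve, direction = c(0.2, 0.3, 1)) {
  pts <- curve_points(curve)
  n <- nrow(pts)
  m <- n - 1L
  if (m < 3L) return(integer(0))
  v <- direction / sqrt(sum(direction^2))
  ref <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- ref - sum(ref * v) * v
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(v[2L] * u1[3L] - v[3L] * u1[2L],
          v[3L] * u1[1L] - v[1L] * u1[3L],
          v[1L] * u1[2L] - v[2L] * u1[1L])
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] > 1L, , drop = FALSE]
  cs <- crossing_signs_2d(pts %*% u1, pts %*% u2, pts %*% v,
                          idx[, 1L], idx[, 2L])
  ord <- order(idx[, 1L], idx[, 2L])
  as.integer(cs[ord][cs[ord] != 0])
}
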