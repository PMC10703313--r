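#' Segment-triangle intersection predicate
#'
#' Inclusive (closed) intersection test between the segment `(p, q)` and the
#' triangle `(a, b, c)`: exact touching — a segment through a vertex or edge,
#' or an endpoint on the triangle — counts as an intersection, so that
#' point-removal decisions in [skmt()] are conservative and a tangency can
#' never destroy entanglement. A degenerate (collinear) triangle never
#' reports an intersection.
#'
#' @param a,b,c triangle vertices (numeric length-3).
#' @param p,q segment endpoints.
#' @param eps tolerance in Angstrom for touching configurations.
#' @return logical.
#' @export
segment_triangle_intersects <- function(a, b, c, p, q, eps = 1e-9) {
  tri_segment_hits(rbind(a), rbind(b), rbind(c),
                   matrix(as.numeric(p), ncol = 3L),
                   matrix(as.numeric(q), ncol = 3L), eps)[1L]
}

# Vectorized over segments: A, B, C are 1 x 3 (the triangle); P, Q are m x 3.
# Returns a logical vector of length m.
tri_segment_hits <- function(A, B, C, P, Q, eps = 1e-9) {
  a <- as.numeric(A); b <- as.numeric(B); cc <- as.numeric(C)
  ab <- b - a; ac <- cc - a
  nrm <- c(ab[2L] * ac[3L] - ab[3L] * ac[2L],
           ab[3L] * ac[1L] - ab[1L] * ac[3L],
           ab[1L] * ac[2L] - ab[2L] * ac[1L])
  nlen <- sqrt(sum(nrm^2))
  m <- nrow(P)
  scale <- max(sqrt(sum(ab^2)), sqrt(sum(ac^2)))
  if (nlen < 1e-12 * max(scale^2, 1e-12)) {
    return(rep(FALSE, m))              # degenerate triangle
  }
  nh <- nrm / nlen
  dp <- as.numeric((P - matrix(a, m, 3L, byrow = TRUE)) %*% nh)
  dq <- as.numeric((Q - matrix(a, m, 3L, byrow = TRUE)) %*% nh)

  out <- rep(FALSE, m)
  same_side <- (dp > eps & dq > eps) | (dp < -eps & dq < -eps)
  coplanar <- abs(dp) <= eps & abs(dq) <= eps
  crossing <- !same_side & !coplanar

  if (any(crossing)) {
    idx <- which(crossing)
    den <- dp[idx] - dq[idx]
    tt <- ifelse(abs(den) < 1e-300, 0, dp[idx] / den)
    tt <- pmin(1, pmax(0, tt))
    X <- P[idx, , drop = FALSE] +
      tt * (Q[idx, , drop = FALSE] - P[idx, , drop = FALSE])
    out[idx] <- point_in_triangle(X, a, ab, ac, eps)
  }
  if (any(coplanar)) {
    idx <- which(coplanar)
    out[idx] <- coplanar_seg_tri(P[idx, , drop = FALSE],
                                 Q[idx, , drop = FALSE], a, b, cc, nh, eps)
  }
  out
}

# Barycentric point-in-triangle, inclusive with tolerance. X: m x 3 points
# assumed (near) the triangle plane.
point_in_triangle <- function(X, a, ab, ac, eps) {
  m <- nrow(X)
  ap <- X - matrix(a, m, 3L, byrow = TRUE)
  d00 <- sum(ab * ab); d01 <- sum(ab * ac); d11 <- sum(ac * ac)
  d20 <- as.numeric(ap %*% ab); d21 <- as.numeric(ap %*% ac)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  tol <- eps / max(sqrt(den), 1e-300) + 1e-12
  v >= -tol & w >= -tol & (v + w) <= 1 + tol
}

# Coplanar case: 2-D overlap test in the triangle's plane (inclusive).
coplanar_seg_tri <- function(P, Q, a, b, cc, nh, eps) {
  # project onto 2 in-plane axes
  ref <- if (abs(nh[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * nh) * nh; u <- u / sqrt(sum(u^2))
  v <- c(nh[2L] * u[3L] - nh[3L] * u[2L],
         nh[3L] * u[1L] - nh[1L] * u[3L],
         nh[1L] * u[2L] - nh[2L] * u[1L])
  to2d <- function(M) cbind(as.numeric(M %*% u), as.numeric(M %*% v))
  t2 <- to2d(rbind(a, b, cc))
  P2 <- to2d(P); Q2 <- to2d(Q)
  m <- nrow(P2)
  out <- rep(FALSE, m)
  for (i in seq_len(m)) {
    out[i] <- seg_tri_overlap_2d(P2[i, ], Q2[i, ], t2, eps)
  }
  out
}

seg_tri_overlap_2d <- function(p, q, tri, eps) {
  inside <- function(x) {
    s <- numeric(3L)
    for (k in 1:3) {
      a <- tri[k, ]; b <- tri[k %% 3L + 1L, ]
      s[k] <- (b[1L] - a[1L]) * (x[2L] - a[2L]) -
        (b[2L] - a[2L]) * (x[1L] - a[1L])
    }
    all(s >= -eps) || all(s <= eps)
  }
  if (inside(p) || inside(q)) return(TRUE)
  for (k in 1:3) {
    a <- tri[k, ]; b <- tri[k %% 3L + 1L, ]
    if (segs_touch_2d(p, q, a, b, eps)) return(TRUE)
  }
  FALSE
}

segs_touch_2d <- function(p, q, a, b, eps) {
  r <- q - p; s <- b - a
  den <- r[1L] * s[2L] - r[2L] * s[1L]
  if (abs(den) < 1e-14) return(FALSE)   # parallel: endpoint test covers it
  t <- ((a[1L] - p[1L]) * s[2L] - (a[2L] - p[2L]) * s[1L]) / den
  u <- ((a[1L] - p[1L]) * r[2L] - (a[2L] - p[2L]) * r[1L]) / den
  t >= -eps && t <= 1 + eps && u >= -eps && u <= 1 + eps
}

#' Secondary-structure-aware KMT smoothing (the SKMT algorithm)
#'
#' Reduces a labelled C-alpha backbone to a minimal curve that represents
#' each secondary structure element by as few edges as possible while
#' preserving the backbone's essential entanglement. Sections are the maximal
#' same-label runs of the (cleaned) assignment, processed N- to C-terminal;
#' adjacent sections share their boundary point, so the section boundaries
#' are the first residue of each run plus the C-terminal residue. Within a
#' section, repeated left-to-right passes remove the middle point of any
#' three consecutive surviving points whose triangle is not intersected by
#' any edge of the current working curve (the two edges being merged
#' excluded), until a full pass makes no removal. Section boundary residues
#' and chain-break endpoints are never removed, and intersection tests are
#' inclusive of touching ([segment_triangle_intersects()]), so a threading
#' linker always retains the interior points that witness the threading.
#'
#' @param backbone a `labeled_backbone` from [pair_backbone()] (the
#'   assignment is already cleaned there), or a list with `curve` and `ss`.
#' @param eps touching tolerance forwarded to the intersection predicate.
#' @return an object of class `smoothed_curve`: list with `curve` (a
#'   [discrete_curve]), `provenance` (original 1-based residue index of each
#'   surviving point, strictly increasing) and `source`.
#' @export
#' @examples
#' mb <- make_mock_backbone(list(c("H", 12)), seed = 1)
#' sk <- skmt(pair_backbone(mb$curve, mb$ss))
#' skmt_length(sk)   # 2: a single unpierced section reduces to one edge
skmt <- function(backbone, eps = 1e-9) {
  if (!inherits(backbone, "labeled_backbone")) {
    backbone <- pair_backbone(backbone$curve, backbone$ss)
  }
  pts <- curve_points(backbone$curve)
  n <- nrow(pts)
  runs <- backbone$ss$sections

  # section boundaries: first residue of each run, chain-break endpoints,
  # and the C terminus; consecutive boundaries delimit one workable section
  bounds <- sort(unique(c(1L, runs$start, n,
                          backbone$breaks, backbone$breaks + 1L)))
  alive <- rep(TRUE, n)

  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    if (hi - lo < 2L) next
    repeat {
      removed_any <- FALSE
      sec <- which(alive)
      sec <- sec[sec >= lo & sec <= hi]
      k <- 2L
      while (k <= length(sec) - 1L) {
        mid <- sec[k]
        tri <- c(sec[k - 1L], mid, sec[k + 1L])
        if (!triangle_pierced(pts, alive, tri, eps)) {
          alive[mid] <- FALSE
          removed_any <- TRUE
          sec <- sec[-k]               # stay at same k: new triple forms
        } else {
          k <- k + 1L
        }
      }
      if (!removed_any) break
    }
  }

  keep <- which(alive)
  structure(list(curve = discrete_curve(pts[keep, , drop = FALSE],
                                        label = backbone$curve$label),
                 provenance = keep,
                 source = backbone$source),
            class = "smoothed_curve")
}

# Is the triangle over surviving points tri = (i1, i2, i3) pierced by any
# edge of the current working curve other than the two edges being merged?
# The two neighbour edges that end at tri[1] / start at tri[3] inevitably
# touch the triangle at that shared vertex; they are tested with the shared
# vertex trimmed off so only a genuine pass through the triangle counts.
triangle_pierced <- function(pts, alive, tri, eps) {
  surv <- which(alive)
  m <- length(surv)
  if (m < 4L) return(FALSE)
  P <- pts[surv[-m], , drop = FALSE]
  Q <- pts[surv[-1L], , drop = FALSE]
  pos <- match(tri[2L], surv)
  trim <- 1e-6
  if (pos - 2L >= 1L) {                     # edge into tri[1]
    e <- pos - 2L
    Q[e, ] <- P[e, ] + (1 - trim) * (Q[e, ] - P[e, ])
  }
  if (pos + 1L <= m - 1L) {                 # edge out of tri[3]
    e <- pos + 1L
    P[e, ] <- Q[e, ] + (1 - trim) * (P[e, ] - Q[e, ])
  }
  keep_e <- setdiff(seq_len(m - 1L), c(pos - 1L, pos))
  if (length(keep_e) == 0L) return(FALSE)
  any(tri_segment_hits(rbind(pts[tri[1L], ]), rbind(pts[tri[2L], ]),
                       rbind(pts[tri[3L], ]),
                       P[keep_e, , drop = FALSE],
                       Q[keep_e, , drop = FALSE], eps))
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat(sprintf("<smoothed_curve> L = %d points (from %d residues)%s\n",
              skmt_length(x), max(x$provenance),
              if (nzchar(x$source)) paste0(" | ", x$source) else ""))
  invisible(x)
}

#' Length of a smoothed curve
#'
#' The length coordinate used by all entanglement bounds: simply the number
#' of points of the SKMT-smoothed curve, which tracks the number of
#' secondary structure elements rather than the residue count or arclength.
#'
#' @param smoothed a `smoothed_curve` (any curve-like object is accepted).
#' @return integer point count.
#' @export
skmt_length <- function(smoothed) {
  n_points(smoothed)
}

#' Serialize a smoothed curve to JSON
#'
#' @param smoothed a `smoothed_curve`.
#' @return JSON string with `label`, `points`, `provenance`, `skmt_length`.
#' @export
smoothed_to_json <- function(smoothed) {
  jsonlite::toJSON(list(label = smoothed$curve$label,
                        source = smoothed$source,
                        skmt_length = skmt_length(smoothed),
                        provenance = smoothed$provenance,
                        points = unname(curve_points(smoothed))),
                   auto_unbox = TRUE, digits = NA)
}
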