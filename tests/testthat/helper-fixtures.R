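# Fixtures built in code; deterministic given their arguments.

# A labelled backbone whose linker section hooks over the middle of an
# earlier straight strand: the linker's chord from boundary to boundary
# passes under the strand while its path passes over, so replacing the
# linker by a straight edge would drag it through the strand. SKMT must
# retain an interior linker point witnessing the threading. A spacer
# section separates strand and hook so no tested edge shares a vertex with
# the candidate triangles.
threaded_backbone <- function(apex = c(0, 0, 5)) {
  pts <- rbind(
    c(0, -8, 1), c(0, -4, 1), c(0, 0, 1), c(0, 4, 1), c(0, 8, 1),  # E strand
    c(4, 8, 1), c(8, 8, 1), c(8, 4, 1), c(8, 0, 1),                # H spacer
    c(5, 0, 0.5), apex, c(-5, 0, 0.5), c(-6.5, 0, 0.3),            # C hook
    c(-8, 0, 0), c(-11, 0, 0), c(-14, 0, 0), c(-17, 0, 0)          # H2
  )
  labels <- c(rep("E", 5), rep("H", 4), rep("C", 4), rep("H", 4))
  pair_backbone(discrete_curve(pts, label = "threaded fixture"),
                ss_assignment(labels))
}

# Same chain but the hook crosses on the same side as its chord (below the
# strand): no threading, every section collapses to a single edge.
unthreaded_backbone <- function() {
  bb <- threaded_backbone(apex = c(0, 0, -3))
  bb$curve$label <- "unthreaded fixture"
  bb
}

# Pair of curves identical except that a straight strand passes through
# (resp. outside) a near-closed planar loop of the same curve; their writhe
# difference witnesses the +/-2 strand-passage jump. The outside position is
# reached across the solid side of the loop (negative x), away from the
# loop's open gap.
passage_pair <- function(n_loop = 24) {
  ang <- seq(15, 345, length.out = n_loop) * pi / 180
  loop <- cbind(3 * cos(ang), 3 * sin(ang), 0)
  detour <- rbind(c(30, 0, 0), c(30, 0, -30), c(0, 0, -30))
  strand <- function(xs) rbind(c(xs, 0, -8), c(xs, 0, 8))
  make <- function(xs) discrete_curve(rbind(loop, detour, strand(xs)),
                                      label = sprintf("passage xs=%g", xs))
  list(through = make(0), outside = make(-9))
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch).
gauss_legendre_01 <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1L)] <- b
  A[cbind(i + 1L, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  ord <- order(e$values)
  list(x = (e$values[ord] + 1) / 2,
       w = 2 * e$vectors[1L, ord]^2 / 2)
}

# Independent quadrature oracle for the Gauss-integral contribution of an
# edge pair: 2-D Gauss-Legendre quadrature of the integrand
# (t1 x t2) . r / |r|^3 over both segments; returns the Omega/4pi analogue.
quad_gauss_pair <- function(p1, p2, p3, p4, n_nodes = 48L) {
  q <- gauss_legendre_01(n_nodes)
  t1 <- p2 - p1
  t2 <- p4 - p3
  cr <- c(t1[2] * t2[3] - t1[3] * t2[2],
          t1[3] * t2[1] - t1[1] * t2[3],
          t1[1] * t2[2] - t1[2] * t2[1])
  s <- rep(q$x, times = n_nodes)
  t <- rep(q$x, each = n_nodes)
  w <- rep(q$w, times = n_nodes) * rep(q$w, each = n_nodes)
  rx <- p1[1] + s * t1[1] - (p3[1] + t * t2[1])
  ry <- p1[2] + s * t1[2] - (p3[2] + t * t2[2])
  rz <- p1[3] + s * t1[3] - (p3[3] + t * t2[3])
  d3 <- (rx^2 + ry^2 + rz^2)^1.5
  sum(w * (cr[1] * rx + cr[2] * ry + cr[3] * rz) / d3) / (4 * pi)
}

# Random well-separated edge pair (separation keeps the integrand smooth
# enough for the quadrature oracle to be trusted at 1e-6).
random_edge_pair <- function() {
  repeat {
    p <- matrix(stats::runif(12, -2, 2), nrow = 4L, byrow = TRUE)
    mid_gap <- sqrt(sum(((p[1, ] + p[2, ]) / 2 - (p[3, ] + p[4, ]) / 2)^2))
    len1 <- sqrt(sum((p[2, ] - p[1, ])^2))
    len2 <- sqrt(sum((p[4, ] - p[3, ])^2))
    if (mid_gap > 0.8 * (len1 + len2) / 2 + 0.5 && len1 > 0.2 && len2 > 0.2) {
      return(p)
    }
  }
}

# Apply a deterministic rigid motion (rotation + translation) to a curve.
rigid_motion <- function(curve, seed = 42L) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3L)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  shift <- stats::runif(3L, -20, 20)
  pts <- curve_points(curve) %*% R
  discrete_curve(sweep(pts, 2L, shift, "+"),
                 label = paste0(curve$label, " (moved)"))
}

# Minimal PDB ATOM text for a set of C-alpha coordinates.
pdb_text <- function(points, chain = "A", resseq = seq_len(nrow(points)),
                     altloc = rep(" ", nrow(points)), atom = "CA") {
  sprintf("ATOM  %5d  %-3s%sGLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          seq_len(nrow(points)), atom, altloc, chain, resseq,
          points[, 1], points[, 2], points[, 3])
}
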