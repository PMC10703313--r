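#' Discrete space curves
#'
#' A `discrete_curve` is an ordered polygonal chain in three dimensions: the
#' fundamental representation of a protein C-alpha backbone (coordinates in
#' Angstrom) or of any synthetic test curve. The curve is open: the two
#' endpoints are distinct and no closing segment is ever added, reflecting the
#' fact that protein backbones have free termini and are therefore not
#' mathematical knots.
#'
#' @param points numeric matrix with 3 columns (x, y, z) and at least 2 rows,
#'   or an object coercible to one. Consecutive points must be distinct
#'   (separation greater than 1e-9).
#' @param label free-text identifier carried through downstream reports.
#'
#' @return an object of class `discrete_curve`: a list with elements
#'   `points` (n x 3 matrix) and `label`.
#' @export
#' @examples
#' cv <- discrete_curve(cbind(0:5, 0, 0), label = "straight line")
#' n_points(cv)
discrete_curve <- function(points, label = "") {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L) {
    stop("`points` must be a numeric matrix with 3 columns (x, y, z)")
  }
  if (nrow(points) < 2L) {
    stop("a discrete curve needs at least 2 points")
  }
  if (anyNA(points) || any(!is.finite(points))) {
    stop("curve coordinates must be finite")
  }
  steps <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
  if (any(steps <= 1e-9)) {
    stop("consecutive curve points must be separated by more than 1e-9")
  }
  dimnames(points) <- NULL
  structure(list(points = points, label = as.character(label)[1L]),
            class = "discrete_curve")
}

#' @export
print.discrete_curve <- function(x, ...) {
  cat(sprintf("<discrete_curve> %d points%s\n", nrow(x$points),
              if (nzchar(x$label)) paste0(" | ", x$label) else ""))
  invisible(x)
}

#' Number of points of a curve
#'
#' @param curve a [discrete_curve] or [smoothed_curve].
#' @return integer point count.
#' @export
n_points <- function(curve) {
  nrow(curve_points(curve))
}

#' Extract the coordinate matrix of a curve-like object
#'
#' @param curve a [discrete_curve], [smoothed_curve] or bare matrix.
#' @return n x 3 numeric matrix.
#' @export
curve_points <- function(curve) {
  if (inherits(curve, "smoothed_curve")) return(curve$curve$points)
  if (inherits(curve, "discrete_curve")) return(curve$points)
  if (is.matrix(curve) && ncol(curve) == 3L) return(curve)
  stop("not a curve-like object")
}

#' Slice a contiguous subsection of a curve
#'
#' @param curve a [discrete_curve].
#' @param i,n 1-based inclusive first and last point indices.
#' @return a [discrete_curve] over points `i..n`.
#' @export
curve_slice <- function(curve, i, n) {
  pts <- curve_points(curve)
  if (i < 1L || n > nrow(pts) || n <= i) stop("invalid slice indices")
  discrete_curve(pts[i:n, , drop = FALSE],
                 label = sprintf("%s[%d:%d]", curve$label, i, n))
}

#' Mirror a curve through the xy-plane
#'
#' Negating one coordinate reverses the chirality of the curve; writhe is
#' exactly antisymmetric under this operation, which makes mirrored curves a
#' convenient oracle in tests.
#'
#' @param curve a [discrete_curve].
#' @return the mirrored [discrete_curve].
#' @export
mirror_curve <- function(curve) {
  pts <- curve_points(curve)
  pts[, 3L] <- -pts[, 3L]
  discrete_curve(pts, label = paste0(curve$label, " (mirror)"))
}

#' Generate a discrete circular helix
#'
#' Points are placed on the right-handed (for positive pitch) helix
#' `x(t) = (R cos t, R sin t, P t / (2 pi))`. Helices have uniform writhe
#' density, so their cumulative writhe grows linearly with arc position;
#' the per-turn value converges to the closed form of
#' [helix_writhe_per_turn()] as the discretization is refined.
#'
#' @param radius helix radius R in Angstrom (>= 0).
#' @param pitch axial rise P per full turn in Angstrom (>= 0; negative values
#'   give a left-handed helix). `radius` and `pitch` must not both be zero.
#' @param points_per_turn number of points per full turn (>= 3).
#' @param n_turns number of turns (positive real).
#' @return a [discrete_curve] with `ceiling(points_per_turn * n_turns) + 1`
#'   points.
#' @export
#' @examples
#' hx <- make_helix(radius = 7.58, pitch = 5.98, points_per_turn = 50,
#'                  n_turns = 14)
make_helix <- function(radius, pitch, points_per_turn, n_turns) {
  if (radius < 0) stop("`radius` must be >= 0")
  if (points_per_turn < 3) stop("`points_per_turn` must be >= 3")
  if (n_turns <= 0) stop("`n_turns` must be positive")
  if (radius == 0 && pitch == 0) {
    stop("degenerate helix: `radius` and `pitch` must not both be zero")
  }
  n_pts <- as.integer(ceiling(points_per_turn * n_turns)) + 1L
  t <- seq(0, 2 * pi * n_turns, length.out = n_pts)
  pts <- cbind(radius * cos(t), radius * sin(t), pitch * t / (2 * pi))
  discrete_curve(pts, label = sprintf("helix R=%g P=%g turns=%g",
                                      radius, pitch, n_turns))
}

#' Generate an open discretized trefoil
#'
#' Standard (2,3) torus-knot parametrization
#' `x(t) = scale * (sin t + 2 sin 2t, cos t - 2 cos 2t, -sin 3t)` sampled on
#' `t in [0, 2 pi)`. The final closing segment is omitted so the curve is
#' open-ended like a protein backbone; it nevertheless retains the trefoil's
#' essential threading, which curve simplification must preserve.
#'
#' @param n_points number of points (>= 30).
#' @param scale overall size factor in Angstrom.
#' @return a [discrete_curve].
#' @export
make_trefoil <- function(n_points, scale = 1) {
  if (n_points < 30) stop("`n_points` must be >= 30")
  t <- seq(0, 2 * pi, length.out = n_points + 1L)[seq_len(n_points)]
  pts <- scale * cbind(sin(t) + 2 * sin(2 * t),
                       cos(t) - 2 * cos(2 * t),
                       -sin(3 * t))
  discrete_curve(pts, label = sprintf("trefoil n=%d", n_points))
}

#' Generate an equilateral random walk
#'
#' Each step is uniform on the sphere of radius `step`; the walk is the
#' classical null model against which protein entanglement growth is
#' compared (random-walk average crossing number grows like n log n).
#'
#' @param n_points number of points (>= 2).
#' @param step step length in Angstrom.
#' @param seed integer seed; the walk is reproducible given the seed.
#' @return a [discrete_curve].
#' @export
make_random_walk <- function(n_points, step = 1, seed = 1L) {
  if (n_points < 2) stop("`n_points` must be >= 2")
  if (step <= 0) stop("`step` must be positive")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n_steps <- n_points - 1L
  # uniform direction on S^2: normalized standard normals
  dirs <- matrix(stats::rnorm(3L * n_steps), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- rbind(c(0, 0, 0), apply(dirs * step, 2L, cumsum))
  if (n_steps == 1L) pts <- rbind(c(0, 0, 0), dirs * step)
  discrete_curve(pts, label = sprintf("random walk n=%d seed=%d",
                                      n_points, as.integer(seed)))
}

# Set the RNG to a reproducible state and return a restore callback.
# Keeps generator usage insulated from (and non-destructive to) the caller's
# RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate a mock C-alpha backbone with secondary structure labels
#'
#' Builds a synthetic backbone from an ordered run-length specification of
#' secondary structure states: `H` runs follow ideal alpha-helix geometry
#' (radius 2.3 A, rise 1.5 A per residue, 3.6 residues per turn), `E` runs are
#' near-straight zig-zag strands (rise 3.3 A per residue), and `C` (linker)
#' runs are random walks with a maximum turning angle, self-avoiding at a
#' 1 A clash radius. Consecutive C-alpha spacing is 3.8 +/- 0.1 A throughout.
#' These constants are canonical protein geometry; the generator is a fixture
#' factory, not a physical model.
#'
#' @param sse_spec list of `c(label, count)` pairs or a 2-column data frame;
#'   labels in `H`, `E`, `C`; counts >= 1.
#' @param seed integer seed controlling linker geometry and section azimuths.
#' @param max_tries retries allowed when linker self-avoidance fails.
#' @return a list with elements `curve` (a [discrete_curve]) and
#'   `ss` (an [ss_assignment]).
#' @export
#' @examples
#' mb <- make_mock_backbone(list(c("H", 10), c("C", 4), c("E", 6)), seed = 7)
make_mock_backbone <- function(sse_spec, seed = 1L, max_tries = 40L) {
  spec <- normalize_sse_spec(sse_spec)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  for (attempt in seq_len(max_tries)) {
    out <- try(build_mock_backbone_once(spec), silent = TRUE)
    if (!inherits(out, "try-error")) {
      curve <- discrete_curve(out, label = sprintf("mock backbone seed=%d",
                                                   as.integer(seed)))
      labels <- rep(spec$label, spec$count)
      return(list(curve = curve, ss = ss_assignment(labels)))
    }
  }
  stop("could not build a self-avoiding mock backbone after ", max_tries,
       " attempts")
}

normalize_sse_spec <- function(sse_spec) {
  if (is.data.frame(sse_spec)) {
    spec <- data.frame(label = as.character(sse_spec[[1L]]),
                       count = as.integer(sse_spec[[2L]]))
  } else {
    spec <- data.frame(
      label = vapply(sse_spec, function(x) as.character(x[[1L]]), ""),
      count = vapply(sse_spec, function(x) as.integer(x[[2L]]), 0L)
    )
  }
  if (!all(spec$label %in% c("H", "E", "C"))) {
    stop("sse_spec labels must be in {H, E, C}")
  }
  if (any(spec$count < 1L)) stop("sse_spec residue counts must be >= 1")
  spec
}

# One attempt at assembling the mock backbone; stops on a clash.
build_mock_backbone_once <- function(spec) {
  ca_step <- 3.8
  clash <- 1.0
  pts <- matrix(c(0, 0, 0), ncol = 3L)
  dir <- c(1, 0, 0)
  for (s in seq_len(nrow(spec))) {
    lab <- spec$label[s]
    cnt <- spec$count[s]
    if (s == 1L) cnt <- cnt - 1L          # origin counts as first residue
    if (cnt == 0L) next
    new_pts <- switch(lab,
      H = helix_section(pts[nrow(pts), ], dir, cnt),
      E = strand_section(pts[nrow(pts), ], dir, cnt),
      C = linker_section(pts, dir, cnt, ca_step, clash)
    )
    # clash check for the rigid sections (linker checks as it grows)
    if (lab != "C" && nrow(pts) > 2L) {
      dmin <- min(cross_dist(new_pts, pts[seq_len(nrow(pts) - 1L), ,
                                          drop = FALSE]))
      if (dmin < clash) stop("clash")
    }
    dir <- new_pts[nrow(new_pts), ] -
      (if (nrow(new_pts) > 1L) new_pts[nrow(new_pts) - 1L, ] else
         pts[nrow(pts), ])
    dir <- dir / sqrt(sum(dir^2))
    pts <- rbind(pts, new_pts)
  }
  pts
}

cross_dist <- function(a, b) {
  # pairwise distances between row sets a and b
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b) -> d2
  sqrt(pmax(d2, 0))
}

# orthonormal frame with z-axis = dir, random azimuth
section_frame <- function(dir) {
  dir <- dir / sqrt(sum(dir^2))
  ref <- if (abs(dir[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2L] * u[3L] - dir[3L] * u[2L],
         dir[3L] * u[1L] - dir[1L] * u[3L],
         dir[1L] * u[2L] - dir[2L] * u[1L])
  phi <- stats::runif(1L, 0, 2 * pi)
  list(u = cos(phi) * u + sin(phi) * v,
       v = -sin(phi) * u + cos(phi) * v,
       w = dir)
}

helix_section <- function(start, dir, count) {
  fr <- section_frame(dir)
  r <- 2.3; rise <- 1.5; theta <- 2 * pi / 3.6
  k <- seq_len(count)
  loc <- cbind(r * (cos(k * theta) - 1), r * sin(k * theta), rise * k)
  world <- loc %*% rbind(fr$u, fr$v, fr$w)
  sweep(world, 2L, start, "+")
}

strand_section <- function(start, dir, count) {
  fr <- section_frame(dir)
  rise <- 3.3
  amp <- sqrt(3.8^2 - rise^2) / 2       # zig-zag amplitude keeps spacing 3.8
  k <- seq_len(count)
  loc <- cbind(amp * ((-1)^k - 1), 0 * k, rise * k)
  world <- loc %*% rbind(fr$u, fr$v, fr$w)
  sweep(world, 2L, start, "+")
}

linker_section <- function(pts, dir, count, step, clash) {
  out <- matrix(NA_real_, nrow = count, ncol = 3L)
  cur <- pts[nrow(pts), ]
  cdir <- dir
  max_turn <- 75 * pi / 180
  for (i in seq_len(count)) {
    placed <- FALSE
    for (try_i in seq_len(50L)) {
      ang <- stats::runif(1L, 0, max_turn)
      phi <- stats::runif(1L, 0, 2 * pi)
      fr <- section_frame(cdir)
      nd <- sin(ang) * (cos(phi) * fr$u + sin(phi) * fr$v) + cos(ang) * fr$w
      cand <- cur + step * nd
      prev <- rbind(pts, out[seq_len(i - 1L), , drop = FALSE])
      prev <- prev[seq_len(max(0L, nrow(prev) - 1L)), , drop = FALSE]
      if (nrow(prev) == 0L ||
          min(cross_dist(matrix(cand, ncol = 3L), prev)) >= clash) {
        out[i, ] <- cand
        cur <- cand
        cdir <- nd
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("clash")
  }
  out
}

#' Write a curve to whitespace-delimited xyz text
#'
#' One point per line, three coordinates. The inverse of [read_xyz()].
#'
#' @param curve a [discrete_curve] or [smoothed_curve].
#' @param path output file path.
#' @export
write_xyz <- function(curve, path) {
  pts <- curve_points(curve)
  utils::write.table(format(pts, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a curve from whitespace-delimited xyz text
#'
#' @param path file path; each non-empty line holds three numbers.
#' @param label identifier for the resulting curve.
#' @return a [discrete_curve].
#' @export
read_xyz <- function(path, label = basename(path)) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   col.names = c("x", "y", "z")))
  discrete_curve(m, label = label)
}

#' Serialize a curve to JSON
#'
#' @param curve a [discrete_curve].
#' @return a JSON string with fields `label` and `points`.
#' @export
curve_to_json <- function(curve) {
  jsonlite::toJSON(list(label = curve$label,
                        points = unname(curve_points(curve))),
                   auto_unbox = TRUE, digits = NA)
}

#' Deserialize a curve from JSON
#'
#' @param json a JSON string or file path as produced by [curve_to_json()].
#' @return a [discrete_curve].
#' @export
curve_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  discrete_curve(obj$points, label = if (is.null(obj$label)) "" else
    obj$label)
}
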