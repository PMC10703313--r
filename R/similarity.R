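#' Writhe-profile similarity score for a pair of equal-length windows
#'
#' Scores the dissimilarity of two equal-length subsections of two smoothed
#' curves by the mean absolute difference of their nested-subsection writhe
#' values, normalized by the typical empirical linear writhe growth
#' (0.12 per point, doubled to 0.24 to span opposite-sign profiles):
#' \deqn{S = \frac{1}{w-4} \sum_{m=4}^{w} \frac{1}{0.24\,m}
#'   |Wr(C^1_{i,i+m}) - Wr(C^2_{l,l+m})|}
#' A score below 0.05 means the average profile difference is under 5% of
#' the typical observed growth. Since subsection writhe values are only
#' stored for spans of at least 5 points, the `m = 4` term reuses the
#' shortest stored value (span 5) at the same anchor; set `m_start = 5` to
#' begin the sum there instead (the prefactor stays `1/(w-4)` either way,
#' matching the defining formula).
#'
#' @param fp1,fp2 [fingerprint()] objects of the two curves.
#' @param i,l 1-based anchor point index of the window on curve 1 / curve 2.
#' @param w window length in points spanned (window covers points
#'   `i..i+w`); `w >= 10`.
#' @param m_start first nested span in the sum (4 per the defining formula,
#'   with the substitution above, or 5).
#' @return the score (non-negative; 0 for identical profiles).
#' @export
window_score <- function(fp1, i, fp2, l, w, m_start = 4L) {
  if (w < 10L) stop("`w` must be >= 10")
  if (i < 1L || i + w > fp1$n_points) stop("window exceeds curve 1")
  if (l < 1L || l + w > fp2$n_points) stop("window exceeds curve 2")
  ms <- seq.int(m_start, w)
  span <- pmax(ms, 5L)                  # m = 4 -> shortest stored span
  d <- abs(fp1$wr[cbind(i, i + span)] - fp2$wr[cbind(l, l + span)])
  sum(d / (0.24 * ms)) / (w - 4)
}

# All-window scores between two fingerprints for a fixed spanned length w.
# Returns matrix score[i, l] over all valid anchors.
window_score_matrix <- function(fp1, fp2, w, m_start = 4L) {
  n1 <- fp1$n_points - w
  n2 <- fp2$n_points - w
  ms <- seq.int(m_start, w)
  span <- pmax(ms, 5L)
  S <- matrix(0, n1, n2)
  for (k in seq_along(ms)) {
    a <- fp1$wr[cbind(seq_len(n1), seq_len(n1) + span[k])]
    b <- fp2$wr[cbind(seq_len(n2), seq_len(n2) + span[k])]
    S <- S + abs(outer(a, b, "-")) / (0.24 * ms[k])
  }
  S / (w - 4)
}

#' Find the largest mutually similar subsections of two smoothed curves
#'
#' Enumerates all pairs of equal-length windows (length >= `min_len` points
#' spanned) of the two curves, scores them with [window_score()], and
#' greedily selects the largest disjoint set of matches with score below the
#' tolerance `s0`: candidates are taken in order of decreasing window
#' length (ties: lower score, then lower anchors) and accepted only if
#' disjoint from all previously accepted matches on curve 1 and,
#' independently, on curve 2. Coverage is the percentage of each curve's
#' points lying inside its matched ranges.
#'
#' @param c1,c2 `smoothed_curve` (or plain curve) objects, or precomputed
#'   [fingerprint()]s.
#' @param s0 similarity tolerance; 0.05 by default (profiles differing by
#'   less than 5% of typical writhe growth).
#' @param min_len minimum window span in points (default 10, to focus on
#'   large-scale similarity).
#' @param m_start see [window_score()].
#' @return an object of class `match_set`: list with `matches` (data frame
#'   `start1`, `end1`, `start2`, `end2`, `score`), `coverage1`, `coverage2`
#'   (percentages), `s0`, `n1`, `n2`.
#' @export
compare_molecules <- function(c1, c2, s0 = 0.05, min_len = 10L,
                              m_start = 4L) {
  fp1 <- if (inherits(c1, "writhe_fingerprint")) c1 else fingerprint(c1)
  fp2 <- if (inherits(c2, "writhe_fingerprint")) c2 else fingerprint(c2)
  n1 <- fp1$n_points; n2 <- fp2$n_points
  if (n1 < min_len + 1L || n2 < min_len + 1L) {
    stop(sprintf("curves must have at least min_len + 1 = %d points",
                 min_len + 1L))
  }

  # incremental scan over window lengths: the Eq-style sum for span w + 1
  # extends the span-w sum by one term, so all window scores over all
  # anchor pairs cost O(n1 * n2 * w_max) in total
  w_max <- min(n1, n2) - 1L
  na1 <- n1 - min_len; na2 <- n2 - min_len
  cum <- matrix(0, na1, na2)
  ms0 <- seq.int(m_start, min_len)
  for (m in ms0) {
    span <- max(m, 5L)
    a <- fp1$wr[cbind(seq_len(na1), seq_len(na1) + span)]
    b <- fp2$wr[cbind(seq_len(na2), seq_len(na2) + span)]
    cum <- cum + abs(outer(a, b, "-")) / (0.24 * m)
  }
  cand <- list()
  for (w in seq.int(min_len, w_max)) {
    v1 <- n1 - w; v2 <- n2 - w
    S <- cum[seq_len(v1), seq_len(v2), drop = FALSE] / (w - 4)
    hit <- which(S < s0, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      cand[[length(cand) + 1L]] <-
        cbind(w = w, i = hit[, 1L], l = hit[, 2L], score = S[hit])
    }
    if (w < w_max) {
      sp <- w + 1L
      v1n <- n1 - sp; v2n <- n2 - sp
      a <- fp1$wr[cbind(seq_len(v1n), seq_len(v1n) + sp)]
      b <- fp2$wr[cbind(seq_len(v2n), seq_len(v2n) + sp)]
      cum <- cum[seq_len(v1n), seq_len(v2n), drop = FALSE] +
        abs(outer(a, b, "-")) / (0.24 * sp)
    }
  }

  matches <- data.frame(start1 = integer(0), end1 = integer(0),
                        start2 = integer(0), end2 = integer(0),
                        score = numeric(0))
  if (length(cand) > 0L) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, "w"], cm[, "score"], cm[, "i"], cm[, "l"]), ,
             drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; l <- cm[r, "l"]; w <- cm[r, "w"]
      ok1 <- all(i + w < matches$start1 | i > matches$end1)
      ok2 <- all(l + w < matches$start2 | l > matches$end2)
      if (ok1 && ok2) {
        matches <- rbind(matches,
                         data.frame(start1 = i, end1 = i + w,
                                    start2 = l, end2 = l + w,
                                    score = cm[r, "score"]))
      }
    }
  }
  rownames(matches) <- NULL
  structure(list(matches = matches,
                 coverage1 = 100 * sum(matches$end1 - matches$start1 + 1) / n1,
                 coverage2 = 100 * sum(matches$end2 - matches$start2 + 1) / n2,
                 s0 = s0, min_len = as.integer(min_len),
                 n1 = n1, n2 = n2),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> s0 = %g | %d match(es) | coverage %.0f%% / %.0f%%\n",
              x$s0, nrow(x$matches), x$coverage1, x$coverage2))
  if (nrow(x$matches) > 0L) print(x$matches)
  invisible(x)
}

#' Coverage as a function of the similarity tolerance
#'
#' Runs [compare_molecules()] over a grid of tolerances and reports the
#' mutual coverage at each; coverage is non-decreasing in `s0`.
#'
#' @param c1,c2 curves or fingerprints as in [compare_molecules()].
#' @param s0_grid tolerances in (0, 1).
#' @param min_len minimum window span.
#' @return data frame with columns `s0`, `coverage1`, `coverage2`.
#' @export
similarity_curve <- function(c1, c2, s0_grid = seq(0.02, 0.2, by = 0.02),
                             min_len = 10L) {
  if (any(s0_grid <= 0 | s0_grid >= 1)) stop("`s0_grid` values must be in (0, 1)")
  fp1 <- if (inherits(c1, "writhe_fingerprint")) c1 else fingerprint(c1)
  fp2 <- if (inherits(c2, "writhe_fingerprint")) c2 else fingerprint(c2)
  out <- lapply(s0_grid, function(s0) {
    ms <- compare_molecules(fp1, fp2, s0 = s0, min_len = min_len)
    data.frame(s0 = s0, coverage1 = ms$coverage1, coverage2 = ms$coverage2)
  })
  do.call(rbind, out)
}

#' Sweep a query curve against a database of smoothed curves
#'
#' Compares the query with every database entry and reports the entries
#' whose mutual coverage passes the threshold. By default both coverages
#' must pass (globally similar structures); with `one_sided = TRUE` only
#' the query's coverage is thresholded, which finds structures containing
#' the query as a similar subsection.
#'
#' @param query a smoothed curve or fingerprint.
#' @param database list of smoothed curves or fingerprints.
#' @param s0 similarity tolerance.
#' @param min_coverage percentage threshold (e.g. 80).
#' @param one_sided apply the threshold to the query coverage only.
#' @param min_len minimum window span.
#' @return list of hits, each a list with `index` and `match` (the
#'   `match_set`).
#' @export
sweep_database <- function(query, database, s0 = 0.05, min_coverage = 80,
                           one_sided = FALSE, min_len = 10L) {
  fpq <- if (inherits(query, "writhe_fingerprint")) query else
    fingerprint(query)
  hits <- list()
  for (k in seq_along(database)) {
    ms <- compare_molecules(fpq, database[[k]], s0 = s0, min_len = min_len)
    pass <- if (one_sided) ms$coverage1 >= min_coverage else
      ms$coverage1 >= min_coverage && ms$coverage2 >= min_coverage
    if (pass) hits[[length(hits) + 1L]] <- list(index = k, match = ms)
  }
  hits
}
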