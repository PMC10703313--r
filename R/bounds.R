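#' Theoretical knot bound on writhe
#'
#' The thick-knot bound `|Wr| <= (1/4) (L/R)^(4/3)`: longer curves (relative
#' to their thickness) can reach more entangled configurations, so the bound
#' grows super-linearly. Applied empirically to smoothed backbones with the
#' length `L` taken as the SKMT point count and an effective radius
#' `R = 2.7` (the mean minimal C-alpha triplet tube thickness in Angstrom).
#'
#' @param L curve length (SKMT point count), positive.
#' @param R effective radius, positive (default 2.7).
#' @return the bound value.
#' @export
knot_bound <- function(L, R = 2.7) {
  if (any(L <= 0) || any(R <= 0)) stop("`L` and `R` must be positive")
  0.25 * (L / R)^(4 / 3)
}

#' Empirical linear writhe bound
#'
#' Linear growth `0.12 L`: the empirically observed ceiling on writhe for
#' smoothed backbones beyond the small-length regime, set by the writhe
#' density of the dominant super-helical geometry.
#'
#' @param L curve length (SKMT point count).
#' @return `0.12 * L`.
#' @export
linear_wr_bound <- function(L) {
  0.12 * L
}

#' Empirical lower bound on acn
#'
#' The curve `(L / 7.5)^1.6 - 3`, an empirically fitted floor under the
#' average crossing number of realistically folded monomers. Values may be
#' negative for small `L` and are deliberately not clamped: the plausibility
#' comparison in [assess_bounds()] then passes automatically for short
#' curves.
#'
#' @param L curve length (SKMT point count), positive.
#' @return the bound value (possibly negative).
#' @export
acn_lower_bound <- function(L) {
  if (any(L <= 0)) stop("`L` must be positive")
  (L / 7.5)^1.6 - 3
}

#' Random-walk-style acn growth curve
#'
#' `(3/16) L log(L)` (natural logarithm): the length scaling of the average
#' crossing number of equilateral random walks, which also serves as a
#' reasonable empirical upper envelope for smoothed backbones.
#'
#' @param L curve length (SKMT point count), positive.
#' @return the bound value.
#' @export
acn_nlogn_bound <- function(L) {
  if (any(L <= 0)) stop("`L` must be positive")
  (3 / 16) * L * log(L)
}

#' Entanglement bounds report for a smoothed backbone
#'
#' Computes the whole-curve writhe and average crossing number of a smoothed
#' backbone, evaluates all bounds at `L = ` [skmt_length()], and applies the
#' fold-plausibility gate: a structure is flagged implausible (e.g. an
#' unrealistically unfolded model pulled apart by a fitting procedure) when
#' its acn falls below the empirical lower bound — a simple step-function
#' criterion.
#'
#' @param smoothed a `smoothed_curve` (or any curve) with at least 6 points.
#' @param R effective radius for [knot_bound()].
#' @return an object of class `bounds_report`: list with `L`, `wr_value`,
#'   `acn_value`, `knot_bound`, `linear_wr_bound`, `acn_upper` (= L),
#'   `acn_lower`, `acn_nlogn`, and logical flags `within_knot`,
#'   `within_linear`, `plausible`.
#' @export
assess_bounds <- function(smoothed, R = 2.7) {
  L <- skmt_length(smoothed)
  if (L < 6L) stop("smoothed curve too short for a bounds report (need >= 6 points)")
  wr <- writhe(smoothed)
  ac <- acn(smoothed)
  rep <- list(L = L,
              wr_value = wr,
              acn_value = ac,
              knot_bound = knot_bound(L, R),
              linear_wr_bound = linear_wr_bound(L),
              acn_upper = as.numeric(L),
              acn_lower = acn_lower_bound(L),
              acn_nlogn = acn_nlogn_bound(L))
  rep$within_knot <- abs(wr) <= rep$knot_bound
  rep$within_linear <- abs(wr) <= rep$linear_wr_bound
  rep$plausible <- ac >= rep$acn_lower
  structure(rep, class = "bounds_report")
}

#' @export
print.bounds_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<bounds_report> L = %d\n",
    "  Wr = %.3f  (knot bound %.3f%s, linear bound %.3f%s)\n",
    "  acn = %.3f (lower bound %.3f -> %s)\n"),
    x$L, x$wr_value, x$knot_bound,
    if (x$within_knot) ", ok" else ", EXCEEDED",
    x$linear_wr_bound, if (x$within_linear) ", ok" else ", EXCEEDED",
    x$acn_value, x$acn_lower,
    if (x$plausible) "plausible" else "IMPLAUSIBLE"))
  invisible(x)
}
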