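---
title: "Measuring protein entanglement with SKMT smoothing and writhe fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein entanglement with SKMT smoothing and writhe fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skmt)
```

## The problem

A protein's tertiary structure is, at heart, a three-dimensional curve: the
chain of C-alpha atoms. Two structures can be "folded the same way" — the
same threading, the same large-scale coiling — while differing substantially
in the local geometry that alignment-based metrics (RMSD, TM-score) measure.
This package quantifies the *entanglement* of a backbone with quantities that
are invariant to rotation, translation and scale, and stable under the
flexible distortions that proteins undergo in solution: the **writhe** and
the **average crossing number (acn)**, computed on a minimal curve
representation called the **SKMT smoothing**.

## The measures

For a discrete curve $C = \{x_k\}_{k=1}^j$, the writhe of the subsection
$C_i^n$ is the discrete Gauss linking integral of the curve with itself,

$$\mathrm{Wr}(C_i^n) \;=\; 2 \sum_{l=i+1}^{n}\sum_{m=l+1}^{n}
\frac{\Omega_{lm}}{4\pi},$$

where $\Omega_{lm}$ is the signed solid angle subtended by the edge pair
$(x_{l-1},x_l)$, $(x_{m-1},x_m)$ — computed here from the four normalized
cross products of the connecting segments, with arcsine arguments clamped to
$[-1,1]$ and a $10^{-12}$ denominator floor (`omega()`). The writhe equals
the average over all viewing directions of the signed crossing count of the
projected curve; replacing $\Omega$ by $|\Omega|$ gives the acn, the
unsigned analogue and a positive-definite measure of fold complexity. The
package carries an independent Monte-Carlo oracle
(`mc_projection_estimate()`) that literally projects and counts crossings;
the test suite requires the two routes to agree within sampling error.

`fingerprint()` stores $\mathrm{Wr}$ and $\mathrm{acn}$ for *every*
contiguous subsection with $n - i \ge 5$ (shorter spans are not considered
meaningful). The pairwise $\Omega$ matrix is computed once and subsection
sums are obtained by two-dimensional prefix sums, so the full fingerprint
costs the same order, $O(j^2)$, as a single whole-curve writhe.

## SKMT smoothing

Raw C-alpha curves mix two scales: the tight coiling of alpha-helices and
strands, and the tertiary arrangement of those elements. The SKMT algorithm
(`skmt()`) removes the first while provably respecting the second. Given a
secondary structure assignment (PSIPRED `.ss2` or a plain `H`/`E`/`C`
string), the chain is cut into sections at the first residue of each
maximal same-label run (adjacent sections share their boundary point).
Within each section, in N-to-C order, repeated passes delete the middle
point of any three consecutive surviving points whose triangle is not
intersected by any edge of the current working curve — the classical KMT
move, applied *locally*. Because an unpierced triangle can be flattened
without the curve crossing itself, the move is an isotopy: threading of a
linker through the rest of the structure is preserved, while every
unentangled section collapses to a single edge.

Numerical choices, made once and fixed:

* **Inclusive intersection predicate** (`segment_triangle_intersects()`,
  `eps` = 1e-9 Å): exact touching counts as intersection, so removal is
  conservative and a tangency can never destroy entanglement. The two
  working-curve edges that share a vertex with the candidate triangle would
  always "touch" it at that vertex; they are tested with the shared vertex
  trimmed off (10^-6 of the edge length), so only a genuine pass through
  the triangle blocks a removal. A degenerate (collinear) triangle never
  blocks: flattening a straight kink is always safe.
* **Removal order**: left-to-right within a section, repeated to a fixed
  point. The order is not specified by the method itself; this choice is
  deterministic and matches common KMT practice.
* **Checks against the current working curve**, not the original: "any edge
  of the rest of the curve" is evaluated at the moment of removal. The
  alternative (checking against the unsmoothed curve) is stricter but can
  block removals against geometry that no longer exists.
* **Chain breaks** (C-alpha separation above 4.5 Å) are flagged on input,
  never bridged, and act as immovable section boundaries: a fictitious long
  edge would otherwise manufacture spurious crossings.
* **Singleton cleaning** (`clean_ss()`): one-residue helices or strands
  sandwiched between linkers are relabelled `C` before smoothing; they are
  almost always assignment noise and would otherwise inflate the section
  count. A singleton at the chain terminus (one-sided linker) is likewise
  relabelled — the boundary case is not settled usage, and the package
  treats the terminus as linker-like.

The **SKMT length** $L$ is simply the number of points of the smoothed
curve. It tracks the number of secondary structure elements rather than the
residue count or arclength, and it is the length coordinate for all bounds
below.

## Entanglement bounds and the plausibility gate

Four reference curves are provided as functions of $L$:

| bound | form | role |
|---|---|---|
| `knot_bound()` | $\tfrac14 (L/R)^{4/3}$, $R = 2.7$ | theoretical ceiling for tightly knotted curves |
| `linear_wr_bound()` | $0.12\,L$ | empirical writhe ceiling; the growth rate of super-helical folds |
| `acn_lower_bound()` | $(L/7.5)^{1.6} - 3$ | empirical acn floor for realistically folded monomers |
| `acn_nlogn_bound()` | $\tfrac{3}{16} L \ln L$ | random-walk acn scaling (natural log; the base is a package choice, matching the random-walk literature the coefficient comes from) |

The acn floor is reported unclamped when negative, so short curves pass the
gate automatically. `assess_bounds()` evaluates all four at
$L$ = `skmt_length()` and sets `plausible = (acn >= acn_lower_bound(L))`, a
deliberate step function: its intended use is vetoing structure predictions
(for example BioSAXS backbone fits) that match scattering data only by
unrealistically pulling domains apart, which collapses the acn. One known
numerical inconsistency in the source material for this gate — a printed
threshold of 56.8 at 84 secondary structure elements, which the formula
does not reproduce at $L = 84$ — is resolved in favour of the formula; the
gate here is defined by the curve, not by that number.

## Helical subsections

Helices of pitch $P$ and radius $R$ have uniform writhe density with
per-turn value $\mathrm{Wr} = 1 - P/\sqrt{P^2 + 4\pi^2 R^2}$
(`helix_writhe_per_turn()`); at the geometry of a typical super-helical
protein fold ($P = 5.98$, $R = 7.58$) this gives 0.88 per turn. A uniform
coil therefore shows up in the cumulative profile $\mathrm{Wr}(C_1^n)$ as a
straight rise. `find_helical_sections()` detects such stretches: the profile
is LOWESS-smoothed (span fraction 0.1 of the profile, floored at 5 points,
no robustness iterations — the profile has no outliers, only curvature),
every window longer than 20 points is scored by its least-squares slope,
windows with $|$slope$| > 0.05$ (about half the maximal observed growth
rate of 0.12) and sign-consistent smoothed first differences qualify, and
the largest disjoint candidates win (greedy by length, ties by
$|$gradient$|$). Sign consistency is the package's operationalization of
"no change of winding direction": the stated condition in the source
routine is notationally ambiguous (it reads as a ratio of writhes), and
first-difference sign consistency is the reading that actually separates a
helix from the junction of a helix with its mirror image. Both chiralities
are detected and the signed gradient is reported.

A caveat established while validating the generators: an *open* discrete
helix carries an $O(1)$ end-effect deficit in its total writhe, so
total/turns underestimates the closed form by 10–15% at 14 turns. The
per-turn value must be measured as a profile *rise* (or a turn-count
increment), which is what the detection gradient does; the tests assert
convergence of that increment to the closed form as the discretization is
refined.

## Comparing structures

`window_score()` implements the profile-similarity score for two
equal-length windows of two smoothed curves,

$$S = \frac{1}{w-4} \sum_{m=4}^{w} \frac{1}{0.24\,m}
\left|\mathrm{Wr}(C^1_{i,i+m}) - \mathrm{Wr}(C^2_{l,l+m})\right|,$$

the mean absolute writhe difference of nested subsections relative to
twice the typical linear growth rate (0.24 per point spans profiles of
opposite sign). A score below the default tolerance $s_0 = 0.05$ means the
profiles differ by less than 5% of typical growth. Two conventions are
resolved explicitly: the $m = 4$ term refers to a span below the
fingerprint's minimum, so it reuses the shortest stored (5-span) value at
the same anchor — keeping the printed $1/(w-4)$ prefactor meaningful — and
the prefactor itself undercounts the $m = 4..w$ terms by one; both the
literal formula and an `m_start = 5` variant are available, with the
literal form the default. `compare_molecules()` scores all window pairs of
equal length (minimum span 10, to focus on meaningful scales; an
incremental recurrence makes the full scan $O(n_1 n_2 w_{\max})$), then
greedily selects the largest disjoint matches — longest first, ties by
lower score then lower anchors; disjointness is enforced independently on
each curve. "Largest disjoint subsets" has no canonical algorithm;
greedy-longest-first is chosen for determinism and transparency over exact
weighted-interval optimization. Coverage is the percentage of each curve's
points inside its matched ranges; `similarity_curve()` charts it against
$s_0$, and `sweep_database()` applies a both-sided (or optionally
one-sided) coverage threshold across a curve collection.

## Synthetic data

All tests run on generated fixtures; nothing is downloaded:

* `make_helix()` — exact circular helices; the stated world for all
  helical-growth and per-turn claims.
* `make_trefoil()` — the standard open (2,3) torus knot. Its endpoints are
  spatially adjacent, which makes it *shallowly* knotted: whole-curve KMT
  can legally unknot it by slipping strands through the endpoint gap (an
  open-curve isotopy, verified by tracking the virtually-closed curve's
  writhe, which jumps by exactly 2 at the slip). Sectioned SKMT smoothing,
  the operation the package actually performs, preserves its writhe to
  within 0.5 and its crossing-sign pattern, and that is what the tests
  assert.
* `make_random_walk()` — equilateral uniform random walks, the null model:
  ensemble writhe symmetric about zero, acn growing like $n \ln n$.
* `make_mock_backbone()` — SSE-labelled chains with canonical local
  geometry (helix radius 2.3 Å, rise 1.5 Å/residue; strand rise
  3.3 Å/residue; C-alpha spacing 3.8 Å; linkers self-avoiding at 1 Å).
  These constants are textbook protein geometry, not fitted values; the
  generator is a fixture factory for the smoothing contracts, not a
  physical model — no side chains, no Ramachandran sampling, no
  hydrogen-bond structure. Hand-built threaded/unthreaded fixtures in the
  test helpers cover the piercing behaviour that random mocks cannot
  guarantee to produce.

A green test on these fixtures establishes the algorithmic contracts —
collapse of unentangled sections, preservation of threading, agreement of
the two crossing-count routes, bound monotonicity — but not the empirical
percentages reported for real PDB ensembles (99.9% within the knot bound
and so on), which depend on a 10k-structure survey outside this package's
scope.

## Known limitations

* Whole-curve (single-section) KMT on shallowly knotted open curves can
  unknot them through the endpoint gap, as described above; this is a
  property of open-curve topology, not a predicate defect.
* The acn floor and linear writhe ceiling are calibrated for SKMT-scale
  curves ($L \approx$ number of SSEs). Applying `assess_bounds()` to a
  densely sampled raw backbone gives meaningless verdicts: the acn of a
  fine helix grows with discretization while the floor grows with $L$.
* PDB input is deliberately minimal: first model, first alternate location,
  single chain, no mmCIF, no structure repair.
* Similarity coverage is greedy, not optimal; ties between equal-length
  equal-score candidates are broken lexicographically, and a rigid motion
  can flip such ties (coverage is invariant; the particular ranges need
  not be).
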