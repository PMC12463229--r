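---
title: "Evolutionary Khovanov homology: models, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary Khovanov homology: models, conventions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ekhom)
```

## The objects

A **link diagram** is stored combinatorially: each crossing is a row of
four arc identifiers in a fixed rotational convention
(counterclockwise, starting from the incoming under-strand), a
handedness sign (+1 right-handed, −1 left-handed), and optionally a
planar coordinate. Circle components without crossings are carried as a
*free-loop* counter so that smoothing never silently loses a component.
PD codes with arcs numbered consecutively along each oriented component
are parsed with `parse_pd()`, which infers the signs from the flow of
the over-strand relative to the under-strand; a face-count of the
rotation system (`diagram_genus()`) certifies that a code is realizable
in the plane.

A **state** assigns 0 or 1 to every crossing; resolving all crossings
(0-smoothing joins the tuple as (a,b)(c,d), 1-smoothing as (a,d)(b,c))
partitions the arcs into circles. The labelling of the two smoothings
is fixed by the state cube of the complex: for an all-left-handed
trefoil the all-0 state has three circles.

## Polynomials

The Kauffman bracket is computed two independent ways — the closed
state sum over all $2^n$ states, and the skein recursion
$\langle L\rangle = \langle L_0\rangle - q\langle L_1\rangle$ — and the
test suite checks the two code paths agree on every fixture. All
coefficients are exact: polynomial arithmetic only ever adds and
multiplies integers, quarter powers of $t$ are kept on an exact
exponent lattice, and the normalized Jones polynomial is obtained by
exact Laurent division by $q+q^{-1}$. Two printed formulas required a
reading choice: the state-sum weight is taken as $a^{\alpha(s)-\beta(s)}$
(the only reading consistent with the defining skein relation), and the
normalization exponent of the unnormalized Jones polynomial as
$q^{\,n_+-2n_-}$ (the only reading consistent with the worked trefoil
value $(-1)^3q^{-6}\langle L\rangle$). The empty diagram (no crossings,
no loops) is assigned bracket 1 as the empty product; a single free
loop gives $q+q^{-1}$.

## The Khovanov complex

The cochain complex lives on the state cube: a state $s$ with $c(s)$
circles contributes $V^{\otimes c(s)}$ at height $k=\ell(s)-n_-$, each
basis vector labels every circle with $v_\pm$, and its quantum degree
is $(\#v_+-\#v_-)+\ell(s)+n_+-2n_-$. Cube edges carry the Frobenius
merge/split maps with the sign $(-1)^{s_1+\dots+s_{i-1}}$. Circles are
ordered by their smallest arc identifier; circle correspondence along
an edge is matched by arc-set equality, which identifies the merged or
split circles without any geometric reasoning. The complex builder
guards the exponential cube with a crossing bound (default 14; the
test-suite diagrams stay at or below 8, and the seven-crossing fixture
builds in a quarter second).

Homology is computed blockwise per (height, degree), since the
differential preserves the quantum degree. Over a field the dimension
is rank–nullity with exact integer Gaussian elimination (gcd-reduced
rows, smallest-pivot selection); over $\mathbb{F}_p$ elimination is
modular; over $\mathbb{Z}$ the Smith normal form (smallest-entry
pivoting, divisibility repair by row addition) yields free ranks and
invariant factors. Every matrix entry stays far below $2^{53}$, so
double-precision integer arithmetic is exact throughout. The suite
asserts $d\circ d=0$, the categorification identity
$\chi_q(H)=\hat J$, and universal-coefficient consistency between
$\mathbb{Q}$, $\mathbb{F}_2$ and $\mathbb{Z}$ on fixtures and random
diagrams.

## The smoothing operator and the tower

The differential of the cube only flips 0-coordinates to 1, so the face
of the cube pinned to 1 at a crossing is the *unique* face closed under
the differential. The smoothing operator `rho()` therefore always takes
the 1-resolution. This is a deliberate design decision at a point where
the printed sources are internally inconsistent: the textual convention
pairs the operator with the 0-resolution at left-handed crossings and
claims height-preserving inclusions for both handednesses, but the
accompanying inclusion maps pin the state coordinate to 1 and the
worked two-stage trefoil computation (whose smoothed stage is a
negative Hopf link) is only consistent with the closed 1-face. With the
1-face convention the subcomplex property — and hence functoriality of
the whole tower and the interval decomposition of its homology — holds
for *every* sign pattern. The price is bookkeeping: at a left-handed
crossing the inclusion preserves height and shifts degree by −1
(exactly as in the worked example), while at a right-handed crossing it
shifts height by +1 and degree by +2. Bars therefore store their
ambient grading together with per-stage (height, degree) profiles;
`bar_height_at_stage()` and `bar_degree_at_stage()` expose the grading
as seen inside each stage complex, which is what matches the
stage-by-stage homology computed independently from the stage diagrams.

A consequence worth stating plainly: smoothing a right-handed crossing
with the 1-resolution is not orientation-compatible, so the *inherited*
signs of a stage diagram need not normalize its bracket to the isotopy
invariant of the underlying curve. The stage complexes and the
persistence module are unaffected (the bracket itself is an unoriented
quantity), but "this stage is an unknotted link" is asserted in the
tests through the bracket shape $\pm q^j(q+q^{-1})^c$ rather than
through the normalized Jones polynomial.

## Persistence computation

`build_filtered_complex()` assigns each ambient basis vector the stage
at which its state becomes compatible with the smoothed set (1 at every
smoothed crossing). Equal weights are smoothed simultaneously — the
smoothing operator commutes, so the result is order-independent. The
standard persistence column reduction then runs over the increasing
tower (most-smoothed complex first), independently on each
(height, degree) block because all stage complexes share the ambient
grading. Over $\mathbb{Q}$ columns are kept as integer vectors and
eliminated by cross-multiplication with gcd normalization (scaling a
column never changes the pairing); over $\mathbb{F}_2$ elimination is
modular. Zero-length intervals are dropped by default. Bars that
survive to the original diagram are the free part of the
decomposition and are flagged `reaches_original`; their intervals are
conceptually half-infinite toward the un-smoothed end of the parameter
axis. Classes "emerge from later moments and persist toward earlier
moments": the module is contravariant on the threshold axis, and both
stage indices and parameter values are reported.

`ekh_rank(w, a, b)` counts bars alive at both window ends; at $a=b$ it
equals the homology of the $a$-indexed link, and the suite cross-checks
this against the independent stage-diagram computation for every
critical parameter. Rank monotonicity over nested windows (the
persistence-module inequality) is asserted as a property test.

## Filtrations

**Distance-based** (descending): the weight of a crossing is the radius
at which a disk grown around it first meets a disk around another
crossing. The defining formula reads as the nearest-neighbour distance,
but the printed table of critical distances for the bundled
seven-crossing configuration consists of *half* pairwise distances —
disk-touching radii — so the default convention is `half`, with `full`
available; the two differ by an exact factor of two, which is also
asserted. Distances are measured in the projection plane (2D), in the
coordinate units of the input curve. `critical_radii()` reports the
radii at which any two disks first touch (the smallest half pairwise
distances), which is the quantity the printed table tabulates: eight
radii for seven crossings, reproduced by the package to three decimals.

**Unzipping** (ascending): crossings are weighted by their first-visit
label in the Gauss code from a chosen starting crossing and direction,
so the link is unzipped from that point onward. The starting crossing
itself receives label 1 (its under-passage opens the traversal).
Multi-component diagrams are traversed component by component in order
of smallest incident arc identifier.

## The bundled diagrams

`fixture_table()` carries a self-checking knot table: crossingless and
kinked unknots, both Hopf links, both trefoils, a figure-eight, a
seven-crossing diagram, and the four-crossing unlink `example31`. The
searched entries were found by bounded brute force over chord diagrams
and committed as PD codes; their identities are certified internally:
the figure-eight by determinant 5 with writhe 0, the seven-crossing
entry by determinant 19 — which separates it from every other knot
realizable with at most seven alternating crossings — together with a
Jones-polynomial exponent span of $2n+2=16$, which certifies the
diagram reduced and alternating with crossing number exactly 7. Both
identifications are up to mirror image; the committed chirality is the
one found.

`example31` realizes the headline phenomenon: a two-component unlink
diagram (four crossings, trivial Jones) with two weightings. One order
passes only through unlink-type stages — each stage homology sits at a
single height with rank $2^{\#\text{components}}$ — while the other
reaches a genuine negative Hopf link stage, so the (2,2)-evolutionary
homology has total rank 4 split across heights −2 and 0. A search over
single-circle shadows proves the phenomenon *requires* a multi-component
diagram: each 1-smoothing changes the component count by exactly one,
so two smoothings of a knot can never produce a two-component link.

## Projection of space curves

Curves are ordered 3D polylines (at least three points per component,
consecutive points distinct); sampling density is the caller's
responsibility — no resampling or smoothing is performed. Closure joins
the terminal points of each component. Projection scans all pairs of
non-adjacent segments quadratically; the strand with the larger value
along the discarded axis is the over-strand, and handedness comes from
the planar cross product of the oriented strand directions (the xz
plane is viewed from $+y$, where the (x,z) frame is left-handed, so the
sign is flipped there). Regularity failures — near-parallel overlaps,
endpoint hits, equal depths, crossings closer than $10^{-6}$ of the
diagram scale — trigger a seeded random rotation of the whole curve
(default seed 0, initial magnitude $10^{-3}$ rad, doubling across at
most 20 retries) rather than pointwise perturbation, preserving
inter-crossing distances as much as possible. Identical input and seed
give byte-identical diagrams.

`synthetic_curve()` supplies the test geometry: `torus(p, q)` samples
torus knots (the (2,3) curve projects to a three-crossing trefoil
diagram whose unnormalized Jones matches the trefoil fixture —
verified through the bracket, not assumed), `circle` gives unknots, and
`random_walk` draws a seeded random Fourier loop — smooth, closed and
reproducible. These curves emulate clean backbone geometry; they do not
emulate noisy coordinates, near-degenerate projections of dense
helices, or chain breaks, so passing tests certify the combinatorial
and algebraic machinery rather than robustness to measurement noise.
Real structures enter through `read_xyz()` (CSV) and `read_backbone()`
(minimal PDB reader restricted to ATOM records, P or CA atoms, record
order, optional chain filter); reproducing any particular published
molecular barcode additionally requires that source's closure,
projection plane, and crossing-numbering conventions, which is why the
pipeline is exercised as a smoke test on synthetic curves instead.

## Problem sizes and limitations

The state cube is exponential: the complex builder is comfortable to 8
crossings in tests (a 7-crossing alternating diagram builds in ~0.3 s
and its integral homology in ~0.4 s) and guarded at 14 by default.
Property tests use 100 random planar diagrams of up to 6 crossings for
the differential and categorification identities and random weighted
diagrams of up to 5 crossings for barcode consistency; these sizes
exercise every code path while keeping the default suite around a
minute. Persistence is over a field ($\mathbb{Q}$ default,
$\mathbb{F}_2$ optional); integral persistence has no interval
decomposition and is out of scope, as are cobordism-induced maps
between different links, reduced or deformed homology theories, zigzag
and multiparameter persistence, and reconstructing a diagram from a
Gauss code.
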