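---
title: "Bi-objective protein de-immunization: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-objective protein de-immunization: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deimmunize)
```

# The problem

Therapeutic proteins can provoke anti-drug antibodies when peptides derived
from them are presented on HLA class II molecules and recognized by CD4+
T cells. De-immunization replaces a small number of residues so that fewer
peptides bind the HLA molecules prevalent in the target patient
population — without destroying the protein's fold and function. This
package treats the task as an exact bi-objective combinatorial
optimization: over all mutants $S'$ of a wild type $S$ with at most $k$
substitutions drawn from per-position candidate sets $M_i$, it minimizes
simultaneously

* $z_1 = I(S')$, a population-weighted immunogenicity score, and
* $z_2 = -E(S')$, the negative evolutionary statistical energy,

and returns the complete Pareto front: every design for which no other
design is at least as good in both objectives and strictly better in one.
Returning the front rather than a single compromise leaves the
immunogenicity/fitness trade-off to the bioengineer, who can synthesize a
handful of designs along it.

# The immunogenicity objective

Each HLA allele $h$ carries a position-specific scoring matrix
$\Phi_h(j, a)$ over a binding core of length $e_n$ (nine for HLA class II);
a peptide scores $\sum_j \Phi_h(j, p_j)$. The package z-score normalizes
each allele's matrix by pooling all its cells — scores of different alleles
then live on one scale — and transforms any previously set threshold
consistently ($\tau \to (\tau - e_n\mu)/\sigma$), which preserves every
epitope call exactly (`znormalize()` and a numerically checked identity in
the test suite).

A binding threshold $\tau_h$ is calibrated per allele as a percentile of a
score distribution (`binding_threshold()`). Two backgrounds are supported:
the empirical distribution over all windows of a context protein (the
default, reproducing a whole-protein epitope screen at, say, the 95th
percentile), and a seeded uniform-random-peptide universe. Which one a
published threshold corresponds to is rarely stated, so the choice is an
explicit, recorded argument rather than a hidden constant.

The score of a sequence for a population $H$ with allele frequencies $p_h$
is a hinge sum over **all** full-length windows ($n - e_n + 1$ of them):

$$ I(S) \;=\; \sum_{h \in H} p_h \sum_{i=1}^{n-e_n+1}
   \max\!\bigl(0,\; \textstyle\sum_{j=0}^{e_n-1}
   \Phi_h(j{+}1, S_{i+j}) - \tau_h\bigr). $$

Only the above-threshold part of a window contributes, each (window,
allele) pair counts independently (a peptide binding two alleles counts
twice), and an allele's contribution is proportional to its population
frequency — designing for Western Europe and for East Asia are genuinely
different problems. When a design region is a sub-range of a larger
domain, windows straddling the boundary are scored in the context of the
full sequence: a mutation near the edge can create or destroy epitopes
that extend outside the region, and the objective must see that.

The hinge makes the objective piecewise linear, hence representable in a
mixed-integer program; this is also why the binding model must stay
linear. Nonlinear affinity predictors (neural networks) cannot be embedded
without giving up proven optimality, which is the point of the exercise.

# The fitness objective

Protein fitness is approximated by the statistical energy of a pairwise
maximum-entropy (Potts) model of the protein family,

$$ E(X) \;=\; \sum_i h_i(X_i) \;+\; \sum_{i<j} J_{ij}(X_i, X_j), $$

with $P(X) \propto e^{E(X)}$ in this package's sign convention: higher
energy means a more probable, fitter sequence, and the second design
objective is the minimization of $-E$. The convention is stated here
because the literature uses both signs; `build_instance()` exposes
`fitness_sense` to flip it, but every report written by the package states
its convention in a header line instead of assuming the reader's. Energy
*differences* between sequences — all that matters for design — are
invariant under gauge transformations of the parameters, which the test
suite verifies numerically.

## Alignment preparation

The model is inferred from a family multiple sequence alignment anchored
on the target: focus columns are those where the target record carries a
residue, and focus position $i$ is reported as protein residue
$i + \text{offset} - 1$. Sequences with $\geq 70\%$ gaps and columns with
$> 50\%$ gaps are excluded; the two rules are iterated to a fixed point so
that filtering is idempotent and both postconditions hold at once (a
single pass can leave a row whose gap fraction rises above threshold after
columns are removed). The target record is always retained.

Phylogenetic redundancy is corrected by inverse cluster-size weights at a
90% identity threshold ($\theta = 0.9$): a sequence's weight is one over
the number of alignment members within $\theta$ identity of it, and
$M_\mathrm{eff} = \sum_s w_s$. Identity is computed over the focus columns
only, with gaps counting as mismatches — only modeled positions should
drive the weights. Duplicating an alignment halves every weight and leaves
$M_\mathrm{eff}$ unchanged, a property test in the suite.

Candidate substitution sets come from conservation: at mutable positions,
$M_i = \{a : f_i(a) \geq \zeta\} \cup \{S_i\}$ with $f_i$ the weighted
residue frequencies after dropping the gap state and renormalizing
(designs cannot contain gaps; during inference the gap is kept as a 21st
state). Rarely observed residues are presumed deleterious, so $\zeta$
directly controls the conservatism of the search space; it shrinks $M_i$
monotonically.

## Inference

`infer_plm()` minimizes the weighted negative log-pseudo-likelihood — the
sum over sites of the conditional multinomial likelihood of each residue
given the rest of its sequence, with a single symmetric coupling set
shared between the two conditionals of each pair — under l2 penalties, by
L-BFGS-B on the full parameter vector. Defaults are $\lambda_h = 0.01$ and
$\lambda_J = 0.01\,M_\mathrm{eff}$, the standard strength when the
likelihood is a weighted sum rather than an average. Convergence is
declared at a gradient infinity norm below `tol` (default $10^{-4}$); a
non-converged fit is returned with its final gradient norm and a warning,
never silently.

Two simulation-based properties pin the implementation down. Sequences
Gibbs-sampled from a known model ($L = 10$, $q = 4$, 5000 training
sequences) yield a refit whose energies correlate with the true model's at
$r \geq 0.9$ on held-out samples. And i.i.d. sequences from a field-only
model leave only shrunken sampling noise in the couplings: at these sizes
the regularized optimum has $\max|J| \approx 0.13$–$0.15$ (confirmed
against an independent ridge-multinomial fit of the same conditionals), an
order of magnitude below the $\approx 0.8$ coupling magnitudes inferred
when real couplings exist. That residual scales as the ratio of sampling
noise to penalized curvature, $\sim \mathrm{sd}(\nabla)/(\mathcal{I} +
2\lambda)$, and is insensitive to the generator's field scale; driving it
below these values requires either more data or materially stronger
regularization than the default.

## Evolutionary couplings

For model-quality assessment, `ec_scores()` reports per-pair coupling
strengths: each $J_{ij}$ block is double-centred over the non-gap states
(zero-sum gauge; the gap state is excluded as standard) and reduced to its
Frobenius norm, then corrected by the average product correction
$\mathrm{apc}(i,j) = \mathrm{fn}(i,j) - \bar f_i \bar f_j / \bar f$ with
means over off-diagonal entries — removing the shared background that
finite sampling and phylogeny induce. `ec_enrichment()` sums a position's
corrected scores over partners (optionally only the top-$N$ pairs, since
both conventions are used in practice) as a marker of structurally and
functionally constrained positions. `top_ecs()` calls significant
long-range pairs (sequence separation $\geq 5$ by default; "long-range" is
conventionally left unquantified, so the separation is an argument) by
fitting a Gaussian background plus lognormal tail mixture to the score
distribution with EM — moment-initialized at the 90th percentile — and
returning pairs with posterior tail membership $\geq 0.9$. Negative scores
have zero lognormal density and automatically belong to the background. If
EM degenerates (component collapse, no positive scores) the call falls
back to the top-$L$ pairs and flags the result rather than failing.

# The mixed-integer encoding

`build_instance()` writes the design problem as a mixed binary/continuous
linear program, borrowing the variable encoding of side-chain placement
ILPs. A binary $x_{i,a}$ selects residue $a \in M_i$ at position $i$;
binary $w_{i,j,a,b}$ select residue pairs and carry the couplings; the
constraints are

* **C1** $\sum_{a \in M_i} x_{i,a} = 1$ for every position $i \in
  \{1..n\}$ (one residue per position),
* **C2/C3** $\sum_b w_{i,j,a,b} = x_{i,a}$ and $\sum_a w_{i,j,a,b} =
  x_{j,b}$ (pair selection consistent with the singles; at integrality
  this forces $w_{i,j,a,b} = x_{i,a} x_{j,b}$),
* **C4** $\sum_i (1 - x_{i,W_i}) \leq k$ (mutation budget).

The immunogenicity objective is linearized with one continuous slack per
(allele, window): $y_{h,i} \geq \sum \Phi x - \tau_h$, $y \geq 0$, and
$z_1 = \sum_h p_h \sum_i y_{h,i}$. Under minimization of $z_1$ the slacks
sit exactly on the hinge, so the linearization is exact; when $z_1$
appears only as a rectangle constraint the slacks are free to inflate,
which is why decoded solutions always re-derive both objectives from the
$x$ assignment and never read them from slacks. `decode()` recomputes
$z_1$ via the plain sliding-window scorer and $z_2$ via the full Potts
energy and raises beyond $10^{-6}$ — every solver answer is
objective-verified against the module that defined the objective.

Positions with a singleton $M_i$ stay out of the combinatorics: pairs of
two immutable positions fold into a constant added to $z_2$ (so reported
values are full-sequence energies comparable across designs), and windows
containing no mutable position fold into a constant in $z_1$. The
classical sign-split relaxation of C2/C3 (inequality rows chosen by the
sign of each $w$'s objective coefficient) is available behind
`relaxed_linking`; it preserves optimal values in single-objective use but
is not safe under arbitrary box constraints, so exact equalities are the
default. The full symbolic program can be exported in LP text format
(`write_lp()`) for inspection with external solvers.

## The solver backend

Proven-optimal single-objective solves are the primitive everything else
builds on. The package ships a native exact branch-and-bound backend
(compiled, `solve_single()`): depth-first search over positions exploiting
the one-hot structure of C1 and the budget C4 directly, with admissible
bounds from per-position decomposition — fields plus couplings to assigned
positions minimized per candidate residue, unassigned pair couplings
bounded by their block minima/maxima, and window hinges bounded by slot
minima/maxima — pruned against both the incumbent and the objective-space
rectangle. Because every bound is admissible, search exhausts the space
and returned solutions are proven optimal; an empty rectangle returns an
explicit infeasible status. The backend is pluggable through S3: the test
suite exercises the Pareto logic against an enumerated point-set backend
(`enum_instance()`) whose ground truth is visible by eye.

# Exact bi-objective solving

A nondominated point inside a rectangle
$R(\mathbf{z}^1, \mathbf{z}^2)$ of objective space is found by
lexicographic minimization (`lexmin()`): minimize the primary objective
within the rectangle, then minimize the secondary subject to the primary
staying within $\delta$ of its optimum. The front's endpoints
$\mathbf{z}^T$ (immunogenicity-first) and $\mathbf{z}^B$ (fitness-first)
come from two independent unbounded lexmins (`compute_boundaries()`),
which may run concurrently.

**Phase 1** seeds the search with up to $m$ evenly spaced points: slice
boundaries $\tau_i = z_1^T + i\,(z_1^B - z_1^T)/m$ partition the $z_1$
range, and slice $i$ solves a z2-first lexmin restricted to $z_1 \leq
\tau_i$. The orientation of that constraint matters more than it looks.
Restricting $z_1$ from *below* and minimizing $z_1$ first — the natural
mirror image — can return a point that is globally dominated by a design
left of the slice boundary, and the phase-2 rectangles spanned between
adjacent points can then never recover the missed dominator (the package's
randomized-toy harness exhibits concrete instances). With the upper-bound
orientation any dominator of a returned point would itself satisfy the
slice constraint and beat the lexicographic optimum, so every phase-1
point is provably on the front; phase 1 always contains $\mathbf{z}^B$
and is verified to be a subset of the final front.

**Phase 2** refines by rectangle splitting (`split_rectangle()`). The
rectangle between adjacent known points $\mathbf{z}^i, \mathbf{z}^j$ is
halved at the mean $z_2$; the bottom half is searched z1-first, and the
top half — truncated at $\bar z_1 - \varepsilon$ left of the bottom
discovery — z2-first. Rediscovering a corner proves its half empty; new
points spawn child rectangles with their adjacent neighbors, and the area
between a top and bottom discovery needs no further search because
anything in it would be dominated by one of them. The recursion terminates
when every rectangle is closed, and a derived guard on the number of
lexicographic solves ($\leq 3|\mathrm{front}| + 2m + 2$) is asserted on
every toy as an efficiency regression check.

Slices and rectangles are independent work items: `solve_pareto()`
processes them in deterministic rounds, merging results under a dominance
filter with duplicates removed at tolerance $\delta$, so the front is
identical for any worker count (asserted for 1 vs 2 and 1 vs 4 workers).
Defaults $\varepsilon = \delta = 10^{-6}$: both objectives take finitely
many values over binary assignments, but their granularity is
data-dependent, so front points closer than these tolerances in an
objective may merge — the documented failure mode — and both are
configurable. `m` defaults to the worker count, matching the intent of
even initial load.

`brute_force_pareto()` is the independent oracle: exhaustive enumeration
of all mutants within the budget, objectives evaluated directly on plain
sequences, dominance filtered. The central correctness statement of the
package is set-identity of `solve_pareto()` with this oracle on randomized
toy problems, which the acceptance suite checks on 25 seeded instances.

# Synthetic data: what it emulates and what it does not

All tests run on generated data (`random_pssm()`, `random_potts()`,
`gibbs_sample()`, `make_toy_problem()`); every generator is a pure
function of its seed (R's default Mersenne-Twister), and none disturbs the
caller's RNG stream. The toy conditions mirror the desk-scale study:
sequences of length 6–10 over 3–4 letter alphabets, candidate sets of at
most 4 residues, budgets $k \leq 3$, 2–3 synthetic alleles with short
cores ($e_n = 3$–5), chosen so the full mutant space (at most a few
thousand candidates) is enumerable by the oracle. Toy allele thresholds
use the median (50th percentile) of the wild type's window scores rather
than the 95th used for real screens: on an 8-residue toy with ~5 windows a
95th-percentile threshold would leave almost every mutant at $z_1 = 0$ and
collapse the front to a single point, whereas the median keeps roughly
half the windows immunogenic and forces a genuine trade-off. Allele
frequencies total 0.9, representing the realistic situation of a
population imperfectly covered by the modeled alleles.

`gibbs_sample()` runs independent single-site Gibbs chains — by default
one chain per requested sequence, vectorized across chains — each burned
in and thinned per its arguments; a zero-coupling model reproduces the
analytic softmax marginals to 0.02 at $n = 10^4$, and a ferromagnetic pair
covaries with the right sign. What the generators do **not** emulate:
phylogenetic correlation between sequences (samples are exchangeable, so
reweighting is exercised mechanically but not under realistic tree
structure), alignment errors and indel patterns, and real HLA binding
chemistry (matrices are Gaussian noise, optionally with a planted binder).
Passing tests therefore certify the algorithms and their contracts, not
the biological fidelity of any particular model input; full-scale use
requires a curated family alignment and published allele matrices, for
which the readers and the 157-residue-scale code paths are in place.

# Numerical choices and degenerate inputs

* Optimality and box tolerances in the backend: $10^{-9}$ feasibility slack
  on rectangle membership, $10^{-12}$ incumbent slack; decoded-objective
  verification at $10^{-6}$; serialization at full 17-digit precision so
  model round trips are exact.
* Ties in lexmin stage 1 are resolved by stage 2; remaining exact ties are
  broken deterministically by search order, so repeated runs and different
  worker counts agree bit-for-bit on the objective vectors.
* Degenerate cases handled explicitly: $k = 0$ or all-singleton $M_i$
  yield the single wild-type point; a degenerate rectangle closes without
  solving; empty populations score zero immunogenicity; a zero-variance
  allele matrix refuses normalization; EM component collapse falls back to
  a rank cutoff with a flag; an all-gap column contributes only the wild
  type to $M_i$.
* The one-residue-per-position constraint is validated on decode, so a
  backend returning an inconsistent assignment fails loudly.

# Problem sizes in the shipped tests

The default suite and the acceptance script are sized for a single CPU:
25 toy design problems (front sizes typically 2–8, brute-force spaces of
$10^2$–$10^4$ candidates), one inference recovery at $L = 10$, $q = 4$
with 5000 training and 500 held-out sequences, and a 1000-peptide
normalization identity. The whole acceptance script runs in well under a
minute; these sizes were chosen as the smallest at which each property is
sharp (recovery correlations stabilize above $n \approx 2000$; front
equivalence is non-trivial once fronts exceed a few points).

# Known limitations

* The immunogenicity model is a linear PSSM with a hard percentile
  threshold; peptide processing, flanking effects and nonlinear binding
  models are out of scope by construction.
* The fitness proxy is a family-level statistical energy: it cannot see
  constraints absent from the alignment (e.g. a binding partner not shared
  by homologs), and alignments of low diversity give weak models — check
  $M_\mathrm{eff}/L$ and the EC quality calls before trusting designs.
* The native backend's bounds exploit the design ILP's structure; it is
  not a general MILP solver, and very large mutable regions with rich
  candidate sets will grow the search. The backend contract is pluggable
  precisely so an external MILP library can stand in where available.
* Front values closer than $\varepsilon$ may merge (see above); lower the
  tolerances for objectives with very fine granularity.
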